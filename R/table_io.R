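#' Read a peptide quantification table
#'
#' Parses a tab-delimited peptide intensity table into a peptide table:
#' a `data.frame` with columns `peptide`, `protein`, one numeric column
#' per MS run, and the run identifiers stored in `attr(x, "runs")`.
#'
#' Two dialects are supported. The `"generic"` dialect has columns
#' `peptide`, `protein`, then one column per run (column name = run id).
#' The `"maxquant"` dialect is the MaxQuant `peptides.txt` layout:
#' `Sequence`, `Proteins`, and one `Intensity <run>` column per run
#' (the run id is the part after `"Intensity "`). All other MaxQuant
#' columns are ignored.
#'
#' Empty intensity cells are read as 0 (the MaxQuant convention: 0 means
#' not detected); any other non-numeric text is an error, as is a
#' negative intensity or a duplicated peptide sequence.
#'
#' @param path path to a tab-delimited file.
#' @param dialect `"generic"` or `"maxquant"`.
#' @return A `data.frame` of class `"rbrid_peptides"` with character
#'   columns `peptide` and `protein` (multiple protein ids separated by
#'   `";"`) and one non-negative numeric column per run; run ids in
#'   `attr(, "runs")`.
#' @seealso [write_peptide_table()], [filter_contaminants()]
#' @export
read_peptide_table <- function(path, dialect = c("generic", "maxquant")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peptide table not found: ", path, call. = FALSE)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, stringsAsFactors = FALSE)
  if (dialect == "generic") {
    seq_col <- "peptide"; prot_col <- "protein"
    for (col in c(seq_col, prot_col)) {
      if (!col %in% names(raw)) {
        stop(sprintf("peptide table is missing mandatory column '%s'", col),
             call. = FALSE)
      }
    }
    run_cols <- setdiff(names(raw), c(seq_col, prot_col))
    runs <- run_cols
  } else {
    seq_col <- "Sequence"; prot_col <- "Proteins"
    for (col in c(seq_col, prot_col)) {
      if (!col %in% names(raw)) {
        stop(sprintf("peptide table is missing mandatory column '%s'", col),
             call. = FALSE)
      }
    }
    run_cols <- grep("^Intensity .+", names(raw), value = TRUE)
    if (length(run_cols) == 0L) {
      stop("peptide table is missing mandatory 'Intensity <run>' columns",
           call. = FALSE)
    }
    runs <- sub("^Intensity ", "", run_cols)
  }
  if (nrow(raw) == 0L) stop("peptide table has no rows", call. = FALSE)

  peptide <- toupper(raw[[seq_col]])
  dup <- duplicated(peptide)
  if (any(dup)) {
    stop(sprintf(
      "duplicate peptide rows (peptides must be unique per table): %s",
      paste(unique(peptide[dup]), collapse = ", ")
    ), call. = FALSE)
  }
  for (i in seq_along(peptide)) {
    if (!nzchar(peptide[i])) stop("empty peptide sequence at row ", i, call. = FALSE)
    validate_aa_string(peptide[i], sprintf("peptide '%s' (row %d)", peptide[i], i))
  }

  intens <- matrix(0, nrow = nrow(raw), ncol = length(runs),
                   dimnames = list(NULL, runs))
  for (k in seq_along(run_cols)) {
    cell <- trimws(raw[[run_cols[k]]])
    val <- rep(0, length(cell))
    filled <- nzchar(cell)
    parsed <- suppressWarnings(as.numeric(cell[filled]))
    if (anyNA(parsed)) {
      bad_row <- which(filled)[which(is.na(parsed))[1L]]
      stop(sprintf("malformed intensity '%s' in column '%s', row %d",
                   cell[filled][which(is.na(parsed))[1L]], run_cols[k], bad_row),
           call. = FALSE)
    }
    val[filled] <- parsed
    neg <- which(val < 0)
    if (length(neg) > 0L) {
      stop(sprintf("negative intensity in column '%s', row %d",
                   run_cols[k], neg[1L]), call. = FALSE)
    }
    intens[, k] <- val
  }

  out <- data.frame(peptide = peptide, protein = raw[[prot_col]],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(intens, check.names = FALSE))
  new_peptide_table(out, runs)
}

new_peptide_table <- function(df, runs) {
  stopifnot(all(c("peptide", "protein") %in% names(df)), all(runs %in% names(df)))
  attr(df, "runs") <- runs
  class(df) <- c("rbrid_peptides", "data.frame")
  df
}

#' Run identifiers of a peptide table
#' @param x a peptide table from [read_peptide_table()].
#' @return Character vector of run ids (intensity column names).
#' @export
peptide_runs <- function(x) {
  runs <- attr(x, "runs")
  if (is.null(runs)) stop("not a peptide table (no 'runs' attribute)", call. = FALSE)
  runs
}

#' Write a peptide table in the generic dialect
#'
#' Emits the `peptide` / `protein` / per-run layout that
#' [read_peptide_table()] reads back; the round trip preserves records.
#'
#' @param x a peptide table.
#' @param path output path.
#' @export
write_peptide_table <- function(x, path) {
  runs <- peptide_runs(x)
  df <- as.data.frame(x)[, c("peptide", "protein", runs)]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove suspected contaminants from a peptide table
#'
#' Drops records whose protein identifiers contain any of the given
#' substrings. The defaults mirror MaxQuant's tagging of its contaminant
#' and decoy database entries (`CON__`, `REV__`).
#'
#' @param x a peptide table.
#' @param patterns non-empty character vector of identifier substrings.
#' @return The filtered peptide table; the number of removed records is
#'   reported via `message()`. Idempotent.
#' @export
filter_contaminants <- function(x, patterns = c("CON__", "REV__")) {
  if (length(patterns) == 0L) stop("`patterns` must be non-empty", call. = FALSE)
  runs <- peptide_runs(x)
  hit <- rep(FALSE, nrow(x))
  for (p in patterns) hit <- hit | grepl(p, x$protein, fixed = TRUE)
  message(sprintf("filter_contaminants: removed %d of %d records",
                  sum(hit), nrow(x)))
  out <- x[!hit, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all records removed as contaminants", call. = FALSE)
  new_peptide_table(out, runs)
}

#' Read the experiment design
#'
#' The design maps each MS run to its condition (+4SU crosslinked or
#' -4SU control), biological replicate, and instrument batch. The file
#' is a TSV with columns `run_id`, `condition`, `replicate`, `batch`.
#' Condition values `+4SU`/`-4SU` (also accepted: `crosslinked`,
#' `control`, `plus`, `minus`, case-insensitively) are normalized to
#' `"+4SU"` and `"-4SU"`.
#'
#' @param path path to the design TSV.
#' @return A `data.frame` of class `"rbrid_design"` with columns
#'   `run_id`, `condition` (`"+4SU"`/`"-4SU"`), `replicate`, `batch`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("run_id", "condition", "replicate", "batch")) {
    if (!col %in% names(df)) {
      stop(sprintf("design is missing mandatory column '%s'", col), call. = FALSE)
    }
  }
  df$condition <- normalize_condition(df$condition)
  df$replicate <- as.integer(df$replicate)
  df$batch <- as.character(df$batch)
  as_design(df[, c("run_id", "condition", "replicate", "batch")])
}

normalize_condition <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("−", "-", key)  # unicode minus
  plus <- key %in% c("+4su", "4su", "crosslinked", "plus", "xl")
  minus <- key %in% c("-4su", "no4su", "control", "minus", "ctrl")
  if (any(!plus & !minus)) {
    stop("unrecognized condition value(s): ",
         paste(unique(x[!plus & !minus]), collapse = ", "), call. = FALSE)
  }
  ifelse(plus, "+4SU", "-4SU")
}

as_design <- function(df) {
  if (anyDuplicated(df$run_id)) stop("design run_ids must be unique", call. = FALSE)
  n_by_cond <- table(df$condition)
  if (!all(c("+4SU", "-4SU") %in% names(n_by_cond)) || any(n_by_cond < 2L)) {
    stop("design needs at least 2 runs per condition (t test needs >= 2 per group)",
         call. = FALSE)
  }
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  class(df) <- c("rbrid_design", "data.frame")
  df
}

#' @export
print.rbrid_design <- function(x, ...) {
  cat(sprintf("Experiment design: %d runs (%d +4SU, %d -4SU), %d batch(es)\n",
              nrow(x), sum(x$condition == "+4SU"), sum(x$condition == "-4SU"),
              length(unique(x$batch))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Reads a protein FASTA, uppercases sequences, strips a trailing `*`
#' stop character, and validates the 20-letter amino-acid alphabet
#' (ambiguity codes B/Z/X/U are rejected: they cannot be located in a
#' 20-letter protein string unambiguously). The accession is the header
#' token before the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of residue strings (names are
#'   accessions; 1-based inclusive coordinates are used throughout).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for ", names(seqs)[i], call. = FALSE)
    validate_aa_string(seqs[i], sprintf("protein '%s'", names(seqs)[i]))
  }
  seqs
}
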