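#' Locate a peptide within a protein sequence
#'
#' Exact substring search reporting every occurrence, including
#' overlapping ones. Matching is done on uppercased sequences; I and L
#' are distinct. A peptide longer than the protein (or absent from it)
#' yields zero intervals with a warning, not an error — in real tables
#' many peptides belong to other proteins or isoforms.
#'
#' @param peptide_seq peptide string.
#' @param protein protein residue string (or a length-1 named element of
#'   [read_protein_fasta()] output).
#' @return A `data.frame` with columns `start`, `end` (1-based
#'   inclusive) and attribute `"multimapped"` (more than one interval).
#' @export
locate_peptide <- function(peptide_seq, protein) {
  pep <- toupper(peptide_seq)
  prot <- toupper(protein[[1]])
  if (nchar(pep) > nchar(prot)) {
    warning(sprintf("peptide '%s' is longer than the protein", pep), call. = FALSE)
    starts <- integer(0)
  } else {
    # lookahead so overlapping occurrences are all reported
    hits <- gregexpr(paste0("(?=", pep, ")"), prot, perl = TRUE)[[1]]
    starts <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  out <- data.frame(start = starts, end = starts + nchar(pep) - 1L)
  attr(out, "multimapped") <- nrow(out) > 1L
  out
}

#' Map scored peptides onto a protein
#'
#' Runs [locate_peptide()] for every row of a peptide statistics table
#' and returns one row per (peptide, occurrence), carrying the score and
#' the number of matches (for the multimapping policy downstream).
#'
#' @param stats a `"rbrid_stats"` data frame (needs `peptide`, `score`).
#' @param protein protein residue string.
#' @return A `data.frame` with columns `peptide`, `start`, `end`,
#'   `n_matches`, `score`. Unmatched peptides are absent.
#' @export
locate_peptides <- function(stats, protein) {
  rows <- vector("list", nrow(stats))
  for (i in seq_len(nrow(stats))) {
    iv <- suppressWarnings(locate_peptide(stats$peptide[i], protein))
    if (nrow(iv) == 0L) next
    rows[[i]] <- data.frame(peptide = stats$peptide[i],
                            start = iv$start, end = iv$end,
                            n_matches = nrow(iv),
                            score = stats$score[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), n_matches = integer(0),
                      score = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Residue-level RBR-ID score profile
#'
#' For each residue of the protein, sums the RBR-ID scores of all
#' peptides whose interval covers that residue; `coverage` counts the
#' overlapping peptides the same way. Peptides matching the protein at
#' more than one position are handled by `multimap_policy`: `"all"`
#' (default) adds the full score at every match, `"drop"` excludes them,
#' `"split"` divides the score evenly across matches.
#'
#' @param located output of [locate_peptides()] (columns `peptide`,
#'   `start`, `end`, `n_matches`, `score`).
#' @param protein_length protein length in residues.
#' @param multimap_policy `"all"`, `"drop"`, or `"split"`.
#' @return A `data.frame` of class `"rbrid_profile"` with one row per
#'   residue: `position`, `raw_score`, `coverage` (and `smoothed_score`
#'   after [smooth_profile()]). Uncovered residues carry raw score 0.
#' @export
residue_score_profile <- function(located, protein_length,
                                  multimap_policy = c("all", "drop", "split")) {
  multimap_policy <- match.arg(multimap_policy)
  if (protein_length < 1L) stop("protein_length must be positive", call. = FALSE)
  bad <- located$start < 1L | located$end > protein_length |
    located$start > located$end
  if (any(bad)) {
    stop("interval out of bounds for peptide(s): ",
         paste(unique(located$peptide[bad]), collapse = ", "), call. = FALSE)
  }
  loc <- located
  if (multimap_policy == "drop") {
    loc <- loc[loc$n_matches == 1L, , drop = FALSE]
  }
  w <- if (multimap_policy == "split" && nrow(loc) > 0L) 1 / loc$n_matches else
    rep(1, nrow(loc))

  # difference-array accumulation: add at start, cancel after end, cumsum
  add_track <- function(values) {
    d <- numeric(protein_length + 1L)
    for (i in seq_along(values)) {
      d[loc$start[i]] <- d[loc$start[i]] + values[i]
      d[loc$end[i] + 1L] <- d[loc$end[i] + 1L] - values[i]
    }
    cumsum(d[seq_len(protein_length)])
  }
  raw <- add_track(loc$score * w)
  cov <- add_track(w)

  out <- data.frame(position = seq_len(protein_length),
                    raw_score = raw, coverage = cov)
  class(out) <- c("rbrid_profile", "data.frame")
  out
}

#' Smooth a residue score profile
#'
#' Adds a `smoothed_score` column by running the variable-span super
#' smoother over the raw per-residue scores, with the residue index as
#' the abscissa. Uncovered residues (raw score 0) participate in the
#' smoothing, giving one continuous track along the primary sequence;
#' with `mask_uncovered = TRUE` only covered residues are smoothed and
#' the gaps carry `NA`.
#'
#' @param profile a `"rbrid_profile"` data frame.
#' @param spans,bass,min_window passed to [supersmooth()].
#' @param mask_uncovered smooth only covered residues (default `FALSE`).
#' @return The profile with a `smoothed_score` column.
#' @export
smooth_profile <- function(profile, spans = c(0.05, 0.2, 0.5), bass = 0,
                           min_window = 5L, mask_uncovered = FALSE) {
  if (mask_uncovered) {
    idx <- which(profile$coverage > 0)
    sm <- rep(NA_real_, nrow(profile))
    if (length(idx) >= min_window) {
      sm[idx] <- supersmooth(profile$position[idx], profile$raw_score[idx],
                             spans, bass, min_window)
    }
    profile$smoothed_score <- sm
  } else {
    profile$smoothed_score <- supersmooth(profile$position, profile$raw_score,
                                          spans, bass, min_window)
  }
  profile
}

#' Call candidate RNA-binding segments from a smoothed profile
#'
#' Thresholds the smoothed residue track at a quantile of its values
#' over covered residues, takes maximal runs of residues above the
#' threshold, merges runs separated by at most `merge_gap` residues,
#' discards merged runs shorter than `min_length`, and returns segments
#' sorted by peak smoothed score (descending).
#'
#' The default quantile (0.85) reflects that a genuine RBR can span on
#' the order of 10-15% of a protein's primary sequence — for ATRX the
#' region is roughly 350 of 2492 residues — so a threshold reserving
#' only the top few percent of residues would truncate regions of the
#' scale the method is meant to recover.
#'
#' @param profile a smoothed `"rbrid_profile"`.
#' @param threshold_quantile quantile of smoothed scores over covered
#'   residues used as the calling threshold (default 0.85).
#' @param min_length minimum segment length in residues (default 10).
#' @param merge_gap merge runs separated by at most this many residues
#'   (default 5).
#' @return A `data.frame` with columns `start`, `end`, `peak_score`,
#'   `mean_score`, sorted by `peak_score` descending. Empty (with a
#'   warning) when no residue is covered.
#' @export
call_rbr_segments <- function(profile, threshold_quantile = 0.85,
                              min_length = 10L, merge_gap = 5L) {
  if (!"smoothed_score" %in% names(profile)) {
    stop("profile has no smoothed_score; run smooth_profile() first", call. = FALSE)
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_score = numeric(0), mean_score = numeric(0))
  covered <- profile$coverage > 0 & !is.na(profile$smoothed_score)
  if (!any(covered)) {
    warning("profile has no covered residues; no segments called", call. = FALSE)
    return(empty)
  }
  threshold <- stats::quantile(profile$smoothed_score[covered],
                               threshold_quantile, names = FALSE)
  above <- !is.na(profile$smoothed_score) & profile$smoothed_score > threshold
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge runs separated by small gaps
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      gap <- seg$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_length, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)

  merged$peak_score <- vapply(seq_len(nrow(merged)), function(i) {
    max(profile$smoothed_score[merged$start[i]:merged$end[i]])
  }, numeric(1))
  merged$mean_score <- vapply(seq_len(nrow(merged)), function(i) {
    mean(profile$smoothed_score[merged$start[i]:merged$end[i]])
  }, numeric(1))
  merged <- merged[order(-merged$peak_score), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}
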