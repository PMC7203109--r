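#' Generate a random protein sequence
#'
#' Residues are drawn from the 20-letter alphabet at average proteome
#' frequencies (K+R together about 11%, so tryptic digestion yields
#' peptides of usable length). Deterministic given the seed; the
#' caller's RNG state is untouched.
#'
#' @param length sequence length, at least 50.
#' @param seed integer seed.
#' @return A single residue string.
#' @export
generate_protein_sequence <- function(length, seed) {
  if (length < 50L) stop("protein length must be at least 50", call. = FALSE)
  with_rng(seed, paste(
    sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ),
    collapse = ""
  ))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of K or R except when the next residue is P, joins
#' up to `missed_cleavages` adjacent fragments, and filters by peptide
#' length. Each peptide carries its 1-based inclusive interval on the
#' protein.
#'
#' @param protein protein residue string.
#' @param missed_cleavages 0, 1, or 2 allowed missed cleavage sites.
#' @param min_len,max_len peptide length filter (defaults 6 and 30,
#'   the usual detectable tryptic range).
#' @return A `data.frame` with columns `peptide`, `start`, `end`,
#'   `missed` (number of internal cleavage sites).
#' @export
digest_tryptic <- function(protein, missed_cleavages = 0L,
                           min_len = 6L, max_len = 30L) {
  if (!missed_cleavages %in% 0:2) {
    stop("missed_cleavages must be 0, 1, or 2", call. = FALSE)
  }
  seq <- toupper(protein[[1]])
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  # cleavage after position i: K/R at i, not followed by P
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  bounds <- c(0L, sites, n)  # fragment f spans (bounds[f]+1) .. bounds[f+1]
  nfrag <- length(bounds) - 1L

  rows <- list()
  for (f in seq_len(nfrag)) {
    for (mc in 0:missed_cleavages) {
      g <- f + mc
      if (g > nfrag) break
      start <- bounds[f] + 1L
      end <- bounds[g + 1L]
      len <- end - start + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(seq, start, end),
        start = start, end = end, missed = mc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Planted RNA-binding region
#'
#' Ground truth for a synthetic experiment: peptides overlapping
#' `[start, end]` have their +4SU intensities multiplied by
#' `depletion_factor` (delta in (0, 1]; 1 means a null experiment with
#' no crosslinking signal).
#'
#' @param start,end 1-based inclusive residue coordinates.
#' @param depletion_factor multiplicative depletion in (0, 1].
#' @export
planted_rbr <- function(start, end, depletion_factor = 0.5) {
  if (start < 1L || end < start) stop("invalid RBR coordinates", call. = FALSE)
  if (depletion_factor <= 0 || depletion_factor > 1) {
    stop("depletion_factor must be in (0, 1]", call. = FALSE)
  }
  structure(list(start = as.integer(start), end = as.integer(end),
                 depletion_factor = depletion_factor),
            class = "rbrid_truth")
}

#' Simulation parameters
#'
#' Defaults emulate the study design this package targets: 8 biological
#' replicates per condition split over 2 instrument batches. Base
#' peptide abundances are log-normal (`abundance_meanlog`,
#' `abundance_sdlog` on the natural-log scale; the defaults give median
#' intensities around 1e7, typical of MS1 peptide quantification).
#' Replicate-to-replicate variation is multiplicative log-normal noise
#' with coefficient of variation `noise_cv`; each batch carries one
#' shared log-normal scale factor (`batch_sdlog`), which run-sum
#' normalization cancels. Detection follows a logistic model in log10
#' intensity: `P(detected) = plogis(steepness * (log10 I - midpoint))`;
#' undetected measurements are recorded as 0, so low-abundance peptides
#' can present all-zero conditions and exercise the imputation rule. Set
#' `dropout_midpoint = -Inf` to disable dropout.
#'
#' @param n_replicates replicates per condition (default 8).
#' @param n_batches instrument batches (default 2).
#' @param abundance_meanlog,abundance_sdlog log-normal base abundance.
#' @param noise_cv multiplicative noise CV (default 0.2).
#' @param batch_sdlog log-sd of the per-batch scale factor.
#' @param dropout_midpoint,dropout_steepness logistic detection model
#'   (log10-intensity units).
#' @param missed_cleavages,min_len,max_len digestion settings.
#' @param overlap_mode `"any"`: a single overlapping residue depletes
#'   the whole peptide (crosslinking at one residue suffices);
#'   `"proportional"`: the effective factor is
#'   `1 - (1 - delta) * overlap_fraction`.
#' @export
simulation_config <- function(n_replicates = 8L, n_batches = 2L,
                              abundance_meanlog = log(1e7),
                              abundance_sdlog = 1.5,
                              noise_cv = 0.2,
                              batch_sdlog = 0.25,
                              dropout_midpoint = 5.5,
                              dropout_steepness = 3,
                              missed_cleavages = 0L,
                              min_len = 6L, max_len = 30L,
                              overlap_mode = c("any", "proportional")) {
  overlap_mode <- match.arg(overlap_mode)
  cfg <- list(n_replicates = as.integer(n_replicates),
              n_batches = as.integer(n_batches),
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              noise_cv = noise_cv,
              batch_sdlog = batch_sdlog,
              dropout_midpoint = dropout_midpoint,
              dropout_steepness = dropout_steepness,
              missed_cleavages = as.integer(missed_cleavages),
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              overlap_mode = overlap_mode)
  if (cfg$n_replicates < 2L || cfg$n_batches < 1L || cfg$noise_cv < 0 ||
      cfg$abundance_sdlog <= 0) {
    stop("invalid simulation parameters", call. = FALSE)
  }
  structure(cfg, class = "rbrid_simconfig")
}

#' Simulate a replicated +/-4SU RBR-ID experiment
#'
#' Digests the protein, assigns each peptide a log-normal base
#' abundance, and builds one intensity column per run: base abundance x
#' batch factor x multiplicative noise, with the planted depletion
#' applied to RBR-overlapping peptides in +4SU runs only, and
#' intensity-dependent dropout zeroing undetected measurements. Fully
#' reproducible from the seed.
#'
#' @param protein protein residue string (e.g. from
#'   [generate_protein_sequence()]).
#' @param truth a [planted_rbr()] (use `depletion_factor = 1` for a
#'   null experiment).
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param accession accession used for the FASTA/table annotation.
#' @return List with `peptides` (a peptide table in the generic
#'   dialect), `design` (an experiment design), `digest` (peptide
#'   intervals), and `truth` (echoed, with the seed attached).
#' @export
simulate_experiment <- function(protein, truth, config = simulation_config(),
                                seed, accession = "SYN1") {
  stopifnot(inherits(truth, "rbrid_truth"), inherits(config, "rbrid_simconfig"))
  seqlen <- nchar(protein[[1]])
  if (truth$end > seqlen) stop("planted RBR exceeds protein bounds", call. = FALSE)
  digest <- digest_tryptic(protein, config$missed_cleavages,
                           config$min_len, config$max_len)
  if (nrow(digest) == 0L) stop("digest is empty; nothing to simulate", call. = FALSE)

  nrep <- config$n_replicates
  batch_of <- rep(seq_len(config$n_batches), length.out = nrep)
  design <- data.frame(
    run_id = c(paste0("plus_r", seq_len(nrep)), paste0("minus_r", seq_len(nrep))),
    condition = rep(c("+4SU", "-4SU"), each = nrep),
    replicate = rep(seq_len(nrep), 2L),
    batch = paste0("batch", rep(batch_of, 2L)),
    stringsAsFactors = FALSE
  )
  design <- as_design(design)

  ov_len <- pmax(0L, pmin(digest$end, truth$end) - pmax(digest$start, truth$start) + 1L)
  dep <- rep(1, nrow(digest))
  if (config$overlap_mode == "any") {
    dep[ov_len > 0L] <- truth$depletion_factor
  } else {
    frac <- ov_len / (digest$end - digest$start + 1L)
    dep <- 1 - (1 - truth$depletion_factor) * frac
  }

  m <- nrow(digest)
  nruns <- nrow(design)
  noise_sdlog <- sqrt(log(1 + config$noise_cv^2))
  intens <- with_rng(seed, {
    base <- rlnorm(m, config$abundance_meanlog, config$abundance_sdlog)
    batch_factor <- rlnorm(config$n_batches, 0, config$batch_sdlog)
    mat <- matrix(0, m, nruns, dimnames = list(NULL, design$run_id))
    for (j in seq_len(nruns)) {
      mu <- base * batch_factor[batch_of[design$replicate[j]]]
      if (design$condition[j] == "+4SU") mu <- mu * dep
      val <- mu * rlnorm(m, 0, noise_sdlog)
      if (is.finite(config$dropout_midpoint)) {
        p_det <- plogis(config$dropout_steepness *
                          (log10(val) - config$dropout_midpoint))
        val[runif(m) > p_det] <- 0
      }
      mat[, j] <- val
    }
    mat
  })

  peptides <- data.frame(peptide = digest$peptide,
                         protein = accession,
                         stringsAsFactors = FALSE)
  peptides <- cbind(peptides, as.data.frame(intens, check.names = FALSE))
  truth$seed <- as.integer(seed)
  list(peptides = new_peptide_table(peptides, design$run_id),
       design = design, digest = digest, truth = truth)
}

#' Recovery metrics for a called segment set
#'
#' Compares the top-ranked called segment with the planted RBR on
#' 1-based inclusive residue intervals: Jaccard index of the residue
#' sets, absolute midpoint error, and whether any overlap exists.
#'
#' @param segments output of [call_rbr_segments()] (sorted by peak).
#' @param truth a [planted_rbr()].
#' @return List with `jaccard`, `center_error`, `detected`.
#' @export
recovery_metrics <- function(segments, truth) {
  if (nrow(segments) == 0L) {
    return(list(jaccard = 0, center_error = NA_real_, detected = FALSE))
  }
  s <- segments[1L, ]
  inter <- max(0L, min(s$end, truth$end) - max(s$start, truth$start) + 1L)
  len_s <- s$end - s$start + 1L
  len_t <- truth$end - truth$start + 1L
  jac <- inter / (len_s + len_t - inter)
  center_error <- abs((s$start + s$end) / 2 - (truth$start + truth$end) / 2)
  list(jaccard = jac, center_error = center_error, detected = inter > 0L)
}
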