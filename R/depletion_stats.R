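#' Normalize intensities by run totals
#'
#' Divides every intensity by the total intensity of its MS run, so each
#' run's peptide intensities sum to 1. This removes run-to-run loading
#' and acquisition differences (any per-run scale factor, including a
#' constant instrument-batch factor, cancels exactly).
#'
#' @param x a peptide table (contaminants should already be removed).
#' @param design the experiment design; every design run must be a
#'   column of `x`.
#' @return The peptide table with normalized intensities.
#' @export
normalize_run_intensities <- function(x, design) {
  runs <- peptide_runs(x)
  missing_runs <- setdiff(design$run_id, runs)
  if (length(missing_runs) > 0L) {
    stop("design run(s) absent from peptide table: ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  }
  for (r in design$run_id) {
    tot <- sum(x[[r]])
    if (!is.finite(tot) || tot <= 0) {
      stop(sprintf("run '%s' has zero total intensity; cannot normalize", r),
           call. = FALSE)
    }
    x[[r]] <- x[[r]] / tot
  }
  x
}

#' Per-condition mean intensities with the zero-imputation rule
#'
#' The condition mean is the arithmetic mean over that condition's runs,
#' zeros included (a zero is a measured non-detection). Only when every
#' replicate value in a condition is zero is the mean imputed, as
#' `floor_factor` times the smallest strictly positive condition mean
#' observed anywhere in the dataset (both conditions, all peptides).
#'
#' @param mat numeric matrix of normalized intensities, one row per
#'   peptide, columns named by run id.
#' @param design the experiment design.
#' @param floor_factor multiplier for the imputation floor (default 0.5).
#' @return List with vectors `mean_plus`, `mean_minus`, logical
#'   `imputed_plus`, `imputed_minus`, and the scalar `floor` used.
#' @export
condition_means <- function(mat, design, floor_factor = 0.5) {
  mat <- as.matrix(mat)
  plus_runs <- design$run_id[design$condition == "+4SU"]
  minus_runs <- design$run_id[design$condition == "-4SU"]
  mean_plus <- rowMeans(mat[, plus_runs, drop = FALSE])
  mean_minus <- rowMeans(mat[, minus_runs, drop = FALSE])
  pos <- c(mean_plus[mean_plus > 0], mean_minus[mean_minus > 0])
  if (length(pos) == 0L) {
    stop("every condition mean is zero; imputation floor undefined", call. = FALSE)
  }
  floor_val <- floor_factor * min(pos)
  imputed_plus <- mean_plus == 0
  imputed_minus <- mean_minus == 0
  mean_plus[imputed_plus] <- floor_val
  mean_minus[imputed_minus] <- floor_val
  list(mean_plus = mean_plus, mean_minus = mean_minus,
       imputed_plus = imputed_plus, imputed_minus = imputed_minus,
       floor = floor_val)
}

#' Log2 depletion ratio
#'
#' `log2(mean_plus / mean_minus)`: the +4SU/-4SU normalized peptide
#' ratio on the log2 scale. Negative values indicate depletion by RNA
#' crosslinking. Vectorized.
#'
#' @param mean_plus,mean_minus positive condition means (post-imputation).
#' @export
depletion_ratio <- function(mean_plus, mean_minus) {
  if (any(mean_plus <= 0) || any(mean_minus <= 0)) {
    stop("condition means must be positive (apply imputation first)",
         call. = FALSE)
  }
  log2(mean_plus / mean_minus)
}

#' Two-sample pooled-variance Student t test P value
#'
#' Classic unpaired, two-sided Student t test with pooled variance and
#' `n1 + n2 - 2` degrees of freedom. Degenerate zero-variance groups:
#' if both group means are equal the test is uninformative (t = 0,
#' p = 1); otherwise p is floored at `p_floor` rather than reported as
#' exactly zero.
#'
#' @param values_plus,values_minus numeric vectors, at least 2 values each.
#' @param p_floor lower bound for degenerate p values (default 1e-15).
#' @return The two-sided P value in `(0, 1]`.
#' @export
peptide_pvalue <- function(values_plus, values_minus, p_floor = 1e-15) {
  n1 <- length(values_plus); n2 <- length(values_minus)
  if (n1 < 2L || n2 < 2L) {
    stop("t test needs at least 2 values per group", call. = FALSE)
  }
  m1 <- mean(values_plus); m2 <- mean(values_minus)
  sp2 <- ((n1 - 1) * stats::var(values_plus) +
          (n2 - 1) * stats::var(values_minus)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    return(if (m1 == m2) 1 else p_floor)
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
}

# Row-wise pooled t test over an intensity matrix; same contract as
# peptide_pvalue but vectorized across peptides.
rowwise_pvalues <- function(mat, plus_runs, minus_runs, p_floor = 1e-15) {
  a <- mat[, plus_runs, drop = FALSE]
  b <- mat[, minus_runs, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  p <- rep(NA_real_, nrow(mat))
  degen <- sp2 <= 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, p_floor)
  ok <- !degen
  tstat <- (m1[ok] - m2[ok]) / sqrt(sp2[ok] * (1 / n1 + 1 / n2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  p
}

#' RBR-ID score
#'
#' `score = -log2_ratio * (log10 p)^2`. The score combines the effect
#' size (fold depletion of the peptide in +4SU runs) with statistical
#' confidence; it is positive for depleted peptides and larger when the
#' depletion is strong and reproducible. P values are clamped to
#' `[p_floor, 1]` before the `(log10 p)^2` term so a degenerate p cannot
#' produce an infinite score. Vectorized.
#'
#' @param log2_ratio log2 depletion ratio(s).
#' @param p_value t-test P value(s) in `(0, 1]`.
#' @param p_floor clamp for small P values (default 1e-15).
#' @export
rbr_score <- function(log2_ratio, p_value, p_floor = 1e-15) {
  if (any(!is.finite(p_value)) || any(p_value <= 0) || any(p_value > 1)) {
    stop("p_value must lie in (0, 1]", call. = FALSE)
  }
  p <- pmax(p_value, p_floor)
  -log2_ratio * log10(p)^2
}

#' Per-peptide depletion statistics
#'
#' Computes, for every peptide of a normalized table, the condition
#' means (with the all-zero imputation rule), the log2 depletion ratio,
#' the pooled-variance Student t-test P value, the RBR-ID score, and the
#' significance call (`p < alpha` and depleted). Peptides detected in no
#' run of either condition carry no information (both means would be
#' imputed to the same floor) and are dropped with a warning.
#'
#' @param x a peptide table with normalized intensities
#'   (see [normalize_run_intensities()]).
#' @param design the experiment design.
#' @param alpha significance level for the depleted-peptide call
#'   (default 0.1).
#' @param floor_factor imputation floor factor (default 0.5).
#' @param p_floor clamp for small P values (default 1e-15).
#' @param test_scale `"linear"` (default) runs the t test on the
#'   normalized intensities themselves, the same quantities the ratio is
#'   built from; `"log"` runs it on log2 intensities after replacing
#'   zeros with half the smallest positive normalized intensity.
#' @return A `data.frame` of class `"rbrid_stats"` with columns
#'   `peptide`, `protein`, `mean_plus`, `mean_minus`, `imputed_plus`,
#'   `imputed_minus`, `log2_ratio`, `p_value`, `score`, `significant`.
#' @export
peptide_stats <- function(x, design, alpha = 0.1, floor_factor = 0.5,
                          p_floor = 1e-15, test_scale = c("linear", "log")) {
  test_scale <- match.arg(test_scale)
  runs <- peptide_runs(x)
  mat <- as.matrix(as.data.frame(x)[, design$run_id, drop = FALSE])
  storage.mode(mat) <- "double"

  detected <- rowSums(mat > 0) > 0
  if (any(!detected)) {
    warning(sprintf("dropping %d peptide(s) detected in no run", sum(!detected)),
            call. = FALSE)
    x <- x[detected, , drop = FALSE]
    mat <- mat[detected, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("no detected peptides to test", call. = FALSE)

  cm <- condition_means(mat, design, floor_factor)
  log2_ratio <- depletion_ratio(cm$mean_plus, cm$mean_minus)

  plus_runs <- design$run_id[design$condition == "+4SU"]
  minus_runs <- design$run_id[design$condition == "-4SU"]
  test_mat <- mat
  if (test_scale == "log") {
    floor_i <- 0.5 * min(mat[mat > 0])
    test_mat[test_mat == 0] <- floor_i
    test_mat <- log2(test_mat)
  }
  p <- rowwise_pvalues(test_mat, plus_runs, minus_runs, p_floor)

  out <- data.frame(
    peptide = x$peptide,
    protein = x$protein,
    mean_plus = cm$mean_plus,
    mean_minus = cm$mean_minus,
    imputed_plus = cm$imputed_plus,
    imputed_minus = cm$imputed_minus,
    log2_ratio = log2_ratio,
    p_value = p,
    score = rbr_score(log2_ratio, p, p_floor),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_value < alpha & out$log2_ratio < 0
  rownames(out) <- NULL
  class(out) <- c("rbrid_stats", "data.frame")
  out
}

#' Significantly depleted peptides
#'
#' Keeps peptides with `p_value < alpha` (strict) that are depleted
#' (`log2_ratio < 0`); enrichment, however significant, is not evidence
#' of RNA binding. Also refreshes the `significant` flag on the input.
#'
#' @param stats a `"rbrid_stats"` data frame from [peptide_stats()].
#' @param alpha significance level (default 0.1).
#' @return The filtered rows.
#' @export
significant_peptides <- function(stats, alpha = 0.1) {
  stats$significant <- stats$p_value < alpha & stats$log2_ratio < 0
  out <- stats[stats$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
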