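#' Fixed-span local linear smoother with leave-one-out residuals
#'
#' The building block of the variable-span super smoother: for each
#' point i, an ordinary least-squares line is fit over the `J` nearest
#' neighbors of i — a symmetric window of `J = 2*ibw + 1` points,
#' `ibw = max(round(span * n / 2), floor(min_window / 2))`, shifted
#' (one-sided) at the boundaries so the window always holds `J` points —
#' and evaluated at `x[i]`. The leave-one-out absolute residual is
#' obtained from the standard deletion identity
#' `|y_i - fit_i| / (1 - h_i)` with leverage
#' `h_i = 1/J + (x_i - xbar)^2 / Sxx`. Window sums are taken from
#' prefix sums, so the cost is linear in n.
#'
#' @param x strictly increasing numeric vector.
#' @param y numeric vector, same length as `x`.
#' @param span window fraction of n in (0, 1].
#' @param min_window minimum window size (default 5, i.e. half-width 2).
#' @return List with `fit` (smoothed values) and `loo` (absolute
#'   leave-one-out cross-validation residuals), both of length n.
#' @export
fixed_span_smooth <- function(x, y, span, min_window = 5L) {
  x <- as.double(x)
  y <- as.double(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < min_window) {
    stop(sprintf("need at least %d points, got %d", min_window, n), call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("x must be strictly increasing (no duplicates)", call. = FALSE)
  }
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)

  ibw <- max(floor(0.5 * span * n + 0.5), max(1L, floor(min_window / 2)))
  J <- min(2L * ibw + 1L, n)
  i <- seq_len(n)
  lo <- pmin(pmax(i - ibw, 1L), n - J + 1L)
  hi <- lo + J - 1L

  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y))
  m <- hi - lo + 1
  sx <- cx[hi + 1L] - cx[lo]
  sy <- cy[hi + 1L] - cy[lo]
  sxx <- cxx[hi + 1L] - cxx[lo]
  sxy <- cxy[hi + 1L] - cxy[lo]
  xbar <- sx / m
  ybar <- sy / m
  Sxx <- sxx - m * xbar^2
  Sxy <- sxy - m * xbar * ybar

  guard <- (1e-7 * (x[n] - x[1]))^2
  slope <- ifelse(Sxx > guard, Sxy / Sxx, 0)
  fit <- ybar + slope * (x - xbar)

  lev <- 1 / m + ifelse(Sxx > guard, (x - xbar)^2 / Sxx, 0)
  denom <- pmax(1 - lev, 1e-10)
  loo <- abs(y - fit) / denom
  list(fit = fit, loo = loo)
}

#' Variable-span "super smoother"
#'
#' A from-scratch implementation of Friedman's variable-span smoother.
#' Three fixed-span local linear smooths are computed at the primary
#' spans (defaults 0.05, 0.2, 0.5 — "tweeter", "midrange", "woofer");
#' their absolute leave-one-out residuals are themselves smoothed with
#' the midrange span to give a cross-validated local error estimate per
#' span; each point picks the span minimizing that estimate, with an
#' optional bass enhancement pulling choices toward the largest span;
#' the chosen span values are smoothed with the midrange span; the final
#' value at each point is interpolated between the two primary-span fits
#' bracketing its (smoothed) chosen span, and the interpolated curve is
#' passed once more through the tweeter-span smoother.
#'
#' @param x strictly increasing numeric vector (for residue profiles,
#'   the residue index 1..L, so ties never arise).
#' @param y numeric vector, same length.
#' @param spans three strictly increasing primary span fractions.
#' @param bass bass enhancement in `[0, 10]`; 0 (default) disables it,
#'   larger values favor smoother (larger-span) fits.
#' @param min_window minimum window size for every internal smooth.
#' @param detail if `TRUE`, attach the three primary fits and the
#'   pre-final interpolated curve as attributes `"fits"` and `"interp"`.
#' @return Numeric vector of smoothed values, length of the input.
#' @export
supersmooth <- function(x, y, spans = c(0.05, 0.2, 0.5), bass = 0,
                        min_window = 5L, detail = FALSE) {
  if (length(spans) != 3L || any(diff(spans) <= 0) ||
      spans[1] <= 0 || spans[3] > 1) {
    stop("spans must be three strictly increasing fractions in (0, 1]",
         call. = FALSE)
  }
  if (bass < 0 || bass > 10) stop("bass must be in [0, 10]", call. = FALSE)
  n <- length(x)

  fits <- matrix(0, n, 3L)
  sres <- matrix(0, n, 3L)
  for (k in 1:3) {
    sm <- fixed_span_smooth(x, y, spans[k], min_window)
    fits[, k] <- sm$fit
    sres[, k] <- fixed_span_smooth(x, sm$loo, spans[2], min_window)$fit
  }

  best <- max.col(-sres, ties.method = "first")
  chosen <- spans[best]
  if (bass > 0) {
    resmin <- sres[cbind(seq_len(n), best)]
    woofer <- sres[, 3L]
    adj <- resmin < woofer & resmin > 0
    ratio <- pmax(1e-7, resmin[adj] / woofer[adj])
    chosen[adj] <- chosen[adj] +
      (spans[3] - chosen[adj]) * ratio^(10 - bass)
  }

  span_sm <- fixed_span_smooth(x, chosen, spans[2], min_window)$fit
  span_sm <- pmin(pmax(span_sm, spans[1]), spans[3])

  interp <- numeric(n)
  lower <- span_sm <= spans[2]
  f <- ifelse(lower,
              (spans[2] - span_sm) / (spans[2] - spans[1]),
              (span_sm - spans[2]) / (spans[3] - spans[2]))
  interp[lower] <- (1 - f[lower]) * fits[lower, 2L] + f[lower] * fits[lower, 1L]
  interp[!lower] <- (1 - f[!lower]) * fits[!lower, 2L] + f[!lower] * fits[!lower, 3L]

  out <- fixed_span_smooth(x, interp, spans[1], min_window)$fit
  if (detail) {
    attr(out, "fits") <- fits
    attr(out, "interp") <- interp
  }
  out
}
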