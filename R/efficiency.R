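#' Estimate PCR efficiency from one amplification curve
#'
#' Window-of-linearity estimation: among all windows of `window_min` to
#' `window_max` consecutive cycles whose readings lie strictly above the
#' baseline noise floor and below the plateau threshold, the ordinary
#' least-squares fit of log10(fluorescence) on cycle with the highest
#' r-squared is selected (ties broken towards the steeper slope, then the
#' earlier window), and the per-cycle amplification factor is
#' `E = 10^slope`.
#'
#' The noise floor is the median of the first eight readings plus ten times
#' their SD; the plateau threshold is 90 % of the curve maximum. Both
#' restrict the fit to the exponential phase.
#'
#' @param curve an `amplification_curve` (list with `reaction_id`,
#'   `amplicon` and per-cycle `fluorescence`), or a bare numeric vector of
#'   readings
#' @param window_min,window_max window length bounds in cycles (defaults 4
#'   and 6)
#' @return an object of class `efficiency_estimate`: list with
#'   `reaction_id`, `amplicon`, `E_hat`, `window` (first and last cycle),
#'   `r_squared` and `log_F0` (fitted intercept, log10 units)
#' @examples
#' f <- 1e-6 * 2 ^ (1:40)
#' estimate_efficiency(f)$E_hat   # exactly 2
#' @export
estimate_efficiency <- function(curve, window_min = 4L, window_max = 6L) {
  if (is.numeric(curve))
    curve <- structure(list(reaction_id = "curve", amplicon = "amp",
                            fluorescence = curve),
                       class = "amplification_curve")
  f <- curve$fluorescence
  if (length(f) < 15L) stop("curve must have at least 15 cycles")
  if (any(!is.finite(f))) stop("non-finite fluorescence readings")
  if (window_min < 3L || window_max < window_min)
    stop("invalid window bounds")
  base <- f[1:8]
  floor_level <- stats::median(base) + 10 * stats::sd(base)
  plateau_level <- 0.9 * max(f)
  eligible <- f > floor_level & f < plateau_level & f > 0

  best <- NULL
  tol <- 1e-9
  for (len in seq(window_min, window_max)) {
    for (start in seq_len(length(f) - len + 1L)) {
      idx <- start:(start + len - 1L)
      if (!all(eligible[idx])) next
      x <- idx
      y <- log10(f[idx])
      vx <- stats::var(x)
      vy <- stats::var(y)
      if (vy == 0) next
      slope <- stats::cov(x, y) / vx
      r2 <- stats::cor(x, y)^2
      cand <- list(start = start, len = len, slope = slope, r2 = r2,
                   intercept = mean(y) - slope * mean(x))
      if (is.null(best)) { best <- cand; next }
      better <-
        (cand$r2 > best$r2 + tol) ||
        (abs(cand$r2 - best$r2) <= tol && cand$slope > best$slope + tol) ||
        (abs(cand$r2 - best$r2) <= tol &&
           abs(cand$slope - best$slope) <= tol && cand$start < best$start)
      if (better) best <- cand
    }
  }
  if (is.null(best)) stop("no exponential phase detected")
  structure(list(reaction_id = curve$reaction_id,
                 amplicon = curve$amplicon,
                 E_hat = 10 ^ best$slope,
                 window = c(best$start, best$start + best$len - 1L),
                 r_squared = best$r2,
                 log_F0 = best$intercept),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("Efficiency estimate %s: E = %.4f (cycles %d-%d, r2 = %.5f)\n",
              x$reaction_id, x$E_hat, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Aggregate per-reaction efficiency estimates per amplicon
#'
#' Filters estimates by fit quality (`r_squared >= r2_min`) and plausibility
#' (`1 < E <= 2.2`), then reports the arithmetic mean and SD (n-1
#' denominator) of E per amplicon, with the number of reactions retained.
#' Amplicons whose mean falls outside (1, 2.2] are flagged with a warning.
#'
#' @param estimates list of `efficiency_estimate` objects
#' @param r2_min minimum r-squared for an estimate to enter the mean
#'   (default 0.99)
#' @return an [efficiency_table()]
#' @export
aggregate_efficiency <- function(estimates, r2_min = 0.99) {
  if (inherits(estimates, "efficiency_estimate")) estimates <- list(estimates)
  if (!length(estimates)) stop("no efficiency estimates supplied")
  amp <- vapply(estimates, `[[`, character(1), "amplicon")
  e <- vapply(estimates, `[[`, numeric(1), "E_hat")
  r2 <- vapply(estimates, `[[`, numeric(1), "r_squared")
  keep <- r2 >= r2_min & e > 1 & e <= 2.2
  if (!any(keep)) stop("no estimate passed quality control")
  amp <- amp[keep]; e <- e[keep]
  labels <- unique(amp)
  mean_E <- vapply(labels, function(a) mean(e[amp == a]), numeric(1))
  sd_E <- vapply(labels, function(a) {
    v <- e[amp == a]
    if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1))
  n <- vapply(labels, function(a) sum(amp == a), integer(1))
  out <- efficiency_table(labels, mean_E, sd_E, n)
  implausible <- out$mean_E <= 1 | out$mean_E > 2.2
  if (any(implausible))
    warning("implausible mean efficiency for: ",
            paste(out$gene[implausible], collapse = ", "))
  out
}
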