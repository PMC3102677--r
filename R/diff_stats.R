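#' Two-group one-way ANOVA on RIA values
#'
#' Standard one-way decomposition for two groups (mixed vs control):
#' `F = MS_between / MS_within` on (1, n-2) degrees of freedom, p-value
#' from the upper tail of the F distribution. Degenerate inputs: zero
#' within-group variance with unequal means reports the smallest
#' representable positive p and is flagged; both groups constant and
#' equal gives F = 0, p = 1.
#'
#' @param mixed,control Numeric vectors of (oriented) RIA values.
#' @return List with `F`, `p`, `df` and `degenerate`.
#' @export
anova_protein <- function(mixed, control) {
  n1 <- length(mixed)
  n2 <- length(control)
  if (n1 < 1L || n2 < 1L || n1 + n2 < 3L)
    stop("need >= 1 value per group and >= 3 in total", call. = FALSE)
  n <- n1 + n2
  m1 <- mean(mixed)
  m2 <- mean(control)
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- sum((mixed - m1)^2) + sum((control - m2)^2)
  if (ssw == 0) {
    if (m1 == m2)
      return(list(F = 0, p = 1, df = c(1L, n - 2L), degenerate = FALSE))
    return(list(F = Inf, p = .Machine$double.xmin, df = c(1L, n - 2L),
                degenerate = TRUE))
  }
  Fstat <- (ssb / 1) / (ssw / (n - 2))
  list(F = Fstat, p = pf(Fstat, 1, n - 2, lower.tail = FALSE),
       df = c(1L, n - 2L), degenerate = FALSE)
}

#' RIA to signed fold change
#'
#' Converts an RIA to the ratio `p = ria/(1-ria)` and reports it as a
#' signed fold: `+p` when `p >= 1`, `-1/p` otherwise, so that the
#' magnitude is always at least 1 and a negative sign denotes a fold
#' decrease. Rounding happens only at presentation time.
#'
#' @param ria RIA values strictly inside (0, 1).
#' @return Signed fold changes.
#' @examples
#' ria_to_fold(0.516)  # 1.066...  (~ +1.07)
#' ria_to_fold(0.490)  # -1.040...
#' @export
ria_to_fold <- function(ria) {
  if (any(ria <= 0 | ria >= 1))
    stop("ria must lie strictly inside (0, 1)", call. = FALSE)
  p <- ria / (1 - ria)
  ifelse(p >= 1, p, -1 / p)
}

#' Fold cutoff to RIA bounds
#'
#' Inverse of [ria_to_fold()] at +/- the cutoff: a fold cutoff `f >= 1`
#' corresponds to `ria_high = f/(1+f)` and `ria_low = 1/(1+f)`.
#'
#' @param fold_cutoff Fold cutoff, >= 1.
#' @return List with `ria_low` and `ria_high`.
#' @examples
#' fold_to_ria_bounds(1.25)  # 0.4444, 0.5556
#' @export
fold_to_ria_bounds <- function(fold_cutoff) {
  if (any(fold_cutoff < 1))
    stop("fold_cutoff must be >= 1", call. = FALSE)
  list(ria_low = 1 / (1 + fold_cutoff),
       ria_high = fold_cutoff / (1 + fold_cutoff))
}

#' Fold cutoff from the control distribution
#'
#' Cumulative-distribution analysis of the pooled control RIAs: the
#' empirical quantiles at `(1-confidence)/2` and `(1+confidence)/2` give
#' RIA bounds outside which a shift cannot be explained by biological
#' noise at the chosen confidence level; the matching fold cutoff is the
#' larger of the two bounds' fold magnitudes.
#'
#' @param control_ria Pooled per-protein per-replicate control RIAs.
#' @param confidence Central coverage (default 0.99).
#' @return List of class `cutoff_result`: `ria_low`, `ria_high`,
#'   `fold_cutoff`, `confidence`, `n`.
#' @export
control_cutoff <- function(control_ria, confidence = 0.99) {
  if (length(control_ria) == 0L)
    stop("control pool is empty", call. = FALSE)
  if (confidence < 0 || confidence >= 1)
    stop("confidence must lie in [0, 1)", call. = FALSE)
  if (length(control_ria) < 50)
    warning("fewer than 50 control values; cutoff will be unstable",
            call. = FALSE)
  qs <- quantile(control_ria,
                 c((1 - confidence) / 2, (1 + confidence) / 2),
                 names = FALSE, type = 7)
  fold_cutoff <- max(abs(ria_to_fold(qs[1L])), abs(ria_to_fold(qs[2L])))
  structure(list(ria_low = qs[1L], ria_high = qs[2L],
                 fold_cutoff = fold_cutoff, confidence = confidence,
                 n = length(control_ria)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "control cutoff (%.0f%% of %d values): RIA outside [%.3f, %.3f], >= %.2f-fold\n",
    100 * x$confidence, x$n, x$ria_low, x$ria_high, x$fold_cutoff))
  invisible(x)
}

#' Flag significant proteins
#'
#' Applies the two screens to a differential-results table: `pass_p`
#' (ANOVA p below `alpha`) and `pass_fold` (mean mixed RIA outside the
#' control-derived bounds), with direction taken from the mean mixed RIA
#' relative to 0.5. A summary of counts is attached as the `"summary"`
#' attribute.
#'
#' @param results data.frame with columns `p` and `mean_mixed_ria`
#'   (e.g. from [differential_expression()]).
#' @param alpha Significance level on the ANOVA p (default 0.01).
#' @param cutoff A `cutoff_result` from [control_cutoff()], or a fixed
#'   fold cutoff passed through [fold_to_ria_bounds()].
#' @return The table with `pass_p`, `pass_fold`, `significant`
#'   (both screens) and `direction` columns added.
#' @export
call_significant <- function(results, alpha = 0.01, cutoff) {
  r <- as.data.table(results)
  if (is.numeric(cutoff)) {
    b <- fold_to_ria_bounds(cutoff)
    cutoff <- list(ria_low = b$ria_low, ria_high = b$ria_high)
  }
  r[, pass_p := p < alpha]
  r[, pass_fold := mean_mixed_ria < cutoff$ria_low |
      mean_mixed_ria > cutoff$ria_high]
  r[, direction := fifelse(mean_mixed_ria > 0.5, "up",
                           fifelse(mean_mixed_ria < 0.5, "down",
                                   "unchanged"))]
  r[, significant := pass_p & pass_fold]
  summ <- list(
    n = nrow(r),
    n_pass_p = sum(r$pass_p),
    n_up_p = sum(r$pass_p & r$direction == "up"),
    n_down_p = sum(r$pass_p & r$direction == "down"),
    n_significant = sum(r$significant),
    n_up = sum(r$significant & r$direction == "up"),
    n_down = sum(r$significant & r$direction == "down")
  )
  setattr(r, "summary", summ)
  r[]
}
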