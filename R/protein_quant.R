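#' Leave-one-out outlier trimming of peptide RIAs
#'
#' For each peptide, the mean and standard deviation of the *other*
#' peptides of the same protein in the same sample are computed; peptides
#' deviating from that mean by more than twice that SD are all removed in
#' a single pass and the protein RIA recomputed. A zero SD of the others
#' with any nonzero deviation marks the peptide as an outlier. Proteins
#' with fewer than `min_n` peptides are returned untouched (the
#' leave-one-out SD needs at least two others). As a guard, never more
#' than `floor(n/2)` peptides are removed; if the rule flags more, only
#' the most deviant `floor(n/2)` go.
#'
#' @param x Numeric vector of peptide RIAs for one protein in one sample.
#' @param min_n Minimum number of peptides for trimming to apply.
#' @return List with `kept` (logical vector), `ria` (mean of kept values)
#'   and `n_removed`.
#' @examples
#' trim_outliers(c(0.50, 0.51, 0.49, 0.90))$ria  # 0.5
#' @export
trim_outliers <- function(x, min_n = 3) {
  n <- length(x)
  if (n < min_n)
    return(list(kept = rep(TRUE, n), ria = mean(x), n_removed = 0L))
  s <- sum(x)
  ss <- sum(x^2)
  mean_o <- (s - x) / (n - 1)
  # sample variance of the n-1 others (denominator n-2)
  var_o <- pmax(0, (ss - x^2 - (n - 1) * mean_o^2) / (n - 2))
  sd_o <- sqrt(var_o)
  dev <- abs(x - mean_o)
  out <- dev > 2 * sd_o   # strict: sd 0 + any deviation flags
  # never remove more than half; with few peptides the leave-one-out rule
  # can flag both extremes of an evenly spread set, so cap at the most
  # deviant floor(n/2)
  max_rm <- floor(n / 2)
  if (sum(out) > max_rm) {
    score <- dev / ifelse(sd_o > 0, sd_o, .Machine$double.xmin)
    worst <- order(score, decreasing = TRUE)[seq_len(max_rm)]
    out <- seq_len(n) %in% worst
  }
  list(kept = !out, ria = mean(x[!out]), n_removed = sum(out))
}

#' Roll peptide RIAs up to proteins
#'
#' Protein RIA in a sample is the arithmetic mean of its constituent
#' peptide RIAs (after optional leave-one-out outlier trimming).
#'
#' @param obs Merged observation table from [merge_technical()]'s
#'   `amt$obs` joined with entry accessions, or any data.frame with
#'   columns `accession`, `sample_type`, `orientation`, `bio_rep`, `ria`.
#' @param trim Apply [trim_outliers()] per protein-sample? Default `TRUE`.
#' @return data.table: `accession`, `sample_type`, `orientation`,
#'   `bio_rep`, `ria`, `n_peptides` (kept), `n_removed`.
#' @export
rollup_proteins <- function(obs, trim = TRUE) {
  o <- as.data.table(obs)
  need <- c("accession", "sample_type", "orientation", "bio_rep", "ria")
  if (!all(need %in% names(o)))
    stop("obs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  o[, {
    tr <- if (trim) trim_outliers(ria)
      else list(kept = rep(TRUE, .N), ria = mean(ria), n_removed = 0L)
    .(ria = tr$ria, n_peptides = sum(tr$kept), n_removed = tr$n_removed)
  }, by = .(accession, sample_type, orientation, bio_rep)]
}

#' Orient RIA values
#'
#' Maps reverse-labeled samples onto the forward scale so that forward
#' and reverse mixed samples enter one statistical group: forward (and
#' control) values are unchanged, reverse values become `1 - RIA`. The
#' operation is an involution.
#'
#' @param ria Numeric RIA vector.
#' @param orientation Character vector, `"forward"` or `"reverse"`.
#' @return Oriented RIA vector.
#' @export
orient_ria <- function(ria, orientation) {
  if (!all(orientation %in% c("forward", "reverse")))
    stop("orientation must be 'forward' or 'reverse'", call. = FALSE)
  if (length(orientation) == 1L)
    orientation <- rep(orientation, length(ria))
  ifelse(orientation == "reverse", 1 - ria, ria)
}

#' Normalize a sample's RIAs to mean 0.5
#'
#' Applies a single multiplicative factor `c` in ratio space: each RIA
#' `r` maps to `c*p/(1+c*p)` with `p = r/(1-r)`, and `c` is found by
#' monotone bisection so that the arithmetic mean of the normalized RIAs
#' is 0.5 within `tol`. This is equivalent to shifting log-ratios by a
#' constant, preserves order statistics and keeps values inside (0, 1)
#' (an additive shift on RIA would not).
#'
#' @param ria Numeric vector of RIAs, all strictly inside (0, 1).
#' @param tol Convergence tolerance on the achieved mean. Default 1e-9.
#' @param max_iter Bisection iteration cap.
#' @return List with `ria` (normalized values) and `result`, a
#'   `normalization_result` carrying `scale` (the factor c),
#'   `achieved_mean` and `iterations`.
#' @export
normalize_sample <- function(ria, tol = 1e-9, max_iter = 200) {
  if (length(ria) < 1L) stop("need at least one RIA", call. = FALSE)
  if (any(ria <= 0 | ria >= 1))
    stop("all RIAs must lie strictly inside (0, 1)", call. = FALSE)
  p <- ria / (1 - ria)
  f <- function(cc) mean(cc * p / (1 + cc * p)) - 0.5
  it <- 0L
  if (abs(f(1)) <= tol) {
    cc <- 1
  } else {
    lo <- hi <- 1
    while (f(lo) > 0 && lo > 1e-12) lo <- lo / 2
    while (f(hi) < 0 && hi < 1e12) hi <- hi * 2
    repeat {
      it <- it + 1L
      cc <- (lo + hi) / 2
      fc <- f(cc)
      if (abs(fc) <= tol || it >= max_iter) break
      if (fc < 0) lo <- cc else hi <- cc
    }
  }
  out <- cc * p / (1 + cc * p)
  res <- structure(list(scale = cc, achieved_mean = mean(out),
                        iterations = it),
                   class = "normalization_result")
  list(ria = out, result = res)
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization: c = %.6g, mean = %.12f (%d iterations)\n",
              x$scale, x$achieved_mean, x$iterations))
  invisible(x)
}

#' Average protein RIAs over biological replicates
#'
#' @param quant Protein-sample table from [rollup_proteins()] (optionally
#'   normalized/oriented), with columns `accession`, `sample_type`,
#'   `bio_rep`, `ria`.
#' @param value Column to average (default `"ria"`).
#' @return data.table: `accession`, `sample_type`, `mean_ria`, `sd_ria`,
#'   `n_reps`.
#' @export
average_biological <- function(quant, value = "ria") {
  q <- as.data.table(quant)
  q[, .(mean_ria = mean(.SD[[1L]]),
        sd_ria = if (.N > 1L) sd(.SD[[1L]]) else NA_real_,
        n_reps = .N),
    by = .(accession, sample_type), .SDcols = value]
}
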