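#' Run the quantification pipeline
#'
#' Chains the stages from per-scan detections to normalized protein
#' quantifications: feature building, SILAC pair matching, identification
#' attachment, AMT database construction with presence/RT filters,
#' technical-replicate merging, peptide-to-protein rollup with outlier
#' trimming, per-sample ratio-space normalization, and orientation of
#' reverse-labeled samples for the statistics path.
#'
#' @param detections Per-scan detection table (see [build_features()]).
#' @param ids Identification table (see [attach_ids()]).
#' @param manifest Run manifest (run_id, sample_type, orientation,
#'   bio_rep, tech_rep).
#' @param ppm_tol Instrument mass accuracy (ppm) used for feature
#'   building, pair matching, id attachment and replicate merging.
#' @param rt_tol RT tolerance (min) for id attachment and merging.
#' @param pair_par A [pair_params()].
#' @param filter_par A [filter_params()].
#' @param normalize_level `"protein"` (default) normalizes protein RIAs
#'   per sample; `"peptide"` normalizes peptide RIAs before rollup.
#' @param trim Apply peptide outlier trimming during rollup?
#' @return List of class `silac_quant`: `samples` (protein x sample long
#'   table with raw, normalized and oriented RIA), `amt` (filtered,
#'   merged database), `normalization` (per-sample results), `n_features`,
#'   `n_pairs`, and the manifest.
#' @export
quantify_experiment <- function(detections, ids, manifest,
                                ppm_tol = 5, rt_tol = 5,
                                pair_par = pair_params(ppm_tol = ppm_tol),
                                filter_par = filter_params(),
                                normalize_level = c("protein", "peptide"),
                                trim = TRUE) {
  normalize_level <- match.arg(normalize_level)
  manifest <- as.data.table(manifest)

  feats <- build_features(detections, ppm_tol = ppm_tol)
  n_features <- nrow(feats)
  pairs <- match_pairs(feats, pair_par)
  rm(feats)
  labeled <- attach_ids(pairs, ids, ppm_tol = ppm_tol, rt_tol = rt_tol)
  n_pairs <- nrow(pairs)
  rm(pairs)
  amt <- build_amt(labeled, manifest)
  amt <- filter_amt(amt, filter_par)
  amt <- merge_technical(amt, ppm_tol = ppm_tol, rt_tol = rt_tol)

  obs <- amt$entries[, .(sequence, charge, accession)][
    amt$obs, on = c("sequence", "charge")]

  norm_results <- list()
  normalize_by_sample <- function(dt, col) {
    dt[, sample_key := paste(sample_type, bio_rep, sep = "_b")]
    dt[, ria_norm := NA_real_]
    for (k in sort(unique(dt$sample_key))) {
      idx <- which(dt$sample_key == k)
      ns <- normalize_sample(dt[[col]][idx])
      set(dt, idx, "ria_norm", ns$ria)
      norm_results[[k]] <<- ns$result
    }
    dt[, sample_key := NULL]
    dt
  }
  if (normalize_level == "peptide") {
    obs <- normalize_by_sample(obs, "ria")
    quant <- rollup_proteins(
      obs[, .(accession, sample_type, orientation, bio_rep,
              ria = ria_norm)], trim = trim)
    setnames(quant, "ria", "ria_norm")
    raw <- rollup_proteins(obs, trim = trim)
    quant[, ria_raw := raw$ria]
  } else {
    quant <- rollup_proteins(obs, trim = trim)
    setnames(quant, "ria", "ria_raw")
    quant <- normalize_by_sample(quant, "ria_raw")
  }
  quant[, ria_oriented := orient_ria(ria_norm, orientation)]
  quant[, is_mixed := sample_type %in%
          sample_design()[is_mixed == TRUE, sample_type]]

  structure(list(samples = quant[], amt = amt,
                 normalization = norm_results,
                 n_features = n_features, n_pairs = n_pairs,
                 manifest = manifest),
            class = "silac_quant")
}

#' @export
print.silac_quant <- function(x, ...) {
  cat(sprintf(
    "silac_quant: %d proteins x %d samples (%d pairs matched)\n",
    length(unique(x$samples$accession)),
    nrow(unique(x$samples[, c("sample_type", "bio_rep")])), x$n_pairs))
  invisible(x)
}

#' Differential expression between mixed and control samples
#'
#' Per protein, compares the oriented normalized RIAs of the mixed
#' samples against the control samples by two-group one-way ANOVA,
#' subject to the inclusion rule (at least `min_mixed` of the mixed and
#' `min_control` of the control replicate-samples observed). The fold
#' cutoff is derived from the pooled control distribution at the given
#' confidence, and both screens (p-value and fold) are applied.
#'
#' @param quant A `silac_quant` from [quantify_experiment()].
#' @param alpha ANOVA significance level (default 0.01).
#' @param confidence Confidence for the control-derived fold cutoff
#'   (default 0.99).
#' @param min_mixed,min_control Inclusion rule (default 3 of 6 each).
#' @return List of class `silac_diff`: `results` (per-protein table with
#'   F, p, mean mixed RIA, signed fold and flags), `cutoff` (the
#'   `cutoff_result`) and `summary` (significance counts).
#' @export
differential_expression <- function(quant, alpha = 0.01,
                                    confidence = 0.99,
                                    min_mixed = 3, min_control = 3) {
  stopifnot(inherits(quant, "silac_quant"))
  s <- quant$samples

  res <- s[, {
    mixed <- ria_oriented[is_mixed]
    ctrl <- ria_oriented[!is_mixed]
    if (length(mixed) >= min_mixed && length(ctrl) >= min_control) {
      a <- anova_protein(mixed, ctrl)
      .(n_mixed = length(mixed), n_control = length(ctrl),
        mean_mixed_ria = mean(mixed), sd_mixed_ria = sd(mixed),
        F = a$F, p = a$p, degenerate = a$degenerate)
    } else NULL
  }, by = accession]
  if (nrow(res) == 0L)
    stop("no protein satisfies the inclusion rule", call. = FALSE)
  res[, fold := ria_to_fold(mean_mixed_ria)]

  ctrl_pool <- s[is_mixed == FALSE, ria_oriented]
  cutoff <- control_cutoff(ctrl_pool, confidence = confidence)
  res <- call_significant(res, alpha = alpha, cutoff = cutoff)
  structure(list(results = res, cutoff = cutoff,
                 summary = attr(res, "summary")),
            class = "silac_diff")
}

#' @export
print.silac_diff <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("silac_diff: %d proteins tested; %d with p < alpha ",
           "(%d up, %d down); %d pass both screens (%d up, %d down)\n"),
    s$n, s$n_pass_p, s$n_up_p, s$n_down_p,
    s$n_significant, s$n_up, s$n_down))
  print(x$cutoff)
  invisible(x)
}

#' Protein x sample RIA matrices for heat-map export
#'
#' Builds the replicate-level matrix (one column per sample_type x
#' biological replicate, 12 columns in the default design) and the
#' averaged matrix (one column per sample type) from a `silac_quant`,
#' in raw (unflipped) orientation.
#'
#' @param quant A `silac_quant`.
#' @param value Which value to use (default `"ria_norm"`).
#' @return List with `replicate` and `averaged` matrices.
#' @export
ria_matrices <- function(quant, value = "ria_norm") {
  s <- as.data.table(quant$samples)
  type_order <- sample_design()$sample_type
  lev <- as.vector(t(outer(type_order, sort(unique(s$bio_rep)),
                           function(a, b) paste(a, b, sep = "_b"))))
  s[, col := factor(paste(sample_type, bio_rep, sep = "_b"),
                    levels = lev)]
  rep_w <- dcast(s, accession ~ col, value.var = value, drop = FALSE)
  rep_m <- as.matrix(rep_w, rownames = "accession")
  avg <- s[, .(v = mean(.SD[[1L]])), by = .(accession, sample_type),
           .SDcols = value]
  avg[, sample_type := factor(sample_type, levels = type_order)]
  avg_w <- dcast(avg, accession ~ sample_type, value.var = "v",
                 drop = FALSE)
  avg_m <- as.matrix(avg_w, rownames = "accession")
  list(replicate = rep_m, averaged = avg_m)
}
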