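#' Trapezoidal integration of an elution trace
#'
#' @param trace A two-column data.frame/matrix of (rt, area) points, or a
#'   numeric vector of areas with an `rt` argument.
#' @return Integrated area. A single point returns its own area value.
#' @examples
#' integrate_area(data.frame(rt = c(0, 1, 2), area = c(0, 2, 0)))  # 2
#' @export
integrate_area <- function(trace) {
  trace <- as.data.frame(trace)
  if (nrow(trace) < 1L) stop("trace must have >= 1 point", call. = FALSE)
  rt <- trace[[1L]]
  a <- trace[[2L]]
  if (length(rt) == 1L) return(a)
  o <- order(rt)
  rt <- rt[o]
  a <- a[o]
  sum(diff(rt) * (head(a, -1L) + tail(a, -1L)) / 2)
}

#' Relative isotope abundance
#'
#' Area of the light isotope distribution divided by the summed light and
#' heavy areas; 0.5 means a 1:1 ratio.
#'
#' @param area_light,area_heavy Integrated channel areas (>= 0, not both 0).
#' @return RIA in \[0, 1\].
#' @examples
#' compute_ria(300, 100)  # 0.75
#' @export
compute_ria <- function(area_light, area_heavy) {
  if (any(area_light < 0) || any(area_heavy < 0))
    stop("areas must be >= 0", call. = FALSE)
  tot <- area_light + area_heavy
  if (any(tot == 0))
    stop("RIA undefined when both areas are zero", call. = FALSE)
  area_light / tot
}

#' Build persistent features from per-scan detections
#'
#' Rows of the same run and charge whose masses agree within `ppm_tol` and
#' that occur in consecutive scans (allowing up to `max_scan_gap` missing
#' scans) are merged into one chromatographic feature. Clustering is the
#' connected-component (transitive) closure of the pairwise relation
#' "within ppm tolerance AND within scan gap"; the scan index of a
#' detection is the rank of its RT among the run's distinct RTs. Feature
#' mass is the area-weighted mean; feature area is the trapezoidal
#' integral of the trace.
#'
#' @param detections data.frame/data.table with columns `run_id`, `rt_min`,
#'   `mono_mass_da`, `charge`, `area`.
#' @param ppm_tol Mass tolerance (ppm) between member detections.
#' @param max_scan_gap Number of missing scans bridged (default 1).
#' @param keep_trace Keep the per-feature trace as a list column?
#' @return data.table of features: `feature_id`, `run_id`, `charge`,
#'   `mass`, `rt_apex`, `rt_start`, `rt_end`, `area`, `n_scans` (and
#'   `trace` if requested).
#' @export
build_features <- function(detections, ppm_tol = 5, max_scan_gap = 1,
                           keep_trace = FALSE) {
  det <- as.data.table(detections)
  empty <- data.table(feature_id = integer(), run_id = character(),
                      charge = integer(), mass = numeric(),
                      rt_apex = numeric(), rt_start = numeric(),
                      rt_end = numeric(), area = numeric(),
                      n_scans = integer())
  if (nrow(det) == 0L) return(empty)
  need <- c("run_id", "rt_min", "mono_mass_da", "charge", "area")
  if (!all(need %in% names(det)))
    stop("detections must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  det <- det[, ..need]
  # one run at a time keeps the join memory bounded
  runs <- unique(det$run_id)
  feats <- rbindlist(lapply(runs, function(r)
    build_features_run(det[run_id == r], ppm_tol, max_scan_gap,
                       keep_trace)))
  setorder(feats, run_id, charge, rt_apex, mass)
  feats[, feature_id := .I]
  setcolorder(feats, c("feature_id", "run_id", "charge", "mass",
                       "rt_apex", "rt_start", "rt_end", "area", "n_scans"))
  feats[]
}

# Connected-component clustering of one run's detections under the
# "within ppm AND within scan gap" relation. Returns cluster ids aligned
# with the input row order.
cluster_detections <- function(det, ppm_tol, max_scan_gap) {
  det <- as.data.table(det)[, .(rt_min, mono_mass_da, charge)]  # copy
  det[, det_id := .I]
  det[, scan := frank(rt_min, ties.method = "dense")]

  # candidate edges: same charge, scan offset 0..max_scan_gap+1, masses
  # within ppm of each other (relative to the larger mass)
  setkey(det, charge, scan)
  edges <- rbindlist(lapply(0:(max_scan_gap + 1L), function(o) {
    shifted <- det[, .(charge, scan = scan + o,
                       det_id2 = det_id, mass2 = mono_mass_da)]
    hit <- det[shifted, on = c("charge", "scan"),
               nomatch = NULL, allow.cartesian = TRUE]
    if (o == 0L) hit <- hit[det_id < det_id2]
    hit[abs(mono_mass_da - mass2) <=
          ppm_tol * 1e-6 * pmax(mono_mass_da, mass2),
        .(from = det_id, to = det_id2)]
  }))

  if (nrow(edges)) {
    g <- igraph::make_graph(rbind(edges$from, edges$to), n = nrow(det),
                            directed = FALSE)
    igraph::components(g)$membership
  } else seq_len(nrow(det))
}

build_features_run <- function(det, ppm_tol, max_scan_gap, keep_trace) {
  det[, cluster := cluster_detections(det, ppm_tol, max_scan_gap)]
  setorder(det, cluster, rt_min)
  # area-weighted mass per cluster (plain mean if the trace has no area)
  mass_tab <- det[, .(mass = if (sum(area) > 0)
    sum(mono_mass_da * area) / sum(area) else mean(mono_mass_da)),
    by = cluster]
  # collapse same-scan members of one cluster before integrating
  tr <- det[, .(area = sum(area)),
            by = .(cluster, run_id, charge, rt_min)]
  feats <- tr[, .(
    rt_apex = rt_min[which.max(area)],
    rt_start = rt_min[1L], rt_end = rt_min[.N],
    area = if (.N == 1L) area else
      sum(diff(rt_min) * (head(area, -1L) + tail(area, -1L)) / 2),
    n_scans = .N
  ), by = .(cluster, run_id, charge)]
  feats <- mass_tab[feats, on = "cluster"]
  if (keep_trace) {
    traces <- det[, .(trace = list(data.frame(rt = rt_min, area = area))),
                  by = cluster]
    feats <- traces[feats, on = "cluster"]
  }
  feats[, cluster := NULL]
  feats[]
}

#' Pair-matching parameters
#'
#' @param ppm_tol Mass tolerance (ppm, relative to the heavy mass) between
#'   the observed light-heavy mass difference and a shift-class delta.
#'   Default 5 ppm, the instrument-accuracy figure reused throughout the
#'   pipeline.
#' @param min_rt_overlap Required RT overlap as a fraction of the shorter
#'   feature's span (default 0.5).
#' @param classes Shift-class table from [shift_classes()].
#' @return List of class `pair_params`.
#' @export
pair_params <- function(ppm_tol = 5, min_rt_overlap = 0.5,
                        classes = shift_classes()) {
  if (ppm_tol <= 0) stop("ppm_tol must be > 0", call. = FALSE)
  if (min_rt_overlap <= 0 || min_rt_overlap > 1)
    stop("min_rt_overlap must lie in (0, 1]", call. = FALSE)
  structure(list(ppm_tol = ppm_tol, min_rt_overlap = min_rt_overlap,
                 classes = classes), class = "pair_params")
}

#' Match SILAC light/heavy feature pairs
#'
#' For each ordered (light, heavy) candidate with equal charge in the same
#' run, the observed mass difference must fall within `ppm_tol` (relative
#' to the heavy mass) of exactly one shift-class delta, and the two
#' features must co-elute (RT interval overlap of at least
#' `min_rt_overlap` of the shorter span; a zero-length span must fall
#' inside the partner's interval). Conflicts are resolved one-to-one by a
#' global greedy pass on ascending absolute ppm error, then RT-apex
#' distance, so every feature joins at most one pair. Candidates matching
#' two class deltas at once are rejected and counted in the
#' `"ambiguous_dropped"` attribute.
#'
#' @param features Feature table from [build_features()] (one or more
#'   runs; pairing never crosses runs).
#' @param params A [pair_params()].
#' @return data.table of pairs: run_id, charge, light/heavy feature ids,
#'   masses, `class`, `ppm_error` (signed), `rt_apex`, areas and `ria`.
#' @export
match_pairs <- function(features, params = pair_params()) {
  f <- as.data.table(features)
  empty <- data.table(run_id = character(), charge = integer(),
                      light_id = integer(), heavy_id = integer(),
                      mass_light = numeric(), mass_heavy = numeric(),
                      class = character(), ppm_error = numeric(),
                      rt_apex = numeric(), area_light = numeric(),
                      area_heavy = numeric(), ria = numeric())
  if (nrow(f) == 0L) return(empty)
  cls <- params$classes
  setorder(f, run_id, charge, mass)

  cand <- rbindlist(lapply(seq_len(nrow(cls)), function(ci) {
    delta <- cls$delta[ci]
    heavy <- f[, .(run_id, charge,
                   mass_target = mass - delta,
                   heavy_id = feature_id, mass_heavy = mass,
                   rt_apex_h = rt_apex, rt_start_h = rt_start,
                   rt_end_h = rt_end, area_heavy = area)]
    tol <- params$ppm_tol * 1e-6 * heavy$mass_heavy
    heavy[, `:=`(lo = mass_target - tol, hi = mass_target + tol)]
    hit <- f[heavy, on = .(run_id, charge, mass >= lo, mass <= hi),
             nomatch = NULL, allow.cartesian = TRUE,
             .(run_id, charge, light_id = feature_id,
               mass_light = x.mass, heavy_id, mass_heavy,
               rt_apex_l = x.rt_apex, rt_start_l = x.rt_start,
               rt_end_l = x.rt_end, area_light = x.area,
               rt_apex_h, rt_start_h, rt_end_h, area_heavy)]
    if (nrow(hit)) hit[, class := cls$label[ci]]
    hit
  }), fill = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[light_id != heavy_id]

  # reject candidates whose mass difference matches two classes at once
  dup <- cand[, .N, by = .(light_id, heavy_id)][N > 1L]
  n_ambi <- nrow(dup)
  if (n_ambi)
    cand <- cand[!dup, on = c("light_id", "heavy_id")]

  # co-elution
  ov <- pmin(cand$rt_end_l, cand$rt_end_h) -
    pmax(cand$rt_start_l, cand$rt_start_h)
  span <- pmin(cand$rt_end_l - cand$rt_start_l,
               cand$rt_end_h - cand$rt_start_h)
  keep <- ifelse(span > 0, ov / span >= params$min_rt_overlap, ov >= 0)
  cand <- cand[keep]
  if (nrow(cand) == 0L) {
    setattr(empty, "ambiguous_dropped", n_ambi)
    return(empty)
  }

  deltas <- setNames(cls$delta, cls$label)
  cand[, ppm_error := (mass_heavy - mass_light - deltas[class]) /
         mass_heavy * 1e6]
  cand[, apex_dist := abs(rt_apex_h - rt_apex_l)]
  cand <- cand[order(abs(ppm_error), apex_dist, light_id, heavy_id)]

  # greedy one-to-one assignment
  used <- logical(max(cand$light_id, cand$heavy_id))
  take <- logical(nrow(cand))
  li <- cand$light_id
  hi <- cand$heavy_id
  for (i in seq_len(nrow(cand))) {
    if (!used[li[i]] && !used[hi[i]]) {
      take[i] <- TRUE
      used[li[i]] <- TRUE
      used[hi[i]] <- TRUE
    }
  }
  out <- cand[take]
  out <- out[area_light + area_heavy > 0]
  out[, ria := area_light / (area_light + area_heavy)]
  out[, rt_apex := (rt_apex_l + rt_apex_h) / 2]
  out <- out[, .(run_id, charge, light_id, heavy_id, mass_light,
                 mass_heavy, class, ppm_error, rt_apex,
                 area_light, area_heavy, ria)]
  setorder(out, run_id, charge, mass_light)
  setattr(out, "ambiguous_dropped", n_ambi)
  out[]
}
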