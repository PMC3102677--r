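#' AMT filter parameters
#'
#' Exclusion rules for accurate-mass-and-time database entries: minimum
#' presence across runs, maximum retention-time span, and excluded RT
#' windows (column wash at the head of the run and post-gradient
#' re-equilibration by default).
#'
#' @param min_presence Minimum fraction of runs with an observation
#'   (default 0.25, i.e. present in at least 25% of the analyzed runs).
#' @param max_rt_span Maximum allowed spread (min) of a peptide's RTs
#'   across runs (default 10).
#' @param excluded_rt_windows List of `c(start, end)` RT windows (min);
#'   entries whose mean RT falls inside any window are excluded. Defaults
#'   to the 0-10 min wash and everything past the 120-min gradient.
#' @return List of class `filter_params`.
#' @export
filter_params <- function(min_presence = 0.25, max_rt_span = 10,
                          excluded_rt_windows = list(c(0, 10),
                                                     c(120, Inf))) {
  if (min_presence <= 0 || min_presence > 1)
    stop("min_presence must lie in (0, 1]", call. = FALSE)
  if (max_rt_span <= 0) stop("max_rt_span must be > 0", call. = FALSE)
  structure(list(min_presence = min_presence, max_rt_span = max_rt_span,
                 excluded_rt_windows = excluded_rt_windows),
            class = "filter_params")
}

#' Attach peptide identifications to SILAC pairs
#'
#' An identification is attached to the pair (same run) whose light or
#' heavy mass matches the identified mass within `ppm_tol` and whose RT
#' apex lies within `rt_tol` of the identification's RT. When several
#' pairs qualify, the nearest in ppm wins; exact ppm ties go to the nearer
#' RT. At most one identification per (pair, sequence) is kept (the
#' highest-scoring one).
#'
#' @param pairs Pair table from [match_pairs()] (any number of runs).
#' @param ids Identification table with columns `sequence`, `charge`,
#'   `mono_mass_da`, `rt_min`, `score`, `accession`, `run_id`.
#' @param ppm_tol Mass tolerance (ppm). Default 5.
#' @param rt_tol RT tolerance (min). Default 5.
#' @return data.table of labeled pairs: the pair columns plus `sequence`,
#'   `accession`, `score`, `id_ppm_error`, `matched_channel`.
#' @export
attach_ids <- function(pairs, ids, ppm_tol = 5, rt_tol = 5) {
  p <- as.data.table(pairs)
  i <- as.data.table(ids)
  empty <- cbind(p[0L], data.table(sequence = character(),
                                   accession = character(),
                                   score = numeric(),
                                   id_ppm_error = numeric(),
                                   matched_channel = character()))
  if (nrow(p) == 0L || nrow(i) == 0L) return(empty)
  i <- i[, .(sequence, charge, id_mass = mono_mass_da, id_rt = rt_min,
             score, accession, run_id, id_idx = .I)]
  i[, `:=`(rt_lo = id_rt - rt_tol, rt_hi = id_rt + rt_tol)]
  p2 <- p[, .(run_id, charge, light_id, heavy_id, mass_light, mass_heavy,
              rt_apex)]
  hit <- p2[i, on = .(run_id, charge, rt_apex >= rt_lo, rt_apex <= rt_hi),
            nomatch = NULL, allow.cartesian = TRUE,
            .(run_id, charge, light_id, heavy_id, mass_light, mass_heavy,
              pair_rt = x.rt_apex, sequence, id_mass, id_rt, score,
              accession, id_idx)]
  if (nrow(hit) == 0L) return(empty)
  hit[, ppm_l := (id_mass - mass_light) / mass_light * 1e6]
  hit[, ppm_h := (id_mass - mass_heavy) / mass_heavy * 1e6]
  hit[, matched_channel := fifelse(abs(ppm_l) <= abs(ppm_h),
                                   "light", "heavy")]
  hit[, id_ppm_error := fifelse(matched_channel == "light", ppm_l, ppm_h)]
  hit <- hit[abs(id_ppm_error) <= ppm_tol]
  if (nrow(hit) == 0L) return(empty)
  # one pair per identification: nearest ppm, then nearest RT
  hit[, rt_dist := abs(pair_rt - id_rt)]
  hit <- hit[order(id_idx, abs(id_ppm_error), rt_dist, light_id)]
  hit <- hit[, .SD[1L], by = id_idx]
  # at most one id per (pair, sequence): keep the best-scoring
  setorder(hit, light_id, heavy_id, sequence, -score)
  hit <- unique(hit, by = c("light_id", "heavy_id", "sequence"))
  out <- p[hit[, .(light_id, heavy_id, run_id, sequence, accession, score,
                   id_ppm_error, matched_channel)],
           on = c("run_id", "light_id", "heavy_id")]
  setorder(out, run_id, charge, mass_light)
  out[]
}

#' Build the accurate-mass-and-time database
#'
#' One entry per identified (sequence, charge): aggregates observed light
#' masses, RT apexes and per-run RIAs across all runs, and records the
#' presence fraction (runs with an observation over all analyzed runs) and
#' RT span. Peptides mapping to multiple accessions are assigned to the
#' accession of their highest-scoring identification.
#'
#' @param labeled Labeled pair table from [attach_ids()] (all runs).
#' @param manifest Run manifest (`run_id`, `sample_type`, `orientation`,
#'   `bio_rep`, `tech_rep`); defines the presence denominator.
#' @param carbamidomethyl Passed to [monoisotopic_mass()] for theoretical
#'   masses.
#' @return List of class `amt_db` with `entries` (sequence, charge,
#'   accession, theo_mass, obs_mass, mean_rt, rt_span, n_runs, presence)
#'   and `obs` (one row per entry per run: ria, mass, rt).
#' @export
build_amt <- function(labeled, manifest, carbamidomethyl = TRUE) {
  lab <- as.data.table(labeled)
  man <- as.data.table(manifest)
  n_runs_total <- nrow(man)
  if (nrow(lab) == 0L) stop("no labeled pairs", call. = FALSE)

  # duplicate observations of one (sequence, charge) within a run are
  # averaged before anything else
  obs <- lab[, .(ria = mean(ria), mass = mean(mass_light),
                 rt = mean(rt_apex), score = max(score),
                 accession = accession[which.max(score)]),
             by = .(sequence, charge, run_id)]
  entries <- obs[, .(
    accession = accession[which.max(score)],
    obs_mass = mean(mass),
    mean_rt = mean(rt),
    rt_span = max(rt) - min(rt),
    n_runs = .N,
    presence = .N / n_runs_total
  ), by = .(sequence, charge)]
  entries[, theo_mass := monoisotopic_mass(sequence, carbamidomethyl)]
  setcolorder(entries, c("sequence", "charge", "accession", "theo_mass",
                         "obs_mass", "mean_rt", "rt_span", "n_runs",
                         "presence"))
  obs[, c("score", "accession") := NULL]
  structure(list(entries = entries[], obs = obs[], manifest = man,
                 merged = FALSE),
            class = "amt_db")
}

#' @export
print.amt_db <- function(x, ...) {
  cat(sprintf("AMT database: %d entries, %d observations (%s)\n",
              nrow(x$entries), nrow(x$obs),
              if (x$merged) "technical replicates merged" else "per run"))
  invisible(x)
}

#' Filter AMT entries
#'
#' Drops entries that (1) are present in fewer than `min_presence` of the
#' analyzed runs, (2) have RTs varying by more than `max_rt_span` minutes,
#' or (3) have a mean RT inside an excluded (wash / re-equilibration)
#' window. Per-rule drop counts (an entry can violate several rules) are
#' returned in the `"drop_counts"` attribute. Filtering is idempotent.
#'
#' @param amt An `amt_db` from [build_amt()].
#' @param params A [filter_params()].
#' @return The filtered `amt_db`.
#' @export
filter_amt <- function(amt, params = filter_params()) {
  stopifnot(inherits(amt, "amt_db"))
  e <- amt$entries
  low_presence <- e$presence < params$min_presence
  wide_rt <- e$rt_span > params$max_rt_span
  in_window <- rep(FALSE, nrow(e))
  for (w in params$excluded_rt_windows)
    in_window <- in_window | (e$mean_rt >= w[1] & e$mean_rt <= w[2])
  drop <- low_presence | wide_rt | in_window
  out <- amt
  out$entries <- e[!drop]
  out$obs <- amt$obs[out$entries[, .(sequence, charge)],
                     on = c("sequence", "charge")]
  structure(out, class = "amt_db",
            drop_counts = c(presence = sum(low_presence),
                            rt_span = sum(wide_rt),
                            rt_window = sum(in_window)))
}

#' Merge technical replicates
#'
#' Within each (sample_type, bio_rep) preparation, observations of the
#' same entry from the technical duplicates are merged into a single
#' record (arithmetic mean of RIA, mass and RT) provided their masses
#' agree within `ppm_tol` and their RTs within `rt_tol`; otherwise the
#' replicates are kept as separate records and counted in the
#' `"unmerged"` attribute. Merging never changes the set of (sequence,
#' charge) entries, only the per-entry observation count.
#'
#' @param amt An `amt_db` (typically after [filter_amt()]).
#' @param ppm_tol Mass agreement tolerance (ppm). Default 5.
#' @param rt_tol RT agreement tolerance (min). Default 5.
#' @return The `amt_db` with `obs` keyed by (sample_type, bio_rep) instead
#'   of run, and `merged = TRUE`.
#' @export
merge_technical <- function(amt, ppm_tol = 5, rt_tol = 5) {
  stopifnot(inherits(amt, "amt_db"))
  man <- amt$manifest
  obs <- man[, .(run_id, sample_type, orientation, bio_rep, tech_rep)][
    amt$obs, on = "run_id"]
  grp <- obs[, {
    ok <- .N >= 2L &&
      (max(mass) - min(mass)) <= ppm_tol * 1e-6 * max(mass) &&
      (max(rt) - min(rt)) <= rt_tol
    if (.N == 1L || ok) {
      .(ria = mean(ria), mass = mean(mass), rt = mean(rt),
        n_tech = .N, merged_ok = TRUE)
    } else {
      .(ria = ria, mass = mass, rt = rt, n_tech = 1L, merged_ok = FALSE)
    }
  }, by = .(sequence, charge, sample_type, orientation, bio_rep)]
  out <- amt
  out$obs <- grp
  out$merged <- TRUE
  structure(out, class = "amt_db",
            unmerged = sum(!grp$merged_ok))
}
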