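#' Simulation configuration
#'
#' Parameters of the synthetic SILAC experiment generator. The defaults
#' describe a desk-scale version of a forward/reverse mixed design with two
#' self-mix controls, each in biological triplicate analyzed in technical
#' duplicate (24 LC-MS runs), 1:1 mixing, a minority of proteins truly
#' changed, ppm-scale mass error, minute-scale retention-time jitter and
#' random missing observations.
#'
#' @param n_proteins Number of simulated proteins.
#' @param seq_length Length range (residues) of simulated proteins.
#' @param frac_up,frac_down Fractions of proteins with true increased /
#'   decreased abundance in the resistant line; `frac_up + frac_down < 1`.
#' @param fold_location,fold_scale Location and scale (log space) of the
#'   true fold-change magnitude distribution; the default is a fixed 2-fold
#'   change (`exp(log(2))`, zero spread).
#' @param sigma_bio SD of per-biological-replicate log-ratio noise.
#' @param sigma_tech SD of per-technical-replicate, per-channel log-area
#'   noise.
#' @param ppm_sigma Mass-error scale (ppm) per observed channel.
#' @param rt_jitter SD (min) of the per-run retention-time shift.
#' @param rt_feature_jitter SD (min) of per-feature residual RT noise.
#' @param rt_range Usable elution window (min) for reference RTs; must lie
#'   inside the gradient.
#' @param detect_prob Per-run probability that a peptide pair is detected.
#' @param id_prob Probability that a detected pair receives an MS/MS
#'   identification in that run.
#' @param wash_frac Fraction of detections emitted as wash-phase artifacts
#'   (RT inside `wash_window`).
#' @param wash_window Column-wash window (min) at the head of each run.
#' @param gradient_end End of the analytical gradient (min).
#' @param total_time Total run length including re-equilibration (min).
#' @param scan_interval Full-scan interval (min); default 2 s.
#' @param peak_sd Range (min) of chromatographic peak SDs.
#' @param mz_window Acquired m/z window; features outside are dropped.
#' @param base_area_meanlog,base_area_sdlog Log-normal parameters of
#'   per-peptide base abundance.
#' @param n_bio,n_tech Biological and technical replicate counts.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 200,
                       seq_length = c(60, 120),
                       frac_up = 0.1, frac_down = 0.1,
                       fold_location = log(2), fold_scale = 0,
                       sigma_bio = 0.1, sigma_tech = 0.05,
                       ppm_sigma = 1.5,
                       rt_jitter = 0.5, rt_feature_jitter = 0.05,
                       rt_range = c(12, 115),
                       detect_prob = 0.7, id_prob = 0.6,
                       wash_frac = 0.01, wash_window = c(0, 10),
                       gradient_end = 120, total_time = 130,
                       scan_interval = 2 / 60,
                       peak_sd = c(0.1, 0.3),
                       mz_window = c(400, 1400),
                       base_area_meanlog = log(1e6),
                       base_area_sdlog = 0.5,
                       n_bio = 3, n_tech = 2,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down >= 1)
    stop("frac_up + frac_down must be < 1 with both >= 0", call. = FALSE)
  if (any(c(sigma_bio, sigma_tech, ppm_sigma, rt_jitter,
            rt_feature_jitter, fold_scale) < 0))
    stop("noise SDs must be >= 0", call. = FALSE)
  if (detect_prob <= 0 || detect_prob > 1 || id_prob <= 0 || id_prob > 1)
    stop("detect_prob and id_prob must lie in (0, 1]", call. = FALSE)
  if (rt_range[1] < 0 || rt_range[2] > gradient_end)
    stop("rt_range must lie within the gradient", call. = FALSE)
  if (wash_frac < 0 || wash_frac >= 1)
    stop("wash_frac must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# The four sample types of the mixing design. `orientation` says which
# population carries the light label in the statistics sense: forward =
# resistant light, reverse = resistant heavy; self-mix controls behave as
# forward (no flip).
sample_design <- function() {
  data.table(
    sample_type = c("mixed_fwd", "mixed_rev", "ctrl_cddp", "ctrl_hela"),
    orientation = c("forward", "reverse", "forward", "forward"),
    is_mixed    = c(TRUE, TRUE, FALSE, FALSE)
  )
}

# Amino-acid sampling weights; K/R at ~11% total gives tryptic peptides
# mostly 6-30 residues long.
AA_FREQ <- c(
  A = 0.08, R = 0.055, N = 0.04, D = 0.05, C = 0.02, E = 0.06, Q = 0.04,
  G = 0.07, H = 0.025, I = 0.05, L = 0.09, K = 0.055, M = 0.02, F = 0.04,
  P = 0.05, S = 0.07, T = 0.055, W = 0.01, Y = 0.03, V = 0.06
)

#' Simulate a ground-truthed proteome
#'
#' Draws random protein sequences, assigns each protein a true fold change
#' `rho` (resistant:parental abundance ratio, 1 for unchanged proteins),
#' digests the proteome and retains the pairing-eligible peptides (one or
#' two labeled K/R, inside the acquired m/z window at the assigned charge),
#' and lays out the 24-run manifest.
#'
#' @param config A [sim_config()].
#' @return A list of class `silac_proteome`: `fasta` (named character
#'   vector of sequences), `proteins` (accession, rho, direction),
#'   `peptides` (per-peptide theoretical masses, charge, reference RT, base
#'   abundance, peak SD), `manifest` (run_id, sample_type, orientation,
#'   bio_rep, tech_rep) and the `config`.
#' @export
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_proteins
  lens <- if (config$seq_length[1] == config$seq_length[2])
    rep(config$seq_length[1], n)
  else sample(config$seq_length[1]:config$seq_length[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = "")
  }, character(1L))
  acc <- sprintf("PROT%04d", seq_len(n))
  names(seqs) <- acc

  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  direction <- rep("unchanged", n)
  if (n_up > 0) direction[seq_len(n_up)] <- "up"
  if (n_down > 0) direction[n_up + seq_len(n_down)] <- "down"
  magnitude <- exp(rnorm(n, config$fold_location, config$fold_scale))
  magnitude <- pmax(magnitude, 1.05)   # a "changed" protein really changes
  rho <- fifelse(direction == "up", magnitude,
                 fifelse(direction == "down", 1 / magnitude, 1))
  proteins <- data.table(accession = acc, rho = rho, direction = direction)

  scheme <- label_scheme()
  peps <- rbindlist(lapply(seq_len(n), function(i) {
    d <- digest(seqs[[i]], max_missed = 1, scheme = scheme)
    d$accession <- acc[i]
    d
  }))
  n_lab <- peps$n_labeled_K + peps$n_labeled_R
  peps <- peps[n_lab >= 1L & n_lab <= 2L & nchar(sequence) >= 6L]
  if (nrow(peps) == 0L)
    stop("no pairing-eligible peptides in the simulated proteome",
         call. = FALSE)
  # collapse duplicated sequences (identical tryptic peptides from two
  # proteins); keep the first accession, matching a shared-peptide pick
  peps <- peps[!duplicated(sequence)]
  peps[, charge := fifelse(nchar(sequence) <= 15L, 2L,
                           sample(2:3, .N, replace = TRUE))]
  inside <- function(m, z) {
    v <- mz(m, z)
    v >= config$mz_window[1] & v <= config$mz_window[2]
  }
  peps <- peps[inside(mass_light, charge) & inside(mass_heavy, charge)]
  if (nrow(peps) == 0L)
    stop("no simulated peptides fall inside the m/z window", call. = FALSE)
  peps[, ref_rt := runif(.N, config$rt_range[1], config$rt_range[2])]
  peps[, base_area := rlnorm(.N, config$base_area_meanlog,
                             config$base_area_sdlog)]
  peps[, peak_sd := runif(.N, config$peak_sd[1], config$peak_sd[2])]
  peps[, c("start", "end", "missed_cleavages") := NULL]

  des <- sample_design()
  manifest <- CJ(sample_type = des$sample_type,
                 bio_rep = seq_len(config$n_bio),
                 tech_rep = seq_len(config$n_tech))
  manifest <- des[manifest, on = "sample_type"]
  manifest[, run_id := sprintf("run_%s_b%d_t%d", sample_type,
                               bio_rep, tech_rep)]
  setcolorder(manifest, c("run_id", "sample_type", "orientation",
                          "bio_rep", "tech_rep"))

  structure(list(fasta = seqs, proteins = proteins, peptides = peps,
                 manifest = manifest[, !"is_mixed"], config = config),
            class = "silac_proteome")
}

#' Simulate an LC-MS SILAC experiment
#'
#' Emits, for every run of the manifest and every detected peptide, a light
#' and a heavy chromatographic elution profile as per-scan detection rows,
#' plus a subsampled identification table. The expected light fraction of a
#' pair encodes the protein's true ratio: with `rho' = rho * exp(bio noise)`
#' a forward mixed run has `E[light/(light+heavy)] = rho'/(1+rho')`, a
#' reverse run the complement, and self-mix controls are centered on 0.5.
#' Masses are perturbed on the ppm scale, RTs jittered per run, detections
#' dropped with probability `1 - detect_prob`, and a small fraction of
#' features is emitted inside the wash window to exercise the wash filter.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param config Optional override of `proteome$config`.
#' @return A list of class `silac_sim`: `detections` (run_id, rt_min,
#'   mono_mass_da, charge, area), `ids` (sequence, charge, mono_mass_da,
#'   rt_min, score, accession, run_id), `manifest`, `truth` (per
#'   peptide-run expected RIA and realized areas) plus the inputs.
#' @export
simulate_experiment <- function(proteome, config = proteome$config) {
  stopifnot(inherits(proteome, "silac_proteome"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  peps <- proteome$peptides
  prot <- proteome$proteins
  des <- sample_design()

  # biological noise: one draw per protein per preparation
  prep <- CJ(accession = prot$accession,
             sample_type = des$sample_type,
             bio_rep = seq_len(config$n_bio))
  prep <- prot[prep, on = "accession"]
  prep <- des[prep, on = "sample_type"]
  prep[, rho_true := fifelse(is_mixed, rho, 1)]
  prep[, rho_prime := rho_true * exp(rnorm(.N, 0, config$sigma_bio))]
  prep[, ria_expected := fifelse(orientation == "reverse",
                                 1 / (1 + rho_prime),
                                 rho_prime / (1 + rho_prime))]

  # per-run RT shift
  runs <- copy(proteome$manifest)
  runs[, rt_shift := rnorm(.N, 0, config$rt_jitter)]

  # peptide x run grid
  pep_cols <- peps[, .(sequence, accession, charge, mass_light,
                       mass_heavy, ref_rt, base_area, peak_sd)]
  np <- nrow(pep_cols)
  nr <- nrow(runs)
  obs <- cbind(pep_cols[rep(seq_len(np), each = nr)],
               runs[rep(seq_len(nr), times = np)])
  obs <- obs[rbinom(.N, 1L, config$detect_prob) == 1L]
  obs <- prep[, .(accession, sample_type, bio_rep, rho_prime, ria_expected)][
    obs, on = c("accession", "sample_type", "bio_rep")]

  # realized RT (run shift + residual jitter; occasional wash artifact)
  obs[, rt_run := ref_rt + rt_shift +
        rnorm(.N, 0, config$rt_feature_jitter)]
  wash <- runif(nrow(obs)) < config$wash_frac
  obs[wash, rt_run := runif(sum(wash), config$wash_window[1],
                            config$wash_window[2])]
  obs <- obs[rt_run > 0 & rt_run < config$total_time]

  # channel areas: nominal split by expected RIA, log-normal tech noise
  obs[, area_light := base_area * ria_expected *
        exp(rnorm(.N, 0, config$sigma_tech))]
  obs[, area_heavy := base_area * (1 - ria_expected) *
        exp(rnorm(.N, 0, config$sigma_tech))]
  obs[, mass_light_obs := mass_light *
        (1 + rnorm(.N, 0, config$ppm_sigma) * 1e-6)]
  obs[, mass_heavy_obs := mass_heavy *
        (1 + rnorm(.N, 0, config$ppm_sigma) * 1e-6)]
  obs[, obs_id := .I]

  detections <- emit_traces(obs, config)

  # identifications: subsample detected pairs; reported mass is the light
  # or heavy channel at random (Mascot reports the sequenced precursor)
  ids <- obs[runif(.N) < config$id_prob]
  pick_heavy <- runif(nrow(ids)) < 0.5
  ids <- ids[, .(
    sequence, charge,
    mono_mass_da = fifelse(pick_heavy, mass_heavy_obs, mass_light_obs),
    rt_min = rt_run + rnorm(.N, 0, 0.2),
    score = round(runif(.N, 25, 120), 1),
    accession, run_id
  )]

  truth <- obs[, .(sequence, accession, charge, run_id, sample_type,
                   orientation, bio_rep, tech_rep, rho_prime, ria_expected,
                   rt_run, area_light, area_heavy)]
  structure(list(detections = detections, ids = ids,
                 manifest = proteome$manifest, truth = truth,
                 proteins = prot, config = config),
            class = "silac_sim")
}

# Expand pair-level observations into per-scan Gaussian trace rows on the
# run's 2-s scan grid, truncated at +/- 2.5 peak SDs (the truncation is
# shared by both channels so it cancels in the RIA).
emit_traces <- function(obs, config) {
  dt <- config$scan_interval
  k1 <- pmax(0L, as.integer(ceiling((obs$rt_run - 2.5 * obs$peak_sd) / dt)))
  k2 <- pmin(as.integer(floor(config$total_time / dt)),
             as.integer(floor((obs$rt_run + 2.5 * obs$peak_sd) / dt)))
  npt <- pmax(k2 - k1 + 1L, 1L)
  idx <- rep.int(seq_len(nrow(obs)), npt)
  scan_k <- k1[idx] + (sequence(npt) - 1L)
  t_scan <- scan_k * dt
  dens <- dnorm(t_scan, obs$rt_run[idx], obs$peak_sd[idx])
  long <- data.table(
    obs_id = obs$obs_id[idx],
    run_id = obs$run_id[idx],
    rt_min = t_scan,
    charge = obs$charge[idx],
    light_h = obs$area_light[idx] * dens,
    heavy_h = obs$area_heavy[idx] * dens,
    mass_light_obs = obs$mass_light_obs[idx],
    mass_heavy_obs = obs$mass_heavy_obs[idx]
  )
  det <- rbind(
    long[, .(run_id, rt_min, mono_mass_da = mass_light_obs,
             charge, area = light_h)],
    long[, .(run_id, rt_min, mono_mass_da = mass_heavy_obs,
             charge, area = heavy_h)]
  )
  # sub-ppm per-scan mass wobble so feature building sees realistic scatter
  det[, mono_mass_da := mono_mass_da *
        (1 + rnorm(.N, 0, 0.3) * 1e-6)]
  setorder(det, run_id, rt_min, mono_mass_da)
  det[]
}
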