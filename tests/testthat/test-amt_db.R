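mk_pair <- function(light_id, mass_light, rt, run = "r1", z = 2L,
                    ria = 0.5) {
  data.table::data.table(
    run_id = run, charge = z, light_id = light_id,
    heavy_id = light_id + 1000L, mass_light = mass_light,
    mass_heavy = mass_light + 8.0142036, class = "K",
    ppm_error = 0, rt_apex = rt, area_light = ria * 2e5,
    area_heavy = (1 - ria) * 2e5, ria = ria)
}

mk_id <- function(seq, mass, rt, run = "r1", z = 2L, score = 50,
                  acc = "P1") {
  data.table::data.table(sequence = seq, charge = z, mono_mass_da = mass,
                         rt_min = rt, score = score, accession = acc,
                         run_id = run)
}

test_that("identification attachment honors both tolerances", {
  p <- mk_pair(1L, 1000.000000, 40.2)
  # within 5 ppm and 5 min: attached
  out <- attach_ids(p, mk_id("SEQK", 1000.000003, 40.0))
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, "SEQK")
  expect_equal(out$matched_channel, "light")
  # heavy-channel id attaches too
  out_h <- attach_ids(p, mk_id("SEQK", 1008.014204, 40.0))
  expect_equal(nrow(out_h), 1L)
  expect_equal(out_h$matched_channel, "heavy")
  # RT gap above 5 min: not attached
  expect_equal(nrow(attach_ids(p, mk_id("SEQK", 1000.000003, 52.0))), 0L)
  # mass off by 20 ppm: not attached
  expect_equal(nrow(attach_ids(p, mk_id("SEQK", 1000.02, 40.0))), 0L)
  # equal-ppm tie between two pairs goes to the nearer RT
  p2 <- rbind(mk_pair(1L, 1000, 42.0), mk_pair(3L, 1000, 40.5))
  tie <- attach_ids(p2, mk_id("SEQK", 1000, 40.0))
  expect_equal(tie$light_id, 3L)
})

test_that("attachment equals the nearest-neighbor oracle", {
  set.seed(17)
  for (i in 1:100) {
    np <- sample(3:10, 1)
    pairs <- do.call(rbind, lapply(seq_len(np), function(k)
      mk_pair(k * 2L, runif(1, 600, 1800), runif(1, 10, 110))))
    nid <- sample(3:10, 1)
    take <- sample(np, nid, replace = TRUE)
    ids <- do.call(rbind, lapply(seq_len(nid), function(k)
      mk_id(paste0("SEQ", k),
            pairs$mass_light[take[k]] *
              (1 + rnorm(1, 0, 3) * 1e-6),
            pairs$rt_apex[take[k]] + rnorm(1, 0, 3))))
    got <- attach_ids(pairs, ids)
    want <- oracle_attach(pairs, ids, ppm_tol = 5, rt_tol = 5)
    want_keys <- paste(ids$sequence[want$id_row], want$light_id)
    expect_setequal(paste(got$sequence, got$light_id),
                    unique(want_keys))
  }
})

manifest24 <- function() {
  pr <- simulate_proteome(sim_config(n_proteins = 2, seed = 1))
  pr$manifest
}

test_that("AMT entries aggregate presence, RT span and accession", {
  man <- manifest24()
  runs <- man$run_id
  lab <- data.table::rbindlist(lapply(runs[1:12], function(r) {
    p <- mk_pair(1L, 1000, 40 + as.numeric(factor(r, levels = runs)) / 10,
                 run = r)
    cbind(p, data.table::data.table(sequence = "AAAK", accession = "P1",
                                    score = 50, id_ppm_error = 0,
                                    matched_channel = "light"))
  }))
  # a second peptide seen once, shared accession decided by score
  one <- cbind(mk_pair(5L, 1200, 60, run = runs[1]),
               data.table::data.table(sequence = "CCCK", accession = "P2",
                                      score = 90, id_ppm_error = 0,
                                      matched_channel = "light"))
  amt <- build_amt(rbind(lab, one), man)
  e <- amt$entries
  expect_equal(nrow(e), 2L)
  expect_equal(e[e$sequence == "AAAK", ]$presence, 0.5)   # 12/24
  expect_equal(e[e$sequence == "CCCK", ]$rt_span, 0)      # single obs
  expect_equal(e[e$sequence == "CCCK", ]$accession, "P2")
})

test_that("the three exclusion rules drop exactly the intended entries", {
  man <- manifest24()
  runs <- man$run_id
  mk_lab <- function(seqs, n_runs, rts, mass = 1000) {
    data.table::rbindlist(lapply(seq_len(n_runs), function(k) {
      cbind(mk_pair(1L, mass, rts[min(k, length(rts))], run = runs[k]),
            data.table::data.table(sequence = seqs, accession = "P1",
                                   score = 50, id_ppm_error = 0,
                                   matched_channel = "light"))
    }))
  }
  lab <- rbind(
    mk_lab("GGDPEPK", 12, rts = 40 + (1:12) / 10),       # survives
    mk_lab("RAREPEPK", 5, rts = 50 + (1:5) / 10),        # presence 5/24 < 0.25
    mk_lab("DRIFTPEPK", 12, rts = seq(30, 42, length.out = 12)), # span 12 > 10
    mk_lab("WASHPEPK", 12, rts = 6 + (1:12) / 50)        # mean rt in wash
  )
  amt <- build_amt(lab, man)
  filt <- filter_amt(amt)
  expect_setequal(filt$entries$sequence, "GGDPEPK")
  dc <- attr(filt, "drop_counts")
  expect_equal(unname(dc["presence"]), 1L)
  expect_equal(unname(dc["rt_span"]), 1L)
  expect_equal(unname(dc["rt_window"]), 1L)

  # idempotence and survivor predicates
  filt2 <- filter_amt(filt)
  expect_identical(filt2$entries, filt$entries)
  p <- filter_params()
  e <- filt$entries
  expect_true(all(e$presence >= p$min_presence))
  expect_true(all(e$rt_span <= p$max_rt_span))
  for (w in p$excluded_rt_windows)
    expect_false(any(e$mean_rt >= w[1] & e$mean_rt <= w[2]))
})

test_that("technical-replicate merging averages within tolerance", {
  man <- manifest24()
  # same preparation, two technical duplicates
  r1 <- man$run_id[man$sample_type == "mixed_fwd" & man$bio_rep == 1][1]
  r2 <- man$run_id[man$sample_type == "mixed_fwd" & man$bio_rep == 1][2]
  lab <- rbind(
    cbind(mk_pair(1L, 1000.000, 40.0, run = r1, ria = 0.60),
          data.table::data.table(sequence = "AAAK", accession = "P1",
                                 score = 50, id_ppm_error = 0,
                                 matched_channel = "light")),
    cbind(mk_pair(1L, 1000.002, 41.0, run = r2, ria = 0.64),
          data.table::data.table(sequence = "AAAK", accession = "P1",
                                 score = 50, id_ppm_error = 0,
                                 matched_channel = "light")))
  amt <- merge_technical(build_amt(lab, man))
  expect_equal(nrow(amt$obs), 1L)
  expect_equal(amt$obs$ria, 0.62)
  expect_equal(amt$obs$n_tech, 2L)

  # masses 11 ppm apart stay separate
  lab2 <- data.table::copy(lab)
  lab2$mass_light[2] <- 1000 * (1 + 11e-6)
  amt2 <- merge_technical(build_amt(lab2, man))
  expect_equal(nrow(amt2$obs), 2L)
  expect_equal(attr(amt2, "unmerged"), 2L)

  # merging never changes the entry set
  expect_identical(amt$entries[, c("sequence", "charge")],
                   amt2$entries[, c("sequence", "charge")])
})
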