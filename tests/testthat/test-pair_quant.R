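test_that("trapezoidal integration matches the oracle", {
  expect_equal(integrate_area(data.frame(rt = c(0, 1), area = c(1, 1))), 1)
  expect_equal(integrate_area(data.frame(rt = c(0, 1, 2),
                                         area = c(0, 2, 0))), 2)
  expect_equal(integrate_area(data.frame(rt = 3.2, area = 17)), 17)
  expect_error(integrate_area(data.frame(rt = numeric(),
                                         area = numeric())), ">= 1")
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    rt <- sort(runif(n, 0, 10))
    a <- runif(n, 0, 100)
    # independent oracle: adaptive quadrature of the linear interpolant,
    # segment by segment so the integrand is smooth on each call
    f <- approxfun(rt, a)
    orc <- sum(vapply(seq_len(n - 1), function(j)
      integrate(f, rt[j], rt[j + 1], rel.tol = 1e-12)$value, numeric(1)))
    expect_equal(integrate_area(data.frame(rt, a)), orc, tolerance = 1e-9)
  }
})

test_that("compute_ria follows its definition", {
  expect_equal(compute_ria(100, 100), 0.5)
  expect_equal(compute_ria(300, 100), 0.75)
  expect_equal(compute_ria(0, 100), 0)
  expect_error(compute_ria(0, 0), "undefined")
  expect_error(compute_ria(-1, 2), ">= 0")
})

make_trace_rows <- function(run, z, mass, rt0, n = 5, dt = 1 / 30,
                            area = NULL) {
  if (is.null(area)) area <- c(1, 3, 5, 3, 1)[seq_len(n)]
  data.frame(run_id = run, rt_min = rt0 + (seq_len(n) - 1) * dt,
             mono_mass_da = mass, charge = z, area = area)
}

test_that("build_features merges consecutive scans into one feature", {
  det <- make_trace_rows("r1", 2, 1000.0000, 20)
  det$mono_mass_da <- det$mono_mass_da * (1 + c(-2, 1, 0, -1, 2) * 1e-6)
  f <- build_features(det, ppm_tol = 5)
  expect_equal(nrow(f), 1L)
  expect_equal(f$rt_apex, det$rt_min[3])      # max-area scan
  expect_equal(f$n_scans, 5L)
  expect_true(f$rt_start <= f$rt_apex && f$rt_apex <= f$rt_end)
  expect_equal(f$area, integrate_area(det[, c("rt_min", "area")]))

  # same mass in two runs stays two features
  det2 <- rbind(make_trace_rows("r1", 2, 1000, 20),
                make_trace_rows("r2", 2, 1000, 20))
  expect_equal(nrow(build_features(det2, ppm_tol = 5)), 2L)

  # different charge never merges
  det3 <- rbind(make_trace_rows("r1", 2, 1000, 20),
                make_trace_rows("r1", 3, 1000, 20))
  expect_equal(nrow(build_features(det3, ppm_tol = 5)), 2L)

  expect_equal(nrow(build_features(det[0, ])), 0L)
})

test_that("clustering equals the transitive-closure oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    det <- data.frame(
      run_id = "r1",
      rt_min = sample(seq(0, 1, by = 1 / 30), n, replace = TRUE),
      mono_mass_da = 1000 * (1 + sample(-6:6, n, replace = TRUE) * 1e-6),
      charge = sample(2:3, n, replace = TRUE),
      area = runif(n, 1, 10))
    gap <- sample(0:2, 1)
    got <- silacquant:::cluster_detections(det, ppm_tol = 5,
                                           max_scan_gap = gap)
    want <- oracle_cluster(det, ppm_tol = 5, max_scan_gap = gap)
    expect_true(same_partition(got, want))
  }
})

test_that("pair matching recovers a constructed K pair and rejects decoys", {
  mk <- function(id, mass, rt0 = 30, z = 2L, area = 1e5) {
    data.frame(feature_id = id, run_id = "r1", charge = z, mass = mass,
               rt_apex = rt0, rt_start = rt0 - 0.5, rt_end = rt0 + 0.5,
               area = area, n_scans = 9L)
  }
  f <- rbind(mk(1, 1000.000000, area = 100), mk(2, 1008.014204, area = 300))
  p <- match_pairs(f)
  expect_equal(nrow(p), 1L)
  expect_equal(p$class, "K")
  expect_equal(p$ria, 100 / 400)
  expect_lt(abs(p$ppm_error), 0.1)

  # ~85 ppm off the K class: no pair
  f2 <- rbind(mk(1, 1000.0), mk(2, 1008.10))
  expect_equal(nrow(match_pairs(f2)), 0L)

  # co-elution violated: apexes 30 vs 40
  f3 <- rbind(mk(1, 1000.000000), mk(2, 1008.014204, rt0 = 40))
  expect_equal(nrow(match_pairs(f3)), 0L)

  # charge mismatch
  f4 <- rbind(mk(1, 1000.000000, z = 2L), mk(2, 1008.014204, z = 3L))
  expect_equal(nrow(match_pairs(f4)), 0L)
})

test_that("pair matching equals the exhaustive assignment oracle", {
  set.seed(11)
  params <- pair_params()
  for (i in 1:100) {
    f <- random_feature_instance(n_pairs = sample(3:10, 1),
                                 n_decoys = sample(5:15, 1))
    got <- match_pairs(f, params)
    want <- oracle_match_pairs(f, params)
    got <- as.data.frame(got[order(got$light_id),
                             c("light_id", "heavy_id", "class")])
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("pairing is one-to-one, order-invariant and ppm-monotone", {
  set.seed(23)
  for (i in 1:20) {
    f <- random_feature_instance(n_pairs = 6, n_decoys = 12,
                                 ppm_sigma = 2)
    p5 <- match_pairs(f, pair_params(ppm_tol = 5))
    # no feature in two pairs
    expect_false(any(duplicated(c(p5$light_id, p5$heavy_id))))
    # permuting the input rows gives the same pair set
    fp <- f[sample(nrow(f)), ]
    pp <- match_pairs(fp, pair_params(ppm_tol = 5))
    expect_setequal(paste(p5$light_id, p5$heavy_id),
                    paste(pp$light_id, pp$heavy_id))
    # shrinking the tolerance never adds pairs
    p2 <- match_pairs(f, pair_params(ppm_tol = 2))
    expect_true(all(paste(p2$light_id, p2$heavy_id) %in%
                      paste(p5$light_id, p5$heavy_id)))
  }
})
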