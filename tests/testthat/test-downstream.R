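test_that("BH adjustment equals the literal step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)              # single p: q = p
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # ties
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_equal(q, p.adjust(p, method = "BH"))   # second independent path
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_true(all(q <= 1 & q >= p - 1e-15))
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # closed-form spot check: N=10, K=5, n=4, k=4
  uni <- paste0("P", 1:10)
  ann <- list(T1 = uni[1:5])
  res <- enrich_terms(uni[1:4], ann, uni)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$k, 4L)

  # a term covering the whole universe is never enriched
  res2 <- enrich_terms(uni[1:4], list(ALL = uni), uni)
  expect_equal(res2$p, 1)

  # terms with no hit are skipped; target must be inside the universe
  res3 <- enrich_terms(uni[1:2], list(T1 = uni[5:6]), uni)
  expect_equal(nrow(res3), 0L)
  expect_error(enrich_terms("X99", list(T1 = uni[1:2]), uni), "subset")

  # exhaustive agreement with subset enumeration for all N <= 12
  for (N in c(5, 8, 12)) {
    u <- paste0("P", seq_len(N))
    for (K in c(1, ceiling(N / 2), N - 1)) {
      for (n in c(1, ceiling(N / 3), N - 1)) {
        ks <- max(1, n + K - N):min(n, K)
        for (k in ks) {
          p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
          target <- c(u[seq_len(k)], u[K + seq_len(n - k)])
          res <- enrich_terms(target, list(T = u[seq_len(K)]), u)
          expect_equal(res$p, p_pkg, tolerance = 1e-12)
          expect_equal(res$p, oracle_hyper(k, K, N, n), tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("hierarchical clustering equals the brute-force agglomerator", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    mat <- matrix(runif(n * 6), n, 6)
    rownames(mat) <- paste0("P", seq_len(n))
    linkage <- sample(c("average", "complete", "single"), 1)
    hc <- hcluster_ria(mat, metric = "euclidean", linkage = linkage)
    d <- silacquant:::pairwise_dist(mat, "euclidean")
    orc <- oracle_agglomerate(d, linkage)
    expect_equal(hc$height, orc$heights, tolerance = 1e-12)
    parts <- merge_partitions(hc$merge, n)
    for (s in seq_along(parts))
      expect_true(same_partition(parts[[s]], orc$partitions[[s]]))
  }
})

test_that("clustering handles identical rows, missing data and row order", {
  mat <- rbind(P1 = c(0.5, 0.6, 0.7, 0.4),
               P2 = c(0.5, 0.6, 0.7, 0.4),
               P3 = c(0.9, 0.1, 0.2, 0.8),
               P4 = c(0.2, 0.9, 0.8, 0.1))
  hc <- hcluster_ria(mat, metric = "euclidean")
  expect_equal(hc$height[1], 0)                 # identical rows merge first
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))

  # heights are non-decreasing (no inversions for these linkages)
  expect_true(all(diff(hc$height) >= -1e-12))

  # permutation invariance up to relabeling
  perm <- c(3, 1, 4, 2)
  hc2 <- hcluster_ria(mat[perm, ], metric = "euclidean")
  expect_equal(sort(hc2$height), sort(hc$height), tolerance = 1e-12)

  # pairwise-complete distances tolerate missing cells
  matna <- mat
  matna[1, 1] <- NA
  expect_s3_class(hcluster_ria(matna), "hclust")
  # a row with < 2 usable values is rejected with its index
  matbad <- mat
  matbad[2, 1:3] <- NA
  expect_error(hcluster_ria(matbad), "2")
  expect_error(hcluster_ria(mat[1, , drop = FALSE]), ">= 2 rows")
})

test_that("heat-map export writes matrix, ordering and image", {
  mat <- matrix(runif(40, 0.2, 0.8), 10, 4,
                dimnames = list(paste0("P", 1:10),
                                c("mixed_fwd", "mixed_rev",
                                  "ctrl_cddp", "ctrl_hela")))
  hc <- hcluster_ria(mat, metric = "euclidean")
  tsv <- tempfile(fileext = ".tsv")
  ordf <- tempfile(fileext = ".txt")
  png <- tempfile(fileext = ".png")
  ord <- export_heatmap(mat, hc, tsv, ordf, png)
  expect_equal(ord, hc$order)
  back <- read.delim(tsv)
  expect_equal(back$accession, rownames(mat)[hc$order])
  expect_equal(readLines(ordf), rownames(mat)[hc$order])
  expect_true(file.size(png) > 0)
  unlink(c(tsv, ordf, png))
})
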