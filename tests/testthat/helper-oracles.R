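# Independent brute-force oracles and small-instance generators used by
# the unit and acceptance tests. Each oracle re-implements the operation
# it checks from its definition, without touching the package internals.

library(data.table)

# ---- transitive-closure clustering oracle -------------------------------

# components of the relation: same charge AND scan gap <= max_scan_gap+1
# AND masses within ppm_tol (relative to the larger mass)
oracle_cluster <- function(det, ppm_tol, max_scan_gap) {
  n <- nrow(det)
  scan <- match(det$rt_min, sort(unique(det$rt_min)))  # dense RT rank
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (det$charge[i] != det$charge[j]) next
    if (abs(scan[i] - scan[j]) > max_scan_gap + 1L) next
    mmax <- max(det$mono_mass_da[i], det$mono_mass_da[j])
    if (abs(det$mono_mass_da[i] - det$mono_mass_da[j]) >
        ppm_tol * 1e-6 * mmax) next
    adj[i, j] <- TRUE
  }
  # reachability by repeated expansion
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        tgt <- min(comp[i], comp[j])
        src <- max(comp[i], comp[j])
        comp[comp == src] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# two partitions of the same elements are the same clustering?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# ---- pair-matching oracle ----------------------------------------------

oracle_match_pairs <- function(features, params) {
  f <- as.data.frame(features)
  cls <- params$classes
  cand <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(f))) {
    if (i == j) next
    if (f$run_id[i] != f$run_id[j] || f$charge[i] != f$charge[j]) next
    delta <- f$mass[j] - f$mass[i]          # j = heavy candidate
    if (delta <= 0) next
    hits <- which(abs(delta - cls$delta) <=
                    params$ppm_tol * 1e-6 * f$mass[j])
    if (length(hits) != 1L) next            # no class or ambiguous
    ov <- min(f$rt_end[i], f$rt_end[j]) - max(f$rt_start[i], f$rt_start[j])
    span <- min(f$rt_end[i] - f$rt_start[i], f$rt_end[j] - f$rt_start[j])
    ok <- if (span > 0) ov / span >= params$min_rt_overlap else ov >= 0
    if (!ok) next
    cand[[length(cand) + 1L]] <- data.frame(
      light_id = f$feature_id[i], heavy_id = f$feature_id[j],
      class = cls$label[hits],
      ppm = (delta - cls$delta[hits]) / f$mass[j] * 1e6,
      apex_dist = abs(f$rt_apex[i] - f$rt_apex[j]))
  }
  if (!length(cand)) return(data.frame(light_id = integer(),
                                       heavy_id = integer(),
                                       class = character()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$ppm), cand$apex_dist,
                     cand$light_id, cand$heavy_id), ]
  used <- integer()
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!(cand$light_id[r] %in% used) && !(cand$heavy_id[r] %in% used)) {
      keep[r] <- TRUE
      used <- c(used, cand$light_id[r], cand$heavy_id[r])
    }
  }
  out <- cand[keep, c("light_id", "heavy_id", "class")]
  out[order(out$light_id), ]
}

# random feature table containing planted pairs plus decoys
random_feature_instance <- function(n_pairs = 8, n_decoys = 10,
                                    ppm_sigma = 1) {
  cls <- silacquant::shift_classes()
  rows <- list()
  fid <- 0L
  for (p in seq_len(n_pairs)) {
    z <- sample(2:3, 1L)
    ml <- runif(1, 600, 2500)
    ci <- sample(nrow(cls), 1L)
    mh <- ml + cls$delta[ci] + rnorm(1, 0, ppm_sigma * 1e-6 * ml)
    rt0 <- runif(1, 10, 100)
    w <- runif(1, 0.3, 1)
    for (m in c(ml, mh)) {
      fid <- fid + 1L
      rows[[fid]] <- data.frame(
        feature_id = fid, run_id = "r1", charge = z, mass = m,
        rt_apex = rt0, rt_start = rt0 - w, rt_end = rt0 + w,
        area = runif(1, 1e4, 1e6), n_scans = 10L)
    }
  }
  for (d in seq_len(n_decoys)) {
    fid <- fid + 1L
    rt0 <- runif(1, 10, 100)
    w <- runif(1, 0.3, 1)
    rows[[fid]] <- data.frame(
      feature_id = fid, run_id = "r1", charge = sample(2:3, 1L),
      mass = runif(1, 600, 2600), rt_apex = rt0,
      rt_start = rt0 - w, rt_end = rt0 + w,
      area = runif(1, 1e4, 1e6), n_scans = 10L)
  }
  out <- do.call(rbind, rows)
  out$feature_id <- seq_len(nrow(out))
  out
}

# ---- identification-attachment oracle ----------------------------------

oracle_attach <- function(pairs, ids, ppm_tol, rt_tol) {
  p <- as.data.frame(pairs)
  i <- as.data.frame(ids)
  res <- list()
  for (r in seq_len(nrow(i))) {
    best <- NULL
    for (q in seq_len(nrow(p))) {
      if (p$run_id[q] != i$run_id[r] || p$charge[q] != i$charge[r]) next
      if (abs(p$rt_apex[q] - i$rt_min[r]) > rt_tol) next
      ppm_l <- (i$mono_mass_da[r] - p$mass_light[q]) / p$mass_light[q] * 1e6
      ppm_h <- (i$mono_mass_da[r] - p$mass_heavy[q]) / p$mass_heavy[q] * 1e6
      ppm <- if (abs(ppm_l) <= abs(ppm_h)) ppm_l else ppm_h
      if (abs(ppm) > ppm_tol) next
      rec <- c(q = q, ppm = abs(ppm), rtd = abs(p$rt_apex[q] - i$rt_min[r]))
      if (is.null(best) || rec["ppm"] < best["ppm"] ||
          (rec["ppm"] == best["ppm"] && rec["rtd"] < best["rtd"]))
        best <- rec
    }
    if (!is.null(best))
      res[[length(res) + 1L]] <- data.frame(
        id_row = r, light_id = p$light_id[best["q"]],
        heavy_id = p$heavy_id[best["q"]])
  }
  if (!length(res)) return(data.frame(id_row = integer(),
                                      light_id = integer(),
                                      heavy_id = integer()))
  do.call(rbind, res)
}

# ---- agglomerative-clustering oracle ------------------------------------

# recompute the linkage between member sets from the original distance
# matrix at every step (no Lance-Williams updates)
oracle_agglomerate <- function(d, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      va <- clusters[[a]]
      vb <- clusters[[b]]
      dd <- d[va, vb, drop = FALSE]
      link <- switch(linkage, average = mean(dd),
                     complete = max(dd), single = min(dd))
      key <- c(link, min(va), min(vb))
      if (is.null(best) || key[1] < best$key[1] ||
          (key[1] == best$key[1] &&
             (key[2] < best$key[2] ||
                (key[2] == best$key[2] && key[3] < best$key[3]))))
        best <- list(a = a, b = b, key = key)
    }
    heights <- c(heights, best$key[1])
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters <- clusters[-c(best$a, best$b)]
    clusters[[length(clusters) + 1L]] <- merged
    # order clusters by smallest member for a deterministic next step
    clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# partition sequence implied by an hclust-style merge matrix
merge_partitions <- function(merge, n) {
  members <- as.list(seq_len(n))
  sets <- list()
  partitions <- list()
  current <- as.list(seq_len(n))
  for (s in seq_len(nrow(merge))) {
    take <- function(v) if (v < 0) -v else sets[[v]]
    newset <- sort(c(take(merge[s, 1L]), take(merge[s, 2L])))
    sets[[s]] <- newset
    current <- Filter(function(x) !any(x %in% newset), current)
    current[[length(current) + 1L]] <- newset
    current <- current[order(vapply(current, min, numeric(1)))]
    part <- integer(n)
    for (ci in seq_along(current)) part[current[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  partitions
}

# ---- misc ----------------------------------------------------------------

# exact upper-tail hypergeometric by enumeration of all n-subsets
oracle_hyper <- function(k, K, N, n) {
  universe <- seq_len(N)
  hits <- seq_len(K)
  subs <- utils::combn(N, n)
  cnt <- sum(apply(subs, 2L, function(s) sum(s %in% hits) >= k))
  cnt / ncol(subs)
}

# step-up BH applied literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(m * p[o[i:m]] / match(o[i:m], o))
  }
  q
}
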