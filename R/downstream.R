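#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of (m * p_(j) / j)` on the sorted p-values,
#' mapped back to input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  q_sorted <- rev(cummin(rev(m * pvals[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the term's
#' accessions in the target set against the universe with the upper-tail
#' hypergeometric probability `P(X >= k)` (population `N`, `K` term
#' members, `n` draws). Terms with no hit in the target are skipped;
#' Benjamini-Hochberg correction is applied over the tested terms.
#'
#' @param target Character vector of target accessions (subset of
#'   `universe`).
#' @param annotation Named list mapping term id to accession vectors, or a
#'   two-column data.frame (term, accession).
#' @param universe Character vector of background accessions; annotations
#'   are intersected with it.
#' @return data.table sorted by `q` then `p`: `term`, `k`, `n`, `K`, `N`,
#'   `p`, `q`.
#' @export
enrich_terms <- function(target, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  target <- unique(target)
  if (!all(target %in% universe))
    stop("target must be a subset of the universe", call. = FALSE)
  if (is.data.frame(annotation))
    annotation <- split(as.character(annotation[[2L]]),
                        as.character(annotation[[1L]]))
  ann <- lapply(annotation, function(a) intersect(unique(a), universe))
  N <- length(universe)
  n <- length(target)
  rows <- lapply(names(ann), function(term) {
    K <- length(ann[[term]])
    k <- length(intersect(ann[[term]], target))
    if (k == 0L) return(NULL)
    data.table(term = term, k = k, n = n, K = K, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  out[, q := bh_adjust(p)]
  setorder(out, q, p, term)
  out[]
}

#' Hierarchical clustering of the protein x sample RIA matrix
#'
#' Agglomerative clustering with pairwise-complete distances (missing
#' positions are ignored pair by pair) and deterministic tie-breaking by
#' lowest row index. The default Pearson-correlation distance (1 - r)
#' with average linkage mirrors the common Gene Cluster configuration for
#' expression heat maps. Undefined correlations (fewer than two complete
#' pairs, or zero variance) get distance 1.
#'
#' @param mat Numeric matrix, proteins in rows, samples in columns; row
#'   names are protein identifiers. Rows need >= 2 non-missing values.
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`
#'   (pairwise-complete, scaled to the full column count).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An object of classes `silac_hclust` and `hclust` (so
#'   `plot()`/`cutree()` work): `merge`, `height`, `order`, `labels`,
#'   `method`, `dist.method`.
#' @export
hcluster_ria <- function(mat, metric = c("pearson", "euclidean"),
                         linkage = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 rows", call. = FALSE)
  n_ok <- rowSums(!is.na(mat))
  if (any(n_ok < 2L))
    stop("rows with < 2 non-missing values: ",
         paste(head(which(n_ok < 2L), 5L), collapse = ", "),
         call. = FALSE)
  d <- pairwise_dist(mat, metric)
  hc <- agglomerate(d, linkage)
  hc$labels <- rownames(mat)
  hc$dist.method <- metric
  hc$method <- linkage
  class(hc) <- c("silac_hclust", "hclust")
  hc
}

# pairwise-complete distance matrix
pairwise_dist <- function(mat, metric) {
  n <- nrow(mat)
  if (metric == "pearson") {
    r <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
    d <- 1 - r
    d[!is.finite(d)] <- 1
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      d[i, j] <- d[j, i] <- if (!any(ok)) NA_real_ else
        sqrt(sum((mat[i, ok] - mat[j, ok])^2) * ncol(mat) / sum(ok))
    }
    d[!is.finite(d)] <- max(d[is.finite(d)], 1)
  }
  diag(d) <- 0
  d
}

# naive agglomeration with Lance-Williams updates on the upper triangle;
# ties broken by the lexicographically smallest (i, j) slot pair, i.e. by
# lowest row index. The merged cluster keeps the lower slot.
agglomerate <- function(d, linkage) {
  n <- nrow(d)
  size <- rep(1L, n)
  # hclust convention: negative = singleton, positive = prior merge
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  work <- d
  work[lower.tri(work, diag = TRUE)] <- Inf
  for (step in seq_len(n - 1L)) {
    m <- min(work)
    idx <- which(work == m, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]
    j <- idx[1L, 2L]
    merge[step, ] <- order_merge_pair(id[i], id[j])
    height[step] <- m
    ks <- which(active)
    ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      iu <- cbind(pmin(i, ks), pmax(i, ks))
      ju <- cbind(pmin(j, ks), pmax(j, ks))
      dik <- work[iu]
      djk <- work[ju]
      new <- switch(linkage,
        average = (size[i] * dik + size[j] * djk) / (size[i] + size[j]),
        complete = pmax(dik, djk),
        single = pmin(dik, djk))
      work[iu] <- new
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    work[j, ] <- Inf
    work[, j] <- Inf
    id[i] <- step
  }
  list(merge = merge, height = height,
       order = hclust_leaf_order(merge))
}

order_merge_pair <- function(a, b) {
  # singletons (negative) before merges, then ascending magnitude
  v <- c(a, b)
  v[order(v >= 0, abs(v))]
}

# leaf order by left-to-right traversal of the merge tree
hclust_leaf_order <- function(merge) {
  res <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    left <- merge[s, 1L]
    right <- merge[s, 2L]
    lv <- if (left < 0) -left else res[[left]]
    rv <- if (right < 0) -right else res[[right]]
    res[[s]] <- c(lv, rv)
  }
  res[[nrow(merge)]]
}

#' Export a heat-map matrix
#'
#' Writes the protein x sample RIA matrix in clustered row order as TSV,
#' an ordering file, and optionally a PNG rendering. The exported matrix
#' keeps raw (unflipped) orientation so forward and reverse mixed columns
#' mirror each other, as on a conventional SILAC heat map.
#'
#' @param mat Numeric matrix (proteins x samples).
#' @param cluster A `silac_hclust` from [hcluster_ria()] on `mat`, or
#'   `NULL` to keep input order.
#' @param file_tsv Path for the matrix TSV.
#' @param file_order Optional path for the leaf-order file.
#' @param file_png Optional path for a PNG rendering.
#' @return Invisibly, the row order used.
#' @export
export_heatmap <- function(mat, cluster = NULL, file_tsv,
                           file_order = NULL, file_png = NULL) {
  ord <- if (is.null(cluster)) seq_len(nrow(mat)) else cluster$order
  m <- mat[ord, , drop = FALSE]
  df <- data.frame(accession = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  write.table(df, file_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(file_order))
    writeLines(rownames(m), file_order)
  if (!is.null(file_png)) {
    png(file_png, width = 480, height = 960)
    image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
          col = hcl.colors(64, "RdYlBu", rev = TRUE),
          axes = FALSE, zlim = c(0, 1))
    axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m),
         las = 2, cex.axis = 0.7)
    dev.off()
  }
  invisible(ord)
}
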