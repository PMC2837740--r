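# independent straight-line oracles, kept free of the package's code paths

# PAGE components recomputed from first principles (own median and SD)
oracle_page <- function(set, logratios) {
  med <- function(v) {
    v <- sort(v); k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
  }
  members <- names(logratios)[names(logratios) %in% toupper(set)]
  m <- length(members)
  Sm <- med(unname(logratios[members]))
  mu <- med(unname(logratios))
  xbar <- sum(logratios) / length(logratios)
  sigma <- sqrt(sum((logratios - xbar)^2) / (length(logratios) - 1))
  list(Sm = Sm, mu = mu, sigma = sigma, m = m,
       z = (Sm - mu) * sqrt(m) / sigma)
}

# naive complete linkage: recompute every cluster-pair distance from scratch
# at every step; returns merge heights and the partition after each merge
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    bestd <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    heights <- c(heights, bestd)
    partitions[[length(partitions) + 1]] <- canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters) {
  out <- lapply(clusters, sort)
  out[order(vapply(out, `[`, numeric(1), 1))]
}

# partition sequence of an hclust tree via cutree at every level
tree_partitions <- function(tree) {
  n <- length(tree$labels)
  lapply(seq(n - 1, 1), function(k) {
    memb <- stats::cutree(tree, k = k)
    canonical_partition(unname(split(seq_len(n), memb)))
  })
}

# Benjamini-Hochberg by its definition: q_i = min over p_j >= p_i of p_j*n/rank_j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n))
    q_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# plain uncentered-Pearson distance matrix, written out longhand
uncentered_distance_ref <- function(profiles) {
  n <- nrow(profiles)
  outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    1 - sum(profiles[i, ] * profiles[j, ]) /
      sqrt(sum(profiles[i, ]^2) * sum(profiles[j, ]^2))))
}
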