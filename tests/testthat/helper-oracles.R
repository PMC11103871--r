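# Independent brute-force oracles used across the suite. These are written
# against the definitions, not the implementation paths they check.

# Benjamini-Hochberg step-up by direct min-cummin on sorted p * m / rank
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# upper-tail hypergeometric by explicit summation
bf_hyper_upper <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# AUC by pair enumeration
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# shortest-path counts from a distance matrix (Floyd-Warshall) plus a DP
# over nodes ordered by distance; betweenness with endpoints excluded and
# each unordered pair counted once
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[adj == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  sigma <- function(s) {
    cnt <- numeric(n); cnt[s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (t in which(D[s, ] == d))
        cnt[t] <- sum(cnt[adj[, t] == 1 & D[s, ] == d - 1])
    }
    cnt
  }
  sig <- t(vapply(1:n, sigma, numeric(n)))  # sig[s, t]
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || sig[s, t] == 0) next
    for (v in 1:n) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  btw
}

# largest connected component among the neighbours of v, by reachability
# closure on the induced submatrix
bf_mnc <- function(adj, v) {
  nb <- which(adj[v, ] == 1)
  if (!length(nb)) return(0L)
  sub <- adj[nb, nb, drop = FALSE]
  n <- length(nb)
  reach <- sub | diag(n)
  for (i in seq_len(n)) reach <- (reach %*% reach) > 0
  max(rowSums(reach))
}

# random simple undirected graph; returns adjacency and the igraph object
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, g = g)
}

# adjacency -> canonical edge list with constant score 0.9
adj_to_edges <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edge_list(rownames(adj)[idx[, 1]], colnames(adj)[idx[, 2]],
            rep(0.9, nrow(idx)))
}

# add default protein/sample dimnames to a bare matrix
named_mat <- function(values) {
  dimnames(values) <- list(sprintf("P%02d", seq_len(nrow(values))),
                           sprintf("s%02d", seq_len(ncol(values))))
  values
}

# tiny QuantMatrix fixture
qm_fixture <- function(values) quant_matrix(named_mat(values))

sample_fixture <- function(qm, n_case) {
  sid <- sample_ids(qm)
  data.frame(sample_id = sid, cohort = "discovery",
             group = rep(c("case", "control"),
                         c(n_case, length(sid) - n_case)),
             bcva_logmar = NA_real_, diabetes_years = NA_real_,
             stringsAsFactors = FALSE)
}

# exhaustive k-NN imputation oracle: direct per-cell search
bf_knn_impute <- function(v, k) {
  out <- v
  for (p in seq_len(nrow(v))) for (s in seq_len(ncol(v))) {
    if (!is.na(v[p, s])) next
    cand <- setdiff(which(!is.na(v[, s])), p)
    d <- sapply(cand, function(q) {
      sh <- which(!is.na(v[p, ]) & !is.na(v[q, ]))
      if (!length(sh)) return(Inf)
      sqrt(sum((v[p, sh] - v[q, sh])^2)) / sqrt(length(sh))
    })
    cand <- cand[is.finite(d)]; d <- d[is.finite(d)]
    ord <- cand[order(d, cand)]
    nb <- ord[seq_len(min(k, length(ord)))]
    out[p, s] <- mean(v[nb, s])
  }
  out
}
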