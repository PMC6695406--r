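# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and igraph routines) they verify.

# Normalized betweenness by explicit all-pairs shortest-path counting:
# BFS distances from every source, shortest-path counts by dynamic
# programming over distance layers, then pair-splitting accumulation.
bf_betweenness <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (u in adj[[v]]) {
        if (!is.finite(dist[s, u])) {
          dist[s, u] <- d
          nxt <- c(nxt, u)
        }
        if (dist[s, u] == d) sigma[s, u] <- sigma[s, u] + sigma[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  bt <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (!is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  names(bt) <- igraph::V(g)$name
  if (n > 2) bt / ((n - 1) * (n - 2) / 2) else bt * 0
}

# Naive O(n^3) agglomerative clustering with average linkage on a distance
# matrix; returns merge heights in order.
naive_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exact hypergeometric upper tail P(X >= x) by direct log-space summation.
hyper_tail <- function(x, K, E, N) {
  if (x <= 0) return(1)
  i <- seq(x, min(K, E))
  if (!length(i)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, E - i) - lchoose(N, E)))
}

# Random small catalog + correlation fixture builders
random_corr <- function(n, seed = 1, prefix = "G") {
  set.seed(seed)
  x <- matrix(rnorm(n * 6), nrow = 6)
  colnames(x) <- sprintf("%s%02d", prefix, seq_len(n))
  stats::cor(x)
}

random_graph <- function(n, p, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("G%02d", seq_len(n))
  g
}

tiny_sim_params <- function(seed = 1, sigma = 0.3) {
  simulation_params(
    tissues = c("gut", "liver", "kidney", "brain", "lung", "heart"),
    samples_per_tissue = 3L,
    modules = list(
      module_spec("m_gut", 6, "gut", "SLC", "SLC5"),
      module_spec("m_liver", 6, "liver", "ABC", "ABCC"),
      module_spec("m_kidney", 6, "kidney", "SLC", "SLC22"),
      module_spec("m_lk", 5, c("liver", "kidney"), "other", "NR",
                  adme_status = "related"),
      module_spec("m_brain", 5, "brain", "control", "GPR")
    ),
    n_background = 20L,
    sigma = sigma,
    seed = seed
  )
}
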