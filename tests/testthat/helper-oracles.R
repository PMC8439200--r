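# Independent oracles, deliberately naive: plain loops and closed forms,
# sharing no code with the package implementations they check.

# Kendall tau-a by explicit enumeration of all sample pairs
brute_force_tau <- function(x, y) {
  n <- length(x)
  concordant <- 0L
  discordant <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      prod <- (x[i] - x[j]) * (y[i] - y[j])
      if (prod > 0) concordant <- concordant + 1L
      if (prod < 0) discordant <- discordant + 1L
    }
  }
  (concordant - discordant) / choose(n, 2)
}

# degree-entropy by direct evaluation: importance then -sum I ln I
brute_force_entropy <- function(adj) {
  n <- nrow(adj)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(adj[i, ])
  total <- sum(k)
  e <- 0
  for (i in seq_len(n)) {
    imp <- k[i] / total
    if (imp > 0) e <- e - imp * log(imp)
  }
  e
}

# upper-tail hypergeometric P(X >= k) by explicit summation
brute_force_hyper_tail <- function(k, pathway, universe, module) {
  other <- universe - pathway
  total <- choose(universe, module)
  p <- 0
  for (x in seq.int(k, min(pathway, module))) {
    p <- p + choose(pathway, x) * choose(other, module - x) / total
  }
  p
}

# small study fixture: explicit group means, optional noise
toy_study <- function(means, n_per_group = 4, noise_sd = 0, seed = 42) {
  # means: metabolite x group matrix of mean abundances (positive)
  groups <- colnames(means)
  samples <- as.vector(vapply(groups, function(g) {
    paste0(g, "_", seq_len(n_per_group))
  }, character(n_per_group)))
  withr::with_seed(seed, {
    vals <- matrix(NA_real_, nrow(means), length(samples),
                   dimnames = list(rownames(means), samples))
    for (gi in seq_along(groups)) {
      cols <- (gi - 1) * n_per_group + seq_len(n_per_group)
      vals[, cols] <- means[, gi] *
        2^matrix(rnorm(nrow(means) * n_per_group, sd = noise_sd),
                 nrow(means))
    }
    expr_study(vals, data.frame(
      sample = samples,
      group = rep(groups, each = n_per_group),
      dose = 0))
  })
}

# igraph built from an edge list matrix, nodes named a, b, c, ...
toy_graph <- function(edges, extra_nodes = character()) {
  nodes <- sort(unique(c(as.vector(edges), extra_nodes)))
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = nodes))
}

clique_edges <- function(nodes) {
  t(utils::combn(nodes, 2))
}

# sync_network fixture straight from a tau value matrix
toy_sync_network <- function(tau, edge_cut = 0.5, sync_cut = 0.7,
                             condition = "toy") {
  tm <- structure(list(tau = tau, nodes = rownames(tau),
                       n_samples = 10L, condition = condition,
                       constant = character()),
                  class = "tau_matrix")
  build_sync_network(tm, edge_cut = edge_cut, sync_cut = sync_cut)
}
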