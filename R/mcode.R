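# Graph used for module detection: nodes of the sync network, one
# undirected edge per pair with |tau| >= sync_cut (synchronous or
# anti-synchronous); the tau sign rides along as an edge attribute and is
# no barrier to module membership.
sync_igraph <- function(net, use_weak = FALSE) {
  edges <- net$edges
  if (!use_weak) edges <- edges[edges$edge_class != "weak", , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "tau")], directed = FALSE,
    vertices = data.frame(name = sort(net$nodes))
  )
  igraph::simplify(g, edge.attr.comb = "first")
}

graph_density_simple <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' Scores each vertex by the density of its core neighborhood: take the
#' closed neighborhood (the vertex plus its neighbors), find the highest
#' k-core of the induced subgraph, and set
#' `weight = k * density(highest k-core)` — the core-clustering coefficient
#' scaled by the core number. Vertices with degree below `degree_cutoff`
#' and isolated vertices get weight 0.
#'
#' @param net A `sync_network` (only edges with `|tau| >= sync_cut` are
#'   used) or an igraph graph.
#' @param degree_cutoff Minimum degree to receive a nonzero weight
#'   (default 2).
#' @return Named numeric vector of vertex weights.
#' @export
vertex_weights <- function(net, degree_cutoff = 2) {
  g <- if (inherits(net, "sync_network")) sync_igraph(net) else net
  deg <- igraph::degree(g)
  w <- setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (v in which(deg >= degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    w[v] <- kmax * graph_density_simple(core_sub)
  }
  w
}

#' MCODE module detection
#'
#' Finds densely connected modules by seeded greedy expansion: vertices are
#' weighted by [vertex_weights()]; the highest-weight unvisited vertex
#' seeds a module, which grows outward through unvisited neighbors whose
#' weight is at least `seed_weight * (1 - node_score_cutoff)`. Each module
#' is then post-processed: it must contain a `k_core`-core to survive;
#' `haircut` iteratively trims members with fewer than 2 connections inside
#' the module; `fluff` optionally adds back neighbors whose closed
#' neighborhood density exceeds `fluff_density` (allowing overlap). Module
#' score is `density * size`; modules are returned sorted by score, ties
#' and expansion order broken lexicographically by node id so the result is
#' independent of input edge order.
#'
#' @param net A `sync_network` or an igraph graph.
#' @param degree_cutoff,node_score_cutoff,k_core,haircut,fluff,fluff_density
#'   MCODE parameters; defaults 2, 0.2, 2, TRUE, FALSE, 0.5.
#' @param min_size Minimum module size (default 3).
#' @return A `module_set`: list with `modules` (tibble `module`, `nodes`
#'   list-column, `size`, `score`, `seed`), `parameters`, `condition`.
#' @export
find_modules <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.5, min_size = 3) {
  g <- if (inherits(net, "sync_network")) sync_igraph(net) else net
  condition <- if (inherits(net, "sync_network")) net$condition else NA_character_
  params <- list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff, k_core = k_core,
                 haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density, min_size = min_size)

  empty <- structure(list(
    modules = tibble(module = integer(), nodes = list(),
                     size = integer(), score = numeric(),
                     seed = character()),
    parameters = params, condition = condition), class = "module_set")
  if (igraph::vcount(g) == 0L) return(empty)

  w <- vertex_weights(g, degree_cutoff = degree_cutoff)
  names_v <- igraph::V(g)$name
  # descending weight, lexicographic node id on ties
  order_seed <- order(-w, names_v)
  visited <- setNames(rep(FALSE, length(w)), names_v)

  raw_modules <- list()
  for (s in order_seed) {
    seed_name <- names_v[s]
    if (visited[seed_name] || w[s] <= 0) next
    threshold <- w[s] * (1 - node_score_cutoff)
    members <- seed_name
    visited[seed_name] <- TRUE
    frontier <- seed_name
    while (length(frontier) > 0L) {
      nxt <- character()
      for (v in frontier) {
        nbs <- igraph::neighbors(g, v)$name
        nbs <- sort(nbs[!visited[nbs]])
        admit <- nbs[w[nbs] >= threshold]
        visited[admit] <- TRUE
        nxt <- c(nxt, admit)
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    raw_modules[[length(raw_modules) + 1L]] <-
      list(members = sort(members), seed = seed_name)
  }

  keep <- list()
  for (mod in raw_modules) {
    sub <- igraph::induced_subgraph(g, mod$members)
    if (max(igraph::coreness(sub)) < k_core) next
    members <- mod$members
    if (haircut) {
      repeat {
        sub <- igraph::induced_subgraph(g, members)
        low <- igraph::V(sub)$name[igraph::degree(sub) < 2]
        if (length(low) == 0L) break
        members <- setdiff(members, low)
        if (length(members) == 0L) break
      }
    }
    if (fluff) {
      extra <- character()
      for (v in members) {
        for (u in setdiff(igraph::neighbors(g, v)$name, members)) {
          nb <- c(u, igraph::neighbors(g, u)$name)
          if (graph_density_simple(igraph::induced_subgraph(g, nb)) >
              fluff_density) {
            extra <- c(extra, u)
          }
        }
      }
      members <- sort(union(members, extra))
    }
    if (length(members) < min_size) next
    sub <- igraph::induced_subgraph(g, members)
    keep[[length(keep) + 1L]] <- tibble(
      nodes = list(sort(members)), size = length(members),
      score = graph_density_simple(sub) * length(members),
      seed = mod$seed)
  }
  if (length(keep) == 0L) return(empty)
  modules <- dplyr::bind_rows(keep)
  modules <- modules[order(-modules$score,
                           vapply(modules$nodes, `[`, character(1), 1)), ]
  modules$module <- seq_len(nrow(modules))
  structure(list(
    modules = modules[, c("module", "nodes", "size", "score", "seed")],
    parameters = params, condition = condition), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("<module_set>", if (!is.na(x$condition %||% NA)) x$condition,
      nrow(x$modules), "module(s)\n")
  for (i in seq_len(nrow(x$modules))) {
    cat(sprintf("  %d. score %.2f: %s\n", x$modules$module[i],
                x$modules$score[i],
                paste(x$modules$nodes[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  if (nrow(x$modules) == 0L) {
    return(tibble(module = integer(), node = character(),
                  score = numeric(), condition = character()))
  }
  tidyr::unnest(
    dplyr::transmute(x$modules, module = .data$module,
                     node = .data$nodes, score = .data$score,
                     condition = x$condition %||% NA_character_),
    "node")
}

#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble(condition = x$condition %||% NA_character_,
         n_modules = nrow(x$modules),
         n_module_nodes = length(unique(unlist(x$modules$nodes))),
         top_score = if (nrow(x$modules)) max(x$modules$score) else NA_real_)
}

#' Convenience pipeline: tau matrix to modules for one condition
#'
#' Runs [tau_matrix()], [build_sync_network()] and [find_modules()] for a
#' set of pooled groups.
#'
#' @inheritParams tau_matrix
#' @inheritParams build_sync_network
#' @param ... Passed to [find_modules()].
#' @return A list with `tau`, `network`, `modules`.
#' @export
sync_modules <- function(study, groups, condition = NULL, edge_cut = 0.5,
                         sync_cut = 0.7, ...) {
  tm <- tau_matrix(study, groups, condition = condition)
  net <- build_sync_network(tm, edge_cut = edge_cut, sync_cut = sync_cut)
  list(tau = tm, network = net, modules = find_modules(net, ...))
}
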