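network_edge_table <- function(net) {
  if (inherits(net, "sync_network")) {
    e <- net$edges
    tibble(from = e$from, to = e$to, weight = e$tau,
           relation = ifelse(e$tau >= 0, "sync", "antisync"),
           edge_class = e$edge_class)
  } else if (inherits(net, "weighted_network")) {
    e <- tidy(net)
    tibble(from = e$from, to = e$to, weight = e$weight,
           relation = "coexpr", edge_class = NA_character_)
  } else {
    abort("net must be a sync_network or weighted_network")
  }
}

#' Write a network to a Cytoscape-readable file
#'
#' Supported formats: SIF (`source <tab> relation <tab> target`, with
#' `sync`/`antisync` relations for signed tau edges and singleton lines for
#' isolated nodes), GraphML (tau/weight carried as an edge attribute;
#' round-trips through [read_network_graphml()]), and a plain edge-list
#' CSV. Nodes and edges are written in sorted order, so output is
#' deterministic.
#'
#' @param net A `sync_network` or `weighted_network` with a nonempty node
#'   set.
#' @param path Output path.
#' @param format `"sif"`, `"graphml"` or `"csv"`; default inferred from
#'   the file extension.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = NULL) {
  if (length(net$nodes) == 0L) abort("network has no nodes")
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("sif", "graphml", "csv")) {
    abort(paste0("unknown network format: ", format))
  }
  edges <- dplyr::arrange(network_edge_table(net), .data$from, .data$to)
  nodes <- sort(net$nodes)
  switch(format,
    sif = {
      lines <- sprintf("%s\t%s\t%s", edges$from, edges$relation, edges$to)
      isolated <- setdiff(nodes, unique(c(edges$from, edges$to)))
      writeLines(c(lines, isolated), path)
    },
    graphml = {
      g <- igraph::graph_from_data_frame(
        edges, directed = FALSE, vertices = data.frame(name = nodes))
      igraph::write_graph(g, path, format = "graphml")
    },
    csv = readr::write_csv(edges, path, na = "")
  )
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path Path to a GraphML file with a `weight` edge attribute.
#' @return A tibble `from`, `to`, `weight` (plus any further edge
#'   attributes), sorted; node set in the `nodes` attribute.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  names(edges)[1:2] <- c("from", "to")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  attr(edges, "nodes") <- sort(igraph::V(g)$name)
  edges
}

#' Write per-module subnetworks as SIF files
#'
#' @param modules A `module_set`.
#' @param net The `sync_network` the modules were detected in.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_module_sifs <- function(modules, net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_len(nrow(modules$modules))) {
    nodes <- modules$modules$nodes[[i]]
    sub <- net
    sub$nodes <- nodes
    sub$edges <- net$edges[net$edges$from %in% nodes &
                             net$edges$to %in% nodes, , drop = FALSE]
    p <- file.path(dir, sprintf("module_%02d.sif", i))
    write_network(sub, p, format = "sif")
    paths <- c(paths, p)
  }
  invisible(paths)
}
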