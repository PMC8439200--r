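jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Match modules between two conditions by Jaccard similarity
#'
#' Greedy best-first bipartite matching: the pair of modules (one from each
#' set) with the highest Jaccard index is matched first and removed, then
#' the next, while the Jaccard index stays at or above `jaccard_min`. Ties
#' are broken by module rank. Raising `jaccard_min` can only shrink the
#' matched set.
#'
#' @param a,b `module_set` objects (from [find_modules()]), or lists of
#'   character node vectors.
#' @param jaccard_min Minimum Jaccard index for a match, in `(0, 1]`
#'   (default 0.5).
#' @return A tibble with one row per matched pair: `module_a`, `module_b`,
#'   `jaccard`, `shared` (list-column of shared node ids).
#' @export
match_modules <- function(a, b, jaccard_min = 0.5) {
  if (!(jaccard_min > 0 && jaccard_min <= 1)) {
    abort("jaccard_min must be in (0, 1]")
  }
  na <- module_node_sets(a)
  nb <- module_node_sets(b)
  out <- tibble(module_a = integer(), module_b = integer(),
                jaccard = numeric(), shared = list())
  if (length(na) == 0L || length(nb) == 0L) return(out)
  jm <- outer(seq_along(na), seq_along(nb),
              Vectorize(function(i, j) jaccard(na[[i]], nb[[j]])))
  while (TRUE) {
    best <- max(jm)
    if (best < jaccard_min) break
    hit <- which(jm == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    out <- dplyr::bind_rows(out, tibble(
      module_a = unname(hit[1]), module_b = unname(hit[2]),
      jaccard = best,
      shared = list(sort(intersect(na[[hit[1]]], nb[[hit[2]]])))))
    jm[hit[1], ] <- -1
    jm[, hit[2]] <- -1
  }
  out
}

module_node_sets <- function(x) {
  if (inherits(x, "module_set")) x$modules$nodes else x
}

#' Classify module dynamics across dose conditions
#'
#' Compares MCODE module sets detected under the full-course condition and
#' the adjacent dose-pair conditions, and labels:
#'
#' * **full-course** — modules of the network pooled over all four dose
#'   groups;
#' * **partial** — the modules of each adjacent dose-pair network;
#' * **conservative-allosteric** — nodes shared by Jaccard-matched modules
#'   of the low-dose pair and the high-dose pair (basic machinery retained
#'   across the dose range);
#' * **emerging** — dose-pair modules whose node set is disjoint from the
#'   preceding pair's module-node union (new machinery appearing at higher
#'   doses);
#' * **persistent pairs** — metabolite pairs with `|tau| > sync_cut` in
#'   every per-group network.
#'
#' @param modulesets Named list of `module_set`s; names must include
#'   `low_pair`, `high_pair` and (for emerging labels) consecutive pairs in
#'   `pair_order`. Conventionally `"DH1/DH2"`, `"DH2/DH3"`, `"DH3/DH4"`,
#'   `"DH1-DH4"`.
#' @param group_networks Optional named list of per-group `sync_network`s
#'   used for persistent-pair detection; `NULL` skips it.
#' @param jaccard_min Module-identity threshold for [match_modules()].
#' @param full_course,low_pair,high_pair,pair_order Names of the conditions
#'   within `modulesets`.
#' @return A `module_dynamics` object: list with tibble/list components
#'   `full_course`, `partial`, `conservative_allosteric` (character
#'   vector), `conservative_matches`, `emerging`, `persistent_pairs`,
#'   `jaccard_min`.
#' @export
classify_dynamics <- function(modulesets, group_networks = NULL,
                              jaccard_min = 0.5,
                              full_course = "DH1-DH4",
                              low_pair = "DH1/DH2", high_pair = "DH3/DH4",
                              pair_order = c("DH1/DH2", "DH2/DH3",
                                             "DH3/DH4")) {
  need <- unique(c(full_course, low_pair, high_pair, pair_order))
  missing_cond <- setdiff(need, names(modulesets))
  if (length(missing_cond) > 0L) {
    abort(paste0("missing condition(s): ",
                 paste(missing_cond, collapse = ", ")))
  }

  cons_matches <- match_modules(modulesets[[low_pair]],
                                modulesets[[high_pair]],
                                jaccard_min = jaccard_min)
  conservative <- sort(unique(unlist(cons_matches$shared)))

  emerging <- list()
  for (i in seq_along(pair_order)[-1]) {
    cur <- pair_order[i]
    prev <- pair_order[i - 1]
    prev_nodes <- unique(unlist(module_node_sets(modulesets[[prev]])))
    sets <- module_node_sets(modulesets[[cur]])
    new <- sets[vapply(sets,
                       function(s) length(intersect(s, prev_nodes)) == 0L,
                       logical(1))]
    emerging[[cur]] <- new
  }

  persistent <- NULL
  if (!is.null(group_networks)) {
    edge_sets <- purrr::map(group_networks, function(net) {
      e <- net$edges[net$edges$edge_class != "weak", , drop = FALSE]
      key <- paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
      list(key = key, tau = setNames(e$tau, key))
    })
    common <- Reduce(intersect, purrr::map(edge_sets, "key"))
    persistent <- tibble(
      from = vapply(strsplit(common, "\r"), `[`, character(1), 1),
      to = vapply(strsplit(common, "\r"), `[`, character(1), 2)
    )
    for (gname in names(edge_sets)) {
      persistent[[paste0("tau_", gname)]] <-
        unname(edge_sets[[gname]]$tau[common])
    }
    persistent <- dplyr::arrange(persistent, .data$from, .data$to)
  }

  structure(list(
    full_course = modulesets[[full_course]]$modules,
    partial = purrr::map(modulesets[pair_order], "modules"),
    conservative_allosteric = conservative,
    conservative_matches = cons_matches,
    emerging = emerging,
    persistent_pairs = persistent,
    jaccard_min = jaccard_min
  ), class = "module_dynamics")
}

#' @export
print.module_dynamics <- function(x, ...) {
  cat("<module_dynamics>\n")
  cat("  full-course modules:", nrow(x$full_course), "\n")
  for (p in names(x$partial)) {
    cat("  ", p, "modules:", nrow(x$partial[[p]]), "\n")
  }
  cat("  conservative-allosteric nodes:",
      if (length(x$conservative_allosteric))
        paste(x$conservative_allosteric, collapse = ", ") else "(none)",
      "\n")
  for (p in names(x$emerging)) {
    n <- length(x$emerging[[p]])
    if (n > 0) cat("  emerging in", p, ":",
                   paste(vapply(x$emerging[[p]], paste, character(1),
                                collapse = "+"), collapse = "; "), "\n")
  }
  if (!is.null(x$persistent_pairs)) {
    cat("  persistent pairs:", nrow(x$persistent_pairs), "\n")
  }
  invisible(x)
}

#' @method tidy module_dynamics
#' @export
tidy.module_dynamics <- function(x, ...) {
  rows <- list()
  fc <- x$full_course
  if (nrow(fc)) {
    rows[[1]] <- tibble(category = "full_course", condition = "DH1-DH4",
                        module = fc$module,
                        nodes = vapply(fc$nodes, paste, character(1),
                                       collapse = ";"))
  }
  for (p in names(x$partial)) {
    m <- x$partial[[p]]
    if (nrow(m)) {
      rows[[length(rows) + 1L]] <-
        tibble(category = "partial", condition = p, module = m$module,
               nodes = vapply(m$nodes, paste, character(1), collapse = ";"))
    }
  }
  if (length(x$conservative_allosteric)) {
    rows[[length(rows) + 1L]] <-
      tibble(category = "conservative_allosteric", condition = "DH1/DH2~DH3/DH4",
             module = 1L,
             nodes = paste(x$conservative_allosteric, collapse = ";"))
  }
  for (p in names(x$emerging)) {
    sets <- x$emerging[[p]]
    if (length(sets)) {
      rows[[length(rows) + 1L]] <-
        tibble(category = "emerging", condition = p,
               module = seq_along(sets),
               nodes = vapply(sets, paste, character(1), collapse = ";"))
    }
  }
  if (length(rows) == 0L) {
    return(tibble(category = character(), condition = character(),
                  module = integer(), nodes = character()))
  }
  dplyr::bind_rows(rows)
}
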