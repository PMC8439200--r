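#' Read a pathway library from a GMT file
#'
#' GMT: one pathway per line, tab-separated `name <tab> description <tab>
#' member ids...`.
#'
#' @param path Path to a GMT file.
#' @param universe Optional metabolite universe; defaults to the union of
#'   all pathway members.
#' @return A `pathway_library`: list with `pathways` (named list of id
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names(fields) <- vapply(fields, `[`, character(1), 1)
  pathways <- purrr::map(fields, function(f) unique(f[-(1:2)]))
  pathway_library(pathways)
}

#' Construct a pathway library
#'
#' @param pathways Named list of character metabolite-id vectors.
#' @param universe Optional universe of metabolite ids; defaults to the
#'   union of all pathways.
#' @return A `pathway_library` object.
#' @export
pathway_library <- function(pathways, universe = NULL) {
  if (is.null(names(pathways)) || any(!nzchar(names(pathways)))) {
    abort("pathways must be a named list")
  }
  empty <- names(pathways)[lengths(pathways) == 0L]
  if (length(empty) > 0L) {
    abort(paste0("empty pathway(s): ", paste(empty, collapse = ", ")))
  }
  universe <- universe %||% sort(unique(unlist(pathways)))
  stray <- setdiff(unlist(pathways), universe)
  if (length(stray) > 0L) {
    abort(paste0("pathway member(s) outside universe: ",
                 paste(sort(unique(stray)), collapse = ", ")))
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat("<pathway_library>", length(x$pathways), "pathways over",
      length(x$universe), "metabolites\n")
  invisible(x)
}

#' Over-representation analysis of a module against pathway sets
#'
#' One-sided hypergeometric test per pathway: the probability of drawing at
#' least the observed overlap when `|module|` metabolites are sampled from
#' the universe without replacement. With `ease = TRUE` the observed
#' overlap is decremented by one before testing (the EASE-score
#' conservative variant). P-values are Benjamini-Hochberg adjusted across
#' pathways; a pathway is significant when its adjusted p is below `alpha`.
#'
#' @param module_nodes Character vector of metabolite ids (must lie in the
#'   library's universe).
#' @param lib A [pathway_library()] (or the result of [read_gmt()]).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param ease Use the EASE modification (default FALSE).
#' @return A tibble with one row per pathway: `pathway`, `pathway_size`,
#'   `module_size`, `overlap`, `expected`, `p_value`, `p_adjust`,
#'   `significant`, sorted by p-value.
#' @export
enrich <- function(module_nodes, lib, alpha = 0.05, ease = FALSE) {
  stopifnot(inherits(lib, "pathway_library"))
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  module_nodes <- unique(module_nodes)
  stray <- setdiff(module_nodes, lib$universe)
  if (length(stray) > 0L) {
    abort(paste0("module node(s) outside universe: ",
                 paste(sort(stray), collapse = ", ")))
  }
  n_univ <- length(lib$universe)
  n_mod <- length(module_nodes)
  res <- purrr::imap_dfr(lib$pathways, function(members, name) {
    k <- length(intersect(module_nodes, members))
    m <- length(members)
    k_test <- if (ease) max(k - 1L, 0L) else k
    # P(X >= k_test), X ~ Hypergeometric(m, n_univ - m, n_mod)
    p <- phyper(k_test - 1L, m, n_univ - m, n_mod, lower.tail = FALSE)
    tibble(pathway = name, pathway_size = m, module_size = n_mod,
           overlap = k, expected = n_mod * m / n_univ, p_value = p)
  })
  res$p_adjust <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adjust < alpha
  dplyr::arrange(res, .data$p_value, .data$pathway)
}
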