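#' Kendall's tau-a rank correlation
#'
#' The tau-a estimator: the number of concordant minus discordant sample
#' pairs divided by the total number of pairs `choose(n, 2)`. Tied pairs
#' (in either coordinate) contribute zero to the numerator but stay in the
#' denominator — there is no tie correction, unlike tau-b.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return A single number in `[-1, 1]`.
#' @examples
#' kendall_tau(1:3, c(10, 20, 30))   # 1
#' kendall_tau(1:3, 3:1)             # -1
#' kendall_tau(1:4, c(2, 1, 4, 3))   # 1/3
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 2L) abort("kendall_tau needs at least 2 observations")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  s <- sum((dx * dy)[upper.tri(dx)])
  s / choose(n, 2)
}

#' Pairwise Kendall tau-a matrix under a condition
#'
#' Computes tau-a between every metabolite pair on the samples pooled
#' across the condition's groups (e.g. a single group `"DH3"`, an adjacent
#' dose pair `c("DH2", "DH3")`, or the full course `DH1..DH4`).
#'
#' A metabolite that is constant across the pooled samples ties every pair;
#' its tau with every partner is defined as 0 and the metabolite is flagged
#' in the `constant` attribute.
#'
#' @param study An [expr_study()].
#' @param groups Character vector of group labels to pool.
#' @param condition Label stored on the result; defaults to the group
#'   labels joined with `/`.
#' @return A `tau_matrix` object: list with `tau` (symmetric matrix, unit
#'   diagonal), `nodes`, `n_samples`, `condition`, `constant`.
#' @export
tau_matrix <- function(study, groups, condition = NULL) {
  samples <- group_samples(study, groups)
  n <- length(samples)
  if (n < 3L) abort("condition must pool at least 3 samples")
  vals <- study$values[, samples, drop = FALSE]
  m <- nrow(vals)

  # sign-difference design: one signed comparison column per metabolite,
  # crossprod sums concordances over all ordered sample pairs at once
  D <- vapply(seq_len(m),
              function(i) as.vector(sign(outer(vals[i, ], vals[i, ], "-"))),
              numeric(n * n))
  tau <- crossprod(D) / (n * (n - 1))
  constant <- apply(vals, 1, function(r) all(r == r[1]))
  tau[constant, ] <- 0
  tau[, constant] <- 0
  diag(tau) <- 1
  dimnames(tau) <- list(study$metabolites, study$metabolites)
  if (any(constant)) {
    warn(paste0("constant metabolite(s) under condition, tau set to 0: ",
                paste(study$metabolites[constant], collapse = ", ")))
  }
  structure(
    list(tau = tau, nodes = study$metabolites, n_samples = n,
         condition = condition %||% paste(groups, collapse = "/"),
         constant = study$metabolites[constant]),
    class = "tau_matrix"
  )
}

#' @export
print.tau_matrix <- function(x, ...) {
  cat("<tau_matrix> ", length(x$nodes), " nodes, condition ", x$condition,
      " (n=", x$n_samples, " samples)\n", sep = "")
  invisible(x)
}

#' @method tidy tau_matrix
#' @export
tidy.tau_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$tau), arr.ind = TRUE)
  tibble(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]],
         tau = x$tau[idx], condition = x$condition)
}

#' Threshold a tau matrix into a synchronous network
#'
#' Keeps metabolite pairs with `|tau| > edge_cut` and classes each edge:
#' `synchronous` when `tau > sync_cut`, `anti-synchronous` when
#' `tau < -sync_cut`, otherwise `weak`. Thresholds are strict; a tau exactly
#' at a cut does not pass it. Isolated nodes are kept in the node set.
#'
#' @param tm A [tau_matrix()].
#' @param edge_cut Minimum `|tau|` for any edge (default 0.5).
#' @param sync_cut `|tau|` above which an edge is (anti-)synchronous
#'   (default 0.7).
#' @return A `sync_network`: list with `nodes`, `edges` (tibble `from`,
#'   `to`, `tau`, `edge_class`), `edge_cut`, `sync_cut`, `condition`.
#' @export
build_sync_network <- function(tm, edge_cut = 0.5, sync_cut = 0.7) {
  stopifnot(inherits(tm, "tau_matrix"))
  if (!(edge_cut >= 0 && edge_cut <= sync_cut && sync_cut <= 1)) {
    abort("need 0 <= edge_cut <= sync_cut <= 1")
  }
  edges <- tidy(tm)
  edges <- edges[abs(edges$tau) > edge_cut, c("from", "to", "tau")]
  edges$edge_class <- dplyr::case_when(
    edges$tau > sync_cut ~ "synchronous",
    edges$tau < -sync_cut ~ "anti-synchronous",
    TRUE ~ "weak"
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(
    list(nodes = tm$nodes, edges = edges,
         edge_cut = edge_cut, sync_cut = sync_cut,
         condition = tm$condition),
    class = "sync_network"
  )
}

#' @export
print.sync_network <- function(x, ...) {
  cat("<sync_network> ", x$condition, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (|tau| > ", x$edge_cut, ")\n", sep = "")
  print(table(x$edges$edge_class))
  invisible(x)
}

#' @method tidy sync_network
#' @export
tidy.sync_network <- function(x, ...) {
  dplyr::mutate(x$edges, condition = x$condition)
}

#' @method glance sync_network
#' @export
glance.sync_network <- function(x, ...) {
  tibble(condition = x$condition,
         n_nodes = length(x$nodes),
         n_edges = nrow(x$edges),
         n_synchronous = sum(x$edges$edge_class == "synchronous"),
         n_antisynchronous = sum(x$edges$edge_class == "anti-synchronous"),
         n_weak = sum(x$edges$edge_class == "weak"),
         edge_cut = x$edge_cut, sync_cut = x$sync_cut)
}
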