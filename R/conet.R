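#' Soft-thresholded correlation network for one group
#'
#' Builds a weighted metabolite co-expression network on one group's
#' samples: the adjacency is `|pearson correlation|^beta` (or the signed
#' correlation mapped to `[0,1]` before powering, with `signed = TRUE`).
#' The soft power `beta` is selected by the scale-free topology criterion:
#' the smallest candidate whose connectivity distribution fits a power law
#' with `R^2 >= r2_cut`; if no candidate reaches the cut, the candidate
#' maximizing `R^2` is used.
#'
#' @param study An [expr_study()].
#' @param group Group label whose samples are used.
#' @param powers Candidate integer soft powers (default `1:20`).
#' @param r2_cut Scale-free fit threshold (default 0.8).
#' @param signed If `TRUE`, adjacency is `((1 + r)/2)^beta` (signed
#'   network); default unsigned `|r|^beta`.
#' @param n_bins Connectivity bins passed to [scale_free_fit()].
#' @return A `weighted_network`: list with `nodes`, `adjacency` (symmetric,
#'   entries in `[0,1]`, zero diagonal), `soft_power`, `scalefree_r2`,
#'   `r2_profile` (tibble power/r2), `group`.
#' @export
build_correlation_network <- function(study, group, powers = 1:20,
                                      r2_cut = 0.8, signed = FALSE,
                                      n_bins = 10) {
  samples <- group_samples(study, group)
  if (length(samples) < 3L) abort("group must have at least 3 samples")
  vals <- study$values[, samples, drop = FALSE]
  if (nrow(vals) < 3L) abort("need at least 3 metabolites")
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance metabolite(s) in group ", group,
                 " (correlation undefined): ",
                 paste(rownames(vals)[sds == 0], collapse = ", ")))
  }
  r <- cor(t(vals), method = "pearson")
  base <- if (signed) (1 + r) / 2 else abs(r)
  diag(base) <- 0

  r2 <- vapply(powers, function(p) {
    k <- rowSums(base^p)
    suppressWarnings(scale_free_fit(k, n_bins = n_bins))
  }, numeric(1))
  hit <- which(r2 >= r2_cut)
  beta <- if (length(hit) > 0L) powers[hit[1]] else powers[which.max(r2)]
  adj <- base^beta
  diag(adj) <- 0

  structure(
    list(nodes = rownames(vals), adjacency = adj,
         soft_power = beta, scalefree_r2 = r2[powers == beta],
         r2_profile = tibble(power = powers, r2 = r2),
         signed = signed, group = group),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> group ", x$group, ": ", length(x$nodes),
      " nodes, soft power ", x$soft_power,
      " (scale-free R^2 = ", signif(x$scalefree_r2, 3), ")\n", sep = "")
  invisible(x)
}

#' @method tidy weighted_network
#' @export
tidy.weighted_network <- function(x, ...) {
  idx <- which(upper.tri(x$adjacency), arr.ind = TRUE)
  tibble(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]],
         weight = x$adjacency[idx], group = x$group)
}

#' @method glance weighted_network
#' @export
glance.weighted_network <- function(x, ...) {
  tibble(group = x$group, n_nodes = length(x$nodes),
         soft_power = x$soft_power, scalefree_r2 = x$scalefree_r2,
         signed = x$signed)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the (weighted) connectivities into `n_bins` equal-width bins, drops
#' empty bins, and returns the `R^2` of the linear regression of
#' `log10(p(k))` on `log10(mean k per bin)` — the standard scale-free
#' topology criterion for soft-threshold selection.
#'
#' All-equal connectivities leave a single occupied bin; the fit is then
#' undefined and 0 is returned with a warning. A fit on only two occupied
#' bins is trivially perfect and is flagged with a warning as
#' low-confidence.
#'
#' @param k Numeric vector of connectivities (ideally named by node).
#' @param n_bins Number of equal-width bins (default 10).
#' @return The regression `R^2`, a single number in `[0, 1]`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 5L) abort("need at least 5 nodes with positive connectivity")
  if (max(k) == min(k)) {
    warn("all connectivities equal; scale-free fit undefined, returning 0")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  k_bar <- tapply(k, bin, mean)
  keep <- !is.na(p_k) & p_k > 0
  p_k <- p_k[keep]
  k_bar <- k_bar[keep]
  if (length(p_k) < 2L) {
    warn("fewer than 2 occupied connectivity bins; returning 0")
    return(0)
  }
  if (length(p_k) == 2L) {
    warn("only 2 occupied connectivity bins; scale-free R^2 is trivially 1")
  }
  fit <- lm(log10(p_k) ~ log10(k_bar))
  summary(fit)$r.squared
}

#' Degree-based network structure entropy
#'
#' Node importance is its share of total connectivity,
#' `I_i = k_i / sum_j k_j`, and the network structure entropy is
#' `E = -sum_i I_i ln I_i` (natural log; `0 ln 0 := 0`). `E` ranges from 0
#' (one node holds all connectivity) to `ln N` (perfectly homogeneous
#' degrees), so it measures how evenly connectivity is spread over the
#' network.
#'
#' @param net A `weighted_network`, a `sync_network` (edges counted with
#'   `|tau|` as weight), or a symmetric adjacency matrix.
#' @param binary If `TRUE`, use hard degree (count of nonzero adjacency
#'   entries) instead of the weighted row sum.
#' @return An `entropy_result`: list with `entropy`, `importance` (named,
#'   sums to 1), `degrees` (named k_i), `n_nodes`, and the label of the
#'   source network.
#' @examples
#' adj <- matrix(1, 4, 4) - diag(4)            # K4: equal degrees
#' rownames(adj) <- colnames(adj) <- paste0("m", 1:4)
#' network_entropy(adj)$entropy                # ln 4
#' @export
network_entropy <- function(net, binary = FALSE) {
  label <- NULL
  if (inherits(net, "weighted_network")) {
    adj <- net$adjacency
    label <- net$group
  } else if (inherits(net, "sync_network")) {
    adj <- sync_adjacency(net, weighted = TRUE)
    label <- net$condition
  } else {
    adj <- as.matrix(net)
  }
  if (is.null(rownames(adj))) {
    rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  }
  k <- if (binary) rowSums(adj != 0) else rowSums(adj)
  total <- sum(k)
  if (total <= 0) abort("all-zero adjacency: node importance undefined")
  imp <- k / total
  terms <- ifelse(imp > 0, imp * log(imp), 0)
  structure(
    list(entropy = -sum(terms),
         importance = imp, degrees = k,
         n_nodes = nrow(adj), label = label),
    class = "entropy_result"
  )
}

# |tau|-weighted (or binary) adjacency matrix of a sync_network
sync_adjacency <- function(net, weighted = TRUE) {
  n <- length(net$nodes)
  adj <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    w <- if (weighted) abs(net$edges$tau) else 1
    adj[cbind(i, j)] <- w
    adj[cbind(j, i)] <- w
  }
  adj
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("<entropy_result>", if (!is.null(x$label)) paste0(x$label, ":"),
      "E =", signif(x$entropy, 4), "over", x$n_nodes,
      "nodes (max ln N =", signif(log(x$n_nodes), 4), ")\n")
  invisible(x)
}

#' @method tidy entropy_result
#' @export
tidy.entropy_result <- function(x, ...) {
  tibble(node = names(x$importance),
         degree = unname(x$degrees),
         importance = unname(x$importance))
}

#' @method glance entropy_result
#' @export
glance.entropy_result <- function(x, ...) {
  tibble(label = x$label %||% NA_character_, entropy = x$entropy,
         n_nodes = x$n_nodes, max_entropy = log(x$n_nodes))
}

#' Entropy recovery of a treated group toward the healthy baseline
#'
#' Expresses a dose group's network entropy as the percentage of the
#' disease-induced entropy loss that treatment has restored:
#' `100 * (E_dose - E_vehicle) / (E_sham - E_vehicle)`. 0% means no
#' recovery (entropy at the diseased vehicle level), 100% means full return
#' to the healthy sham level.
#'
#' @param e_sham,e_vehicle,e_dose Network entropies of the sham (healthy),
#'   vehicle (diseased, untreated) and treated group.
#' @return Recovery percentage (can exceed 100 for overshoot).
#' @examples
#' entropy_recovery(3.59, 3.51, 3.52)  # 12.5
#' @export
entropy_recovery <- function(e_sham, e_vehicle, e_dose) {
  if (e_sham == e_vehicle) {
    abort("sham and vehicle entropies equal: recovery fraction undefined")
  }
  100 * (e_dose - e_vehicle) / (e_sham - e_vehicle)
}
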