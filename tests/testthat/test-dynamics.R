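mods <- function(...) lapply(list(...), sort)

test_that("match_modules pairs by greedy best Jaccard", {
  a <- mods(c("A", "B", "C", "D"), c("X", "Y", "Z"))
  ident <- match_modules(a, a, jaccard_min = 0.5)
  expect_equal(nrow(ident), 2L)
  expect_equal(ident$jaccard, c(1, 1))

  disjoint <- match_modules(mods(c("A", "B", "C")),
                            mods(c("X", "Y", "Z")))
  expect_equal(nrow(disjoint), 0L)

  partial <- match_modules(mods(c("A", "B", "C", "D")),
                           mods(c("B", "C", "D", "E")), jaccard_min = 0.5)
  expect_equal(partial$jaccard, 3 / 5)
  expect_equal(partial$shared[[1]], c("B", "C", "D"))

  expect_error(match_modules(a, a, jaccard_min = 0), "jaccard_min")
})

test_that("raising jaccard_min never grows the matched set", {
  withr::with_seed(401, {
    pool <- sprintf("m%02d", 1:20)
    a <- lapply(1:4, function(i) sample(pool, sample(3:6, 1)))
    b <- lapply(1:4, function(i) sample(pool, sample(3:6, 1)))
  })
  cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  n_matches <- vapply(cuts, function(j) {
    nrow(match_modules(a, b, jaccard_min = j))
  }, numeric(1))
  expect_true(all(diff(n_matches) <= 0))
})

fake_module_set <- function(node_sets, condition) {
  node_sets <- lapply(node_sets, sort)
  structure(list(
    modules = tibble::tibble(
      module = seq_along(node_sets), nodes = node_sets,
      size = lengths(node_sets), score = rev(seq_along(node_sets)),
      seed = vapply(node_sets, `[`, character(1), 1)),
    parameters = list(), condition = condition), class = "module_set")
}

test_that("classify_dynamics labels conservative and emerging modules", {
  triple <- c("tau", "tyr", "leu")         # conserved across dose pairs
  sets <- list(
    "DH1/DH2" = fake_module_set(list(c(triple, "x1"),
                                     c("a", "b", "c")), "DH1/DH2"),
    "DH2/DH3" = fake_module_set(list(c("a", "b", "c")), "DH2/DH3"),
    "DH3/DH4" = fake_module_set(list(c(triple, "y1"),
                                     c("gly", "glu", "val")), "DH3/DH4"),
    "DH1-DH4" = fake_module_set(list(c("a", "b", "c")), "DH1-DH4"))
  dyn <- classify_dynamics(sets, jaccard_min = 0.5)
  expect_equal(dyn$conservative_allosteric, sort(triple))
  # conservative nodes live in both dose-pair module unions
  expect_true(all(dyn$conservative_allosteric %in%
                    unlist(module_sets <- sets[["DH1/DH2"]]$modules$nodes)))
  expect_true(all(dyn$conservative_allosteric %in%
                    unlist(sets[["DH3/DH4"]]$modules$nodes)))
  # gly/glu/val absent from DH2/DH3 modules: emerging in DH3/DH4
  expect_equal(dyn$emerging[["DH3/DH4"]],
               list(sort(c(triple, "y1")), sort(c("gly", "glu", "val"))))
  # a-b-c present in DH1/DH2: nothing emerges in DH2/DH3
  expect_equal(length(dyn$emerging[["DH2/DH3"]]), 0L)
  # emerging sets are disjoint from the preceding pair's node union
  for (p in names(dyn$emerging)) {
    prev <- names(sets)[match(p, c("DH2/DH3", "DH3/DH4"))]
    prev_nodes <- unlist(sets[[prev]]$modules$nodes)
    for (s in dyn$emerging[[p]]) {
      expect_equal(intersect(s, prev_nodes), character(0))
    }
  }
})

test_that("a module shared by all conditions emerges nowhere", {
  shared <- fake_module_set(list(c("a", "b", "c")), "x")
  sets <- list("DH1/DH2" = shared, "DH2/DH3" = shared,
               "DH3/DH4" = shared, "DH1-DH4" = shared)
  dyn <- classify_dynamics(sets)
  expect_equal(lengths(dyn$emerging), c("DH2/DH3" = 0L, "DH3/DH4" = 0L))
  expect_equal(dyn$conservative_allosteric, c("a", "b", "c"))
})

test_that("classify_dynamics is order invariant and names missing input", {
  shared <- fake_module_set(list(c("a", "b", "c")), "x")
  sets <- list("DH1/DH2" = shared, "DH2/DH3" = shared,
               "DH3/DH4" = shared, "DH1-DH4" = shared)
  d1 <- classify_dynamics(sets)
  d2 <- classify_dynamics(rev(sets))
  expect_equal(tidy(d1), tidy(d2))
  expect_error(classify_dynamics(sets[-2]), "DH2/DH3")
})

test_that("persistent pairs must be synchronous in every group network", {
  tau_ab_high <- diag(3)
  dimnames(tau_ab_high) <- list(c("a", "b", "c"), c("a", "b", "c"))
  tau_ab_high["a", "b"] <- tau_ab_high["b", "a"] <- 0.9
  tau_ab_low <- tau_ab_high
  tau_ab_low["a", "b"] <- tau_ab_low["b", "a"] <- 0.6

  nets_all <- lapply(paste0("DH", 1:4), function(g) {
    toy_sync_network(tau_ab_high, condition = g)
  })
  names(nets_all) <- paste0("DH", 1:4)
  shared <- fake_module_set(list(c("a", "b", "c")), "x")
  sets <- list("DH1/DH2" = shared, "DH2/DH3" = shared,
               "DH3/DH4" = shared, "DH1-DH4" = shared)
  dyn <- classify_dynamics(sets, group_networks = nets_all)
  expect_equal(dyn$persistent_pairs$from, "a")
  expect_equal(dyn$persistent_pairs$to, "b")

  nets_drop <- nets_all
  nets_drop[["DH3"]] <- toy_sync_network(tau_ab_low, condition = "DH3")
  dyn2 <- classify_dynamics(sets, group_networks = nets_drop)
  expect_equal(nrow(dyn2$persistent_pairs), 0L)
})

test_that("simulated dynamics recover the planted module structure", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_study(cfg)
  conds <- list("DH1/DH2" = c("DH1", "DH2"), "DH2/DH3" = c("DH2", "DH3"),
                "DH3/DH4" = c("DH3", "DH4"),
                "DH1-DH4" = paste0("DH", 1:4))
  sets <- lapply(names(conds), function(cn) {
    sync_modules(sim$study, conds[[cn]], condition = cn)$modules
  })
  names(sets) <- names(conds)
  group_nets <- lapply(paste0("DH", 1:4), function(g) {
    build_sync_network(tau_matrix(sim$study, g))
  })
  names(group_nets) <- paste0("DH", 1:4)
  dyn <- classify_dynamics(sets, group_networks = group_nets)

  # conservative core: the nodes shared by the planted low- and high-pair
  # modules survive the matching
  shared_truth <- intersect(sim$truth$true_modules$low_pair$nodes,
                            sim$truth$true_modules$high_pair$nodes)
  expect_true(all(shared_truth %in% dyn$conservative_allosteric))
  # the planted emerging module surfaces in DH3/DH4
  emerging_truth <- sort(sim$truth$true_modules$emerging$nodes)
  hits <- vapply(dyn$emerging[["DH3/DH4"]], function(s) {
    length(intersect(s, emerging_truth)) / length(union(s, emerging_truth))
  }, numeric(1))
  expect_gte(max(c(hits, 0)), 0.8)
  # the planted persistent pair shows up in every group network
  pp <- sim$truth$true_modules$persistent_pair$nodes
  key <- paste(dyn$persistent_pairs$from, dyn$persistent_pairs$to)
  expect_true(paste(pp[1], pp[2]) %in% key)
})
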