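test_that("the six pattern regions classify exactly as defined", {
  cases <- tibble::tribble(
    ~v1,  ~v2,  ~pattern, ~yinyang,
    -0.5,  0.3, "PT", "Yang",
     0.4, -0.2, "NT", "Yin",
     0.3,  0.8, "PA", "Yang",
     0.8,  0.3, "PR", "Yin",
    -0.8, -0.3, "NA", "Yang",
    -0.3, -0.8, "NR", "Yin",
     0.0,  0.0, "NC", "neutral",
     0.0,  0.5, "NC", "neutral",
     0.5,  0.5, "NC", "neutral",
    -0.2, -0.2, "NC", "neutral"
  )
  out <- classify_patterns(cases[, c("v1", "v2")])
  expect_equal(out$pattern, cases$pattern)
  expect_equal(out$yinyang, cases$yinyang)
})

test_that("classification is a total partition of the change plane", {
  withr::with_seed(11, {
    v1 <- c(runif(400, -3, 3), 0, 0, 1, -1)
    v2 <- c(runif(400, -3, 3), 0, 1, 0, -1)
  })
  out <- classify_patterns(data.frame(v1 = v1, v2 = v2))
  expect_true(all(out$pattern %in%
                    c("PT", "NT", "PA", "PR", "NA", "NR", "NC")))
  # each point hits exactly one region: re-deriving membership by explicit
  # region predicates must agree everywhere
  regions <- cbind(
    PT = v1 < 0 & v2 > 0, NT = v1 > 0 & v2 < 0,
    PA = v1 > 0 & v2 > v1, PR = v2 > 0 & v1 > v2,
    "NA" = v2 < 0 & v1 < v2, NR = v1 < 0 & v2 < v1)
  hits <- rowSums(regions)
  expect_true(all(hits <= 1))
  expect_equal(out$pattern == "NC", hits == 0)
})

test_that("global sign flip maps PT<->NT, PA<->NR, NA<->PR", {
  withr::with_seed(12, {
    v1 <- runif(300, -2, 2)
    v2 <- runif(300, -2, 2)
  })
  a <- classify_patterns(data.frame(v1 = v1, v2 = v2))$pattern
  b <- classify_patterns(data.frame(v1 = -v1, v2 = -v2))$pattern
  flip <- c(PT = "NT", NT = "PT", PA = "NR", NR = "PA",
            "NA" = "PR", PR = "NA", NC = "NC")
  expect_equal(unname(flip[a]), b)
})

test_that("compute_changes recovers planted log2 fold changes", {
  means <- cbind(sham = c(100, 100, 100),
                 vehicle = c(100, 200, 50),
                 DH1 = c(100, 100, 100))
  rownames(means) <- c("flat", "up", "down")
  study <- toy_study(means, noise_sd = 0)
  ch <- compute_changes(study, eps = 0.01)
  expect_equal(ch$v1, c(0, 1, -1))          # log2(1), log2(2), log2(0.5)
  expect_equal(ch$v2, c(0, -1, 1))
  # the eps band snaps small changes to exactly zero
  ch_wide <- compute_changes(study, eps = 1.5)
  expect_true(all(ch_wide$v1 == 0 & ch_wide$v2 == 0))
  expect_error(compute_changes(study, eps = -1), "nonnegative")
})

test_that("compute_changes rejects nonpositive abundances", {
  means <- cbind(sham = c(1, 1, 1), vehicle = c(1, 1, 1), DH1 = c(1, 1, 1))
  rownames(means) <- paste0("m", 1:3)
  study <- toy_study(means, noise_sd = 0)
  study$values[1, 1] <- -1
  expect_error(compute_changes(study), "strictly positive")
})

test_that("summarize_yinyang counts and the four statistics are consistent", {
  assignments <- tibble::tibble(
    metabolite = sprintf("m%02d", 1:24),
    group = "DH1",
    pattern = rep(c("PT", "NT", "PA", "PR", "NA", "NR", "NC"),
                  c(10, 5, 2, 3, 1, 2, 1)))
  s <- summarize_yinyang(assignments)
  expect_equal(s$n_PT, 10L)
  expect_equal(s$separate_ratio, 2)
  expect_equal(s$separate_difference, 5L)
  expect_equal(s$yang, 13L)          # PT + PA + NA
  expect_equal(s$yin, 10L)           # NT + PR + NR
  expect_equal(s$overall_ratio, 1.3)
  expect_equal(s$overall_difference, 3L)
  # counts including NC partition the metabolite list
  expect_equal(sum(s[paste0("n_", c("PT", "NT", "PA", "PR",
                                    "NA", "NR", "NC"))]),
               nrow(assignments))

  balanced <- tibble::tibble(metabolite = sprintf("m%d", 1:6),
                             group = "DH2",
                             pattern = c("PT", "NT", "PA", "PR", "NA", "NR"))
  sb <- summarize_yinyang(balanced)
  expect_equal(sb$overall_ratio, 1)
  expect_equal(sb$overall_difference, 0L)
  # zero denominator reported as Inf (undefined)
  no_yin <- tibble::tibble(metabolite = "m1", group = "g", pattern = "PT")
  expect_equal(summarize_yinyang(no_yin)$separate_ratio, Inf)
})

test_that("overall difference negates under a global sign flip", {
  withr::with_seed(13, {
    ch <- data.frame(metabolite = sprintf("m%d", 1:50), group = "DH1",
                     v1 = runif(50, -2, 2), v2 = runif(50, -2, 2))
  })
  s_pos <- summarize_yinyang(classify_patterns(ch))
  ch_neg <- transform(ch, v1 = -v1, v2 = -v2)
  s_neg <- summarize_yinyang(classify_patterns(ch_neg))
  expect_equal(s_pos$overall_difference, -s_neg$overall_difference)
})

test_that("vehicle_yinyang classifies the disease stage by v1 sign", {
  means <- cbind(sham = c(100, 100, 100), vehicle = c(150, 70, 100),
                 DH1 = c(100, 100, 100))
  rownames(means) <- c("up", "down", "flat")
  study <- toy_study(means, noise_sd = 0)
  vy <- vehicle_yinyang(study, eps = 0.05)
  expect_equal(setNames(vy$state, vy$metabolite),
               c(up = "Yang", down = "Yin", flat = "neutral"))
})

test_that("a two-thirds-Yin plan yields a two-thirds Yin vehicle state", {
  cfg <- sim_config(n_metabolites = 30, n_per_group = 10, seed = 21,
                    module_plan = list())
  sim <- simulate_study(cfg)
  vy <- vehicle_yinyang(sim$study)
  expect_equal(mean(vy$state == "Yin"), 2 / 3, tolerance = 0.1)
})

test_that("dose_trend fits counts against the dose axis", {
  exact <- dose_trend(data.frame(group = paste0("DH", 1:4),
                                 count = c(8, 6, 4, 2)))
  expect_equal(exact$r, -1)
  expect_equal(exact$slope, -2)
  expect_equal(exact$intercept, 10)

  # independent check of Pearson r by its definition
  y <- c(3, 5, 4, 8)
  x <- 1:4
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- dose_trend(data.frame(group = paste0("DH", 1:4), count = y))
  expect_equal(got$r, r_manual)

  flat <- dose_trend(data.frame(group = paste0("DH", 1:4),
                                count = rep(4, 4)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))
  expect_equal(flat$slope, 0)

  expect_error(dose_trend(data.frame(group = "a", count = 1)), "3 groups")
})

test_that("pattern_overlap tracks a pattern's metabolites across groups", {
  assignments <- tibble::tibble(
    metabolite = c("a", "a", "b", "c"),
    group = c("DH1", "DH2", "DH1", "DH2"),
    pattern = c("PT", "PT", "PT", "NT"))
  ov <- pattern_overlap(assignments, "PT")
  expect_equal(ov$metabolite, c("a", "b"))
  expect_equal(ov$n_groups, c(2, 1))
})
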