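#' Simulation configuration for a synthetic dose-response study
#'
#' Describes a metabolomics study to generate: metabolite and group layout,
#' a pattern plan (which six-pattern label each metabolite should carry in
#' each treated group), a module plan (which metabolite sets should form
#' synchronous modules at a target Kendall tau under which conditions), and
#' the noise model.
#'
#' Values are simulated on a log2 abundance scale — baseline plus planted
#' group-mean shifts plus module latent factors plus i.i.d. Gaussian noise
#' — and exponentiated, so emitted abundances are strictly positive and
#' roughly log-normal. Latent factors are centered within each group, so
#' planting a module never moves group means: pattern labels and module
#' correlations are controlled independently.
#'
#' @param n_metabolites Number of metabolites (default 41).
#' @param n_per_group Samples per group (default 10; minimum 3).
#' @param group_names Ordered group labels (default sham, vehicle,
#'   DH1..DH4).
#' @param dose_levels Named doses in ml/kg (default DH1:1, DH2:2.5, DH3:5,
#'   DH4:10, others 0).
#' @param pattern_plan Data frame `metabolite`, `group`, `pattern`; default
#'   [default_pattern_plan()] over the treated groups.
#' @param module_plan List of entries `list(nodes, tau, sign, groups)`
#'   (target absolute tau in (0, 1]; sign +1 for all-positive loadings, -1
#'   for alternating signs giving anti-synchronous edges); default
#'   [default_module_plan()].
#' @param noise_sd Per-sample Gaussian noise SD in log2 units
#'   (default 0.2).
#' @param baseline_mean Baseline log2 abundance (default 10).
#' @param effect_size Log2 mean shift implementing one sign unit of change
#'   (default 1).
#' @param dose_gain Per-dose-rank multiplier on treatment effects: group at
#'   dose rank r has its effect scaled by `1 + dose_gain * (r - 1)`,
#'   producing monotone dose trends in the pattern magnitudes
#'   (default 0.25).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_metabolites = 41, n_per_group = 10,
                       group_names = c("sham", "vehicle",
                                       paste0("DH", 1:4)),
                       dose_levels = NULL,
                       pattern_plan = NULL, module_plan = NULL,
                       noise_sd = 0.2, baseline_mean = 10,
                       effect_size = 1, dose_gain = 0.25, seed = 1) {
  if (n_per_group < 3L) {
    abort("n_per_group must be >= 3 (rank correlation degenerate below)")
  }
  if (noise_sd < 0 || effect_size < 0) {
    abort("noise_sd and effect_size must be nonnegative")
  }
  metabolites <- sprintf("M%02d", seq_len(n_metabolites))
  treated <- setdiff(group_names, c("sham", "vehicle"))
  if (is.null(dose_levels)) {
    defaults <- c(DH1 = 1, DH2 = 2.5, DH3 = 5, DH4 = 10)
    dose_levels <- setNames(rep(0, length(group_names)), group_names)
    known <- intersect(group_names, names(defaults))
    dose_levels[known] <- defaults[known]
  }
  pattern_plan <- pattern_plan %||%
    default_pattern_plan(metabolites, treated)
  pattern_plan <- as_tibble(pattern_plan)
  stray <- setdiff(pattern_plan$metabolite, metabolites)
  if (length(stray) > 0L) {
    abort(paste0("pattern_plan names unknown metabolite(s): ",
                 paste(unique(stray), collapse = ", ")))
  }
  module_plan <- module_plan %||% default_module_plan(metabolites)
  for (entry in module_plan) {
    stray <- setdiff(entry$nodes, metabolites)
    if (length(stray) > 0L) {
      abort(paste0("module_plan names unknown metabolite(s): ",
                   paste(stray, collapse = ", ")))
    }
    if (!(entry$tau > 0 && entry$tau <= 1)) {
      abort("module target |tau| must be in (0, 1]")
    }
  }
  structure(list(
    n_metabolites = n_metabolites, n_per_group = n_per_group,
    group_names = group_names, dose_levels = dose_levels,
    metabolites = metabolites, treated = treated,
    pattern_plan = pattern_plan, module_plan = module_plan,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    effect_size = effect_size, dose_gain = dose_gain, seed = seed
  ), class = "sim_config")
}

#' Default pattern plan emulating a dose-responsive biomarker panel
#'
#' Splits the metabolites into a disease-downregulated pool (about two
#' thirds, matching the Yin-dominated disease state) and an upregulated
#' pool, then assigns per-group patterns with monotone dose trends: PT
#' counts rise and NT counts fall with dose rank, NA/PR grow, PA stays
#' small. The first metabolites of the downregulated pool are PT in every
#' group (constantly reversed dose-sensitive markers).
#'
#' @param metabolites Character vector of metabolite ids.
#' @param treated Treated group labels in increasing dose order.
#' @return A tibble `metabolite`, `group`, `pattern`.
#' @export
default_pattern_plan <- function(metabolites,
                                 treated = paste0("DH", 1:4)) {
  n <- length(metabolites)
  n_neg <- round(2 * n / 3)
  neg <- metabolites[seq_len(n_neg)]
  pos <- metabolites[seq.int(n_neg + 1L, n)]
  k <- length(treated)
  frac <- function(start, step, pool_n) {
    pmin(pmax(round(start + step * (seq_len(k) - 1)), 0), pool_n)
  }
  n_pt <- frac(round(0.45 * n_neg), max(1, round(0.07 * n_neg)), n_neg)
  n_na <- pmin(frac(round(0.2 * n_neg), 1, n_neg), n_neg - n_pt)
  n_nt <- frac(round(0.6 * length(pos)), -max(1, round(0.15 * length(pos))),
               length(pos))
  n_pr <- pmin(frac(round(0.25 * length(pos)), 1, length(pos)),
               length(pos) - n_nt)
  purrr::map_dfr(seq_len(k), function(i) {
    g <- treated[i]
    neg_pat <- rep("NR", length(neg))
    neg_pat[seq_len(n_pt[i])] <- "PT"
    if (n_na[i] > 0) neg_pat[n_pt[i] + seq_len(n_na[i])] <- "NA"
    pos_pat <- rep("PA", length(pos))
    pos_pat[seq_len(n_nt[i])] <- "NT"
    if (n_pr[i] > 0) pos_pat[n_nt[i] + seq_len(n_pr[i])] <- "PR"
    tibble(metabolite = c(neg, pos), group = g,
           pattern = c(neg_pat, pos_pat))
  })
}

#' Default module plan emulating cross-dose module dynamics
#'
#' Plants five synchronous structures: a full-course module present in all
#' four treated groups; a low-dose-pair and a high-dose-pair module that
#' share three nodes (a conservative-allosteric core); a module unique to
#' the middle pair; an emerging module present only at the two highest
#' doses; and one persistent two-node pair present in every treated group.
#'
#' @param metabolites Character vector of at least 19 metabolite ids.
#' @param tau Target absolute Kendall tau for the modules (default 0.9).
#' @return A named list of module-plan entries.
#' @export
default_module_plan <- function(metabolites, tau = 0.9) {
  if (length(metabolites) < 19L) {
    return(list())
  }
  m <- metabolites
  list(
    full_course = list(nodes = m[1:4], tau = tau, sign = 1,
                       groups = paste0("DH", 1:4)),
    low_pair = list(nodes = m[5:8], tau = tau, sign = 1,
                    groups = c("DH1", "DH2")),
    high_pair = list(nodes = m[6:9], tau = tau, sign = 1,
                     groups = c("DH3", "DH4")),
    # members chosen so their planned patterns agree between DH2 and DH3:
    # a synchronous module's metabolites must co-move under its condition
    mid_pair = list(nodes = m[if (length(m) >= 31) 28:31 else 14:17],
                    tau = tau, sign = 1,
                    groups = c("DH2", "DH3")),
    emerging = list(nodes = m[10:13], tau = tau, sign = 1,
                    groups = c("DH3", "DH4")),
    persistent_pair = list(nodes = m[18:19], tau = 0.95, sign = 1,
                           groups = paste0("DH", 1:4))
  )
}

# planted (v1, v2) in log2 units for a pattern at effect e and dose scale f
planted_changes <- function(pattern, e, f) {
  v1 <- switch(pattern,
               PT = -e, "NA" = -e, NR = -e,
               NT = e, PA = e, PR = e,
               NC = 0)
  v2 <- switch(pattern,
               PT = e * f,
               NT = -e * f,
               PA = v1 * (1 + f),
               NR = v1 * (1 + f),
               PR = v1 / (1 + f),
               "NA" = v1 / (1 + f),
               NC = 0)
  c(v1 = v1, v2 = v2)
}

#' Simulate a dose-response metabolomics study with planted ground truth
#'
#' Builds group means so that the two-stage log2 changes (vehicle vs sham,
#' then each treated group vs vehicle) land in the exact pattern regions of
#' the plan; adds one centered latent factor per planted module with
#' loading chosen through the Gaussian sine relation
#' `tau = (2/pi) * asin(rho)` so pairwise Kendall tau hits the target in
#' expectation; adds i.i.d. Gaussian noise; and exponentiates to strictly
#' positive abundances. Identical config and seed give an identical matrix.
#'
#' A metabolite whose planned patterns demand both an upregulated and a
#' downregulated disease stage (e.g. PT in one group, PA in another) is a
#' contradiction and is rejected by name.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result`: `study` (an [expr_study()]) and
#'   `truth` (list with `true_patterns`, `true_modules`,
#'   `vehicle_states`, `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mets <- config$metabolites
  e <- config$effect_size
  treated <- config$treated
  ranks <- setNames(seq_along(treated), treated)
  f_of <- function(g) 1 + config$dose_gain * (ranks[[g]] - 1)

  # resolve plan into per-(metabolite, group) shifts; v1 shared per metabolite
  plan <- config$pattern_plan
  plan_key <- split(plan, plan$metabolite)
  v1 <- setNames(rep(0, length(mets)), mets)
  delta <- matrix(0, length(mets), length(config$group_names),
                  dimnames = list(mets, config$group_names))
  for (m in names(plan_key)) {
    pats <- plan_key[[m]]
    needs_neg <- any(pats$pattern %in% c("PT", "NA", "NR"))
    needs_pos <- any(pats$pattern %in% c("NT", "PA", "PR"))
    if (needs_neg && needs_pos) {
      abort(paste0("contradictory pattern plan for metabolite ", m,
                   ": patterns require both downregulated and upregulated",
                   " disease stage"))
    }
    any_pat <- pats$pattern[pats$pattern != "NC"][1]
    v1[m] <- if (is.na(any_pat)) 0 else {
      planted_changes(any_pat, e, 1)[["v1"]]
    }
    delta[m, "vehicle"] <- v1[m]
    for (i in seq_len(nrow(pats))) {
      g <- pats$group[i]
      ch <- planted_changes(pats$pattern[i], e, f_of(g))
      if (ch[["v1"]] != v1[m]) {
        abort(paste0("contradictory pattern plan for metabolite ", m))
      }
      delta[m, g] <- v1[m] + ch[["v2"]]
    }
    # treated groups without a planned pattern keep the vehicle mean
    unplanned <- setdiff(treated, pats$group)
    delta[m, unplanned] <- v1[m]
  }
  # metabolites absent from the plan: flat across all groups (delta 0)

  # module loading from the Gaussian tau-to-Pearson sine relation
  loading_for <- function(tau_target) {
    rho <- sin(pi * tau_target / 2)
    if (config$noise_sd == 0) return(1)
    if (rho >= 1 - 1e-12) return(config$noise_sd * 1e6)
    config$noise_sd * sqrt(rho / (1 - rho))
  }
  check_module_conflicts(config$module_plan)

  n <- config$n_per_group
  samples <- unlist(lapply(config$group_names,
                           function(g) sprintf("%s_%02d", g, seq_len(n))))
  sample_group <- rep(config$group_names, each = n)

  vals <- withr::with_seed(config$seed, {
    x <- matrix(rnorm(length(mets) * length(samples),
                      sd = config$noise_sd),
                nrow = length(mets),
                dimnames = list(mets, samples))
    x <- x + config$baseline_mean + delta[, sample_group]
    for (entry in config$module_plan) {
      lam <- loading_for(entry$tau)
      signs <- if (isTRUE(entry$sign == -1) || identical(entry$sign, -1L)) {
        rep_len(c(1, -1), length(entry$nodes))
      } else rep(1, length(entry$nodes))
      for (g in entry$groups) {
        cols <- which(sample_group == g)
        f <- rnorm(length(cols))
        f <- f - mean(f)              # keep group means untouched
        x[entry$nodes, cols] <- x[entry$nodes, cols] +
          lam * outer(signs, f)
      }
    }
    x
  })

  design <- tibble(sample = samples, group = sample_group,
                   dose = unname(config$dose_levels[sample_group]))
  study <- expr_study(2^vals, design)

  true_modules <- purrr::map(config$module_plan, function(entry) {
    list(nodes = entry$nodes, tau = entry$tau, sign = entry$sign,
         condition = paste(entry$groups, collapse = "/"))
  })
  vehicle_states <- tibble(
    metabolite = mets,
    state = dplyr::case_when(v1 > 0 ~ "Yang", v1 < 0 ~ "Yin",
                             TRUE ~ "neutral"))
  structure(list(
    study = study,
    truth = list(true_patterns = plan, true_modules = true_modules,
                 vehicle_states = vehicle_states, config = config)
  ), class = "sim_result")
}

check_module_conflicts <- function(module_plan) {
  if (length(module_plan) < 2L) return(invisible(NULL))
  for (i in seq_along(module_plan)) {
    for (j in seq_along(module_plan)) {
      if (j <= i) next
      a <- module_plan[[i]]
      b <- module_plan[[j]]
      shared <- intersect(a$nodes, b$nodes)
      if (length(shared) > 0L &&
          length(intersect(a$groups, b$groups)) > 0L) {
        abort(paste0("metabolite(s) ", paste(shared, collapse = ", "),
                     " planted in two modules under overlapping groups;",
                     " target tau would be ambiguous"))
      }
    }
  }
  invisible(NULL)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>\n")
  print(x$study)
  cat("planted:", nrow(x$truth$true_patterns), "pattern labels,",
      length(x$truth$true_modules), "module(s)\n")
  invisible(x)
}

#' Write a simulated study and its ground truth to disk
#'
#' @param sim A `sim_result` from [simulate_study()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  paths <- write_study(sim$study, dir, prefix = "simulated")
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- sim$truth
  truth$config <- unclass(truth$config)[
    c("n_metabolites", "n_per_group", "group_names", "dose_levels",
      "noise_sd", "baseline_mean", "effect_size", "dose_gain", "seed")]
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, truth = truth_path))
}
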