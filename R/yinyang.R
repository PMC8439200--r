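#' Two-stage expression changes per metabolite
#'
#' For each metabolite, computes the disease change `v1` (vehicle vs sham)
#' and, for every treated group, the treatment change `v2` (treated group
#' vs vehicle), both as log2 fold changes of group means. Changes smaller
#' in magnitude than `eps` are snapped to exactly 0 ("no change" band), so
#' the downstream six-pattern classifier can use strict sign tests.
#'
#' With `mean_type = "geometric"` (default) the fold change is the
#' difference of group means of `log2(value)` — the usual choice for
#' log-scale abundance data; `"arithmetic"` uses `log2(mean(value))`.
#'
#' @param study An [expr_study()] with strictly positive abundances.
#' @param eps Zero band half-width in log2 units (default 0.05).
#' @param sham,vehicle Labels of the healthy and diseased-untreated groups.
#' @param treated Labels of treated groups; default every other group, in
#'   design order.
#' @param mean_type `"geometric"` or `"arithmetic"` group mean.
#' @return A tibble with columns `metabolite`, `group`, `v1`, `v2`.
#' @export
compute_changes <- function(study, eps = 0.05, sham = "sham",
                            vehicle = "vehicle", treated = NULL,
                            mean_type = c("geometric", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  if (eps < 0) abort("eps must be nonnegative")
  groups <- unique(study$design$group)
  for (g in c(sham, vehicle)) {
    if (!g %in% groups) abort(paste0("group not in study: ", g))
  }
  treated <- treated %||% setdiff(groups, c(sham, vehicle))
  if (length(treated) == 0L) abort("no treated groups in study")
  if (any(study$values <= 0)) {
    abort("abundances must be strictly positive for log2 fold changes")
  }

  log2_group_mean <- function(g) {
    vals <- study$values[, group_samples(study, g), drop = FALSE]
    switch(mean_type,
           geometric = rowMeans(log2(vals)),
           arithmetic = log2(rowMeans(vals)))
  }
  mu <- vapply(c(sham, vehicle, treated), log2_group_mean,
               numeric(length(study$metabolites)))
  snap <- function(v) ifelse(abs(v) < eps, 0, v)

  v1 <- snap(mu[, vehicle] - mu[, sham])
  purrr::map_dfr(treated, function(g) {
    tibble(metabolite = study$metabolites, group = g,
           v1 = unname(v1),
           v2 = unname(snap(mu[, g] - mu[, vehicle])))
  })
}

#' Classify two-stage changes into the six Yin/Yang patterns
#'
#' Each metabolite's pair of signed changes `(v1, v2)` — disease stage then
#' treatment stage — falls into one of six transformation patterns:
#'
#' * `PT` positive transformation: negative to positive (`v1 < 0 < v2`)
#' * `NT` negative transformation: positive to negative (`v2 < 0 < v1`)
#' * `PA` positive add: positive and rising (`0 < v1 < v2`)
#' * `PR` positive reduce: positive but falling (`0 < v2 < v1`)
#' * `NA` negative add: negative but rising (`v1 < v2 < 0`)
#' * `NR` negative reduce: negative and falling (`v2 < v1 < 0`)
#'
#' `PT`, `PA`, `NA` carry upregulation character (Yang); `NT`, `PR`, `NR`
#' downregulation character (Yin). Any snapped zero or exact tie is `NC`
#' (no change / unclassified), which makes the classification a total
#' partition of the plane.
#'
#' @param changes A data frame with columns `v1`, `v2` (already
#'   eps-snapped), e.g. from [compute_changes()].
#' @return The input tibble with `pattern` and `yinyang` columns added.
#' @examples
#' classify_patterns(data.frame(v1 = c(-0.5, 0.4), v2 = c(0.3, -0.2)))
#' @export
classify_patterns <- function(changes) {
  changes <- as_tibble(changes)
  if (!all(c("v1", "v2") %in% names(changes))) {
    abort("changes must have columns v1 and v2")
  }
  if (any(!is.finite(changes$v1)) || any(!is.finite(changes$v2))) {
    abort("v1 and v2 must be finite")
  }
  changes$pattern <- pattern_label(changes$v1, changes$v2)
  changes$yinyang <- pattern_polarity(changes$pattern)
  changes
}

pattern_label <- function(v1, v2) {
  dplyr::case_when(
    v1 < 0 & v2 > 0 ~ "PT",
    v1 > 0 & v2 < 0 ~ "NT",
    0 < v1 & v1 < v2 ~ "PA",
    0 < v2 & v2 < v1 ~ "PR",
    v1 < v2 & v2 < 0 ~ "NA",
    v2 < v1 & v1 < 0 ~ "NR",
    TRUE ~ "NC"
  )
}

#' Yin/Yang polarity of a pattern label
#'
#' @param pattern Character vector of pattern labels.
#' @return `"Yang"` for PT/PA/NA, `"Yin"` for NT/PR/NR, `"neutral"` for NC.
#' @export
pattern_polarity <- function(pattern) {
  dplyr::case_when(
    pattern %in% c("PT", "PA", "NA") ~ "Yang",
    pattern %in% c("NT", "PR", "NR") ~ "Yin",
    TRUE ~ "neutral"
  )
}

pattern_levels <- c("PT", "NT", "PA", "PR", "NA", "NR", "NC")

#' Per-group cumulative pattern counts and Yin/Yang statistics
#'
#' Counts each pattern per treated group and derives the four summary
#' statistics: `separate_ratio = PT/NT` and `separate_difference = PT - NT`
#' compare the two qualitative-change patterns in isolation;
#' `overall_ratio = (PT+PA+NA)/(NT+PR+NR)` and `overall_difference` compare
#' total Yang against total Yin. A ratio with zero denominator is reported
#' as `Inf` (undefined).
#'
#' @param assignments A data frame with columns `group` and `pattern`, e.g.
#'   from [classify_patterns()].
#' @return A tibble, one row per group: the seven pattern counts (`n_PT`,
#'   ..., `n_NC`), `yang`, `yin`, and the four statistics.
#' @export
summarize_yinyang <- function(assignments) {
  assignments <- as_tibble(assignments)
  counts <- dplyr::count(assignments, .data$group, .data$pattern)
  counts <- tidyr::pivot_wider(counts, names_from = "pattern",
                               values_from = "n", values_fill = 0L,
                               names_prefix = "n_")
  for (p in pattern_levels) {
    col <- paste0("n_", p)
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts[, c("group", paste0("n_", pattern_levels))]
  dplyr::mutate(
    counts,
    yang = .data$n_PT + .data$n_PA + .data$n_NA,
    yin = .data$n_NT + .data$n_PR + .data$n_NR,
    separate_ratio = ifelse(.data$n_NT == 0, Inf, .data$n_PT / .data$n_NT),
    separate_difference = .data$n_PT - .data$n_NT,
    overall_ratio = ifelse(.data$yin == 0, Inf, .data$yang / .data$yin),
    overall_difference = .data$yang - .data$yin
  )
}

#' Yin/Yang state of the diseased (vehicle) condition
#'
#' Classifies each metabolite by the sign of its disease-stage change
#' alone: Yang (upregulated) if `v1 > 0`, Yin (downregulated) if `v1 < 0`,
#' neutral if snapped to zero. The Yin fraction of this map summarizes how
#' strongly downregulation dominates the disease state.
#'
#' @inheritParams compute_changes
#' @return A tibble with columns `metabolite`, `v1`, `state`.
#' @export
vehicle_yinyang <- function(study, eps = 0.05, sham = "sham",
                            vehicle = "vehicle",
                            mean_type = c("geometric", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  treated <- setdiff(unique(study$design$group), c(sham, vehicle))[1]
  ch <- compute_changes(study, eps = eps, sham = sham, vehicle = vehicle,
                        treated = treated, mean_type = mean_type)
  tibble(metabolite = ch$metabolite,
         v1 = ch$v1,
         state = dplyr::case_when(ch$v1 > 0 ~ "Yang",
                                  ch$v1 < 0 ~ "Yin",
                                  TRUE ~ "neutral"))
}

#' Dose trend of a pattern count
#'
#' Pearson correlation and least-squares line of per-group counts against a
#' dose axis: the dose rank (1..k, default), the dose itself, or log2 dose.
#'
#' @param counts_by_group A data frame with columns `group` and `count`
#'   (or `n`), ordered by increasing dose.
#' @param dose_axis `"rank"`, `"dose"` or `"log2dose"`.
#' @param doses Numeric doses per group, required unless `dose_axis` is
#'   `"rank"`.
#' @return One-row tibble: `r`, `slope`, `intercept`, `dose_axis`,
#'   `n_groups`, `degenerate` (TRUE when the counts have zero variance, in
#'   which case `r` is `NA` and the slope 0).
#' @examples
#' dose_trend(data.frame(group = paste0("DH", 1:4), count = c(8, 6, 4, 2)))
#' @export
dose_trend <- function(counts_by_group,
                       dose_axis = c("rank", "dose", "log2dose"),
                       doses = NULL) {
  dose_axis <- match.arg(dose_axis)
  counts_by_group <- as_tibble(counts_by_group)
  if (!"count" %in% names(counts_by_group) && "n" %in% names(counts_by_group)) {
    counts_by_group$count <- counts_by_group$n
  }
  y <- counts_by_group$count
  if (length(y) < 3L) abort("need at least 3 groups for a dose trend")
  x <- switch(dose_axis,
              rank = seq_along(y),
              dose = {
                if (is.null(doses)) abort("doses required for dose axis")
                doses
              },
              log2dose = {
                if (is.null(doses)) abort("doses required for log2dose axis")
                log2(doses)
              })
  if (stats::var(y) == 0) {
    return(tibble(r = NA_real_, slope = 0, intercept = y[1],
                  dose_axis = dose_axis, n_groups = length(y),
                  degenerate = TRUE))
  }
  fit <- lm(y ~ x)
  tibble(r = cor(x, y), slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), dose_axis = dose_axis,
         n_groups = length(y), degenerate = FALSE)
}

#' Overlap of a pattern's metabolite sets across groups
#'
#' For one pattern (say PT), reports which metabolites carry it in which
#' treated groups — the cross-group membership table behind Venn-style
#' overlap summaries.
#'
#' @param assignments Output of [classify_patterns()].
#' @param pattern A single pattern label.
#' @return A tibble, metabolites x groups, logical membership, plus an
#'   `n_groups` column counting in how many groups the metabolite shows the
#'   pattern.
#' @export
pattern_overlap <- function(assignments, pattern = "PT") {
  sel <- assignments[assignments$pattern == pattern,
                     c("metabolite", "group")]
  if (nrow(sel) == 0L) {
    return(tibble(metabolite = character(), n_groups = integer()))
  }
  wide <- tidyr::pivot_wider(dplyr::mutate(sel, present = TRUE),
                             names_from = "group", values_from = "present",
                             values_fill = FALSE)
  wide$n_groups <- rowSums(as.matrix(wide[, -1]))
  dplyr::arrange(wide, dplyr::desc(.data$n_groups), .data$metabolite)
}
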