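#' Expression study container
#'
#' An `expr_study` bundles a metabolite-by-sample abundance matrix with the
#' sample design (group label and dose). It is the single input object for
#' every analysis stage: correlation networks, entropy, Yin/Yang pattern
#' classification and Kendall-tau synchronous networks.
#'
#' @param values A data frame or matrix of abundances with metabolites in
#'   rows and samples in columns. A data frame may carry metabolite ids in
#'   its first character column (conventionally `metabolite`); a matrix uses
#'   its rownames.
#' @param design A data frame with columns `sample`, `group` and `dose`
#'   (dose in ml/kg; 0 for untreated groups).
#' @return An object of class `expr_study` with elements `values` (numeric
#'   matrix, metabolites x samples), `design` (tibble) and the id vectors
#'   `metabolites` and `samples`.
#' @examples
#' vals <- data.frame(metabolite = c("m1", "m2"),
#'                    s1 = c(1, 2), s2 = c(2, 3), s3 = c(3, 4))
#' des <- data.frame(sample = c("s1", "s2", "s3"),
#'                   group = "sham", dose = 0)
#' expr_study(vals, des)
#' @export
expr_study <- function(values, design) {
  if (is.data.frame(values)) {
    id_col <- which(!vapply(values, is.numeric, logical(1)))
    if (length(id_col) > 1L) {
      abort("expression table must have at most one non-numeric (id) column")
    }
    if (length(id_col) == 1L) {
      ids <- as.character(values[[id_col]])
      values <- as.matrix(values[, -id_col, drop = FALSE])
      rownames(values) <- ids
    } else {
      values <- as.matrix(values)
    }
  }
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    abort("metabolite ids missing: supply rownames or an id column")
  }
  if (is.null(colnames(values))) {
    abort("sample ids missing: supply column names")
  }
  design <- as_tibble(design)
  required <- c("sample", "group")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0L) {
    abort(paste0("design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"dose" %in% names(design)) design$dose <- NA_real_
  design$sample <- as.character(design$sample)
  design$group <- as.character(design$group)

  study <- structure(
    list(values = values,
         design = design[, c("sample", "group", "dose")],
         metabolites = rownames(values),
         samples = colnames(values)),
    class = "expr_study"
  )
  validate_expr_study(study)
}

validate_expr_study <- function(study) {
  vals <- study$values
  if (anyDuplicated(rownames(vals))) {
    dup <- unique(rownames(vals)[duplicated(rownames(vals))])
    abort(paste0("duplicate metabolite id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(vals))) {
    dup <- unique(colnames(vals)[duplicated(colnames(vals))])
    abort(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(paste0("missing value at metabolite '", rownames(vals)[bad[1]],
                 "', sample '", colnames(vals)[bad[2]],
                 "'; impute or drop before constructing the study"))
  }
  des <- study$design
  if (anyDuplicated(des$sample)) {
    dup <- unique(des$sample[duplicated(des$sample)])
    abort(paste0("sample(s) listed twice in design: ",
                 paste(dup, collapse = ", ")))
  }
  not_in_design <- setdiff(colnames(vals), des$sample)
  if (length(not_in_design) > 0L) {
    abort(paste0("sample(s) in matrix but not in design: ",
                 paste(not_in_design, collapse = ", ")))
  }
  not_in_matrix <- setdiff(des$sample, colnames(vals))
  if (length(not_in_matrix) > 0L) {
    abort(paste0("sample(s) in design but not in matrix: ",
                 paste(not_in_matrix, collapse = ", ")))
  }
  study
}

#' @export
print.expr_study <- function(x, ...) {
  groups <- dplyr::count(x$design, .data$group)
  cat("<expr_study> ", length(x$metabolites), " metabolites x ",
      length(x$samples), " samples\n", sep = "")
  cat("groups:", paste0(groups$group, " (n=", groups$n, ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_study <- function(x) dim(x$values)

#' Samples belonging to one or more groups
#'
#' @param study An [expr_study()].
#' @param groups Character vector of group labels.
#' @return Character vector of sample ids, in matrix column order.
#' @export
group_samples <- function(study, groups) {
  unknown <- setdiff(groups, unique(study$design$group))
  if (length(unknown) > 0L) {
    abort(paste0("unknown group(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- study$design$sample[study$design$group %in% groups]
  intersect(study$samples, keep)
}

#' Tidy a study into long format
#'
#' @param x An [expr_study()].
#' @param ... Unused.
#' @return A tibble with columns `metabolite`, `sample`, `group`, `dose`,
#'   `value`, one row per measurement.
#' @method tidy expr_study
#' @export
tidy.expr_study <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "metabolite")
  long <- tidyr::pivot_longer(long, -"metabolite",
                              names_to = "sample", values_to = "value")
  dplyr::left_join(long, x$design, by = "sample")[
    , c("metabolite", "sample", "group", "dose", "value")]
}

#' @method glance expr_study
#' @export
glance.expr_study <- function(x, ...) {
  tibble(n_metabolites = length(x$metabolites),
         n_samples = length(x$samples),
         n_groups = dplyr::n_distinct(x$design$group))
}

#' Read an expression study from disk
#'
#' Reads a metabolite-by-sample abundance table plus a sample design table.
#' The delimiter is inferred from the extension (`.tsv`/`.txt` are
#' tab-separated, anything else comma-separated). Samples present in the
#' matrix but absent from the design (or vice versa) are an error, never
#' silently dropped.
#'
#' @param matrix_path Path to the expression table: first column metabolite
#'   ids, remaining columns one per sample with sample ids as header.
#' @param design_path Path to the design table with columns `sample`,
#'   `group` and optionally `dose`.
#' @return An [expr_study()].
#' @export
read_study <- function(matrix_path, design_path) {
  vals <- read_delim_auto(matrix_path)
  nonnum <- vapply(vals[-1], function(col) !is.numeric(col), logical(1))
  if (any(nonnum)) {
    abort(paste0("non-numeric value column(s) in ", matrix_path, ": ",
                 paste(names(vals[-1])[nonnum], collapse = ", ")))
  }
  design <- read_delim_auto(design_path)
  expr_study(as.data.frame(vals), design)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = "")
}

#' Write an expression study to disk
#'
#' Writes the abundance matrix (`<prefix>_expression.csv`, metabolites in
#' rows) and the design (`<prefix>_design.csv`). Output is deterministic:
#' rows and columns keep the study's stored order.
#'
#' @param study An [expr_study()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"study"`.
#' @return Invisibly, the two paths written.
#' @export
write_study <- function(study, dir, prefix = "study") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat_path <- file.path(dir, paste0(prefix, "_expression.csv"))
  des_path <- file.path(dir, paste0(prefix, "_design.csv"))
  tab <- as_tibble(study$values, rownames = "metabolite")
  readr::write_csv(tab, mat_path, na = "")
  readr::write_csv(study$design, des_path, na = "")
  invisible(c(expression = mat_path, design = des_path))
}
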