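#' Construct a two-group cortical-thickness cohort
#'
#' @param values numeric matrix, subjects in rows and regions in columns,
#'   with subject ids as rownames and region ids as colnames; entries are
#'   mean cortical thickness in millimetres.
#' @param groups character or factor of length `nrow(values)` with
#'   exactly two levels.
#' @return An object of class `thickness_cohort` with elements
#'   `subject_ids`, `groups`, `regions`, `values`.
#' @export
thickness_cohort <- function(values, groups) {
  check_matrix(values, "thickness values")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("thickness matrix must have region ids as column names",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("region ids must be unique", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(values)) {
    stop("length(groups) must equal the number of subjects", call. = FALSE)
  }
  lv <- unique(groups)
  if (length(lv) != 2L) {
    stop("exactly two groups required (found ", length(lv), ": ",
         paste(lv, collapse = ", "), ")", call. = FALSE)
  }
  if (any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("thickness must be positive; first violation at subject %s, region %s",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  structure(
    list(subject_ids = rownames(values), groups = groups,
         regions = colnames(values), values = values),
    class = "thickness_cohort"
  )
}

#' Read a thickness cohort from TSV
#'
#' Expects a tab-separated file with header columns `subject_id`,
#' `group`, then one column per region. Cells must be numeric and
#' complete; exactly two group labels must be present.
#'
#' @param path file path.
#' @return A [thickness_cohort()].
#' @export
read_thickness <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df))) {
    stop("thickness file must have 'subject_id' and 'group' columns",
         call. = FALSE)
  }
  region_cols <- setdiff(names(df), need)
  if (length(region_cols) == 0L) {
    stop("thickness file has no region columns", call. = FALSE)
  }
  vals <- df[region_cols]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    stop("non-numeric thickness in region column(s): ",
         paste(region_cols[nonnum], collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(vals)
  rownames(values) <- df$subject_id
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    cells <- apply(bad, 1L, function(i) {
      paste0(df$subject_id[i[1L]], "/", region_cols[i[2L]])
    })
    stop("missing thickness values at (subject/region): ",
         paste(utils::head(cells, 10L), collapse = ", "), call. = FALSE)
  }
  thickness_cohort(values, groups = df$group)
}

#' Write a thickness cohort to TSV
#'
#' @param cohort a [thickness_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thickness <- function(cohort, path) {
  stopifnot(inherits(cohort, "thickness_cohort"))
  df <- data.frame(subject_id = cohort$subject_ids, group = cohort$groups,
                   cohort$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-region group difference in mean cortical thickness
#'
#' For every region, the mean thickness over `group_a` subjects minus the
#' mean over `group_b` subjects. With group A the stable group and group
#' B the converter group, positive values mean the cortex is thinner in
#' converters.
#'
#' @param cohort a [thickness_cohort()].
#' @param group_a,group_b group labels present in the cohort; defaults
#'   are the first and second label in order of appearance.
#' @return An object of class `delta_ct`: list with `regions`, `values`
#'   (named numeric, mm), `group_a`, `group_b`.
#' @export
compute_delta_ct <- function(cohort,
                             group_a = unique(cohort$groups)[1L],
                             group_b = unique(cohort$groups)[2L]) {
  stopifnot(inherits(cohort, "thickness_cohort"))
  for (g in c(group_a, group_b)) {
    if (!g %in% cohort$groups) {
      stop("unknown group label: ", g, call. = FALSE)
    }
  }
  if (identical(group_a, group_b)) {
    stop("group_a and group_b must differ", call. = FALSE)
  }
  mu_a <- colMeans(cohort$values[cohort$groups == group_a, , drop = FALSE])
  mu_b <- colMeans(cohort$values[cohort$groups == group_b, , drop = FALSE])
  structure(
    list(regions = cohort$regions, values = mu_a - mu_b,
         group_a = group_a, group_b = group_b),
    class = "delta_ct"
  )
}

#' @export
print.delta_ct <- function(x, ...) {
  cat(sprintf("Thickness difference %s - %s over %d regions (range %.4g to %.4g mm)\n",
              x$group_a, x$group_b, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.thickness_cohort <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("Thickness cohort: %d subjects (%s) x %d regions\n",
              length(x$subject_ids),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              length(x$regions)))
  invisible(x)
}

#' Write a per-region thickness difference to TSV
#' @param dct a `delta_ct` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_delta_ct <- function(dct, path) {
  stopifnot(inherits(dct, "delta_ct"))
  df <- data.frame(region_id = dct$regions, delta_ct = unname(dct$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-region thickness difference from TSV
#' @param path file with columns `region_id`, `delta_ct`.
#' @param group_a,group_b optional labels recorded on the result.
#' @return A `delta_ct` object.
#' @export
read_delta_ct <- function(path, group_a = "group_a", group_b = "group_b") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "delta_ct") %in% names(df))) {
    stop("file must have 'region_id' and 'delta_ct' columns", call. = FALSE)
  }
  if (anyNA(df$delta_ct) || !is.numeric(df$delta_ct)) {
    stop("'delta_ct' column must be numeric and complete", call. = FALSE)
  }
  structure(
    list(regions = df$region_id,
         values = stats::setNames(df$delta_ct, df$region_id),
         group_a = group_a, group_b = group_b),
    class = "delta_ct"
  )
}
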