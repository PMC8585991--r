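# Expression matrices are plain numeric matrices: regions in rows
# (rownames = region ids), genes in columns (colnames = gene ids).

#' Read a region-by-gene expression matrix from TSV
#'
#' Expects a header row with `region_id` followed by gene ids, one row
#' per region.
#'
#' @param path file path.
#' @return Numeric matrix with region rownames and gene colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "region_id") {
    stop("expression file must start with a 'region_id' column",
         call. = FALSE)
  }
  m <- as.matrix(df[-1L])
  rownames(m) <- df$region_id
  if (anyDuplicated(rownames(m))) stop("region ids must be unique",
                                       call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("gene ids must be unique",
                                       call. = FALSE)
  check_matrix(m, "expression matrix")
  m
}

#' Write a region-by-gene expression matrix to TSV
#' @param expr expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  check_matrix(expr, "expression matrix")
  df <- data.frame(region_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Standardize gene columns to zero mean and unit variance
#'
#' Each gene column is centred and scaled to unit sample variance
#' (denominator `n - 1`) across regions, the usual pre-processing before
#' partial least squares so that gene weights are comparable across
#' genes. Zero-variance genes carry no regional information and are
#' dropped with a warning.
#'
#' @param expr expression matrix (regions x genes).
#' @param tol variance below which a gene counts as constant.
#' @return The standardized matrix, possibly with fewer columns.
#' @export
standardize_genes <- function(expr, tol = 1e-12) {
  check_matrix(expr, "expression matrix")
  if (nrow(expr) < 2L) stop("need at least 2 regions to standardize",
                            call. = FALSE)
  v <- apply(expr, 2L, stats::var)
  drop <- v < tol
  if (all(drop)) stop("all genes have zero variance across regions",
                      call. = FALSE)
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) dropped: ",
            paste(utils::head(colnames(expr)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "", call. = FALSE)
    expr <- expr[, !drop, drop = FALSE]
    v <- v[!drop]
  }
  out <- sweep(expr, 2L, colMeans(expr), "-")
  sweep(out, 2L, sqrt(v), "/")
}

#' Align an expression matrix and a thickness difference by region id
#'
#' Restricts and reorders both inputs to the sorted intersection of
#' their region ids, guarding against silent positional misalignment
#' between the imaging and expression files.
#'
#' @param expr expression matrix with region rownames.
#' @param dct a `delta_ct` object.
#' @param min_regions minimum acceptable intersection size (default 10).
#' @return List with aligned `expr` and `dct`.
#' @export
align_regions <- function(expr, dct, min_regions = 10L) {
  stopifnot(inherits(dct, "delta_ct"))
  check_matrix(expr, "expression matrix")
  common <- sort(intersect(rownames(expr), dct$regions))
  if (length(common) == 0L) {
    stop("expression and thickness-difference region ids are disjoint",
         call. = FALSE)
  }
  if (length(common) < min_regions) {
    stop("only ", length(common), " regions shared between expression ",
         "and thickness difference (need >= ", min_regions, ")",
         call. = FALSE)
  }
  dct_vals <- dct$values[match(common, dct$regions)]
  names(dct_vals) <- common
  list(
    expr = expr[common, , drop = FALSE],
    dct = structure(list(regions = common, values = dct_vals,
                         group_a = dct$group_a, group_b = dct$group_b),
                    class = "delta_ct")
  )
}
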