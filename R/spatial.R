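#' Regional scores for a gene weight vector
#'
#' Projects each region's (standardized) expression profile onto a
#' component weight vector and centres the result across regions,
#' giving the spatial map of the component.
#'
#' @param X standardized expression matrix (regions x genes).
#' @param weights numeric weight vector of length `ncol(X)` (e.g. one
#'   column of a `pls_ct` fit's `weights`).
#' @return Named numeric vector of mean-centred regional scores.
#' @export
regional_scores <- function(X, weights) {
  check_matrix(X, "X")
  weights <- as.numeric(weights)
  if (length(weights) != ncol(X)) {
    stop("length(weights) = ", length(weights),
         " must equal ncol(X) = ", ncol(X), call. = FALSE)
  }
  s <- as.vector(X %*% weights)
  s <- s - mean(s)
  names(s) <- rownames(X)
  s
}

#' Read a region-to-class map from TSV
#'
#' @param path file with columns `region_id`, `class_label` (integer)
#'   and optionally `class_name`.
#' @return data.frame with `region_id`, `class_label`, `class_name`.
#' @export
read_class_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "class_label") %in% names(df))) {
    stop("class map must have 'region_id' and 'class_label' columns",
         call. = FALSE)
  }
  if (is.null(df$class_name)) {
    df$class_name <- paste0("class_", df$class_label)
  }
  df[c("region_id", "class_label", "class_name")]
}

#' Write a region-to-class map to TSV
#' @param class_map data.frame with `region_id`, `class_label` and
#'   optionally `class_name`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(class_map, path) {
  utils::write.table(class_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Permutation test of class-wise over/under-expression of a score map
#'
#' For each cytoarchitectonic class the statistic is the mean regional
#' score of its member regions. The null permutes the region-to-class
#' assignment `n_perm` times; the two-sided p-value compares the
#' absolute observed class mean with the absolute permuted class means
#' using add-one smoothing. Direction is "over" when the observed mean
#' exceeds the null median, "under" otherwise. Benjamini-Hochberg
#' adjustment is applied across classes.
#'
#' @param scores named numeric vector of mean-centred regional scores
#'   (see [regional_scores()]).
#' @param class_map data.frame with `region_id`, `class_label` and
#'   optionally `class_name`, covering exactly the regions of `scores`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return A `class_enrichment` data.frame with columns `class_label`,
#'   `class_name`, `n_regions`, `mean_score`, `direction`, `p`, `q`.
#' @export
class_enrichment <- function(scores, class_map, n_perm = 10000L,
                             seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (is.null(names(scores))) {
    stop("scores must be named by region id", call. = FALSE)
  }
  if (!setequal(names(scores), class_map$region_id)) {
    stop("scores and class map must cover identical regions",
         call. = FALSE)
  }
  scores <- scores - mean(scores)
  cm <- class_map[match(names(scores), class_map$region_id), ]
  labels <- cm$class_label
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  sizes <- as.vector(table(factor(labels, levels = classes)))
  if (any(sizes < 2L)) {
    warning("class(es) with fewer than 2 regions: ",
            paste(classes[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  R <- length(scores)
  # indicator matrix turns each permutation's class means into one
  # matrix product
  M <- outer(classes, labels, "==") * 1
  M <- M / sizes
  observed <- as.vector(M %*% scores)

  null_means <- with_seed(derive_seeds(seed, "class_perm"), {
    P <- vapply(seq_len(n_perm), function(i) scores[sample.int(R)],
                numeric(R))
    M %*% P                              # classes x n_perm
  })
  p <- vapply(seq_along(classes), function(ci) {
    (1 + sum(abs(null_means[ci, ]) >= abs(observed[ci]))) / (n_perm + 1)
  }, numeric(1))
  direction <- ifelse(observed > apply(null_means, 1L, stats::median),
                      "over", "under")
  name_of <- cm$class_name %||% paste0("class_", labels)
  cname <- vapply(classes, function(cl) {
    as.character(name_of[match(cl, labels)])
  }, character(1))
  structure(
    data.frame(class_label = classes, class_name = cname,
               n_regions = sizes, mean_score = observed,
               direction = direction, p = p, q = fdr_bh(p),
               stringsAsFactors = FALSE),
    class = c("class_enrichment", "data.frame"),
    n_perm = n_perm, seed = as.integer(seed)
  )
}
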