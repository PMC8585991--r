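#' Construct a gene-set collection over a fixed universe
#'
#' Gene sets are restricted to the universe; genes outside it are
#' dropped with a message reporting the count, and sets that become
#' empty are removed with a warning.
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe character vector of gene ids forming the sampling
#'   frame (typically the genes of the post-QC expression matrix).
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (named list, unique ids, subset of universe) and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all gene sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  dropped <- sum(vapply(sets, function(s) sum(!s %in% universe),
                        integer(1)))
  if (dropped > 0L) {
    message(dropped, " gene id(s) outside the universe dropped from sets")
    sets <- lapply(sets, function(s) s[s %in% universe])
  }
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning("empty gene set(s) removed: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no non-empty gene sets", call. = FALSE)
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are set name,
#' description, then member gene ids.
#'
#' @param path GMT file path.
#' @param universe optional universe to restrict to; defaults to the
#'   union of all sets.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s) (need name, description, >=1 gene): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  sets <- stats::setNames(
    lapply(parts, function(x) x[-(1:2)]),
    vapply(parts, `[[`, character(1), 1L)
  )
  gene_set_collection(sets,
                      universe %||% unique(unlist(sets, use.names = FALSE)))
}

#' Write gene sets to a GMT file
#' @param collection a [gene_set_collection()] (or named list of sets).
#' @param path output file path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  sets <- if (inherits(collection, "gene_set_collection")) {
    collection$sets
  } else collection
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

hypergeom_upper <- function(n_overlap, n_list, n_set, n_universe) {
  stats::phyper(n_overlap - 1L, n_list, n_universe - n_list, n_set,
                lower.tail = FALSE)
}

#' Permutation and hypergeometric overlap test of a gene list against
#' marker sets
#'
#' For each set the statistic is the number of genes shared with
#' `gene_list`. The null resamples `length(gene_list)` genes uniformly
#' without replacement from the universe `n_perm` times;
#' `p_perm = (1 + #(null >= observed)) / (n_perm + 1)` (one-sided,
#' enrichment only). The exact upper-tail hypergeometric probability is
#' reported alongside, since the resampling null is hypergeometric in
#' the limit. Benjamini-Hochberg adjustment across sets is applied to
#' the permutation p-values.
#'
#' @param gene_list character vector of gene ids (e.g. the significant
#'   positive-weight genes); ids outside the universe are dropped with a
#'   message.
#' @param collection a [gene_set_collection()].
#' @param n_perm number of resamples (default 10000).
#' @param seed integer seed.
#' @return An `overlap_result` data.frame with columns `set_name`,
#'   `n_overlap`, `n_list`, `n_set`, `n_universe`, `p_perm`,
#'   `p_hypergeom`, `q`.
#' @export
overlap_test <- function(gene_list, collection, n_perm = 10000L,
                         seed = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  n_perm <- check_count(n_perm, "n_perm")
  gene_list <- unique(as.character(gene_list))
  outside <- !gene_list %in% collection$universe
  if (any(outside)) {
    message(sum(outside), " gene id(s) outside the universe dropped ",
            "from the query list")
    gene_list <- gene_list[!outside]
  }
  if (length(gene_list) == 0L) {
    stop("empty gene list (after restriction to the universe)",
         call. = FALSE)
  }
  N <- length(collection$universe)
  n_list <- length(gene_list)
  sets <- collection$sets
  S <- length(sets)
  # universe x sets membership, so each resample's overlaps are one
  # indexed colSums
  M <- vapply(sets, function(s) collection$universe %in% s,
              logical(N))
  observed <- as.integer(colSums(M[collection$universe %in% gene_list, ,
                                   drop = FALSE]))
  n_set <- vapply(sets, length, integer(1))

  exceed <- integer(S)
  with_seed(derive_seeds(seed, "overlap_perm"), {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(N, n_list)
      exceed <- exceed + (colSums(M[idx, , drop = FALSE]) >= observed)
    }
  })
  p_perm <- (1 + exceed) / (n_perm + 1)
  p_hyp <- hypergeom_upper(observed, n_list, n_set, N)
  structure(
    data.frame(set_name = names(sets), n_overlap = observed,
               n_list = n_list, n_set = unname(n_set), n_universe = N,
               p_perm = unname(p_perm), p_hypergeom = unname(p_hyp),
               q = unname(fdr_bh(p_perm)), stringsAsFactors = FALSE,
               row.names = NULL),
    class = c("overlap_result", "data.frame"),
    n_perm = n_perm, seed = as.integer(seed)
  )
}

#' Hypergeometric over-representation analysis of a gene list
#'
#' Exact upper-tail hypergeometric test of the overlap between the gene
#' list and each annotation set, with Benjamini-Hochberg adjustment
#' across sets; results are sorted by ascending p-value. This is the
#' in-package over-representation analysis for user-supplied GMT
#' collections.
#'
#' @inheritParams overlap_test
#' @param annotations a [gene_set_collection()].
#' @return An `overlap_result` data.frame (columns as in
#'   [overlap_test()], without `p_perm`; `q` adjusts `p_hypergeom`).
#' @export
ora <- function(gene_list, annotations) {
  stopifnot(inherits(annotations, "gene_set_collection"))
  gene_list <- unique(as.character(gene_list))
  outside <- !gene_list %in% annotations$universe
  if (any(outside)) {
    message(sum(outside), " gene id(s) outside the universe dropped ",
            "from the query list")
    gene_list <- gene_list[!outside]
  }
  if (length(gene_list) == 0L) {
    stop("empty gene list (after restriction to the universe)",
         call. = FALSE)
  }
  N <- length(annotations$universe)
  n_list <- length(gene_list)
  observed <- vapply(annotations$sets, function(s) {
    length(intersect(s, gene_list))
  }, integer(1))
  n_set <- vapply(annotations$sets, length, integer(1))
  p <- hypergeom_upper(observed, n_list, n_set, N)
  out <- data.frame(set_name = names(annotations$sets),
                    n_overlap = unname(observed), n_list = n_list,
                    n_set = unname(n_set), n_universe = N,
                    p_hypergeom = unname(p), q = unname(fdr_bh(p)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_hypergeom, out$set_name), ]
  rownames(out) <- NULL
  structure(out, class = c("overlap_result", "data.frame"))
}
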