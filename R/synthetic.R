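#' Configuration for the synthetic imaging-transcriptomics generator
#'
#' Bundles and validates the parameters of the generative model used to
#' exercise the pipeline against known ground truth. The model plants a
#' linear link between expression and the group difference in cortical
#' thickness: a sparse set of `n_causal` genes with Gaussian weights
#' defines a standardized regional pattern `d`, and subjects in group B
#' are thinned by `effect_size * delta_scale * d` millimetres on top of
#' i.i.d. Gaussian subject noise.
#'
#' Defaults emulate the scale of a whole-cortex parcellation study: 308
#' regions, an unbalanced two-group cohort (100 vs 40 subjects), 2000
#' genes of which 50 carry signal, and mild spatial autocorrelation of
#' expression along the region ordering.
#'
#' @param n_regions number of cortical regions (rows of the expression
#'   matrix).
#' @param n_genes number of genes (columns).
#' @param n_subjects_a,n_subjects_b group sizes; group A is the reference
#'   ("stable") group, group B the affected ("converter") group.
#' @param n_causal number of genes with nonzero planted weight (may be 0
#'   for a global-null dataset).
#' @param effect_size magnitude of the planted group difference, in
#'   standard-deviation units of the standardized regional pattern.
#' @param subject_noise_sd standard deviation of per-subject, per-region
#'   thickness noise (mm).
#' @param expr_spatial_rho AR(1) autocorrelation of each gene's expression
#'   along the region ordering, in `[0, 1)`.
#' @param baseline_thickness mean cortical thickness (mm).
#' @param delta_scale millimetres of group-B thinning per unit of the
#'   standardized planted pattern (default 0.1 mm, a typical
#'   cortical-thickness effect magnitude).
#' @param seed integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @return A `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_regions = 60, n_genes = 100, n_causal = 10)
#' expr <- generate_expression(cfg)
#' dim(expr)
simulation_config <- function(n_regions = 308L, n_genes = 2000L,
                              n_subjects_a = 100L, n_subjects_b = 40L,
                              n_causal = 50L, effect_size = 1.5,
                              subject_noise_sd = 0.1,
                              expr_spatial_rho = 0.3,
                              baseline_thickness = 2.5,
                              delta_scale = 0.1, seed = 1L) {
  cfg <- list(
    n_regions = check_count(n_regions, "n_regions"),
    n_genes = check_count(n_genes, "n_genes"),
    n_subjects_a = check_count(n_subjects_a, "n_subjects_a"),
    n_subjects_b = check_count(n_subjects_b, "n_subjects_b"),
    n_causal = check_count(n_causal, "n_causal", min = 0L),
    effect_size = check_scalar(effect_size, "effect_size"),
    subject_noise_sd = check_scalar(subject_noise_sd, "subject_noise_sd",
                                    min = 0),
    expr_spatial_rho = check_scalar(expr_spatial_rho, "expr_spatial_rho",
                                    min = 0, max = 1, max_open = TRUE),
    baseline_thickness = check_scalar(baseline_thickness,
                                      "baseline_thickness", min = 0,
                                      min_open = TRUE),
    delta_scale = check_scalar(delta_scale, "delta_scale", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_causal > cfg$n_genes) {
    stop("'n_causal' must not exceed 'n_genes'", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

region_ids <- function(n) sprintf("R%04d", seq_len(n))
gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a region-by-gene expression matrix
#'
#' Each gene is an independent draw from a stationary AR(1) Gaussian
#' process over the (arbitrary but fixed) region ordering with lag-1
#' correlation `expr_spatial_rho` and unit marginal variance, mimicking
#' the smooth spatial structure of cortical expression maps without
#' requiring surface geometry.
#'
#' @param config a [simulation_config()].
#' @return Numeric matrix `n_regions x n_genes`, rownames `R0001...`,
#'   colnames `G00001...`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  R <- config$n_regions
  G <- config$n_genes
  rho <- config$expr_spatial_rho
  E <- with_seed(derive_seeds(config$seed, "expression"), {
    e <- matrix(stats::rnorm(R * G), nrow = R, ncol = G)
    if (rho > 0 && R > 1) {
      s <- sqrt(1 - rho^2)
      for (r in 2:R) e[r, ] <- rho * e[r - 1L, ] + s * e[r, ]
    }
    e
  })
  dimnames(E) <- list(region_ids(R), gene_ids(G))
  E
}

#' Generate a two-group thickness cohort with a planted expression signal
#'
#' Draws `n_causal` causal genes uniformly without replacement with
#' weights from N(0, 1); the planted regional pattern is the standardized
#' projection `d = standardize(E[, causal] %*% w)` (zero mean, unit
#' sample variance). Group A subjects have thickness
#' `N(baseline_thickness, subject_noise_sd^2)` per region; group B
#' subjects are additionally thinned by
#' `effect_size * delta_scale * d[r]`, so the group difference A minus B
#' tracks `+effect_size * delta_scale * d` — positive differences mean
#' "thinner in the affected group".
#'
#' @param expr expression matrix from [generate_expression()].
#' @param config the matching [simulation_config()].
#' @return A list with elements `cohort` (a [thickness_cohort()]) and
#'   `truth` (class `ground_truth`: `causal_genes`, `causal_weights`
#'   named by gene, `planted_delta` named by region, and the `scale`
#'   in mm per unit pattern actually applied).
#' @export
generate_cohort <- function(expr, config) {
  stopifnot(inherits(config, "simulation_config"))
  check_matrix(expr, "expr")
  if (nrow(expr) != config$n_regions) {
    stop("expr has ", nrow(expr), " regions but config$n_regions is ",
         config$n_regions, call. = FALSE)
  }
  if (config$n_causal > ncol(expr)) {
    stop("'n_causal' must not exceed the number of genes in expr",
         call. = FALSE)
  }
  R <- config$n_regions
  genes <- colnames(expr) %||% gene_ids(ncol(expr))

  with_seed(derive_seeds(config$seed, "cohort"), {
    if (config$n_causal > 0L) {
      causal <- sort(sample(genes, config$n_causal))
      w <- stats::setNames(stats::rnorm(config$n_causal), causal)
      raw <- as.vector(expr[, causal, drop = FALSE] %*% w)
      d <- (raw - mean(raw)) / stats::sd(raw)
    } else {
      causal <- character(0)
      w <- stats::setNames(numeric(0), character(0))
      d <- rep(0, R)
    }
    names(d) <- rownames(expr)

    nA <- config$n_subjects_a
    nB <- config$n_subjects_b
    shift <- config$effect_size * config$delta_scale * d
    A <- matrix(stats::rnorm(nA * R, mean = config$baseline_thickness,
                             sd = config$subject_noise_sd),
                nrow = nA, ncol = R, byrow = FALSE)
    B <- matrix(stats::rnorm(nB * R, mean = 0,
                             sd = config$subject_noise_sd),
                nrow = nB, ncol = R) +
      matrix(config$baseline_thickness - shift, nrow = nB, ncol = R,
             byrow = TRUE)
    values <- rbind(A, B)
    dimnames(values) <- list(sprintf("S%04d", seq_len(nA + nB)),
                             rownames(expr))
    cohort <- thickness_cohort(
      values,
      groups = rep(c("stable", "converter"), c(nA, nB))
    )
    truth <- structure(
      list(causal_genes = causal, causal_weights = w, planted_delta = d,
           scale = config$delta_scale),
      class = "ground_truth"
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Generate marker gene sets and a region-class map with known overlap
#'
#' Emulates cell-type marker collections: `n_sets` gene sets over the
#' expression matrix's genes, where set 1 contains
#' `round(causal_overlap_frac * set_size)` causal genes (the planted
#' "marker" class) and all remaining members are drawn from non-causal
#' genes. Also partitions the regions into `n_classes` contiguous
#' cytoarchitectonic-style classes of near-equal size (sizes differ by at
#' most one).
#'
#' @param expr expression matrix (supplies the gene universe and region
#'   ids).
#' @param truth `ground_truth` from [generate_cohort()].
#' @param n_sets number of gene sets (default 7, the canonical cortical
#'   cell-type classes).
#' @param set_size genes per set.
#' @param causal_overlap_frac fraction of set 1 drawn from the causal
#'   genes, in `[0, 1]`.
#' @param n_classes number of region classes (default 7: five Von Economo
#'   classes plus limbic and insular subtypes).
#' @param seed integer seed.
#' @return A list with `collection` (a [gene_set_collection()]) and
#'   `class_map` (data.frame: `region_id`, `class_label`, `class_name`).
#' @export
generate_annotations <- function(expr, truth, n_sets = 7L,
                                 set_size = 100L,
                                 causal_overlap_frac = 0.5,
                                 n_classes = 7L, seed = 1L) {
  check_matrix(expr, "expr")
  n_sets <- check_count(n_sets, "n_sets")
  set_size <- check_count(set_size, "set_size")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  check_scalar(causal_overlap_frac, "causal_overlap_frac", min = 0, max = 1)
  genes <- colnames(expr)
  if (set_size > length(genes)) {
    stop("'set_size' must not exceed the number of genes", call. = FALSE)
  }
  causal <- truth$causal_genes
  n_over <- round(causal_overlap_frac * set_size)
  if (n_over > length(causal)) {
    stop("requested causal overlap (", n_over,
         " genes) exceeds the ", length(causal),
         " available causal genes", call. = FALSE)
  }
  noncausal <- setdiff(genes, causal)
  if (set_size - n_over > length(noncausal) ||
      set_size > length(noncausal) && n_sets > 1L) {
    stop("not enough non-causal genes to build sets of size ", set_size,
         call. = FALSE)
  }

  set_names <- c("astrocytes", "excitatory_neurons", "inhibitory_neurons",
                 "endothelial_cells", "oligodendrocytes",
                 "oligodendrocyte_precursors", "microglia")
  if (n_sets > length(set_names)) {
    set_names <- c(set_names,
                   sprintf("markers_%02d", seq.int(length(set_names) + 1L,
                                                   n_sets)))
  }
  set_names <- set_names[seq_len(n_sets)]

  sets <- with_seed(derive_seeds(seed, "annotations"), {
    out <- vector("list", n_sets)
    out[[1L]] <- sort(c(
      if (n_over > 0L) sample(causal, n_over) else character(0),
      sample(noncausal, set_size - n_over)
    ))
    for (i in seq_len(n_sets - 1L) + 1L) {
      out[[i]] <- sort(sample(noncausal, set_size))
    }
    stats::setNames(out, set_names)
  })
  collection <- gene_set_collection(sets, universe = genes)

  class_names <- c("primary_motor", "association", "association_2",
                   "secondary_sensory", "primary_sensory", "limbic",
                   "insular")
  if (n_classes > length(class_names)) {
    class_names <- c(class_names,
                     sprintf("class_%02d", seq.int(length(class_names) + 1L,
                                                   n_classes)))
  }
  class_names <- class_names[seq_len(n_classes)]
  labels <- sort(rep_len(seq_len(n_classes), nrow(expr)))
  class_map <- data.frame(
    region_id = rownames(expr),
    class_label = labels,
    class_name = class_names[labels],
    stringsAsFactors = FALSE
  )
  list(collection = collection, class_map = class_map)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d regions x %d genes; %d + %d subjects\n",
              x$n_regions, x$n_genes, x$n_subjects_a, x$n_subjects_b))
  cat(sprintf("  %d causal genes, effect size %.3g (scale %.3g mm), noise sd %.3g mm\n",
              x$n_causal, x$effect_size, x$delta_scale, x$subject_noise_sd))
  cat(sprintf("  expression AR(1) rho %.2f, seed %d\n",
              x$expr_spatial_rho, x$seed))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted ground truth:", length(x$causal_genes), "causal genes,",
      length(x$planted_delta), "regions\n")
  invisible(x)
}
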