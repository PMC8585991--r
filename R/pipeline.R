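# End-to-end orchestration: thickness -> delta-CT -> standardize ->
# align -> CV component selection -> fit -> permutation test ->
# bootstrap gene table -> significant lists -> class profile ->
# cell-type overlap, with all artifacts written to an output directory
# and a machine-readable report returned.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `simulation` (a [simulation_config()], run on
#' generated data with ground truth) or `inputs` (a named list of file
#' paths: `thickness`, `expression`, `class_map`, `gmt`) must be given.
#'
#' @param simulation optional [simulation_config()].
#' @param inputs optional named list of input file paths.
#' @param group_a,group_b group labels; the thickness difference is
#'   group A minus group B (convention: group A is the stable group).
#'   Defaults match the synthetic generator's labels.
#' @param max_components largest component count tried in
#'   cross-validation (default 35).
#' @param folds CV folds (default 10).
#' @param n_perm,n_boot resampling sizes; `profile = "full"` uses
#'   10000/1000, `profile = "test"` 1000/200; explicit values override
#'   the profile.
#' @param z_threshold,q_threshold gene-significance thresholds
#'   (defaults 1.96 and 0.05).
#' @param annotations optional list of arguments to
#'   [generate_annotations()] used in simulation mode (`n_sets`,
#'   `set_size`, `causal_overlap_frac`).
#' @param seed integer seed for the whole run.
#' @param outdir output directory (created if missing); `NULL` skips
#'   writing artifacts.
#' @param profile `"full"` or `"test"` resampling profile.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            group_a = "stable", group_b = "converter",
                            max_components = 35L, folds = 10L,
                            n_perm = NULL, n_boot = NULL,
                            z_threshold = 1.96, q_threshold = 0.05,
                            annotations = list(), seed = 1L,
                            outdir = NULL, profile = c("full", "test")) {
  profile <- match.arg(profile)
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of 'simulation' or 'inputs' must be supplied",
         call. = FALSE)
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation,
                                               "simulation_config"))
  if (!is.null(inputs)) {
    need <- c("thickness", "expression", "class_map", "gmt")
    missing_keys <- setdiff(need, names(inputs))
    if (length(missing_keys) > 0L) {
      stop("inputs must name: ", paste(missing_keys, collapse = ", "),
           call. = FALSE)
    }
  }
  defaults <- if (profile == "full") c(10000L, 1000L) else c(1000L, 200L)
  structure(
    list(simulation = simulation, inputs = inputs, group_a = group_a,
         group_b = group_b,
         max_components = check_count(max_components, "max_components"),
         folds = check_count(folds, "folds", min = 2L),
         n_perm = check_count(n_perm %||% defaults[1L], "n_perm"),
         n_boot = check_count(n_boot %||% defaults[2L], "n_boot",
                              min = 100L),
         z_threshold = check_scalar(z_threshold, "z_threshold", min = 0,
                                    min_open = TRUE),
         q_threshold = check_scalar(q_threshold, "q_threshold", min = 0,
                                    max = 1, min_open = TRUE),
         annotations = annotations, seed = check_count(seed, "seed",
                                                       min = 0L),
         outdir = outdir, profile = profile),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         "\n  (check the stage's inputs; upstream artifacts are kept)",
         call. = FALSE)
  })
}

#' Run the full imaging-transcriptomics analysis
#'
#' Executes every stage on either synthetic or file inputs and returns
#' a `run_report`. When `config$outdir` is set, all intermediate and
#' final artifacts (delta-CT, gene weight table, gene lists, class
#' enrichment, cell-type overlap, report JSON) are written there.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report` list: `selected_k`, `variance_explained`,
#'   `permutation` (component-1 permutation test summary),
#'   `gene_table`, `up`/`down` gene lists, `class_table`,
#'   `overlap_table`, `n_regions`, `n_genes`, `seed`, `n_perm`,
#'   `n_boot`, `timing` (seconds), and in simulation mode `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  message("pipeline: seed ", config$seed, ", profile ", config$profile,
          " (n_perm = ", config$n_perm, ", n_boot = ", config$n_boot, ")")
  seeds <- derive_seeds(config$seed,
                        c("cv", "perm", "boot", "class", "overlap"))

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    expr_raw <- pipeline_stage("simulate", {
      generate_expression(sim)
    })
    gen <- pipeline_stage("simulate", generate_cohort(expr_raw, sim))
    cohort <- gen$cohort
    truth <- gen$truth
    ann <- pipeline_stage("simulate", do.call(generate_annotations, c(
      list(expr = expr_raw, truth = truth, seed = sim$seed),
      config$annotations
    )))
    collection <- ann$collection
    class_map <- ann$class_map
  } else {
    cohort <- pipeline_stage("read thickness",
                             read_thickness(config$inputs$thickness))
    expr_raw <- pipeline_stage("read expression",
                               read_expression(config$inputs$expression))
    class_map <- pipeline_stage("read class map",
                                read_class_map(config$inputs$class_map))
    collection <- pipeline_stage("read gene sets",
                                 read_gmt(config$inputs$gmt,
                                          universe = colnames(expr_raw)))
  }

  dct <- pipeline_stage("delta-CT",
                        compute_delta_ct(cohort, config$group_a,
                                         config$group_b))
  X <- pipeline_stage("standardize", standardize_genes(expr_raw))
  aligned <- pipeline_stage("align", align_regions(X, dct))
  X <- aligned$expr
  dct <- aligned$dct
  message("pipeline: ", nrow(X), " regions x ", ncol(X),
          " genes after alignment")

  selected_k <- pipeline_stage("component selection", {
    select_components_cv(X, dct, max_k = config$max_components,
                         folds = config$folds, seed = seeds[["cv"]])
  })
  fit <- pipeline_stage("PLS fit", fit_pls(X, dct, k = selected_k))
  perm <- pipeline_stage("permutation test", {
    permutation_test_variance(X, dct, component = 1L,
                              n_perm = config$n_perm,
                              seed = seeds[["perm"]])
  })
  gene_table <- pipeline_stage("bootstrap", {
    bootstrap_gene_weights(X, dct, component = 1L,
                           n_boot = config$n_boot,
                           seed = seeds[["boot"]],
                           z_threshold = config$z_threshold,
                           q_threshold = config$q_threshold)
  })
  lists <- significant_gene_lists(gene_table)
  scores <- regional_scores(X, fit$weights[, 1L])
  class_map_used <- class_map[class_map$region_id %in% names(scores), ]
  class_table <- pipeline_stage("class enrichment", {
    class_enrichment(scores, class_map_used, n_perm = config$n_perm,
                     seed = seeds[["class"]])
  })
  overlap_table <- if (length(lists$up) > 0L) {
    pipeline_stage("cell-type overlap", {
      overlap_test(lists$up, collection, n_perm = config$n_perm,
                   seed = seeds[["overlap"]])
    })
  } else NULL

  report <- structure(
    list(
      selected_k = as.integer(selected_k),
      variance_explained = unname(fit$y_variance_explained),
      permutation = list(component = 1L,
                         statistic = perm$statistic_observed,
                         p = perm$p, n_perm = perm$n_perm),
      n_up = length(lists$up), n_down = length(lists$down),
      up = lists$up, down = lists$down,
      gene_table = as.data.frame(gene_table),
      class_table = as.data.frame(class_table),
      overlap_table = if (!is.null(overlap_table)) {
        as.data.frame(overlap_table)
      },
      n_regions = nrow(X), n_genes = ncol(X),
      group_a = config$group_a, group_b = config$group_b,
      seed = config$seed, n_perm = config$n_perm,
      n_boot = config$n_boot, profile = config$profile,
      package_version = as.character(utils::packageVersion("plsct")),
      truth = truth,
      timing = NULL
    ),
    class = "run_report"
  )
  report$timing <- round(proc.time()[["elapsed"]] - t0, 3)

  if (!is.null(config$outdir)) {
    write_report_artifacts(report, dct, config$outdir)
  }
  report
}

write_report_artifacts <- function(report, dct, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_delta_ct(dct, file.path(outdir, "delta_ct.tsv"))
  write_gene_weights(report$gene_table,
                     file.path(outdir, "gene_weights.tsv"))
  writeLines(report$up, file.path(outdir, "genes_up.txt"))
  writeLines(report$down, file.path(outdir, "genes_down.txt"))
  utils::write.table(report$class_table,
                     file.path(outdir, "class_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$overlap_table)) {
    utils::write.table(report$overlap_table,
                       file.path(outdir, "celltype_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- report
  json$gene_table <- NULL                 # kept in its own TSV
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Imaging-transcriptomics run report\n")
  cat(sprintf("  %d regions x %d genes; seed %d\n", x$n_regions,
              x$n_genes, x$seed))
  cat(sprintf("  selected %d component(s); component 1 explains %.1f%% of delta-CT variance (p = %.4g, %d permutations)\n",
              x$selected_k, 100 * x$variance_explained[1L],
              x$permutation$p, x$permutation$n_perm))
  cat(sprintf("  significant genes: %d up, %d down\n", x$n_up, x$n_down))
  sig <- x$class_table$q < 0.05
  if (any(sig)) {
    cat("  class profile (q < 0.05):",
        paste(sprintf("%s %s", x$class_table$class_name[sig],
                      x$class_table$direction[sig]), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Compare two runs for concordance
#'
#' The package's analogue of a discovery/validation comparison: given
#' two reports over the same gene universe it computes the Jaccard
#' overlap of the significant positive gene lists, the Spearman rank
#' correlation of the gene z-scores, and the fraction of classes whose
#' over/under direction agrees.
#'
#' @param report_a,report_b two `run_report` objects whose gene tables
#'   cover the same genes.
#' @return List with `jaccard_up`, `z_rank_correlation`,
#'   `class_direction_agreement`.
#' @export
validate_run <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "run_report"),
            inherits(report_b, "run_report"))
  ga <- report_a$gene_table
  gb <- report_b$gene_table
  if (!setequal(ga$gene, gb$gene)) {
    stop("reports have different gene universes", call. = FALSE)
  }
  gb <- gb[match(ga$gene, gb$gene), ]
  uni <- union(report_a$up, report_b$up)
  jac <- if (length(uni) == 0L) {
    1
  } else length(intersect(report_a$up, report_b$up)) / length(uni)
  rho <- stats::cor(ga$z, gb$z, method = "spearman")
  ca <- report_a$class_table
  cb <- report_b$class_table
  cb <- cb[match(ca$class_label, cb$class_label), ]
  list(jaccard_up = jac, z_rank_correlation = unname(rho),
       class_direction_agreement = mean(ca$direction == cb$direction))
}
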