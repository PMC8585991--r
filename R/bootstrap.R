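#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: on the sorted p-values,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, mapped back to the input order
#' and clipped at 1. Delegates to [stats::p.adjust()] after validating
#' the input range; the test suite checks the result against a
#' brute-force implementation of the step-up definition.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (q-values), same length and order.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Bootstrap-standardized gene weights for one PLS component
#'
#' Resamples regions with replacement `n_boot` times, refits the PLS
#' model, and records the chosen component's weight vector per
#' resample. Each bootstrap weight vector's sign is aligned to the
#' original component (sign of the inner product) so that the
#' reflection ambiguity of PLS does not inflate the spread, and the
#' spread is measured on the component's covariance scale (the weight
#' vector times its pre-normalization norm): resampling with
#' replacement inflates the norm of the covariance vector, so
#' normalizing each resample to unit length would systematically
#' understate the per-gene variability and overdisperse the z-scores
#' under a null response. The bootstrap standard error per gene then
#' standardizes the original weight into a z-score; two-sided normal
#' p-values are Benjamini-Hochberg adjusted across all genes, and a
#' gene is called significant when it passes both the z threshold and
#' the q threshold.
#'
#' Resamples in which the response is constant (possible for tiny R)
#' are redrawn and counted in the `n_redrawn` attribute.
#'
#' @param X standardized expression matrix (regions x genes).
#' @param y response vector or `delta_ct`.
#' @param component which component's weights to standardize (default 1).
#' @param n_boot number of bootstrap resamples (default 1000, minimum
#'   100).
#' @param seed integer seed.
#' @param z_threshold,q_threshold significance thresholds (defaults
#'   1.96 and 0.05).
#' @return A `gene_weight_table` data.frame with columns `gene`,
#'   `weight`, `boot_se`, `z`, `p`, `q`, `significant_up`,
#'   `significant_down`, one row per gene in input column order.
#' @export
bootstrap_gene_weights <- function(X, y, component = 1L, n_boot = 1000L,
                                   seed = 1L, z_threshold = 1.96,
                                   q_threshold = 0.05) {
  if (inherits(y, "delta_ct")) y <- y$values
  check_matrix(X, "X")
  y <- as.numeric(y)
  component <- check_count(component, "component")
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  R <- nrow(X)
  G <- ncol(X)
  if (length(y) != R) stop("length(y) must equal nrow(X)", call. = FALSE)

  fit <- fit_pls(X, y, k = component)
  w0 <- fit$weights[, component]
  w0_raw <- w0 * fit$weight_norms[component]

  sum_w <- numeric(G)
  sum_w2 <- numeric(G)
  n_redrawn <- 0L
  with_seed(derive_seeds(seed, "bootstrap"), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(R, R, replace = TRUE)
        if (stats::var(y[idx]) > 1e-24) break
        n_redrawn <- n_redrawn + 1L
      }
      bfit <- pls1_core(X[idx, , drop = FALSE], y[idx], component,
                        allow_fewer = TRUE)
      if (bfit$n_components < component) {
        # rank-deficient resample: treat like a degenerate draw
        n_redrawn <- n_redrawn + 1L
        wb <- w0_raw
      } else {
        wb <- bfit$weights[, component] *
          bfit$weight_norms[component]
        if (sum(wb * w0_raw) < 0) wb <- -wb
      }
      sum_w <- sum_w + wb
      sum_w2 <- sum_w2 + wb * wb
    }
  })
  if (n_redrawn > 0L) {
    message(n_redrawn, " degenerate bootstrap resample(s) redrawn")
  }
  # SE on the covariance scale, reported on the unit-weight scale so
  # that z = weight / boot_se holds for the tabulated columns
  se_raw <- sqrt(pmax(0, (sum_w2 - sum_w^2 / n_boot) / (n_boot - 1)))
  boot_se <- se_raw / fit$weight_norms[component]
  z <- ifelse(boot_se > 0, w0 / boot_se,
              sign(w0) * Inf)
  p <- 2 * stats::pnorm(-abs(z))
  q <- fdr_bh(p)
  out <- data.frame(
    gene = colnames(X) %||% sprintf("G%05d", seq_len(G)),
    weight = unname(w0),
    boot_se = unname(boot_se),
    z = unname(z),
    p = unname(p),
    q = unname(q),
    significant_up = unname(z > z_threshold & q < q_threshold),
    significant_down = unname(z < -z_threshold & q < q_threshold),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("gene_weight_table", "data.frame"),
            component = component, n_boot = n_boot,
            seed = as.integer(seed), n_redrawn = n_redrawn,
            z_threshold = z_threshold, q_threshold = q_threshold)
}

#' Extract the significant positive- and negative-weight gene lists
#'
#' @param table a `gene_weight_table` from [bootstrap_gene_weights()].
#' @return List with `up` and `down`: disjoint character vectors of
#'   gene ids sorted by decreasing `|z|`.
#' @export
significant_gene_lists <- function(table) {
  stopifnot(inherits(table, "gene_weight_table") ||
              all(c("gene", "z", "significant_up", "significant_down")
                  %in% names(table)))
  ord <- order(-abs(table$z))
  t2 <- table[ord, , drop = FALSE]
  list(up = t2$gene[t2$significant_up],
       down = t2$gene[t2$significant_down])
}

#' Write a gene weight table to TSV
#' @param table a `gene_weight_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_weights <- function(table, path) {
  df <- as.data.frame(table)
  df$direction <- ifelse(df$significant_up, "up",
                         ifelse(df$significant_down, "down", "ns"))
  utils::write.table(
    df[c("gene", "weight", "boot_se", "z", "p", "q", "direction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
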