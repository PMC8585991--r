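# Single-response partial least squares (PLS1) linking regional gene
# expression (X, regions x genes) to a per-region thickness difference
# (y). NIPALS-style extraction with X-block deflation only: for a single
# response this is exact (no inner iteration) and the first component
# has the closed form w1 proportional to X'y, which doubles as an
# independent oracle in the test suite.

#' Fit a single-response partial least squares regression
#'
#' Extracts `k` components of a PLS1 fit of `y` on `X`. Component
#' weights are unit-norm vectors in gene space; region scores are the
#' projections of the (deflated) predictor block and are mutually
#' orthogonal. Each score column is sign-flipped so that it correlates
#' non-negatively with `y`, fixing the reflection ambiguity. The
#' variance-explained entries are the incremental R-squared of `y` on
#' the first `k` orthogonal scores.
#'
#' @param X numeric matrix, regions x genes, columns standardized (see
#'   [standardize_genes()]); an unscaled matrix is accepted but weights
#'   are then not comparable across genes.
#' @param y numeric vector of length `nrow(X)` (e.g. a thickness
#'   difference), or a `delta_ct` object.
#' @param k number of components, `1 <= k <= min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `pls_ct`: list with `weights` (genes x k,
#'   unit-norm columns), `scores` (regions x k, orthogonal),
#'   `x_loadings` (genes x k), `y_loadings` (length k),
#'   `y_variance_explained` (length k, fractions of var(y)),
#'   `weight_norms` (length k: the norm of each pre-normalization
#'   covariance vector, giving the component's covariance scale),
#'   `n_components`, `x_means`, `y_mean`, and the inputs' dimnames.
#' @export
#' @examples
#' X <- matrix(rnorm(100 * 20), 100, 20)
#' X <- standardize_genes(`dimnames<-`(X, list(sprintf("R%03d", 1:100),
#'                                             sprintf("G%02d", 1:20))))
#' y <- X[, 1] - 0.5 * X[, 2] + rnorm(100, sd = 0.1)
#' fit <- fit_pls(X, y, k = 3)
#' fit$y_variance_explained
fit_pls <- function(X, y, k = 1L) {
  if (inherits(y, "delta_ct")) y <- y$values
  check_matrix(X, "X")
  y <- as.numeric(y)
  R <- nrow(X)
  G <- ncol(X)
  if (length(y) != R) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) stop("y contains non-finite values",
                                           call. = FALSE)
  k <- check_count(k, "k")
  if (stats::var(y) < 1e-24) stop("y is constant; PLS undefined",
                                  call. = FALSE)
  if (k > min(R - 1L, G)) {
    stop("k = ", k, " exceeds the maximum rank min(R - 1, G) = ",
         min(R - 1L, G), call. = FALSE)
  }
  fit <- pls1_core(X, y, k, allow_fewer = FALSE)
  structure(fit, class = "pls_ct")
}

# Workhorse: k-component PLS1 on centred data. With allow_fewer = TRUE
# the extraction stops early (returning fewer components) when the
# deflated block carries no further covariance with y, instead of
# erroring; cross-validation folds use this.
pls1_core <- function(X, y, k, allow_fewer = FALSE, tol = 1e-12) {
  R <- nrow(X)
  G <- ncol(X)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2L, x_means, "-")
  yc <- y - y_mean
  yss <- sum(yc^2)

  W <- matrix(0, G, k)
  Tm <- matrix(0, R, k)
  P <- matrix(0, G, k)
  qv <- numeric(k)
  r2 <- numeric(k)
  nrm <- numeric(k)

  got <- 0L
  for (j in seq_len(k)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w * w))
    if (nw < tol) {
      if (allow_fewer) break
      stop("component ", j, " exceeds the informative rank of X",
           call. = FALSE)
    }
    w <- w / nw
    t <- as.vector(Xd %*% w)
    tt <- sum(t * t)
    if (tt < tol) {
      if (allow_fewer) break
      stop("component ", j, " exceeds the informative rank of X",
           call. = FALSE)
    }
    q <- sum(yc * t) / tt
    if (q < 0) {                       # sign convention: corr(t, y) >= 0
      w <- -w
      t <- -t
      q <- -q
    }
    p <- as.vector(crossprod(Xd, t)) / tt
    Xd <- Xd - tcrossprod(t, p)
    # scores are orthogonal, so incremental R^2 decomposes additively
    r2[j] <- q^2 * tt / yss
    W[, j] <- w
    Tm[, j] <- t
    P[, j] <- p
    qv[j] <- q
    nrm[j] <- nw
    got <- j
  }
  idx <- seq_len(got)
  cn <- paste0("PLS", idx)
  list(
    weights = `dimnames<-`(W[, idx, drop = FALSE], list(colnames(X), cn)),
    scores = `dimnames<-`(Tm[, idx, drop = FALSE],
                          list(rownames(X), cn)),
    x_loadings = `dimnames<-`(P[, idx, drop = FALSE],
                              list(colnames(X), cn)),
    y_loadings = qv[idx],
    y_variance_explained = r2[idx],
    weight_norms = nrm[idx],
    n_components = got,
    x_means = x_means,
    y_mean = y_mean
  )
}

# Out-of-sample predictions of y for every component count 1..K at once
# (column k of the result uses the first k components).
pls1_predict_all <- function(fit, Xnew) {
  K <- fit$n_components
  Xd <- sweep(Xnew, 2L, fit$x_means, "-")
  preds <- matrix(fit$y_mean, nrow(Xnew), K)
  acc <- rep(fit$y_mean, nrow(Xnew))
  for (j in seq_len(K)) {
    t_new <- as.vector(Xd %*% fit$weights[, j])
    acc <- acc + fit$y_loadings[j] * t_new
    Xd <- Xd - tcrossprod(t_new, fit$x_loadings[, j])
    preds[, j] <- acc
  }
  preds
}

#' Predict the response from a fitted PLS model
#'
#' @param object a `pls_ct` fit.
#' @param newdata matrix with the same gene columns as the training `X`.
#' @param k number of components to use (default: all fitted).
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pls_ct <- function(object, newdata, k = object$n_components, ...) {
  k <- check_count(k, "k")
  if (k > object$n_components) {
    stop("k exceeds the number of fitted components", call. = FALSE)
  }
  if (ncol(newdata) != nrow(object$weights)) {
    stop("newdata has ", ncol(newdata), " genes; model was fitted with ",
         nrow(object$weights), call. = FALSE)
  }
  pls1_predict_all(object, newdata)[, k]
}

#' @export
print.pls_ct <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d component(s), %d regions x %d genes\n",
              x$n_components, nrow(x$scores), nrow(x$weights)))
  cat("  y variance explained:",
      paste(sprintf("%.3f", x$y_variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of PLS components by cross-validation
#'
#' Splits regions into `folds` random folds (fixed by `seed`), fits up
#' to `max_k` components on each training set, and scores out-of-fold
#' squared prediction error of `y`. Returns the component count with the
#' smallest mean CV error; ties break toward fewer components.
#'
#' @param X standardized expression matrix (regions x genes).
#' @param y response vector or `delta_ct`.
#' @param max_k largest component count considered (default 35).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @return The selected component count (integer) with attribute
#'   `cv_mse`, the length-`max_k` mean squared CV error curve.
#' @export
select_components_cv <- function(X, y, max_k = 35L, folds = 10L,
                                 seed = 1L) {
  if (inherits(y, "delta_ct")) y <- y$values
  check_matrix(X, "X")
  y <- as.numeric(y)
  R <- nrow(X)
  max_k <- check_count(max_k, "max_k")
  folds <- check_count(folds, "folds", min = 2L)
  if (R < folds) stop("need at least as many regions as folds",
                      call. = FALSE)
  if (max_k >= R - ceiling(R / folds)) {
    stop("max_k = ", max_k, " is too large for ", R, " regions with ",
         folds, "-fold CV (training sets have ",
         R - ceiling(R / folds), " regions)", call. = FALSE)
  }
  fold_id <- with_seed(derive_seeds(seed, "cv_folds"),
                       sample(rep_len(seq_len(folds), R)))
  sse <- matrix(NA_real_, folds, max_k)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- pls1_core(X[!test, , drop = FALSE], y[!test], max_k,
                     allow_fewer = TRUE)
    preds <- pls1_predict_all(fit, X[test, , drop = FALSE])
    if (fit$n_components < max_k) {
      # rank exhausted: predictions are unchanged beyond the last
      # extractable component
      extra <- matrix(preds[, fit$n_components],
                      nrow(preds), max_k - fit$n_components)
      preds <- cbind(preds, extra)
    }
    sse[f, ] <- colSums((y[test] - preds)^2)
  }
  cv_mse <- colSums(sse) / R
  selected <- which.min(cv_mse)          # first minimum = smallest k
  structure(as.integer(selected), cv_mse = cv_mse)
}

# Fast component-1 variance-explained statistic for a block of response
# vectors (columns of Y): R^2 = (t'y)^2 / (|t|^2 |y|^2) with t = Xc w,
# w proportional to Xc'y (scale of w cancels).
varexp1_block <- function(Xc, Y) {
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  W <- crossprod(Xc, Yc)
  Tm <- Xc %*% W
  num <- colSums(Tm * Yc)^2
  den <- colSums(Tm * Tm) * colSums(Yc * Yc)
  ifelse(den > 0, num / den, 0)
}

#' Permutation test of the variance explained by one PLS component
#'
#' The observed statistic is the fraction of variance of `y` explained
#' by the chosen component. The null distribution is built by refitting
#' after permuting `y` across regions `n_perm` times, which destroys any
#' region-to-region correspondence between expression and thickness
#' while preserving both marginals. The p-value uses add-one smoothing,
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`, so it is never zero.
#'
#' @param X standardized expression matrix.
#' @param y response vector or `delta_ct`.
#' @param component which component's variance explained to test
#'   (default 1).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return An object of class `permutation_result`: list with
#'   `statistic_observed`, `null_values`, `p`, `n_perm`, `seed`,
#'   `component`.
#' @export
permutation_test_variance <- function(X, y, component = 1L,
                                      n_perm = 10000L, seed = 1L) {
  if (inherits(y, "delta_ct")) y <- y$values
  check_matrix(X, "X")
  y <- as.numeric(y)
  component <- check_count(component, "component")
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100L) {
    warning("n_perm < 100 gives a coarse p-value resolution of ",
            signif(1 / (n_perm + 1), 3), call. = FALSE)
  }
  R <- nrow(X)
  if (length(y) != R) stop("length(y) must equal nrow(X)", call. = FALSE)

  null_values <- numeric(n_perm)
  if (component == 1L) {
    # fully vectorised: component-1 statistic for permuted responses in
    # blocks, one matrix product per block
    Xc <- sweep(X, 2L, colMeans(X), "-")
    observed <- varexp1_block(Xc, matrix(y, ncol = 1L))[1L]
    block <- max(1L, min(n_perm, floor(2e6 / max(1L, ncol(X)))))
    with_seed(derive_seeds(seed, "permutation"), {
      done <- 0L
      while (done < n_perm) {
        b <- min(block, n_perm - done)
        Y <- vapply(seq_len(b), function(i) y[sample.int(R)],
                    numeric(R))
        null_values[done + seq_len(b)] <- varexp1_block(Xc, Y)
        done <- done + b
      }
    })
  } else {
    fit <- fit_pls(X, y, k = component)
    observed <- fit$y_variance_explained[component]
    with_seed(derive_seeds(seed, "permutation"), {
      for (i in seq_len(n_perm)) {
        perm_fit <- pls1_core(X, y[sample.int(R)], component,
                              allow_fewer = TRUE)
        null_values[i] <- if (perm_fit$n_components >= component) {
          perm_fit$y_variance_explained[component]
        } else 0
      }
    })
  }
  structure(
    list(statistic_observed = observed, null_values = null_values,
         p = (1 + sum(null_values >= observed)) / (n_perm + 1),
         n_perm = n_perm, seed = as.integer(seed),
         component = component),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test, component %d: observed %.4f, p = %.4g (%d permutations)\n",
              x$component, x$statistic_observed, x$p, x$n_perm))
  invisible(x)
}
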