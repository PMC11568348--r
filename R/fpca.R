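#' Functional principal component analysis of summary curves
#'
#' Decomposes a set of curves on a shared radius grid into a mean function
#' plus orthonormal eigenfunctions with per-sample scores:
#' \deqn{X_i(r) = \mu(r) + \sum_k \xi_{ik}\,\phi_k(r).}
#' The covariance is the sample covariance of the demeaned curves (optionally
#' smoothed), eigendecomposed with trapezoidal quadrature weights so the
#' eigenfunctions are orthonormal with respect to integration over the grid.
#' Negative eigenvalues are truncated to zero and components are retained
#' until the requested proportion of variance is explained. Eigenfunction
#' signs are fixed so that \eqn{\int \phi_k(r)\,dr > 0} (falling back to a
#' positive value at the largest-magnitude point), making fits reproducible.
#'
#' @param curves A `summary_set`, or a long data frame with `sample_id`,
#'   `r` and the value column.
#' @param value Curve column to analyze; default `"fundiff"` (degree of
#'   clustering beyond chance), `"observed"` also common.
#' @param pve Proportion of variance to explain (default 0.99); sets the
#'   number of retained components.
#' @param npc Optional fixed number of components (overrides `pve`).
#' @param smooth Logical; smooth the mean and covariance surface with
#'   penalized splines (requires mgcv) before eigendecomposition. Default
#'   `FALSE`: summary-function curves are already smooth and the unsmoothed
#'   estimator is exactly reproducible.
#' @return An object of class `sfda_fpca`: grid, `mu`, matrix `efuncs`
#'   (grid x K), `evalues`, `scores` (sample x K), cumulative `pve`,
#'   total variance, and the analyzed value column.
#' @seealso [fpca_component_band()], [reconstruct()], [fit_mfpca()]
#' @export
fit_fpca <- function(curves, value = "fundiff", pve = 0.99, npc = NULL,
                     smooth = FALSE) {
  cm <- as_curve_matrix(curves, value)
  Y <- cm$Y; grid <- cm$grid
  n <- nrow(Y); p <- length(grid)
  if (n < 3) abort("FPCA needs at least 3 curves", class = "sfda_fpca_error")

  mu <- colMeans(Y)
  if (smooth) mu <- smooth_curve(grid, mu)
  Yc <- sweep(Y, 2, mu)
  if (max(abs(Yc)) < 1e-12) {
    abort("zero variance: all curves are identical", class = "sfda_fpca_error")
  }
  C <- crossprod(Yc) / (n - 1)
  if (smooth) C <- smooth_covariance(grid, C)

  eig <- weighted_eigen(C, grid)
  lambda <- eig$values
  pos <- lambda > max(lambda) * 1e-12
  cum <- cumsum(lambda) / sum(lambda)
  K <- if (!is.null(npc)) {
    min(npc, sum(pos))
  } else {
    max(1L, which(cum >= pve)[1])
  }
  K <- min(K, sum(pos))
  phi <- eig$vectors[, seq_len(K), drop = FALSE]

  w <- trapz_weights(grid)
  # sign convention: integral positive; tie-break on the largest |value|
  for (k in seq_len(K)) {
    s <- sum(w * phi[, k])
    if (abs(s) < 1e-8) s <- phi[which.max(abs(phi[, k])), k]
    if (s < 0) phi[, k] <- -phi[, k]
  }
  scores <- Yc %*% (w * phi)
  rownames(scores) <- rownames(Y)
  colnames(scores) <- paste0("PC", seq_len(K))
  colnames(phi) <- paste0("PC", seq_len(K))

  structure(list(grid = grid, mu = mu, efuncs = phi,
                 evalues = lambda[seq_len(K)], all_evalues = lambda,
                 scores = scores, pve = cum[seq_len(K)], npc = K,
                 total_variance = sum(lambda), value = value,
                 smooth = smooth),
            class = "sfda_fpca")
}

# coerce summary_set / long df to samples-by-grid matrix; missing values are
# tolerated only at the grid ends, where the affected radii are trimmed
as_curve_matrix <- function(curves, value) {
  if (is.matrix(curves)) {
    grid <- attr(curves, "grid") %||% seq_len(ncol(curves))
    Y <- curves
  } else if (inherits(curves, "summary_set")) {
    Y <- curve_matrix(curves, value)
    grid <- attr(Y, "grid")
  } else {
    df <- tibble::as_tibble(curves)
    need <- c("sample_id", "r", value)
    if (!all(need %in% names(df))) {
      abort(sprintf("curves must contain columns %s",
                    paste(need, collapse = ", ")))
    }
    wide <- tidyr::pivot_wider(df[need], names_from = "r",
                               values_from = dplyr::all_of(value))
    grid <- as.numeric(names(wide)[-1])
    Y <- as.matrix(wide[-1])
    rownames(Y) <- as.character(wide$sample_id)
  }
  any_na <- apply(Y, 2, anyNA)
  if (any(any_na)) {
    keep <- !any_na
    # only leading/trailing NA runs may be trimmed
    if (any(!keep & !(cumsum(keep) == 0 | rev(cumsum(rev(keep))) == 0))) {
      abort("missing curve values in the grid interior",
            class = "sfda_fpca_error")
    }
    Y <- Y[, keep, drop = FALSE]
    grid <- grid[keep]
  }
  if (length(grid) < 2) abort("need at least 2 usable grid points")
  list(Y = Y, grid = as.numeric(grid))
}

trapz_weights <- function(grid) {
  p <- length(grid)
  w <- numeric(p)
  w[1] <- (grid[2] - grid[1]) / 2
  w[p] <- (grid[p] - grid[p - 1]) / 2
  if (p > 2) w[2:(p - 1)] <- (grid[3:p] - grid[1:(p - 2)]) / 2
  w
}

# eigendecomposition of a covariance kernel with quadrature weights:
# solve the symmetric problem on W^(1/2) C W^(1/2), map back, truncate
# negative eigenvalues to zero
weighted_eigen <- function(C, grid) {
  w <- trapz_weights(grid)
  sw <- sqrt(w)
  A <- (C * sw) * rep(sw, each = nrow(C))  # diag(sw) %*% C %*% diag(sw)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  values <- pmax(e$values, 0)
  vectors <- e$vectors / sw
  list(values = values, vectors = vectors, weights = w)
}

smooth_curve <- function(grid, y) {
  if (!requireNamespace("mgcv", quietly = TRUE)) {
    abort("`smooth = TRUE` requires the mgcv package")
  }
  k <- min(10, length(grid) - 1)
  fit <- mgcv::gam(y ~ s(grid, k = k))
  as.numeric(fit$fitted.values)
}

# bivariate penalized-spline smooth of the covariance surface, excluding the
# diagonal (which carries the measurement-error nugget), then symmetrized
smooth_covariance <- function(grid, C) {
  if (!requireNamespace("mgcv", quietly = TRUE)) {
    abort("`smooth = TRUE` requires the mgcv package")
  }
  p <- length(grid)
  df <- expand.grid(g1 = grid, g2 = grid)
  df$cv <- as.vector(C)
  off <- as.vector(row(C) != col(C))
  k <- min(10, p - 1)
  fit <- mgcv::gam(cv ~ te(g1, g2, k = c(k, k)), data = df[off, ])
  Cs <- matrix(mgcv::predict.gam(fit, newdata = df), p, p)
  (Cs + t(Cs)) / 2
}

#' @export
print.sfda_fpca <- function(x, ...) {
  cat(sprintf("FPCA of '%s' curves: %d samples, %d components (pve %.1f%%)\n",
              x$value, nrow(x$scores), x$npc, 100 * x$pve[x$npc]))
  cat("  eigenvalues:", paste(signif(x$evalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mean +/- one standard deviation band of a principal component
#'
#' Returns the pair of curves \eqn{\mu(r) \pm \sqrt{\lambda_k}\,\phi_k(r)}
#' used to visualize what pattern component `k` represents.
#'
#' @param fit An `sfda_fpca`.
#' @param k Component index, `1 <= k <= npc`.
#' @return Tibble with `r`, `mean`, `lower`, `upper`.
#' @export
fpca_component_band <- function(fit, k) {
  stopifnot(inherits(fit, "sfda_fpca"))
  if (k < 1 || k > fit$npc) {
    abort(sprintf("component %d out of range (1..%d)", k, fit$npc))
  }
  half <- sqrt(fit$evalues[k]) * fit$efuncs[, k]
  tibble::tibble(r = fit$grid, mean = fit$mu,
                 lower = fit$mu - half, upper = fit$mu + half)
}

#' Reconstruct a sample's curve from leading components
#'
#' \eqn{\hat X_i(r) = \mu(r) + \sum_{k \le K'} \xi_{ik} \phi_k(r)}.
#'
#' @param fit An `sfda_fpca`.
#' @param sample Sample id (row of the score matrix).
#' @param k Number of components `K'` to use, `0 <= K' <= npc`
#'   (default all retained).
#' @return Tibble with `r`, `value`.
#' @export
reconstruct <- function(fit, sample, k = fit$npc) {
  stopifnot(inherits(fit, "sfda_fpca"))
  if (k < 0 || k > fit$npc) {
    abort(sprintf("k = %d out of range (0..%d)", k, fit$npc))
  }
  if (!sample %in% rownames(fit$scores)) {
    abort(sprintf("unknown sample '%s'", sample), class = "sfda_key_error")
  }
  v <- fit$mu
  if (k > 0) {
    v <- v + as.numeric(fit$efuncs[, seq_len(k), drop = FALSE] %*%
                          fit$scores[sample, seq_len(k)])
  }
  tibble::tibble(r = fit$grid, value = v)
}

#' Multilevel FPCA for repeated samples per subject
#'
#' When subjects contribute several tissue samples, curve variation splits
#' into a between-subject level (subject-specific deviations from the grand
#' mean) and a within-subject level (sample-specific deviations from the
#' subject mean). Both covariances are estimated by method of moments — the
#' within-covariance from within-subject deviations, the between-covariance
#' from subject means bias-corrected by the within-covariance divided by the
#' average number of samples — and each is eigendecomposed as in
#' [fit_fpca()]. The variance share
#' \eqn{\rho = \sum\lambda^{(1)} / (\sum\lambda^{(1)} + \sum\lambda^{(2)})}
#' quantifies how much of the curve variation is between subjects.
#'
#' @param curves A `summary_set` or long data frame (`sample_id`, `r`,
#'   value column).
#' @param subjects Data frame mapping `sample_id` to `subject_id`.
#' @param value Curve column to analyze (default `"fundiff"`).
#' @param pve Proportion of variance per level (default 0.99).
#' @return An `sfda_mfpca` with per-level eigensystems (`between`,
#'   `within`, each like an `sfda_fpca`), subject- and sample-level scores,
#'   and `rho`.
#' @export
fit_mfpca <- function(curves, subjects, value = "fundiff", pve = 0.99) {
  cm <- as_curve_matrix(curves, value)
  Y <- cm$Y; grid <- cm$grid
  subjects <- tibble::as_tibble(subjects)
  stopifnot(all(c("sample_id", "subject_id") %in% names(subjects)))
  subj <- subjects$subject_id[match(rownames(Y), subjects$sample_id)]
  if (anyNA(subj)) abort("every curve sample needs a subject mapping",
                         class = "sfda_key_error")
  subj <- as.character(subj)
  ids <- unique(subj)
  n_i <- table(subj)[ids]
  if (length(ids) < 3) abort("MFPCA needs at least 3 subjects")
  if (all(n_i == 1)) {
    abort("every subject has a single sample; use fit_fpca()",
          class = "sfda_mfpca_error")
  }

  mu <- colMeans(Y)
  Ybar <- rowsum(Y, subj) / as.vector(table(subj))  # subject means (rows sorted)
  dev_within <- Y - Ybar[subj, , drop = FALSE]

  df_w <- sum(n_i - 1)
  if (df_w == 0) abort("no within-subject replication")
  Kw <- crossprod(dev_within) / df_w
  Ybar_c <- sweep(Ybar, 2, mu)
  Gb <- crossprod(Ybar_c) / (nrow(Ybar) - 1)
  Kb <- Gb - Kw * mean(1 / as.vector(table(subj)))

  eig_b <- weighted_eigen((Kb + t(Kb)) / 2, grid)
  eig_w <- weighted_eigen((Kw + t(Kw)) / 2, grid)
  tot_b <- sum(eig_b$values); tot_w <- sum(eig_w$values)
  if (tot_b + tot_w <= 0) abort("zero variance at both levels",
                                class = "sfda_mfpca_error")
  rho <- tot_b / (tot_b + tot_w)
  w <- trapz_weights(grid)

  level <- function(eig, tot) {
    lambda <- eig$values
    cum <- if (tot > 0) cumsum(lambda) / tot else rep(1, length(lambda))
    K <- max(1L, which(cum >= pve)[1])
    K <- min(K, max(1L, sum(lambda > max(lambda, 1e-300) * 1e-12)))
    phi <- eig$vectors[, seq_len(K), drop = FALSE]
    for (k in seq_len(K)) {
      s <- sum(w * phi[, k])
      if (abs(s) < 1e-8) s <- phi[which.max(abs(phi[, k])), k]
      if (s < 0) phi[, k] <- -phi[, k]
    }
    colnames(phi) <- paste0("PC", seq_len(K))
    list(efuncs = phi, evalues = lambda[seq_len(K)], pve = cum[seq_len(K)],
         npc = K, total_variance = tot)
  }
  between <- level(eig_b, tot_b)
  within <- level(eig_w, tot_w)

  subj_scores <- Ybar_c %*% (w * between$efuncs)
  samp_scores <- dev_within %*% (w * within$efuncs)
  rownames(samp_scores) <- rownames(Y)

  structure(list(grid = grid, mu = mu, between = between, within = within,
                 rho = rho, subject_scores = subj_scores,
                 sample_scores = samp_scores, value = value),
            class = "sfda_mfpca")
}

#' @export
print.sfda_mfpca <- function(x, ...) {
  cat(sprintf(
    "multilevel FPCA of '%s': %d subjects, %d samples; rho = %.3f\n",
    x$value, nrow(x$subject_scores), nrow(x$sample_scores), x$rho))
  cat(sprintf("  between level: %d components\n", x$between$npc))
  cat(sprintf("  within level:  %d components\n", x$within$npc))
  invisible(x)
}
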