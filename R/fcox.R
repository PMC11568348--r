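#' Penalized functional Cox regression
#'
#' Fits the linear functional Cox model
#' \deqn{\log h_i(t) = \log h_0(t) + Z_i'\gamma + \int X_i(r)\beta(r)\,dr,}
#' where \eqn{X_i(r)} is a subject's spatial summary curve and
#' \eqn{\exp\beta(r)} is the hazard ratio associated with a unit increase of
#' the curve at radius `r`. The coefficient function is expanded in cubic
#' B-splines ([functional_design()]) and estimated by maximizing the
#' penalized Cox partial likelihood (Breslow tie handling)
#' \eqn{\ell(b, \gamma) - \tfrac{\lambda}{2}\, b' S b}
#' with Newton iterations. The smoothing parameter is chosen by minimizing
#' \eqn{AIC = -2\ell + 2\,\mathrm{edf}} over a log-spaced grid, where
#' \eqn{\mathrm{edf} = \mathrm{tr}\{(H + \lambda S)^{-1} H\}}. Pointwise
#' standard errors come from \eqn{\theta(r)'(H+\lambda S)^{-1}\theta(r)};
#' the reported bands are pointwise 95\% Wald intervals on the hazard-ratio
#' scale.
#'
#' Curves are mean-centered across subjects before fitting (the baseline
#' hazard absorbs the center); subjects with several samples have their
#' curves averaged.
#'
#' @param curves A `summary_set`, long data frame (`sample_id`, `r`, value
#'   column), or samples-by-grid matrix with a `grid` attribute.
#' @param metadata Subject-level data frame containing `subject_id`, the
#'   outcome columns and any scalar covariates.
#' @param time,event Names of the survival time and event indicator columns
#'   in `metadata` (event: 1/TRUE = observed, 0/FALSE = censored).
#' @param covariates Character vector of scalar covariate columns in
#'   `metadata` (optional).
#' @param subjects Optional data frame mapping `sample_id` to `subject_id`;
#'   when omitted, curve sample ids are taken to be subject ids.
#' @param value Curve column to use (default `"fundiff"`).
#' @param k_basis B-spline basis dimension (default 10).
#' @param lambda Optional fixed smoothing parameter or vector of candidates;
#'   default is a data-scaled log grid of `n_lambda` values.
#' @param n_lambda Length of the default smoothing grid (default 20).
#' @param conf_level Confidence level for the pointwise bands (default 0.95).
#' @return An object of class `sfda_fcox`; see [tidy.sfda_fcox()] for the
#'   per-radius table and [glance.sfda_fcox()] for fit statistics.
#' @examples
#' sim <- simulate_outcomes(n = 60, seed = 1)
#' fit <- fit_functional_cox(sim$curves, sim$metadata, k_basis = 8)
#' glance(fit)
#' @export
fit_functional_cox <- function(curves, metadata, time = "time",
                               event = "event", covariates = NULL,
                               subjects = NULL, value = "fundiff",
                               k_basis = 10, lambda = NULL, n_lambda = 20,
                               conf_level = 0.95) {
  al <- align_curves(curves, metadata, value, subjects)
  X <- al$X; grid <- al$grid; meta <- al$metadata
  n <- nrow(X)
  for (col in c(time, event, covariates)) {
    if (!col %in% names(meta)) {
      abort(sprintf("metadata is missing column '%s'", col),
            class = "sfda_schema_error")
    }
  }
  tt <- as.numeric(meta[[time]])
  dd <- as.numeric(meta[[event]])
  if (any(!is.finite(tt)) || any(tt <= 0)) abort("survival times must be positive")
  if (!all(dd %in% c(0, 1))) abort("event indicator must be 0/1")
  if (sum(dd) == 0) abort("no events in the data", class = "sfda_fit_error")
  if (n < 20) warn(sprintf("only %d subjects; functional Cox fits are unstable below ~20", n))

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  fd <- functional_design(Xc, grid, k_basis)

  Zcov <- scalar_covariate_matrix(meta, covariates)
  M <- cbind(Zcov, fd$design)
  p_z <- ncol(Zcov)
  Sfull <- matrix(0, ncol(M), ncol(M))
  Sfull[(p_z + 1):ncol(M), (p_z + 1):ncol(M)] <- fd$penalty
  # weak fixed ridge on the functional block: pins directions the observed
  # curves do not span (the curvature penalty has a linear null space and
  # rank-deficient curve sets leave those directions unidentified)
  Rfull <- diag(c(rep(0, p_z), rep(1, fd$k_basis)))

  fit <- penalized_cox_path(M, tt, dd, Sfull, Rfull, lambda, n_lambda)

  V <- fit$vcov
  idx_f <- (p_z + 1):ncol(M)
  b_f <- fit$coef[idx_f]
  beta <- as.numeric(fd$basis %*% b_f)
  se <- sqrt(pmax(rowSums((fd$basis %*% V[idx_f, idx_f]) * fd$basis), 0))
  z <- qnorm(1 - (1 - conf_level) / 2)

  gamma <- if (p_z > 0) {
    tibble::tibble(term = colnames(Zcov),
                   estimate = unname(fit$coef[seq_len(p_z)]),
                   std.error = unname(sqrt(diag(V)[seq_len(p_z)])))
  } else tibble::tibble(term = character(0), estimate = numeric(0),
                        std.error = numeric(0))

  structure(list(
    grid = grid, beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    gamma = gamma, knots = fd$knots, coef = fit$coef, vcov = V,
    k_basis = k_basis, lambda = fit$lambda, edf = fit$edf,
    loglik = fit$loglik, aic = fit$aic, aic_path = fit$path,
    n = n, n_events = sum(dd), value = value, center = center,
    conf_level = conf_level),
    class = "sfda_fcox")
}

scalar_covariate_matrix <- function(meta, covariates) {
  if (is.null(covariates) || !length(covariates)) {
    return(matrix(numeric(0), nrow(meta), 0))
  }
  Z <- stats::model.matrix(
    stats::reformulate(covariates, intercept = FALSE), data = meta)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    abort(sprintf("collinear scalar covariate(s): %s",
                  paste(bad, collapse = ", ")),
          class = "sfda_fit_error")
  }
  Z
}

# map curve samples onto subjects and align with metadata rows; multiple
# samples per subject are averaged
align_curves <- function(curves, metadata, value, subjects = NULL) {
  cm <- as_curve_matrix(curves, value)
  Y <- cm$Y
  metadata <- tibble::as_tibble(metadata)
  if (!"subject_id" %in% names(metadata)) {
    abort("metadata must contain a 'subject_id' column",
          class = "sfda_schema_error")
  }
  metadata$subject_id <- as.character(metadata$subject_id)
  subj <- if (!is.null(subjects)) {
    subjects <- tibble::as_tibble(subjects)
    as.character(subjects$subject_id[match(rownames(Y), subjects$sample_id)])
  } else {
    rownames(Y)
  }
  if (anyNA(subj)) abort("unmapped curve sample(s)", class = "sfda_key_error")
  Ybar <- rowsum(Y, subj) / as.vector(table(subj))
  keep <- intersect(metadata$subject_id, rownames(Ybar))
  if (!length(keep)) abort("no subjects shared between curves and metadata",
                           class = "sfda_key_error")
  meta <- metadata[match(keep, metadata$subject_id), , drop = FALSE]
  list(X = Ybar[keep, , drop = FALSE], grid = cm$grid, metadata = meta)
}

# ---- penalized Cox core (Breslow ties) -------------------------------------

# inverse with escalating ridge jitter; the information matrix is singular
# when the observed curves span fewer directions than the basis dimension
robust_solve <- function(A, b = NULL) {
  rhs <- if (is.null(b)) diag(nrow(A)) else b
  out <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (!is.null(out)) return(out)
  d <- max(abs(diag(A)), 1e-300)
  for (jit in 10^seq(-12, -4)) {
    out <- tryCatch(solve(A + diag(jit * d, nrow(A)), rhs),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  abort("information matrix is numerically singular", class = "sfda_fit_error")
}

# partial likelihood, gradient and Hessian at eta = M %*% theta, computed
# with prefix sums over the risk sets (times sorted decreasing)
cox_pl_parts <- function(M, ord, tie_idx, is_event, theta, need_hess = TRUE) {
  n <- nrow(M); p <- ncol(M)
  eta <- as.numeric(M %*% theta)
  eta_s <- eta[ord]
  M_s <- M[ord, , drop = FALSE]
  w <- exp(eta_s)
  S0 <- cumsum(w)
  S1 <- apply(w * M_s, 2, cumsum)
  ev <- which(is_event)
  k <- tie_idx[ev]
  pl <- sum(eta_s[ev]) - sum(log(S0[k]))
  U <- S1[k, , drop = FALSE] / S0[k]
  grad <- colSums(M_s[ev, , drop = FALSE]) - colSums(U)
  H <- NULL
  if (need_hess) {
    # n x p^2 array of w_j * x_j x_j' (column-major outer products)
    P <- w * (M_s[, rep(seq_len(p), times = p), drop = FALSE] *
                M_s[, rep(seq_len(p), each = p), drop = FALSE])
    C2 <- apply(P, 2, cumsum)
    if (length(ev) == 1) {
      A <- C2[k, ] / S0[k]
    } else {
      A <- colSums(C2[k, , drop = FALSE] / S0[k])
    }
    H <- matrix(A, p, p) - crossprod(U)
    H <- (H + t(H)) / 2
  }
  list(pl = pl, grad = grad, hess = H)
}

newton_cox <- function(M, ord, tie_idx, is_event, P, theta0,
                       tol = 1e-8, max_iter = 100) {
  theta <- theta0
  pen_pl <- function(parts, th) parts$pl - sum(th * (P %*% th)) / 2
  parts <- cox_pl_parts(M, ord, tie_idx, is_event, theta)
  q_old <- pen_pl(parts, theta)
  for (it in seq_len(max_iter)) {
    g <- parts$grad - as.numeric(P %*% theta)
    Hp <- parts$hess + P
    step <- robust_solve(Hp, g)
    # converged when the quadratic model predicts a negligible gain
    if (0.5 * sum(g * step) <= tol * (abs(q_old) + 1)) {
      return(list(theta = theta, parts = parts, iters = it))
    }
    # step halving on the penalized partial likelihood; acceptance is
    # tolerant of floating-point rounding at the optimum
    alpha <- 1
    repeat {
      theta_new <- theta + alpha * step
      parts_new <- cox_pl_parts(M, ord, tie_idx, is_event, theta_new)
      q_new <- pen_pl(parts_new, theta_new)
      if (is.finite(q_new) &&
          q_new >= q_old - 1e-10 * (abs(q_old) + 1)) break
      alpha <- alpha / 2
      if (alpha < 1e-10) {
        abort("functional Cox fit did not converge (step halving failed)",
              class = "sfda_fit_error")
      }
    }
    converged <- abs(q_new - q_old) < tol * (abs(q_old) + 1)
    theta <- theta_new; parts <- parts_new; q_old <- q_new
    if (converged) {
      return(list(theta = theta, parts = parts, iters = it))
    }
  }
  abort("functional Cox fit did not converge within 100 iterations",
        class = "sfda_fit_error")
}

penalized_cox_path <- function(M, tt, dd, S, R = NULL, lambda = NULL,
                               n_lambda = 20, ridge_rel = 1e-2) {
  ord <- order(tt, decreasing = TRUE)
  t_s <- tt[ord]
  # index of the last risk-set member at each subject's own time (Breslow)
  tie_idx <- vapply(seq_along(t_s),
                    function(i) max(which(t_s == t_s[i])), integer(1))
  is_event <- dd[ord] == 1
  p <- ncol(M)
  if (is.null(R)) R <- diag(p)

  parts0 <- cox_pl_parts(M, ord, tie_idx, is_event, rep(0, p))
  scale_h <- sum(abs(diag(parts0$hess)))
  ridge <- ridge_rel * scale_h / p
  if (is.null(lambda)) {
    scale_s <- sum(abs(diag(S)))
    ref <- if (scale_s > 0) scale_h / scale_s else 1
    lambda <- ref * 10^seq(5, -5, length.out = n_lambda)
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }

  theta <- rep(0, p)
  fits <- vector("list", length(lambda))
  path <- tibble::tibble(lambda = numeric(0), edf = numeric(0),
                         loglik = numeric(0), aic = numeric(0))
  for (i in seq_along(lambda)) {
    lam <- lambda[i]
    fit <- tryCatch(
      newton_cox(M, ord, tie_idx, is_event, lam * S + ridge * R, theta),
      sfda_fit_error = function(e) e)
    if (inherits(fit, "error")) {
      # the path descends lambda; once Newton fails the smaller values are
      # only less identified, so stop unless nothing converged at all
      if (i == 1 || length(lambda) == 1) stop(fit)
      fits <- fits[seq_len(i - 1)]
      break
    }
    theta <- fit$theta  # warm start the next (smaller) lambda
    Hp <- fit$parts$hess + lam * S + ridge * R
    Hp_inv <- robust_solve(Hp)
    edf <- sum(diag(Hp_inv %*% fit$parts$hess))
    aic <- -2 * fit$parts$pl + 2 * edf
    path <- dplyr::bind_rows(path, tibble::tibble(
      lambda = lam, edf = edf, loglik = fit$parts$pl, aic = aic))
    fits[[i]] <- list(coef = fit$theta, vcov = Hp_inv, lambda = lam,
                      edf = edf, loglik = fit$parts$pl, aic = aic)
  }
  # AIC differences under ~2 are not meaningful; among the candidates within
  # 2 of the minimum take the smoothest (largest lambda) to avoid drifting
  # into weakly identified directions on a flat plateau
  pick <- which(path$aic <= min(path$aic) + 2)[1]
  best <- fits[[pick]]
  best$path <- path
  best
}

#' @export
print.sfda_fcox <- function(x, ...) {
  cat(sprintf(
    "functional Cox model: %d subjects, %d events; k_basis = %d\n",
    x$n, x$n_events, x$k_basis))
  cat(sprintf("  lambda = %.4g, edf = %.2f, penalized log PL = %.3f\n",
              x$lambda, x$edf, x$loglik))
  if (nrow(x$gamma)) {
    cat("  scalar coefficients:\n")
    print(as.data.frame(x$gamma), row.names = FALSE)
  }
  sig <- significant_range(x)
  if (nrow(sig)) {
    cat("  HR bands exclude 1 on:",
        paste(sprintf("[%.3g, %.3g]", sig$r_start, sig$r_end),
              collapse = ", "), "\n")
  } else {
    cat("  HR bands contain 1 at every radius\n")
  }
  invisible(x)
}
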