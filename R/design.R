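#' Functional design block for scalar-on-function terms
#'
#' Discretizes the functional term \eqn{\int X_i(r)\beta(r)\,dr} of a
#' scalar-on-function model. The coefficient function is expanded in a cubic
#' B-spline basis, \eqn{\beta(r) = \sum_l b_l \theta_l(r)}, so the term
#' becomes a linear predictor with design entries
#' \eqn{Z_{il} = \sum_j w_j X_i(r_j)\theta_l(r_j)} under trapezoidal
#' quadrature weights \eqn{w_j}. Smoothness is controlled by the usual
#' second-derivative penalty \eqn{S_{lm} = \int \theta_l''\theta_m''\,dr},
#' whose null space contains all linear functions of `r`.
#'
#' @param X Numeric matrix of curves, one row per subject, columns on `grid`.
#' @param grid Radius grid (strictly increasing).
#' @param k_basis Number of B-spline basis functions (default 10, minimum 4,
#'   at most the number of grid points).
#' @return A list: `design` (n x k_basis), `basis` (grid x k_basis),
#'   `penalty` (k_basis x k_basis), `knots`, `grid`, `weights`.
#' @export
functional_design <- function(X, grid, k_basis = 10) {
  grid <- check_grid(grid)
  X <- as.matrix(X)
  if (ncol(X) != length(grid)) abort("curve columns must match the grid")
  if (anyNA(X)) abort("curves must be complete on the grid")
  if (k_basis > length(grid)) {
    abort("`k_basis` exceeds the number of grid points")
  }
  if (k_basis < 4) abort("`k_basis` must be at least 4 for cubic B-splines")
  knots <- spline_knots(range(grid), k_basis)
  theta <- splines::splineDesign(knots, grid, ord = 4)
  w <- trapz_weights(grid)
  design <- X %*% (w * theta)
  colnames(design) <- paste0("bs", seq_len(k_basis))
  list(design = design, basis = theta, penalty = second_deriv_penalty(knots),
       knots = knots, grid = grid, weights = w, k_basis = k_basis)
}

spline_knots <- function(rng, k_basis) {
  n_interior <- k_basis - 4
  interior <- if (n_interior > 0) {
    seq(rng[1], rng[2], length.out = n_interior + 2)[-c(1, n_interior + 2)]
  } else numeric(0)
  c(rep(rng[1], 4), interior, rep(rng[2], 4))
}

# S_lm = int theta_l'' theta_m'' dr by fine-grid trapezoid quadrature;
# exact up to quadrature error (the integrand is piecewise linear in r for
# cubic splines, so a dense grid is effectively exact)
second_deriv_penalty <- function(knots) {
  rng <- range(knots)
  fine <- seq(rng[1], rng[2], length.out = 2001)
  d2 <- splines::splineDesign(knots, fine, ord = 4, derivs = 2)
  wf <- trapz_weights(fine)
  S <- crossprod(d2, wf * d2)
  (S + t(S)) / 2
}

# evaluate a basis-coefficient function on arbitrary radii
eval_beta <- function(knots, coef, r) {
  theta <- splines::splineDesign(knots, r, ord = 4)
  as.numeric(theta %*% coef)
}
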