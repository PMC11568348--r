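#' Spatial summary function estimators
#'
#' Estimators for Ripley's K, the nearest-neighbor distance distribution G,
#' and the variance-stabilized L function, in univariate (single phenotype)
#' and bivariate (colocalization of two phenotypes) forms. All estimators
#' evaluate on a user-supplied radius grid and use the closed inequality
#' `d <= r` in the indicator.
#'
#' `estimate_K()` computes
#' \deqn{\hat K(r) = \frac{|A|}{m(m-1)} \sum_i \sum_{j \ne i}
#'   1(d_{ij} \le r)\, e_{ij}}
#' where `|A|` is the window area, `m` the number of points of the target
#' phenotype, and `e_ij` an edge-correction weight. With
#' `correction = "none"` all weights are 1; `"translation"` uses the
#' rectangle translation weights of [edge_weights_translation()];
#' `"border"` restricts the outer sum to points further than `r` from the
#' boundary and rescales by the retained count.
#'
#' `estimate_G()` computes the empirical distribution of nearest-neighbor
#' distances, \eqn{\hat G(r) = m^{-1} \sum_i 1(d^{NN}_i \le r)}; the border
#' (reduced-sample) correction keeps only points with boundary distance
#' greater than `r` and is `NA` where no points remain.
#'
#' `estimate_L()` is \eqn{\sqrt{\hat K(r)/\pi}}, which equals `r` under
#' complete spatial randomness.
#'
#' @param pattern A [point_pattern()].
#' @param mark Target phenotype label; `NULL` uses all points.
#' @param mark1,mark2 Phenotype labels for the bivariate forms.
#' @param grid Radius grid (strictly increasing, starting at >= 0); defaults
#'   to [default_radius_grid()] of the pattern's window.
#' @param correction Edge correction: `"none"`, `"translation"` (K/L), or
#'   `"border"`.
#' @return A tibble with columns `r` and the estimate (`K`, `G`, `L`, or the
#'   cross versions `K12`, `G12`).
#' @seealso [extract_summary_functions()] for batch extraction over a study.
#' @name summary-estimators
NULL

check_grid <- function(grid) {
  if (is.null(grid) || length(grid) < 1 || any(!is.finite(grid)) ||
      grid[1] < 0 || (length(grid) > 1 && any(diff(grid) <= 0))) {
    abort("`grid` must be non-negative and strictly increasing",
          class = "sfda_grid_error")
  }
  as.numeric(grid)
}

insufficient <- function(what) {
  abort(paste0("insufficient cells: ", what),
        class = "sfda_insufficient_cells")
}

target_pattern <- function(pattern, mark) {
  if (is.null(mark)) pattern else subset_pattern(pattern, mark)
}

# step-function evaluation: number of values <= each grid point, done in
# O((n + length(grid)) log n) via sorted counts
count_leq <- function(values, grid) {
  findInterval(grid, sort(values))
}

#' @rdname summary-estimators
#' @export
estimate_K <- function(pattern, mark = NULL, grid = NULL,
                       correction = c("translation", "none", "border")) {
  correction <- match.arg(correction)
  pp <- target_pattern(pattern, mark)
  grid <- check_grid(grid %||% default_radius_grid(pattern$window))
  if (pp$n < 2) insufficient("univariate K needs >= 2 points of the target mark")
  area <- window_area(pp$window)
  d <- as.matrix(dist(cbind(pp$x, pp$y)))
  m <- pp$n
  if (correction == "border") {
    b <- boundary_distance(pp)
    k <- vapply(grid, function(r) {
      keep <- b > r
      n_r <- sum(keep)
      if (n_r == 0) return(NA_real_)
      area * sum(d[keep, , drop = FALSE] <= r) - area * n_r  # subtract diagonal
    }, numeric(1))
    n_kept <- vapply(grid, function(r) sum(b > r), numeric(1))
    k <- k / (pmax(n_kept, 1) * (m - 1))
    k[n_kept == 0] <- NA_real_
  } else {
    e <- if (correction == "translation") edge_weights_translation(pp) else {
      em <- matrix(1, m, m); diag(em) <- 0; em
    }
    # off-diagonal pairs only; diagonal weight is 0 by construction
    dv <- d[upper.tri(d)]
    ev <- e[upper.tri(e)]
    ord <- order(dv)
    cum_e <- cumsum(ev[ord])
    idx <- findInterval(grid, dv[ord])
    pair_sum <- 2 * ifelse(idx > 0, cum_e[pmax(idx, 1)], 0)
    k <- area * pair_sum / (m * (m - 1))
  }
  tibble::tibble(r = grid, K = k)
}

#' @rdname summary-estimators
#' @export
estimate_K_cross <- function(pattern, mark1, mark2, grid = NULL,
                             correction = c("translation", "none", "border")) {
  correction <- match.arg(correction)
  grid <- check_grid(grid %||% default_radius_grid(pattern$window))
  if (is.null(pattern$marks)) abort("pattern has no marks")
  i1 <- which(pattern$marks %in% mark1)
  i2 <- which(pattern$marks %in% mark2)
  if (length(i1) < 1 || length(i2) < 1) {
    insufficient("bivariate K needs >= 1 point of each mark")
  }
  area <- window_area(pattern$window)
  dx <- outer(pattern$x[i1], pattern$x[i2], "-")
  dy <- outer(pattern$y[i1], pattern$y[i2], "-")
  d <- sqrt(dx^2 + dy^2)
  same <- outer(i1, i2, "==")  # identical cells when marks overlap
  if (correction == "translation") {
    a <- diff(pattern$window$xrange); b <- diff(pattern$window$yrange)
    e <- (a * b) / ((a - abs(dx)) * (b - abs(dy)))
  } else {
    e <- matrix(1, length(i1), length(i2))
  }
  e[same] <- 0
  if (correction == "border") {
    b1 <- boundary_distance(pattern)[i1]
    k12 <- vapply(grid, function(r) {
      keep <- b1 > r
      n_r <- sum(keep)
      if (n_r == 0) return(NA_real_)
      area * sum((d[keep, , drop = FALSE] <= r) *
                   e[keep, , drop = FALSE]) / (n_r * length(i2))
    }, numeric(1))
  } else {
    dv <- as.vector(d); ev <- as.vector(e)
    ord <- order(dv)
    cum_e <- cumsum(ev[ord])
    idx <- findInterval(grid, dv[ord])
    k12 <- area * ifelse(idx > 0, cum_e[pmax(idx, 1)], 0) /
      (length(i1) * length(i2))
  }
  tibble::tibble(r = grid, K12 = k12)
}

#' @rdname summary-estimators
#' @export
estimate_G <- function(pattern, mark = NULL, grid = NULL,
                       correction = c("border", "none")) {
  correction <- match.arg(correction)
  pp <- target_pattern(pattern, mark)
  grid <- check_grid(grid %||% default_radius_grid(pattern$window))
  if (pp$n < 2) insufficient("univariate G needs >= 2 points of the target mark")
  d <- as.matrix(dist(cbind(pp$x, pp$y)))
  dnn <- apply(d + diag(Inf, pp$n), 1, min)
  g_curve(dnn, boundary_distance(pp), grid, correction)
}

#' @rdname summary-estimators
#' @export
estimate_G_cross <- function(pattern, mark1, mark2, grid = NULL,
                             correction = c("border", "none")) {
  correction <- match.arg(correction)
  grid <- check_grid(grid %||% default_radius_grid(pattern$window))
  if (is.null(pattern$marks)) abort("pattern has no marks")
  i1 <- which(pattern$marks %in% mark1)
  i2 <- which(pattern$marks %in% mark2)
  if (length(i1) < 1 || length(i2) < 1) {
    insufficient("bivariate G needs >= 1 point of each mark")
  }
  dx <- outer(pattern$x[i1], pattern$x[i2], "-")
  dy <- outer(pattern$y[i1], pattern$y[i2], "-")
  d <- sqrt(dx^2 + dy^2)
  d[outer(i1, i2, "==")] <- Inf  # a cell of both types is not its own neighbor
  if (all(!is.finite(d))) insufficient("no cross-type neighbor available")
  dnn <- apply(d, 1, min)
  out <- g_curve(dnn, boundary_distance(pattern)[i1], grid, correction)
  names(out)[2] <- "G12"
  out
}

g_curve <- function(dnn, b, grid, correction) {
  if (correction == "none") {
    g <- count_leq(dnn, grid) / length(dnn)
  } else {
    g <- vapply(grid, function(r) {
      keep <- b > r
      if (!any(keep)) return(NA_real_)
      sum(dnn[keep] <= r) / sum(keep)
    }, numeric(1))
  }
  tibble::tibble(r = grid, G = g)
}

#' @rdname summary-estimators
#' @export
estimate_L <- function(pattern, mark = NULL, grid = NULL,
                       correction = c("translation", "none", "border")) {
  k <- estimate_K(pattern, mark = mark, grid = grid, correction = correction)
  tibble::tibble(r = k$r, L = sqrt(k$K / pi))
}

#' Theoretical summary functions under complete spatial randomness
#'
#' Closed-form values of the summary functions for a homogeneous Poisson
#' process: \eqn{K(r) = \pi r^2}, \eqn{L(r) = r}, and
#' \eqn{G(r) = 1 - \exp(-\lambda \pi r^2)} where \eqn{\lambda} is the
#' intensity of the (target) phenotype.
#'
#' @param metric One of `"K"`, `"L"`, `"G"`.
#' @param grid Radius grid.
#' @param lambda Intensity (points per unit area); required for `"G"`.
#' @return Numeric vector of theoretical values on `grid`.
#' @export
csr_theoretical <- function(metric, grid, lambda = NULL) {
  grid <- check_grid(grid)
  switch(metric,
         K = pi * grid^2,
         L = grid,
         G = {
           if (is.null(lambda) || lambda <= 0) {
             abort("`lambda` > 0 required for the G baseline")
           }
           1 - exp(-lambda * pi * grid^2)
         },
         abort(sprintf("no theoretical CSR form for metric '%s'", metric),
               class = "sfda_metric_error"))
}

# evaluate any metric (builtin or plugin) as a bare numeric curve;
# marks is NULL, length-1 (univariate) or length-2 (bivariate)
metric_curve <- function(metric, pattern, marks, grid, correction) {
  if (metric %in% c("K", "L", "G")) {
    bivar <- length(marks) == 2
    est <- switch(metric,
      K = if (bivar) estimate_K_cross(pattern, marks[1], marks[2], grid, correction)
          else estimate_K(pattern, marks, grid, correction),
      L = {
        if (bivar) {
          k <- estimate_K_cross(pattern, marks[1], marks[2], grid, correction)
          tibble::tibble(r = k$r, L = sqrt(k$K12 / pi))
        } else estimate_L(pattern, marks, grid, correction)
      },
      G = if (bivar) estimate_G_cross(pattern, marks[1], marks[2], grid, correction)
          else estimate_G(pattern, marks, grid, correction))
    est[[2]]
  } else {
    fn <- get_summary_plugin(metric)
    as.numeric(fn(pattern, marks, grid))
  }
}

#' Permutation-based empirical CSR baseline
#'
#' Reassigns the phenotype labels uniformly at random across the fixed cell
#' locations (preserving label counts), recomputes the summary function for
#' each permutation, and returns the pointwise mean. Unlike the theoretical
#' Poisson baseline, this conditions on where cells could be observed at all,
#' so it is robust to holes in the tissue.
#'
#' @param pattern A marked [point_pattern()].
#' @param marks Target mark (length 1) or mark pair (length 2).
#' @param metric `"K"`, `"L"`, `"G"`, or a registered plugin name.
#' @param grid Radius grid.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param correction Edge correction passed to the estimator.
#' @param envelope_probs Optional length-2 probability vector; when given,
#'   pointwise quantile envelopes across permutations are returned too.
#' @return Tibble with `r`, `csr_permuted`, and optionally `env_lo`/`env_hi`.
#' @export
csr_permuted <- function(pattern, marks, metric = "G", grid = NULL,
                         n_perm = 100, seed = NULL,
                         correction = default_correction(metric),
                         envelope_probs = NULL) {
  grid <- check_grid(grid %||% default_radius_grid(pattern$window))
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  if (pattern$n < 2) insufficient("permutation baseline needs >= 2 cells")
  if (is.null(pattern$marks)) abort("pattern has no marks")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  curves <- matrix(NA_real_, n_perm, length(grid))
  for (p in seq_len(n_perm)) {
    perm <- pattern
    perm$marks <- pattern$marks[sample.int(pattern$n)]
    curves[p, ] <- metric_curve(metric, perm, marks, grid, correction)
  }
  out <- tibble::tibble(r = grid, csr_permuted = colMeans(curves))
  if (!is.null(envelope_probs)) {
    qs <- apply(curves, 2, quantile, probs = sort(envelope_probs),
                na.rm = TRUE, names = FALSE)
    out$env_lo <- qs[1, ]
    out$env_hi <- qs[2, ]
  }
  out
}

default_correction <- function(metric) {
  switch(metric, G = "border", K = "translation", L = "translation", "none")
}
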