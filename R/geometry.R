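#' Rectangular observation window
#'
#' Observation windows describe the tissue region over which a point pattern
#' was observed. Only axis-aligned rectangles are supported; the area `|A|`
#' enters the K-function normalization and the window sides determine the
#' translation edge-correction weights.
#'
#' @param xrange,yrange Numeric length-2 vectors, `c(min, max)` in microns.
#' @return An object of class `sfda_window` with elements `xrange`, `yrange`.
#' @examples
#' owin_rect(c(0, 1), c(0, 1))
#' @export
owin_rect <- function(xrange = c(0, 1), yrange = c(0, 1)) {
  stopifnot(length(xrange) == 2, length(yrange) == 2,
            is.finite(xrange), is.finite(yrange))
  if (diff(xrange) <= 0 || diff(yrange) <= 0) {
    abort("window must have positive width and height", class = "sfda_window_error")
  }
  structure(list(xrange = as.numeric(xrange), yrange = as.numeric(yrange)),
            class = "sfda_window")
}

#' @export
print.sfda_window <- function(x, ...) {
  cat(sprintf("window: rectangle [%g, %g] x [%g, %g] (area %g)\n",
              x$xrange[1], x$xrange[2], x$yrange[1], x$yrange[2],
              window_area(x)))
  invisible(x)
}

#' Area of an observation window
#'
#' @param window An [owin_rect()] window.
#' @return Area in squared coordinate units.
#' @export
window_area <- function(window) {
  diff(window$xrange) * diff(window$yrange)
}

# bounding-box window for a set of points (the default when no tissue
# boundary is supplied)
bbox_window <- function(x, y) {
  rx <- range(x); ry <- range(y)
  # degenerate (single point / collinear) patterns get a tiny positive extent
  if (diff(rx) <= 0) rx <- rx + c(-0.5, 0.5)
  if (diff(ry) <= 0) ry <- ry + c(-0.5, 0.5)
  owin_rect(rx, ry)
}

#' Default radius grid for spatial summary functions
#'
#' Radii run from 0 to one quarter of the window's shorter side, the usual
#' conservative upper bound beyond which edge-corrected estimates become
#' unstable.
#'
#' @param window An [owin_rect()] window.
#' @param n_r Number of equally spaced radii (default 100).
#' @return Numeric vector of radii, strictly increasing from 0.
#' @examples
#' default_radius_grid(owin_rect(c(0, 1), c(0, 1)), n_r = 6)
#' @export
default_radius_grid <- function(window, n_r = 100) {
  if (!inherits(window, "sfda_window")) abort("`window` must be an owin_rect()")
  if (n_r < 2) abort("`n_r` must be at least 2", class = "sfda_grid_error")
  short <- min(diff(window$xrange), diff(window$yrange))
  seq(0, short / 4, length.out = n_r)
}

#' Planar marked point pattern
#'
#' A point pattern holds the cell centroid coordinates of one tissue sample,
#' an optional phenotype mark per cell, and the observation window. When no
#' window is given the bounding box of the points is used.
#'
#' @param x,y Numeric coordinate vectors (microns).
#' @param marks Optional character/factor vector of phenotype labels, one per
#'   point. The factor levels declare the mark set.
#' @param window Optional [owin_rect()]; defaults to the points' bounding box.
#' @return An object of class `sfda_ppp` with elements `x`, `y`, `marks`
#'   (factor or `NULL`), `window` and point count `n`.
#' @examples
#' pp <- point_pattern(runif(20), runif(20),
#'                     marks = sample(c("immune", "tumor"), 20, TRUE),
#'                     window = owin_rect())
#' pp
#' @export
point_pattern <- function(x, y, marks = NULL, window = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) && any(!is.finite(x) | !is.finite(y))) {
    abort("coordinates must be finite", class = "sfda_pattern_error")
  }
  if (is.null(window)) {
    window <- if (length(x)) bbox_window(x, y) else owin_rect()
  }
  tol <- 1e-9
  inside <- x >= window$xrange[1] - tol & x <= window$xrange[2] + tol &
    y >= window$yrange[1] - tol & y <= window$yrange[2] + tol
  if (length(x) && !all(inside)) {
    abort(sprintf("%d point(s) fall outside the window", sum(!inside)),
          class = "sfda_pattern_error")
  }
  if (!is.null(marks)) {
    if (length(marks) != length(x)) abort("`marks` must match the number of points")
    marks <- as.factor(marks)
  }
  structure(list(x = x, y = y, marks = marks, window = window, n = length(x)),
            class = "sfda_ppp")
}

#' @export
print.sfda_ppp <- function(x, ...) {
  cat(sprintf("planar point pattern: %d points\n", x$n))
  if (!is.null(x$marks)) {
    tab <- table(x$marks)
    cat("marks:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  print(x$window)
  invisible(x)
}

# restrict a pattern to points carrying a mark (or any of several marks)
subset_pattern <- function(pattern, mark) {
  if (is.null(pattern$marks)) abort("pattern has no marks")
  keep <- pattern$marks %in% mark
  point_pattern(pattern$x[keep], pattern$y[keep],
                marks = droplevels(pattern$marks[keep]),
                window = pattern$window)
}

#' Translation edge-correction weights
#'
#' For a rectangular window with sides `a`, `b` the translation correction
#' weights each pair by the reciprocal of the proportion of translations of
#' the pair that keep both points inside the window:
#' `e_ij = (a * b) / ((a - |dx_ij|) * (b - |dy_ij|))`. Weights are >= 1 and
#' grow as a pair spans more of the window.
#'
#' @param pattern An [point_pattern()] on a rectangular window.
#' @return An `n x n` matrix of weights; the diagonal is set to 0 (unused).
#' @export
edge_weights_translation <- function(pattern) {
  w <- pattern$window
  a <- diff(w$xrange); b <- diff(w$yrange)
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  if (any(dx >= a) || any(dy >= b)) {
    abort("pair separation exceeds window side; points outside window?",
          class = "sfda_pattern_error")
  }
  e <- (a * b) / ((a - dx) * (b - dy))
  diag(e) <- 0
  e
}

# distance from each point to the nearest window edge
boundary_distance <- function(pattern) {
  w <- pattern$window
  pmin(pattern$x - w$xrange[1], w$xrange[2] - pattern$x,
       pattern$y - w$yrange[1], w$yrange[2] - pattern$y)
}

#' Pairwise geometry of a point pattern
#'
#' Computes the ingredients of the summary-function estimators: the pairwise
#' distance matrix, nearest-neighbor distances, distances to the window
#' boundary, and (for rectangles) translation edge weights.
#'
#' @param pattern A [point_pattern()].
#' @return A list with `d` (distance matrix, zero diagonal), `dnn`
#'   (nearest-neighbor distances), `b` (boundary distances), and `e_translation`
#'   (translation weights).
#' @export
pairwise_geometry <- function(pattern) {
  d <- as.matrix(dist(cbind(pattern$x, pattern$y)))
  dimnames(d) <- NULL
  dnn <- if (pattern$n >= 2) {
    apply(d + diag(Inf, pattern$n), 1, min)
  } else {
    rep(Inf, pattern$n)
  }
  list(d = d,
       dnn = dnn,
       b = boundary_distance(pattern),
       e_translation = edge_weights_translation(pattern))
}
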