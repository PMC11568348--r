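# independent brute-force oracles and small fixture builders used across
# the suite; these deliberately use plain double loops, not the package's
# vectorized code paths

k_oracle <- function(pp, grid, e = NULL) {
  m <- pp$n
  area <- diff(pp$window$xrange) * diff(pp$window$yrange)
  out <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    acc <- 0
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        dij <- sqrt((pp$x[i] - pp$x[j])^2 + (pp$y[i] - pp$y[j])^2)
        if (dij <= grid[gi]) {
          acc <- acc + if (is.null(e)) 1 else e[i, j]
        }
      }
    }
    out[gi] <- area * acc / (m * (m - 1))
  }
  out
}

kcross_oracle <- function(pp, mark1, mark2, grid) {
  i1 <- which(pp$marks == mark1)
  i2 <- which(pp$marks == mark2)
  area <- diff(pp$window$xrange) * diff(pp$window$yrange)
  out <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    acc <- 0
    for (i in i1) {
      for (j in i2) {
        if (i == j) next
        dij <- sqrt((pp$x[i] - pp$x[j])^2 + (pp$y[i] - pp$y[j])^2)
        if (dij <= grid[gi]) acc <- acc + 1
      }
    }
    out[gi] <- area * acc / (length(i1) * length(i2))
  }
  out
}

g_oracle <- function(pp, grid) {
  m <- pp$n
  dnn <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in seq_len(m)) {
      if (i == j) next
      dij <- sqrt((pp$x[i] - pp$x[j])^2 + (pp$y[i] - pp$y[j])^2)
      if (dij < best) best <- dij
    }
    dnn[i] <- best
  }
  vapply(grid, function(r) mean(dnn <= r), numeric(1))
}

edge_weights_oracle <- function(pp) {
  a <- diff(pp$window$xrange); b <- diff(pp$window$yrange)
  m <- pp$n
  e <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      e[i, j] <- (a * b) /
        ((a - abs(pp$x[i] - pp$x[j])) * (b - abs(pp$y[i] - pp$y[j])))
    }
  }
  e
}

cos_sim <- function(a, b, w) {
  abs(sum(w * a * b)) / sqrt(sum(w * a^2) * sum(w * b^2))
}

toy_cells <- function() {
  tibble::tibble(
    sample_id = rep(c("A", "B"), each = 3),
    subject_id = rep(c("S1", "S2"), each = 3),
    x = c(0.2, 0.5, 0.8, 0.3, 0.6, 0.9),
    y = c(0.2, 0.6, 0.4, 0.7, 0.3, 0.5),
    phenotype = c("immune", "tumor", "immune", "immune", "immune", "tumor"))
}

toy_metadata <- function() {
  tibble::tibble(subject_id = c("S1", "S2"), age = c(60, 55),
                 time = c(3.2, 1.4), event = c(1L, 0L))
}

# curves with known two-component structure on [0, 1]
two_component_curves <- function(n = 200, seed = 42,
                                 grid = seq(0, 1, length.out = 101)) {
  set.seed(seed)
  phi1 <- sqrt(2) * sin(2 * pi * grid)
  phi2 <- sqrt(2) * cos(2 * pi * grid)
  xi1 <- rnorm(n, sd = 2)
  xi2 <- rnorm(n, sd = 1)
  Y <- outer(xi1, phi1) + outer(xi2, phi2)
  rownames(Y) <- sprintf("s%03d", seq_len(n))
  attr(Y, "grid") <- grid
  list(Y = Y, grid = grid, phi1 = phi1, phi2 = phi2, xi1 = xi1, xi2 = xi2)
}
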