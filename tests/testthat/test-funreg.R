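recovery_sim <- function(n = 500, seed = 1, beta = NULL, noise_sd = 0.25,
                         censoring = 0.15) {
  simulate_outcomes(
    n = n, seed = seed, beta = beta,
    phi1 = function(r) sqrt(2) * sin(pi * r),
    phi2 = function(r) sqrt(2) * sin(3 * pi * r),
    noise_sd = noise_sd, censoring = censoring)
}

test_that("the functional design block discretizes the integral correctly", {
  grid <- seq(0, 1, length.out = 41)
  X <- matrix(1, 5, 41)
  fd <- functional_design(X, grid, k_basis = 7)
  # constant curves: each row equals the integral of each basis function
  w <- spatialfda:::trapz_weights(grid)
  expect_equal(fd$design[1, ], colSums(w * fd$basis), ignore_attr = TRUE)
  expect_equal(fd$design[1, ], fd$design[5, ])
  # cubic B-splines are a partition of unity: the integrals sum to |range|
  expect_equal(sum(fd$design[1, ]), 1)
  expect_error(functional_design(X, grid, k_basis = 50))
  expect_error(functional_design(X, grid, k_basis = 3))
})

test_that("a basis-representable coefficient reproduces the fine-grid integral", {
  grid <- seq(0, 1, length.out = 101)
  set.seed(3)
  # smooth curves so both quadratures converge to the same integral
  X <- outer(rnorm(20), sin(2 * pi * grid)) +
    outer(rnorm(20), cos(pi * grid)) + outer(rnorm(20), grid^2)
  fd <- functional_design(X, grid, k_basis = 8)
  b <- rnorm(8)
  beta_grid <- as.numeric(fd$basis %*% b)
  # independent Riemann oracle on a 10x finer grid via linear interpolation
  fine <- seq(0, 1, length.out = 1001)
  beta_fine <- as.numeric(
    splines::splineDesign(fd$knots, fine, ord = 4) %*% b)
  oracle <- vapply(seq_len(20), function(i) {
    xi <- approx(grid, X[i, ], xout = fine)$y
    pracma::trapz(fine, xi * beta_fine)
  }, numeric(1))
  # agreement is limited by the coarse grid's own quadrature error
  expect_lt(max(abs(as.numeric(fd$design %*% b) - oracle)), 1e-3)
})

test_that("the curvature penalty is PSD with a linear null space", {
  grid <- seq(0, 2, length.out = 51)
  fd <- functional_design(matrix(0, 3, 51), grid, k_basis = 9)
  S <- fd$penalty
  expect_equal(S, t(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # coefficients reproducing constant and linear functions are unpenalized
  for (f in list(function(r) rep(1, length(r)), function(r) r)) {
    b <- qr.solve(fd$basis, f(grid))
    expect_lt(as.numeric(t(b) %*% S %*% b), 1e-6)
  }
})

test_that("degenerate constant curves reduce to a scalar Cox model", {
  skip_if_not_installed("survival")
  set.seed(7)
  n <- 300
  x <- rnorm(n)
  grid <- seq(0, 1, length.out = 51)
  curves <- tibble::tibble(
    sample_id = rep(sprintf("s%03d", seq_len(n)), each = 51),
    r = rep(grid, n), fundiff = rep(x, each = 51))
  tt <- rexp(n, rate = exp(0.8 * x))
  cens <- runif(n, 0, 2 * quantile(tt, 0.9))
  meta <- tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)),
                         time = pmin(tt, cens),
                         event = as.integer(tt <= cens))
  fc <- fit_functional_cox(curves, meta, k_basis = 8)
  # the functional term collapses to x * int beta(r) dr
  w <- spatialfda:::trapz_weights(grid)
  est <- sum(w * tidy(fc)$beta)
  ref <- unname(survival::coxph(
    survival::Surv(meta$time, meta$event) ~ x)$coefficients)
  expect_lt(abs(est - ref) / abs(ref), 0.02)
  # beta(r) itself is approximately constant in r
  expect_lt(diff(range(tidy(fc)$beta)) / abs(mean(tidy(fc)$beta)), 0.1)
})

test_that("the functional Cox model recovers a smooth coefficient", {
  so <- recovery_sim(seed = 21)
  fc <- fit_functional_cox(so$curves, so$metadata)
  td <- tidy(fc)
  beta_true <- sin(pi * td$r / max(td$r))
  w <- spatialfda:::trapz_weights(td$r)
  ise <- sum(w * (td$beta - beta_true)^2)
  expect_lt(ise, sum(w * beta_true^2) / 4)
  # sign is right wherever the signal is strong
  strong <- abs(beta_true) > max(beta_true) / 2
  expect_true(all(sign(td$beta[strong]) == sign(beta_true[strong])))
  # hazard-ratio bands are coherent
  expect_equal(td$hr, exp(td$beta))
  expect_true(all(td$ci_low < td$hr & td$hr < td$ci_high))
})

test_that("edf and roughness decrease as lambda grows", {
  so <- recovery_sim(n = 150, seed = 33)
  lams <- 10^seq(-2, 3, length.out = 6)
  edfs <- numeric(length(lams)); rough <- numeric(length(lams))
  for (i in seq_along(lams)) {
    fc <- fit_functional_cox(so$curves, so$metadata, lambda = lams[i])
    edfs[i] <- fc$edf
    d2 <- diff(diff(fc$beta))
    rough[i] <- sum(d2^2)
  }
  expect_true(all(diff(edfs) <= 1e-6))
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("an extreme penalty leaves an approximately linear coefficient", {
  so <- recovery_sim(n = 200, seed = 44)
  fc <- fit_functional_cox(so$curves, so$metadata, lambda = 1e8)
  b <- tidy(fc)$beta
  r <- tidy(fc)$r
  lin <- lm(b ~ r)
  expect_lt(max(abs(residuals(lin))), 1e-3 * max(abs(b) + 1e-12))
})

test_that("functional Cox fits are reproducible and validate inputs", {
  so <- recovery_sim(n = 100, seed = 55)
  f1 <- fit_functional_cox(so$curves, so$metadata)
  f2 <- fit_functional_cox(so$curves, so$metadata)
  expect_identical(tidy(f1), tidy(f2))
  meta0 <- so$metadata
  meta0$event <- 0L
  expect_error(fit_functional_cox(so$curves, meta0), class = "sfda_fit_error")
  meta2 <- so$metadata
  meta2$z1 <- rnorm(100)
  meta2$z2 <- 2 * meta2$z1
  expect_error(
    fit_functional_cox(so$curves, meta2, covariates = c("z1", "z2")),
    regexp = "z2", class = "sfda_fit_error")
  expect_warning(
    fit_functional_cox(so$curves[so$curves$sample_id %in%
                                   sprintf("subj%03d", 1:15), ],
                       so$metadata[1:15, ]),
    regexp = "unstable")
})

test_that("scalar covariates are estimated alongside the functional term", {
  so <- recovery_sim(n = 300, seed = 66, beta = function(r) rep(0, length(r)))
  meta <- so$metadata
  set.seed(1234)  # independent of the curve generator's stream
  meta$z <- rnorm(300)
  # inject a scalar effect by re-simulating times from z alone
  meta$time <- rexp(300, rate = exp(0.7 * meta$z))
  meta$event <- 1L
  fc <- fit_functional_cox(so$curves, meta, covariates = "z")
  expect_equal(fc$gamma$estimate[fc$gamma$term == "z"], 0.7,
               tolerance = 0.15)
})

test_that("scalar-on-function regression recovers beta with identity link", {
  grid <- seq(0, 1, length.out = 101)
  so <- recovery_sim(n = 300, seed = 77)
  # continuous outcome with small noise: y = eta + eps, eps sd 1 (generator)
  sf <- fit_sofr(so$curves, so$metadata, outcome = "y_continuous")
  td <- tidy(sf)
  beta_true <- sin(pi * td$r / max(td$r))
  w <- spatialfda:::trapz_weights(td$r)
  expect_lt(sum(w * (td$beta - beta_true)^2), sum(w * beta_true^2) / 4)
})

test_that("a constant outcome gives a flat zero coefficient", {
  so <- recovery_sim(n = 100, seed = 88)
  meta <- so$metadata
  meta$yconst <- 5
  sf <- fit_sofr(so$curves, meta, outcome = "yconst")
  expect_lt(max(abs(tidy(sf)$beta)), 1e-6)
})

test_that("logit-link null data keep the band around zero", {
  so <- recovery_sim(n = 300, seed = 99, beta = function(r) rep(0, length(r)))
  meta <- so$metadata
  set.seed(99)
  meta$yb <- rbinom(300, 1, 0.5)
  sf <- fit_sofr(so$curves, meta, outcome = "yb", link = "logit")
  td <- tidy(sf)
  expect_gte(mean(td$ci_low <= 0 & td$ci_high >= 0), 0.9)
})

test_that("significant ranges are maximal intervals excluding the null", {
  so <- recovery_sim(n = 120, seed = 111,
                     beta = function(r) rep(0, length(r)))
  fc <- fit_functional_cox(so$curves, so$metadata, lambda = 10)
  # hand-built bands: force significance on a known index range
  fc$ci_low <- rep(0.5, length(fc$grid))
  fc$ci_high <- rep(1.5, length(fc$grid))
  expect_equal(nrow(significant_range(fc)), 0)
  fc$ci_high[1:45] <- 0.9  # entirely below 1 on grid indices 1..45
  out <- significant_range(fc)
  expect_equal(nrow(out), 1)
  expect_equal(out$r_start, fc$grid[1])
  expect_equal(out$r_end, fc$grid[45])
  expect_equal(out$direction, "below")
})
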