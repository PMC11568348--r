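test_that("FPCA recovers two known orthonormal components", {
  tc <- two_component_curves(n = 200, seed = 42)
  fit <- fit_fpca(tc$Y, pve = 0.99)
  w <- spatialfda:::trapz_weights(tc$grid)
  expect_gte(cos_sim(fit$efuncs[, 1], tc$phi1, w), 0.95)
  expect_gte(cos_sim(fit$efuncs[, 2], tc$phi2, w), 0.95)
  ratio <- fit$evalues[1] / fit$evalues[2]
  expect_lt(abs(ratio - 4) / 4, 0.25)
  # scores track the generating coefficients (up to the fitted sign)
  expect_gt(abs(cor(fit$scores[, 1], tc$xi1)), 0.99)
})

test_that("a rank-1 construction is explained by one component", {
  grid <- seq(0, 1, length.out = 51)
  shape <- sin(pi * grid) + 0.5
  set.seed(2)
  Y <- outer(rnorm(30), shape)
  attr(Y, "grid") <- grid
  fit <- fit_fpca(Y, pve = 0.99)
  expect_equal(fit$npc, 1)
  expect_gte(fit$pve[1], 0.99)
})

test_that("degenerate inputs raise the documented errors", {
  grid <- seq(0, 1, length.out = 21)
  Y <- matrix(rep(sin(grid), 5), nrow = 5, byrow = TRUE)
  attr(Y, "grid") <- grid
  expect_error(fit_fpca(Y), regexp = "zero variance")
  expect_error(fit_fpca(Y[1:2, ]), regexp = "at least 3")
  # interior missing values are an error; end runs are trimmed
  Yna <- Y + matrix(rnorm(5 * 21, sd = 0.1), 5)
  Yna[2, 11] <- NA
  attr(Yna, "grid") <- grid
  expect_error(fit_fpca(Yna), class = "sfda_fpca_error")
  Yend <- Y + matrix(rnorm(5 * 21, sd = 0.1), 5)
  Yend[, 21] <- NA
  attr(Yend, "grid") <- grid
  fit <- fit_fpca(Yend)
  expect_length(fit$grid, 20)
})

test_that("orthonormality, centered scores and Parseval hold on random data", {
  for (s in 1:3) {
    set.seed(s)
    grid <- seq(0, 2, length.out = 41)
    Y <- matrix(rnorm(25 * 41), 25) + outer(rnorm(25), grid)
    attr(Y, "grid") <- grid
    fit <- fit_fpca(Y, pve = 1)
    w <- spatialfda:::trapz_weights(grid)
    G <- t(fit$efuncs) %*% (w * fit$efuncs)
    expect_lt(max(abs(G - diag(fit$npc))), 1e-6)
    expect_lt(max(abs(colMeans(fit$scores))), 1e-8)
    # Parseval: total eigenvalue mass = integrated pointwise variance
    vtot <- sum(w * apply(sweep(Y, 2, fit$mu), 2, var))
    expect_lt(abs(sum(fit$all_evalues) - vtot) / vtot, 0.05)
    # eigenvalues sorted and non-negative
    expect_true(all(diff(fit$all_evalues) <= 1e-12))
    expect_true(all(fit$all_evalues >= 0))
  }
})

test_that("FPCA is deterministic and scale-equivariant", {
  tc <- two_component_curves(n = 60, seed = 7)
  f1 <- fit_fpca(tc$Y)
  f2 <- fit_fpca(tc$Y)
  expect_identical(f1, f2)
  Y2 <- tc$Y * 3
  attr(Y2, "grid") <- tc$grid
  f3 <- fit_fpca(Y2)
  expect_equal(f3$evalues, 9 * f1$evalues, tolerance = 1e-8)
  expect_equal(abs(f3$efuncs[, 1]), abs(f1$efuncs[, 1]), tolerance = 1e-8)
})

test_that("component bands are mean +/- sd times the eigenfunction", {
  tc <- two_component_curves(n = 80, seed = 3)
  fit <- fit_fpca(tc$Y, npc = 2)
  b1 <- fpca_component_band(fit, 1)
  half <- sqrt(fit$evalues[1]) * fit$efuncs[, 1]
  expect_equal(b1$upper - b1$mean, half)
  expect_equal(b1$mean - b1$lower, half)
  expect_equal(b1$mean, fit$mu)
  expect_error(fpca_component_band(fit, 3))
  # zero-variance component collapses the band onto the mean
  fit0 <- fit
  fit0$evalues[2] <- 0
  b2 <- fpca_component_band(fit0, 2)
  expect_equal(b2$lower, b2$upper)
})

test_that("reconstruction error is non-increasing in the component count", {
  tc <- two_component_curves(n = 100, seed = 12)
  fit <- fit_fpca(tc$Y, npc = 2)
  ids <- rownames(tc$Y)
  mise <- function(k) {
    mean(vapply(ids, function(id) {
      rec <- reconstruct(fit, id, k)$value
      mean((tc$Y[id, ] - rec)^2)
    }, numeric(1)))
  }
  m0 <- mise(0); m1 <- mise(1); m2 <- mise(2)
  expect_lt(m1, m0)
  expect_lt(m2, m1)
  expect_equal(reconstruct(fit, ids[1], 0)$value, fit$mu)
  expect_error(reconstruct(fit, ids[1], 5))
  expect_error(reconstruct(fit, "nope", 1), class = "sfda_key_error")
})

test_that("multilevel FPCA separates between- and within-subject variation", {
  set.seed(11)
  grid <- seq(0, 1, length.out = 51)
  phiA <- sqrt(2) * sin(2 * pi * grid)
  phiB <- sqrt(2) * cos(2 * pi * grid)
  rows <- list(); maps <- list()
  for (i in 1:100) {
    bi <- rnorm(1, sd = 2)
    for (s in 1:3) {
      sid <- sprintf("p%03d_s%d", i, s)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sid, r = grid,
        fundiff = bi * phiA + rnorm(1) * phiB)
      maps[[length(maps) + 1]] <- tibble::tibble(
        sample_id = sid, subject_id = sprintf("p%03d", i))
    }
  }
  mf <- fit_mfpca(dplyr::bind_rows(rows), dplyr::bind_rows(maps))
  expect_lt(abs(mf$rho - 0.8), 0.1)
  w <- spatialfda:::trapz_weights(grid)
  expect_gte(cos_sim(mf$between$efuncs[, 1], phiA, w), 0.9)
  expect_gte(cos_sim(mf$within$efuncs[, 1], phiB, w), 0.9)
  expect_true(mf$rho >= 0 && mf$rho <= 1)
})

test_that("multilevel FPCA limit cases behave as documented", {
  grid <- seq(0, 1, length.out = 21)
  phiA <- sqrt(2) * sin(2 * pi * grid)
  set.seed(5)
  rows <- list(); maps <- list()
  for (i in 1:10) {
    bi <- rnorm(1, sd = 2)
    for (s in 1:2) {
      sid <- sprintf("q%02d_s%d", i, s)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sid, r = grid, fundiff = bi * phiA)
      maps[[length(maps) + 1]] <- tibble::tibble(
        sample_id = sid, subject_id = sprintf("q%02d", i))
    }
  }
  mf <- fit_mfpca(dplyr::bind_rows(rows), dplyr::bind_rows(maps))
  expect_gte(mf$rho, 0.99)  # no within-subject noise
  # one sample per subject cannot be decomposed
  one <- dplyr::bind_rows(rows)[rep(seq_len(21), 10) +
                                  rep(seq(0, 9) * 42, each = 21), ]
  map1 <- dplyr::bind_rows(maps) |>
    dplyr::filter(grepl("_s1$", sample_id))
  expect_error(
    fit_mfpca(dplyr::filter(dplyr::bind_rows(rows),
                            grepl("_s1$", sample_id)), map1),
    class = "sfda_mfpca_error")
})
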