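test_that("two-point patterns reproduce the estimators' closed forms", {
  pp <- point_pattern(c(0.25, 0.75), c(0.5, 0.5), window = owin_rect())
  grid <- c(0.1, 0.4999, 0.5, 0.9)
  k <- estimate_K(pp, grid = grid, correction = "none")$K
  expect_equal(k, c(0, 0, 1, 1))  # |A|/(2*1) * 2 pairs once d <= r
  g <- estimate_G(pp, grid = grid, correction = "none")$G
  expect_equal(g, c(0, 0, 1, 1))
  l <- estimate_L(pp, grid = grid, correction = "none")$L
  expect_equal(l, sqrt(k / pi))
})

test_that("cross-type estimators satisfy plug-in values and symmetry", {
  pp <- point_pattern(c(0.25, 0.75), c(0.5, 0.5),
                      marks = c("m1", "m2"), window = owin_rect())
  grid <- c(0.1, 0.5, 0.9)
  k12 <- estimate_K_cross(pp, "m1", "m2", grid, correction = "none")$K12
  expect_equal(k12, c(0, 1, 1))
  k21 <- estimate_K_cross(pp, "m2", "m1", grid, correction = "none")$K12
  expect_equal(k12, k21)
  g12 <- estimate_G_cross(pp, "m1", "m2", grid, correction = "none")$G12
  expect_equal(g12, c(0, 1, 1))
})

test_that("vectorized estimators equal double-loop oracles exactly", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    pp <- point_pattern(runif(n), runif(n),
                        marks = sample(c("a", "b"), n, replace = TRUE),
                        window = owin_rect())
    grid <- seq(0, 0.3, length.out = 16)
    expect_equal(estimate_K(pp, grid = grid, correction = "none")$K,
                 k_oracle(pp, grid))
    expect_equal(estimate_G(pp, grid = grid, correction = "none")$G,
                 g_oracle(pp, grid))
    if (sum(pp$marks == "a") >= 1 && sum(pp$marks == "b") >= 1) {
      expect_equal(
        estimate_K_cross(pp, "a", "b", grid, correction = "none")$K12,
        kcross_oracle(pp, "a", "b", grid))
    }
    # translation-corrected K equals the loop oracle with explicit weights
    e <- edge_weights_oracle(pp)
    expect_equal(estimate_K(pp, grid = grid, correction = "translation")$K,
                 k_oracle(pp, grid, e = e))
  }
})

test_that("estimator output is invariant to the order of input points", {
  set.seed(77)
  n <- 40
  x <- runif(n); y <- runif(n)
  marks <- sample(c("a", "b"), n, replace = TRUE)
  grid <- seq(0, 0.25, length.out = 11)
  perm <- sample.int(n)
  pp1 <- point_pattern(x, y, marks, window = owin_rect())
  pp2 <- point_pattern(x[perm], y[perm], marks[perm], window = owin_rect())
  expect_equal(estimate_K(pp1, "a", grid, "translation"),
               estimate_K(pp2, "a", grid, "translation"))
  expect_equal(estimate_G(pp1, "a", grid, "border"),
               estimate_G(pp2, "a", grid, "border"))
})

test_that("K is non-decreasing and G stays within [0, 1]", {
  set.seed(13)
  for (rep in 1:5) {
    pp <- point_pattern(runif(60), runif(60), window = owin_rect())
    grid <- seq(0, 0.25, length.out = 30)
    k <- estimate_K(pp, grid = grid, correction = "translation")$K
    expect_true(all(diff(k) >= -1e-12))
    g <- estimate_G(pp, grid = grid, correction = "none")$G
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(diff(g) >= 0))
  }
})

test_that("G saturates at 1 beyond the largest nearest-neighbor distance", {
  set.seed(21)
  pp <- point_pattern(runif(30), runif(30), window = owin_rect())
  dnn_max <- max(pairwise_geometry(pp)$dnn)
  g <- estimate_G(pp, grid = c(dnn_max, dnn_max * 1.5), correction = "none")$G
  expect_equal(g, c(1, 1))
})

test_that("border-corrected G is undefined where no points are retained", {
  pp <- point_pattern(c(0.5, 0.52), c(0.5, 0.5), window = owin_rect())
  g <- estimate_G(pp, grid = c(0.1, 0.6), correction = "border")$G
  expect_false(is.na(g[1]))
  expect_true(is.na(g[2]))  # r = 0.6 exceeds every boundary distance
})

test_that("small samples are flagged as insufficient, not computed", {
  pp <- point_pattern(0.5, 0.5, window = owin_rect())
  expect_error(estimate_K(pp, grid = c(0, 0.1)),
               class = "sfda_insufficient_cells")
  expect_error(estimate_G(pp, grid = c(0, 0.1)),
               class = "sfda_insufficient_cells")
})

test_that("theoretical CSR forms evaluate correctly", {
  expect_equal(csr_theoretical("K", c(0, 1)), c(0, pi))
  expect_equal(csr_theoretical("L", c(0, 2)), c(0, 2))
  expect_equal(csr_theoretical("G", c(0, 0.05), lambda = 100),
               c(0, 1 - exp(-100 * pi * 0.0025)))
  # independent evaluation of the closed form at r = 0.05
  expect_equal(csr_theoretical("G", 0.05, lambda = 100), 0.5441, tolerance = 1e-4)
  expect_error(csr_theoretical("X", c(0, 1)), class = "sfda_metric_error")
  expect_error(csr_theoretical("G", c(0, 1)))
})

test_that("L is the variance-stabilized K elementwise", {
  set.seed(4)
  pp <- point_pattern(runif(40), runif(40), window = owin_rect())
  grid <- seq(0, 0.25, length.out = 12)
  k <- estimate_K(pp, grid = grid, correction = "translation")$K
  l <- estimate_L(pp, grid = grid, correction = "translation")$L
  expect_equal(l^2 * pi, k)
})

test_that("permutation baseline is deterministic and reduces to identity", {
  set.seed(55)
  pp <- point_pattern(runif(30), runif(30),
                      marks = rep("only", 30), window = owin_rect())
  grid <- seq(0, 0.2, length.out = 9)
  obs <- estimate_G(pp, "only", grid, correction = "none")$G
  # all cells carry the target mark: any permutation leaves marks unchanged
  perm <- csr_permuted(pp, "only", "G", grid, n_perm = 7, seed = 1,
                       correction = "none")
  expect_equal(perm$csr_permuted, obs)
  # identical seeds give bit-identical output
  pp2 <- point_pattern(pp$x, pp$y,
                       marks = sample(c("a", "b"), 30, replace = TRUE),
                       window = pp$window)
  p1 <- csr_permuted(pp2, "a", "G", grid, n_perm = 19, seed = 99)
  p2 <- csr_permuted(pp2, "a", "G", grid, n_perm = 19, seed = 99)
  expect_identical(p1, p2)
})

test_that("a single seeded permutation equals its direct replay", {
  set.seed(8)
  pp <- point_pattern(runif(25), runif(25),
                      marks = sample(c("a", "b"), 25, replace = TRUE),
                      window = owin_rect())
  grid <- seq(0, 0.2, length.out = 8)
  p1 <- csr_permuted(pp, "a", "G", grid, n_perm = 1, seed = 123,
                     correction = "none")
  # replay: same RNG stream produces the same label shuffle
  set.seed(123)
  idx <- sample.int(pp$n)
  pp_perm <- point_pattern(pp$x, pp$y, marks = pp$marks[idx],
                           window = pp$window)
  expect_equal(p1$csr_permuted,
               estimate_G(pp_perm, "a", grid, correction = "none")$G)
})

test_that("permutation envelopes bracket the permutation mean", {
  set.seed(14)
  pp <- point_pattern(runif(40), runif(40),
                      marks = sample(c("a", "b"), 40, replace = TRUE),
                      window = owin_rect())
  grid <- seq(0.02, 0.2, length.out = 6)
  p <- csr_permuted(pp, "a", "G", grid, n_perm = 25, seed = 3,
                    correction = "none", envelope_probs = c(0.05, 0.95))
  expect_true(all(p$env_lo <= p$csr_permuted + 1e-12))
  expect_true(all(p$env_hi >= p$csr_permuted - 1e-12))
})
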