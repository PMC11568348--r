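#' Point process and outcome simulators
#'
#' Seed-deterministic generators with known ground truth, so every pipeline
#' stage can be validated offline against closed forms: a homogeneous
#' Poisson process (complete spatial randomness), a Thomas cluster process
#' (clustered alternative, with closed-form K function
#' \eqn{\pi r^2 + (1/\kappa)(1 - e^{-r^2/(4\sigma^2)})}), and outcome data
#' whose hazard depends on a functional covariate through a known
#' \eqn{\beta(r)}.
#'
#' @name simulators
NULL

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @rdname simulators
#' @param lambda Intensity, points per unit area.
#' @param window An [owin_rect()] observation window.
#' @param mark_probs Optional named probability vector; marks are assigned
#'   iid across points.
#' @param seed Optional integer seed (identical seeds give identical output).
#' @return A [point_pattern()].
#' @examples
#' pp <- simulate_poisson(100, seed = 1)
#' @export
simulate_poisson <- function(lambda, window = owin_rect(), mark_probs = NULL,
                             seed = NULL) {
  stopifnot(lambda > 0)
  with_seed(seed, {
    n <- rpois(1, lambda * window_area(window))
    x <- runif(n, window$xrange[1], window$xrange[2])
    y <- runif(n, window$yrange[1], window$yrange[2])
    marks <- assign_marks(n, mark_probs)
    point_pattern(x, y, marks = marks, window = window)
  })
}

assign_marks <- function(n, mark_probs) {
  if (is.null(mark_probs)) return(NULL)
  stopifnot(!is.null(names(mark_probs)), all(mark_probs >= 0))
  factor(sample(names(mark_probs), n, replace = TRUE, prob = mark_probs),
         levels = names(mark_probs))
}

#' @rdname simulators
#' @param kappa Parent intensity (parents per unit area).
#' @param mu_off Mean offspring per parent.
#' @param sigma Isotropic Gaussian offspring dispersion.
#' @export
simulate_thomas <- function(kappa, mu_off, sigma, window = owin_rect(),
                            mark_probs = NULL, seed = NULL) {
  stopifnot(kappa > 0, mu_off > 0, sigma > 0)
  with_seed(seed, {
    # parents live in a guard band of 4 sigma so clusters straddling the
    # boundary are represented without bias
    gx <- window$xrange + c(-4, 4) * sigma
    gy <- window$yrange + c(-4, 4) * sigma
    n_par <- rpois(1, kappa * diff(gx) * diff(gy))
    px <- runif(n_par, gx[1], gx[2])
    py <- runif(n_par, gy[1], gy[2])
    n_off <- rpois(n_par, mu_off)
    x <- rep(px, n_off) + rnorm(sum(n_off), sd = sigma)
    y <- rep(py, n_off) + rnorm(sum(n_off), sd = sigma)
    keep <- x >= window$xrange[1] & x <= window$xrange[2] &
      y >= window$yrange[1] & y <= window$yrange[2]
    x <- x[keep]; y <- y[keep]
    marks <- assign_marks(length(x), mark_probs)
    point_pattern(x, y, marks = marks, window = window)
  })
}

#' Theoretical K function of the Thomas process
#'
#' @param r Radii.
#' @param kappa Parent intensity.
#' @param sigma Offspring dispersion.
#' @return \eqn{\pi r^2 + (1/\kappa)(1 - \exp(-r^2/(4\sigma^2)))}.
#' @export
thomas_K <- function(r, kappa, sigma) {
  pi * r^2 + (1 / kappa) * (1 - exp(-r^2 / (4 * sigma^2)))
}

#' Simulate outcome data with a functional covariate effect
#'
#' Generates per-subject curves from a two-component FPCA-type model,
#' \eqn{X_i(r) = \mu(r) + \xi_{i1}\phi_1(r) + \xi_{i2}\phi_2(r) +
#' \varepsilon_i(r)}, and outcomes driven by the linear predictor
#' \eqn{\eta_i = \int X_i(r)\beta(r)\,dr} (trapezoidal quadrature):
#' survival times by inverse transform under an exponential or Weibull
#' baseline hazard with independent uniform censoring calibrated to a target
#' censoring fraction, plus continuous (\eqn{Y = \eta + \epsilon}) and
#' binary (\eqn{Y \sim \mathrm{Bernoulli(logit^{-1}\eta)}}) outcomes.
#'
#' @param n Number of subjects.
#' @param grid Radius grid for the curves (default 101 points on \[0, 1\]).
#' @param beta True coefficient function: a function of `r`, or a numeric
#'   vector on `grid`. Default \eqn{\sin(\pi r / r_{max})}.
#' @param mu Mean curve (function or vector; default 0).
#' @param phi1,phi2 Component shapes (functions or vectors; defaults
#'   \eqn{\sqrt2\sin(2\pi r/r_{max})}, \eqn{\sqrt2\cos(2\pi r/r_{max})},
#'   orthonormal on the grid).
#' @param score_sd Standard deviations of the two component scores
#'   (default `c(2, 1)`, i.e. variances 4 and 1).
#' @param noise_sd Pointwise white-noise level added to curves (default 0).
#' @param baseline_rate Exponential baseline hazard rate (default 1).
#' @param weibull_shape Weibull shape; 1 (default) gives the exponential.
#' @param censoring Target censoring fraction via independent
#'   `Uniform(0, c)` censoring, with `c` calibrated on the simulated times
#'   (default 0.3; 0 disables censoring).
#' @param seed Optional integer seed.
#' @return A list: `curves` (long tibble `sample_id`, `r`, `fundiff`),
#'   `metadata` (tibble `subject_id`, `time`, `event`, `y_continuous`,
#'   `y_binary`, true `eta`), and `spec` (the generating settings, JSON-able,
#'   including the calibrated censoring bound and true beta values).
#' @export
simulate_outcomes <- function(n, grid = seq(0, 1, length.out = 101),
                              beta = NULL, mu = NULL, phi1 = NULL,
                              phi2 = NULL, score_sd = c(2, 1),
                              noise_sd = 0, baseline_rate = 1,
                              weibull_shape = 1, censoring = 0.3,
                              seed = NULL) {
  grid <- check_grid(grid)
  r_max <- max(grid)
  as_curve <- function(f, default) {
    f <- f %||% default
    if (is.function(f)) f(grid) else {
      stopifnot(length(f) == length(grid)); as.numeric(f)
    }
  }
  beta_v <- as_curve(beta, function(r) sin(pi * r / r_max))
  mu_v <- as_curve(mu, function(r) rep(0, length(r)))
  phi1_v <- as_curve(phi1, function(r) sqrt(2) * sin(2 * pi * r / r_max))
  phi2_v <- as_curve(phi2, function(r) sqrt(2) * cos(2 * pi * r / r_max))

  with_seed(seed, {
    xi1 <- rnorm(n, sd = score_sd[1])
    xi2 <- rnorm(n, sd = score_sd[2])
    X <- outer(rep(1, n), mu_v) + outer(xi1, phi1_v) + outer(xi2, phi2_v)
    if (noise_sd > 0) X <- X + matrix(rnorm(n * length(grid), sd = noise_sd),
                                      n, length(grid))
    w <- trapz_weights(grid)
    eta <- as.numeric(X %*% (w * beta_v))

    u <- runif(n)
    t_raw <- (-log(u) / (baseline_rate * exp(eta)))^(1 / weibull_shape)
    if (censoring > 0) {
      # expected censored fraction under C ~ Uniform(0, cc) is
      # mean(min(T_i/cc, 1)), decreasing in cc; calibrate cc to the target
      cens_frac <- function(cc) mean(pmin(t_raw / cc, 1))
      cc <- stats::uniroot(function(cc) cens_frac(cc) - censoring,
                           interval = c(max(min(t_raw), 1e-12) * 1e-3,
                                        max(t_raw) * 100),
                           extendInt = "downX")$root
      cens <- runif(n, 0, cc)
      time <- pmin(t_raw, cens)
      event <- as.integer(t_raw <= cens)
    } else {
      cc <- NA_real_
      time <- t_raw
      event <- rep(1L, n)
    }

    y_cont <- eta + rnorm(n)
    y_bin <- rbinom(n, 1, 1 / (1 + exp(-eta)))

    ids <- sprintf("subj%03d", seq_len(n))
    curves <- tibble::tibble(
      sample_id = rep(ids, each = length(grid)),
      r = rep(grid, n),
      fundiff = as.vector(t(X)))
    metadata <- tibble::tibble(
      subject_id = ids, time = time, event = event,
      y_continuous = y_cont, y_binary = y_bin, eta = eta)
    spec <- list(n = n, grid = grid, beta = beta_v, score_sd = score_sd,
                 noise_sd = noise_sd, baseline_rate = baseline_rate,
                 weibull_shape = weibull_shape,
                 censoring_target = censoring, censoring_bound = cc,
                 seed = seed)
    list(curves = curves, metadata = metadata, spec = spec)
  })
}

#' Simulate a whole multi-sample study
#'
#' Builds a cell-level table plus subject metadata emulating a multiplex
#' imaging cohort: each sample is a Poisson (CSR) or Thomas (clustered)
#' pattern of `"immune"` and `"other"` cells, and each subject carries a
#' survival outcome. Useful for end-to-end pipeline tests.
#'
#' @param n_subjects Number of subjects.
#' @param samples_per_subject Samples (images) per subject (default 1).
#' @param window Observation window shared by all samples (default the unit
#'   square; use microns-scaled windows to mimic real tissue).
#' @param lambda Total cell intensity per sample.
#' @param p_immune Probability a cell is phenotyped immune (default 0.3).
#' @param clustered Fraction of subjects whose immune cells come from a
#'   Thomas process instead of CSR (default 0.5).
#' @param kappa,mu_off,sigma Thomas parameters for the clustered subjects.
#' @param seed Optional integer seed.
#' @return List with `cells`, `metadata` tibbles ready for [make_study()],
#'   and `spec`.
#' @export
simulate_study <- function(n_subjects = 20, samples_per_subject = 1,
                           window = owin_rect(), lambda = 200,
                           p_immune = 0.3, clustered = 0.5,
                           kappa = 20, mu_off = NULL, sigma = 0.03,
                           seed = NULL) {
  with_seed(seed, {
    n_immune_mean <- lambda * p_immune * window_area(window)
    mu_off <- mu_off %||% (n_immune_mean / (kappa * window_area(window)))
    is_clustered <- runif(n_subjects) < clustered
    cells <- list()
    for (i in seq_len(n_subjects)) {
      for (s in seq_len(samples_per_subject)) {
        other <- simulate_poisson(lambda * (1 - p_immune), window)
        immune <- if (is_clustered[i]) {
          simulate_thomas(kappa, mu_off, sigma, window)
        } else {
          simulate_poisson(lambda * p_immune, window)
        }
        cells[[length(cells) + 1]] <- tibble::tibble(
          sample_id = sprintf("subj%03d_s%d", i, s),
          subject_id = sprintf("subj%03d", i),
          x = c(other$x, immune$x), y = c(other$y, immune$y),
          phenotype = rep(c("other", "immune"), c(other$n, immune$n)))
      }
    }
    cells <- dplyr::bind_rows(cells)
    t_raw <- rexp(n_subjects, rate = ifelse(is_clustered, 0.5, 1))
    cens <- runif(n_subjects, 0, 2 * stats::quantile(t_raw, 0.9))
    metadata <- tibble::tibble(
      subject_id = sprintf("subj%03d", seq_len(n_subjects)),
      clustered = is_clustered,
      age = round(runif(n_subjects, 40, 85)),
      time = pmin(t_raw, cens),
      event = as.integer(t_raw <= cens))
    list(cells = cells, metadata = metadata,
         spec = list(n_subjects = n_subjects,
                     samples_per_subject = samples_per_subject,
                     lambda = lambda, p_immune = p_immune,
                     clustered = clustered, kappa = kappa, mu_off = mu_off,
                     sigma = sigma, seed = seed))
  })
}
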