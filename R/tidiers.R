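#' Tidy a summary function set
#'
#' @param x A `summary_set`.
#' @param ... Unused.
#' @return The long curve tibble with the extraction settings as columns.
#' @method tidy summary_set
#' @export
tidy.summary_set <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(metric = attr(x, "metric"), variate = attr(x, "variate"),
                  marks = paste(attr(x, "marks"), collapse = ":"))
}

#' @rdname tidy.summary_set
#' @method glance summary_set
#' @export
glance.summary_set <- function(x, ...) {
  tibble::tibble(
    metric = attr(x, "metric"), variate = attr(x, "variate"),
    marks = paste(attr(x, "marks"), collapse = ":"),
    correction = attr(x, "correction"), baseline = attr(x, "baseline"),
    n_samples = dplyr::n_distinct(x$sample_id),
    n_r = length(attr(x, "grid")),
    n_excluded = nrow(attr(x, "exclusions")))
}

#' Tidy an FPCA fit
#'
#' @param x An `sfda_fpca`.
#' @param what `"eigenfunctions"` (default; long tibble of `r`, `component`,
#'   `value`, with the mean as component `"mean"`) or `"scores"` (one row per
#'   sample).
#' @param ... Unused.
#' @method tidy sfda_fpca
#' @export
tidy.sfda_fpca <- function(x, what = c("eigenfunctions", "scores"), ...) {
  what <- match.arg(what)
  if (what == "scores") {
    return(dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(x$scores)),
      tibble::as_tibble(x$scores)))
  }
  ef <- tibble::as_tibble(x$efuncs) |>
    dplyr::mutate(r = x$grid) |>
    tidyr::pivot_longer(-"r", names_to = "component", values_to = "value")
  dplyr::bind_rows(
    tibble::tibble(r = x$grid, component = "mean", value = x$mu), ef)
}

#' @rdname tidy.sfda_fpca
#' @method glance sfda_fpca
#' @export
glance.sfda_fpca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores), npc = x$npc,
    pve = x$pve[x$npc], total_variance = x$total_variance,
    lambda_1 = x$evalues[1],
    pve_1 = x$evalues[1] / x$total_variance,
    pve_2 = if (x$npc >= 2) x$evalues[2] / x$total_variance else NA_real_)
}

#' @rdname tidy.sfda_fpca
#' @method glance sfda_mfpca
#' @export
glance.sfda_mfpca <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subject_scores), n_samples = nrow(x$sample_scores),
    rho = x$rho, npc_between = x$between$npc, npc_within = x$within$npc)
}

#' Tidy a functional Cox fit
#'
#' @param x An `sfda_fcox`.
#' @param ... Unused.
#' @return One row per radius: `r`, `beta`, `se`, `hr`, `ci_low`, `ci_high`.
#' @method tidy sfda_fcox
#' @export
tidy.sfda_fcox <- function(x, ...) {
  tibble::tibble(r = x$grid, beta = x$beta, se = x$se, hr = x$hr,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @rdname tidy.sfda_fcox
#' @method glance sfda_fcox
#' @export
glance.sfda_fcox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, k_basis = x$k_basis,
                 lambda = x$lambda, edf = x$edf, loglik = x$loglik,
                 aic = x$aic)
}

#' Tidy a scalar-on-function fit
#'
#' @param x An `sfda_sofr`.
#' @param ... Unused.
#' @return One row per radius: `r`, `beta`, `se`, `ci_low`, `ci_high`.
#' @method tidy sfda_sofr
#' @export
tidy.sfda_sofr <- function(x, ...) {
  tibble::tibble(r = x$grid, beta = x$beta, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @rdname tidy.sfda_sofr
#' @method glance sfda_sofr
#' @export
glance.sfda_sofr <- function(x, ...) {
  tibble::tibble(n = x$n, link = x$link, k_basis = x$k_basis,
                 lambda = x$lambda, edf = x$edf, dispersion = x$dispersion)
}
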