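#' Construct a summary function set from a curve table
#'
#' A `summary_set` is a tibble in long format — columns `sample_id`, `r`,
#' `observed`, `csr_theoretical`, `csr_permuted`, `fundiff` — carrying the
#' extraction settings as attributes. All samples share one strictly
#' increasing radius grid. `fundiff`, the degree of clustering, is
#' `observed - baseline` (permutation baseline when computed, theoretical
#' otherwise), so positive values mean clustering beyond chance.
#'
#' @param df Data frame with at least `sample_id`, `r`, `observed`.
#' @param metric Metric name (`"K"`, `"L"`, `"G"`, or a plugin name).
#' @param variate `"univariate"` or `"bivariate"`.
#' @param marks Mark label (univariate) or ordered label pair (bivariate).
#' @param correction,baseline,n_perm,seed Extraction settings (metadata).
#' @param exclusions Tibble of excluded samples (`sample_id`, `reason`).
#' @return A `summary_set` tibble.
#' @export
as_summary_set <- function(df, metric, variate = c("univariate", "bivariate"),
                           marks, correction = "none",
                           baseline = "theoretical", n_perm = NA_integer_,
                           seed = NA_integer_, exclusions = NULL) {
  variate <- match.arg(variate)
  df <- tibble::as_tibble(df)
  need <- c("sample_id", "r", "observed")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("curve table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "sfda_schema_error")
  }
  if (!"csr_theoretical" %in% names(df)) df$csr_theoretical <- NA_real_
  if (!"csr_permuted" %in% names(df)) df$csr_permuted <- NA_real_
  base_col <- if (identical(baseline, "permutation")) "csr_permuted" else "csr_theoretical"
  if (!"fundiff" %in% names(df)) df$fundiff <- df$observed - df[[base_col]]
  grid <- sort(unique(df$r))
  check_grid(grid)
  by_sample <- split(df$r, df$sample_id)
  if (!all(vapply(by_sample, function(r) identical(as.numeric(r), grid),
                  logical(1)))) {
    abort("all samples must share one radius grid", class = "sfda_grid_error")
  }
  structure(
    df[c("sample_id", "r", "observed", "csr_theoretical", "csr_permuted",
         "fundiff", intersect(names(df), c("env_lo", "env_hi")))],
    metric = metric, variate = variate, marks = marks,
    correction = correction, baseline = baseline,
    n_perm = n_perm, seed = seed, grid = grid,
    exclusions = exclusions %||%
      tibble::tibble(sample_id = character(0), reason = character(0)),
    class = c("summary_set", class(tibble::tibble())))
}

#' @export
print.summary_set <- function(x, ...) {
  cat(sprintf(
    "summary set: metric %s (%s, marks %s), %d sample(s), %d radii, correction %s, baseline %s\n",
    attr(x, "metric"), attr(x, "variate"),
    paste(attr(x, "marks"), collapse = " vs "),
    dplyr::n_distinct(x$sample_id), length(attr(x, "grid")),
    attr(x, "correction"), attr(x, "baseline")))
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    cat(sprintf("  excluded samples: %s\n",
                paste(excl$sample_id, collapse = ", ")))
  }
  NextMethod()
}

# single-sample pattern from the study's cell table; marks collapse the
# phenotype indicators of interest to one label per cell ("other" elsewhere)
sample_pattern <- function(cells, phenos, marks) {
  lab <- rep("other", nrow(cells))
  for (m in rev(marks)) {  # first mark wins on overlap
    col <- if (m %in% names(cells)) m else paste0("phenotype_", m)
    if (!col %in% names(cells)) {
      abort(sprintf("unknown phenotype '%s'", m), class = "sfda_schema_error")
    }
    lab[cells[[col]] %in% TRUE] <- m
  }
  point_pattern(cells$x, cells$y,
                marks = factor(lab, levels = unique(c(marks, "other"))))
}

#' Extract spatial summary functions for every sample in a study
#'
#' Runs the chosen estimator over each sample's point pattern on one shared
#' radius grid, together with its complete-spatial-randomness baseline:
#' either the closed-form Poisson expression (`baseline = "theoretical"`) or
#' the mean over random relabelings of the cells' phenotypes
#' (`baseline = "permutation"`, robust to tissue holes). Samples with fewer
#' than `min_cells` cells of a required mark are excluded and reported, not
#' errors.
#'
#' @param study A `spatial_study` from [make_study()].
#' @param metric `"K"`, `"L"`, `"G"`, or a registered plugin name.
#' @param variate `"univariate"` or `"bivariate"`.
#' @param marks Phenotype label (univariate) or ordered pair
#'   `c(from, to)` (bivariate). Labels are the phenotype column names without
#'   the `phenotype_` prefix.
#' @param grid Shared radius grid; default `n_r` points from 0 to a quarter
#'   of the shortest window side across eligible samples.
#' @param n_r Grid length when `grid` is `NULL` (default 100).
#' @param correction Edge correction (default: translation for K/L, border
#'   for G, none for plugins).
#' @param baseline `"theoretical"` or `"permutation"`.
#' @param n_perm Label permutations per sample for the permutation baseline.
#' @param min_cells Minimum cells per required mark for a sample to be
#'   eligible (default 2).
#' @param seed Integer seed driving the permutation baseline.
#' @param envelope_probs Optional length-2 probabilities for permutation
#'   envelopes (extra `env_lo`/`env_hi` columns).
#' @return A [as_summary_set()] tibble; excluded samples are recorded in the
#'   `exclusions` attribute.
#' @examples
#' study <- make_study(
#'   data.frame(sample_id = rep("A", 30), subject_id = "S1",
#'              x = runif(30), y = runif(30),
#'              phenotype = rep(c("immune", "tumor"), 15)),
#'   data.frame(subject_id = "S1"))
#' extract_summary_functions(study, metric = "G", marks = "immune",
#'                           n_r = 20)
#' @export
extract_summary_functions <- function(study, metric = "G",
                                      variate = c("univariate", "bivariate"),
                                      marks, grid = NULL, n_r = 100,
                                      correction = default_correction(metric),
                                      baseline = c("theoretical", "permutation"),
                                      n_perm = 100, min_cells = 2,
                                      seed = NULL, envelope_probs = NULL) {
  stopifnot(inherits(study, "spatial_study"))
  variate <- match.arg(variate)
  baseline <- match.arg(baseline)
  if (length(marks) != if (variate == "univariate") 1L else 2L) {
    abort("`marks` must have length 1 (univariate) or 2 (bivariate)")
  }
  builtin <- metric %in% c("K", "L", "G")
  if (!builtin) get_summary_plugin(metric)  # fail early on unknown metric
  if (!builtin && baseline == "theoretical") {
    abort(sprintf(
      "no theoretical CSR form for plugin metric '%s'; use baseline = \"permutation\"",
      metric), class = "sfda_metric_error")
  }

  samples <- split(study$cells, study$cells$sample_id)
  patterns <- purrr::map(samples, sample_pattern,
                         phenos = study$phenotypes, marks = marks)

  exclusions <- tibble::tibble(sample_id = character(0), reason = character(0))
  exclude <- function(id, reason) {
    exclusions <<- dplyr::bind_rows(
      exclusions, tibble::tibble(sample_id = id, reason = reason))
  }
  eligible <- character(0)
  for (id in names(patterns)) {
    counts <- table(patterns[[id]]$marks)[marks]
    counts[is.na(counts)] <- 0
    if (any(counts < max(min_cells, if (variate == "univariate") 2 else 1))) {
      exclude(id, sprintf("fewer than %d cells of mark(s) %s",
                          max(min_cells, 2),
                          paste(marks[counts < max(min_cells, 2)],
                                collapse = ", ")))
    } else {
      eligible <- c(eligible, id)
    }
  }
  if (!length(eligible)) {
    abort(sprintf("no eligible samples (min_cells = %d)", min_cells),
          class = "sfda_no_samples_error")
  }

  if (is.null(grid)) {
    short <- min(vapply(patterns[eligible], function(p) {
      w <- p$window
      min(diff(w$xrange), diff(w$yrange))
    }, numeric(1)))
    grid <- seq(0, short / 4, length.out = n_r)
  }
  grid <- check_grid(grid)

  rows <- vector("list", length(eligible))
  names(rows) <- eligible
  for (k in seq_along(eligible)) {
    id <- eligible[k]
    pp <- patterns[[id]]
    row <- tryCatch({
      obs <- metric_curve(metric, pp, marks, grid, correction)
      theo <- if (builtin) {
        lam_mark <- if (variate == "univariate") marks else marks[2]
        lam <- sum(pp$marks == lam_mark) / window_area(pp$window)
        csr_theoretical(metric, grid, lambda = lam)
      } else rep(NA_real_, length(grid))
      out <- tibble::tibble(sample_id = id, r = grid, observed = obs,
                            csr_theoretical = theo,
                            csr_permuted = NA_real_)
      if (baseline == "permutation") {
        perm <- csr_permuted(pp, marks, metric, grid, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else seed + k,
                             correction = correction,
                             envelope_probs = envelope_probs)
        out$csr_permuted <- perm$csr_permuted
        if (!is.null(envelope_probs)) {
          out$env_lo <- perm$env_lo
          out$env_hi <- perm$env_hi
        }
      }
      out
    }, sfda_insufficient_cells = function(e) {
      exclude(id, conditionMessage(e)); NULL
    }, error = function(e) {
      exclude(id, paste("estimator failed:", conditionMessage(e))); NULL
    })
    rows[[k]] <- row
  }
  rows <- purrr::compact(rows)
  if (!length(rows)) {
    abort(sprintf("no eligible samples (min_cells = %d)", min_cells),
          class = "sfda_no_samples_error")
  }
  as_summary_set(dplyr::bind_rows(rows), metric = metric, variate = variate,
                 marks = marks, correction = correction, baseline = baseline,
                 n_perm = if (baseline == "permutation") as.integer(n_perm) else NA_integer_,
                 seed = seed %||% NA_integer_, exclusions = exclusions)
}

#' Curves of a summary set as a samples-by-radii matrix
#'
#' @param sset A `summary_set`.
#' @param value Which column to spread: `"fundiff"` (default) or
#'   `"observed"` (or any curve column present).
#' @return Numeric matrix, one row per sample (rownames = sample ids),
#'   columns ordered by the shared grid.
#' @export
curve_matrix <- function(sset, value = "fundiff") {
  stopifnot(inherits(sset, "summary_set"))
  if (!value %in% names(sset)) {
    abort(sprintf("no column '%s' in summary set", value))
  }
  grid <- attr(sset, "grid")
  wide <- tidyr::pivot_wider(
    sset[c("sample_id", "r", value)],
    names_from = "r", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  colnames(m) <- NULL
  attr(m, "grid") <- grid
  m
}
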