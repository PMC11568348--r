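#' Read a cell-level table from CSV or TSV
#'
#' Reads the post-segmentation, post-phenotyping tabular format: one row per
#' cell with sample/subject identifiers, x/y coordinates in microns and
#' phenotype columns. The delimiter follows the file extension (`.tsv` /
#' `.txt` tab, otherwise comma). Coordinates are validated row-by-row and a
#' parse error names the offending row.
#'
#' @param path Path to the CSV/TSV file (header required, UTF-8).
#' @param sample_id,subject_id Key column names in the file.
#' @return A validated tibble with standardized `sample_id`, `subject_id`
#'   key columns.
#' @export
read_cell_table <- function(path, sample_id = "sample_id",
                            subject_id = "subject_id") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(sample_id, subject_id, "x", "y")) {
    if (!col %in% names(tab)) {
      abort(sprintf("cell table is missing required column '%s'", col),
            class = "sfda_schema_error")
    }
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s' at data row %d",
                    col, bad[1]),
            class = "sfda_parse_error")
    }
    tab[[col]] <- v
  }
  inform(sprintf("read %d cells from %s", nrow(tab), basename(path)))
  tab <- dplyr::rename(tab,
                       sample_id = dplyr::all_of(sample_id),
                       subject_id = dplyr::all_of(subject_id))
  tab
}

#' Write / read a summary function set
#'
#' The curve table goes to a long-format CSV (`sample_id, r, observed,
#' csr_theoretical, csr_permuted, fundiff`) and the extraction settings to a
#' JSON sidecar (`<path>.json`). `read_curves()` reassembles the
#' `summary_set` and fails if the sidecar disagrees with the CSV.
#'
#' @param sset A `summary_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_curves()` returns `path` invisibly; `read_curves()` the
#'   reconstructed `summary_set`.
#' @export
write_curves <- function(sset, path) {
  stopifnot(inherits(sset, "summary_set"))
  readr::write_csv(tibble::as_tibble(sset), path)
  sidecar <- list(
    format = "spatialfda_curves", version = 1L,
    metric = attr(sset, "metric"), variate = attr(sset, "variate"),
    marks = attr(sset, "marks"), correction = attr(sset, "correction"),
    baseline = attr(sset, "baseline"),
    n_perm = attr(sset, "n_perm"), seed = attr(sset, "seed"),
    n_samples = dplyr::n_distinct(sset$sample_id),
    n_r = length(attr(sset, "grid")),
    exclusions = attr(sset, "exclusions"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    abort("curve CSV or its JSON sidecar is missing", class = "sfda_io_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(meta$format, "spatialfda_curves")) {
    abort("sidecar is not a spatialfda curves manifest", class = "sfda_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dplyr::n_distinct(df$sample_id) != meta$n_samples ||
      dplyr::n_distinct(df$r) != meta$n_r) {
    abort("curve CSV does not match its sidecar (sample or grid count)",
          class = "sfda_integrity_error")
  }
  df$sample_id <- as.character(df$sample_id)
  for (col in intersect(names(df), c("r", "observed", "csr_theoretical",
                                     "csr_permuted", "fundiff",
                                     "env_lo", "env_hi"))) {
    df[[col]] <- as.numeric(df[[col]])  # all-NA columns parse as logical
  }
  excl <- meta$exclusions
  excl <- if (is.null(excl) || !length(excl)) NULL else tibble::as_tibble(excl)
  as_summary_set(df, metric = meta$metric, variate = meta$variate,
                 marks = meta$marks, correction = meta$correction,
                 baseline = meta$baseline,
                 n_perm = meta$n_perm %||% NA_integer_,
                 seed = meta$seed %||% NA_integer_,
                 exclusions = excl)
}

#' Record run metadata alongside outputs
#'
#' Writes a `run.json` capturing the call configuration, package version and
#' seed so that any deterministic stage can be reproduced from its output
#' directory alone.
#'
#' @param dir Output directory.
#' @param config Named list of settings (coerced to JSON).
#' @param seed Integer seed used, if any.
#' @return Path to `run.json`, invisibly.
#' @export
write_run_metadata <- function(dir, config, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run.json")
  jsonlite::write_json(
    list(package = "spatialfda",
         version = as.character(utils::packageVersion("spatialfda")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = config),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
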