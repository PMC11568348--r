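#' Assemble a spatial FDA study container
#'
#' The study container links everything one analysis needs by consistent
#' keys: the cell-level table (one row per cell, with sample and subject
#' identifiers, coordinates in microns, and phenotype indicators), the
#' subject-level metadata (outcomes and scalar covariates), and — as the
#' pipeline runs — derived spatial summary curve sets, FPCA results, and
#' functional regression fits.
#'
#' Phenotypes may arrive either as logical indicator columns (prefixed
#' `phenotype_` or declared via `phenotypes`) or as a single categorical
#' `phenotype` column; both are normalized to indicator columns internally.
#'
#' @param cells Data frame, one row per cell. Required columns: sample id,
#'   subject id, `x`, `y`, plus phenotype information (see Details).
#' @param metadata Data frame, one row per subject, containing the subject id
#'   column and any outcome/covariate columns.
#' @param sample_id,subject_id Names of the key columns (defaults
#'   `"sample_id"`, `"subject_id"`).
#' @param phenotypes Optional character vector naming the phenotype indicator
#'   columns; defaults to every column prefixed `phenotype_`, or to the
#'   levels of a categorical `phenotype` column when present.
#' @return An object of class `spatial_study`.
#' @examples
#' cells <- data.frame(
#'   sample_id = rep(c("A", "B"), each = 3),
#'   subject_id = rep(c("S1", "S2"), each = 3),
#'   x = runif(6), y = runif(6),
#'   phenotype = sample(c("immune", "tumor"), 6, TRUE)
#' )
#' meta <- data.frame(subject_id = c("S1", "S2"), age = c(61, 54))
#' study <- make_study(cells, meta)
#' summary(study)
#' @export
make_study <- function(cells, metadata,
                       sample_id = "sample_id", subject_id = "subject_id",
                       phenotypes = NULL) {
  cells <- tibble::as_tibble(cells)
  metadata <- tibble::as_tibble(metadata)
  for (col in c(sample_id, subject_id)) {
    if (!col %in% names(cells)) {
      abort(sprintf("cell table is missing required column '%s'", col),
            class = "sfda_schema_error")
    }
  }
  for (col in c("x", "y")) {
    if (!col %in% names(cells)) {
      abort(sprintf("cell table is missing required column '%s'", col),
            class = "sfda_schema_error")
    }
    if (nrow(cells) && any(!is.finite(cells[[col]]))) {
      abort(sprintf("non-finite values in coordinate column '%s'", col),
            class = "sfda_schema_error")
    }
  }
  if (!subject_id %in% names(metadata)) {
    abort(sprintf("metadata is missing subject id column '%s'", subject_id),
          class = "sfda_schema_error")
  }
  if (anyNA(cells[[sample_id]]) || anyNA(cells[[subject_id]])) {
    abort("key columns must be non-missing", class = "sfda_key_error")
  }

  cells <- dplyr::rename(cells,
                         sample_id = dplyr::all_of(sample_id),
                         subject_id = dplyr::all_of(subject_id))
  metadata <- dplyr::rename(metadata, subject_id = dplyr::all_of(subject_id))
  cells$sample_id <- as.character(cells$sample_id)
  cells$subject_id <- as.character(cells$subject_id)
  metadata$subject_id <- as.character(metadata$subject_id)

  cells <- normalize_phenotypes(cells, phenotypes)
  pheno_cols <- attr(cells, "phenotypes")

  # every sample must map to exactly one subject
  map <- dplyr::distinct(cells, .data$sample_id, .data$subject_id)
  dup <- map$sample_id[duplicated(map$sample_id)]
  if (length(dup)) {
    abort(sprintf("sample(s) mapped to more than one subject: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "sfda_key_error")
  }
  missing_subj <- setdiff(map$subject_id, metadata$subject_id)
  if (length(missing_subj)) {
    abort(sprintf("subject(s) in cells but absent from metadata: %s",
                  paste(missing_subj, collapse = ", ")),
          class = "sfda_key_error")
  }
  if (anyDuplicated(metadata$subject_id)) {
    abort("metadata must have one row per subject", class = "sfda_key_error")
  }

  if (nrow(cells)) {
    dup_cells <- dplyr::count(cells, .data$sample_id, .data$x, .data$y,
                              dplyr::across(dplyr::all_of(pheno_cols))) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup_cells)) {
      warn(sprintf("%d duplicated (sample, x, y, phenotype) cell row(s)",
                   sum(dup_cells$n - 1)))
    }
  }

  structure(
    list(cells = cells, metadata = metadata, phenotypes = pheno_cols,
         summaries = list(), fpca = list(), fits = list()),
    class = "spatial_study")
}

# accept `phenotype` categorical column or phenotype_* logical indicators;
# canonical form: logical indicator columns + recorded phenotype names
normalize_phenotypes <- function(cells, phenotypes = NULL) {
  if (is.null(phenotypes)) {
    if ("phenotype" %in% names(cells)) {
      labs <- sort(unique(as.character(cells$phenotype)))
      for (lab in labs) {
        cells[[paste0("phenotype_", lab)]] <- cells$phenotype == lab
      }
      phenotypes <- paste0("phenotype_", labs)
    } else {
      phenotypes <- grep("^phenotype_", names(cells), value = TRUE)
    }
  } else {
    missing <- setdiff(phenotypes, names(cells))
    if (length(missing)) {
      abort(sprintf("declared phenotype column(s) not found: %s",
                    paste(missing, collapse = ", ")),
            class = "sfda_schema_error")
    }
  }
  for (col in phenotypes) {
    v <- cells[[col]]
    if (is.numeric(v) && !all(v %in% c(0, 1, NA))) {
      abort(sprintf("phenotype column '%s' is not an indicator", col),
            class = "sfda_schema_error")
    }
    cells[[col]] <- as.logical(v)
  }
  attr(cells, "phenotypes") <- phenotypes
  cells
}

# short label for a phenotype column ("phenotype_immune" -> "immune")
pheno_label <- function(col) sub("^phenotype_", "", col)

#' @export
print.spatial_study <- function(x, ...) {
  cat(format_study_summary(x), sep = "\n")
  invisible(x)
}

#' Summarize a study container
#'
#' Reports subject/sample counts, cells per sample, phenotype abundances and
#' which derived summaries, FPCA results and model fits are populated.
#'
#' @param object A `spatial_study`.
#' @param ... Unused.
#' @return The report lines, invisibly, after printing them.
#' @export
summary.spatial_study <- function(object, ...) {
  lines <- format_study_summary(object)
  cat(lines, sep = "\n")
  invisible(lines)
}

format_study_summary <- function(study) {
  cells <- study$cells
  n_samples <- dplyr::n_distinct(cells$sample_id)
  lines <- c(
    "spatial FDA study",
    sprintf("  subjects: %d", nrow(study$metadata)),
    sprintf("  samples:  %d", n_samples))
  if (n_samples > 0) {
    per <- dplyr::count(cells, .data$sample_id)$n
    lines <- c(lines, sprintf(
      "  cells per sample: min %d / median %g / max %d",
      min(per), median(per), max(per)))
    for (col in study$phenotypes) {
      lines <- c(lines, sprintf("  phenotype %s: %d cells",
                                pheno_label(col), sum(cells[[col]], na.rm = TRUE)))
    }
  } else {
    lines <- c(lines, "  cells per sample: none (0 samples)")
  }
  if (length(study$summaries)) {
    for (key in names(study$summaries)) {
      s <- study$summaries[[key]]
      lines <- c(lines, sprintf(
        "  summary [%s]: metric %s, %s, marks %s, %d samples", key,
        attr(s, "metric"), attr(s, "variate"),
        paste(attr(s, "marks"), collapse = " vs "),
        dplyr::n_distinct(s$sample_id)))
    }
  } else {
    lines <- c(lines, "  summaries: none")
  }
  lines <- c(lines,
             sprintf("  fpca results: %s",
                     if (length(study$fpca)) paste(names(study$fpca), collapse = ", ")
                     else "none"),
             sprintf("  model fits: %d", length(study$fits)))
  lines
}

#' Attach a summary function set to a study
#'
#' Stores the set under its `(metric, variate, marks)` key. Attaching a set
#' under an existing key replaces it, with a warning.
#'
#' @param study A `spatial_study`.
#' @param sset A `summary_set` (see [extract_summary_functions()] /
#'   [as_summary_set()]).
#' @return The updated study.
#' @export
attach_summary <- function(study, sset) {
  stopifnot(inherits(study, "spatial_study"), inherits(sset, "summary_set"))
  foreign <- setdiff(unique(sset$sample_id), unique(study$cells$sample_id))
  if (length(foreign)) {
    abort(sprintf("summary set references unknown sample(s): %s",
                  paste(foreign, collapse = ", ")),
          class = "sfda_key_error")
  }
  key <- summary_key(sset)
  if (key %in% names(study$summaries)) {
    warn(sprintf("replacing existing summary set under key '%s'", key))
  }
  study$summaries[[key]] <- sset
  study
}

#' @rdname attach_summary
#' @param fpca_result An `sfda_fpca` or `sfda_mfpca` fit of the curves stored
#'   under `key`.
#' @param key Summary key the FPCA result belongs to.
#' @export
attach_fpca <- function(study, fpca_result, key) {
  stopifnot(inherits(study, "spatial_study"))
  if (!key %in% names(study$summaries)) {
    abort(sprintf("no summary set under key '%s'", key),
          class = "sfda_key_error")
  }
  study$fpca[[key]] <- fpca_result
  study
}

#' @rdname attach_summary
#' @param fit A functional regression fit to store.
#' @export
attach_fit <- function(study, fit) {
  stopifnot(inherits(study, "spatial_study"))
  study$fits <- c(study$fits, list(fit))
  study
}

summary_key <- function(sset) {
  paste(attr(sset, "metric"), attr(sset, "variate"),
        paste(attr(sset, "marks"), collapse = ":"), sep = "_")
}

#' Write / read a study container as plain-text files
#'
#' `write_study()` writes `cells.csv`, `metadata.csv`, one curve CSV (plus
#' JSON sidecar) per attached summary set, and a `manifest.json` listing the
#' parts. `read_study()` reverses it. FPCA results and model fits are not
#' serialized.
#'
#' @param study A `spatial_study`.
#' @param dir Directory (created if needed).
#' @return `write_study()` the directory, invisibly; `read_study()` the
#'   reconstructed study.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$cells, file.path(dir, "cells.csv"))
  readr::write_csv(study$metadata, file.path(dir, "metadata.csv"))
  curve_files <- character(0)
  for (key in names(study$summaries)) {
    fn <- paste0("curves_", gsub("[^A-Za-z0-9_.-]", "-", key), ".csv")
    write_curves(study$summaries[[key]], file.path(dir, fn))
    curve_files[key] <- fn
  }
  manifest <- list(format = "spatialfda_study", version = 1L,
                   cells = "cells.csv", metadata = "metadata.csv",
                   phenotypes = study$phenotypes,
                   summaries = as.list(curve_files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "spatialfda_study")) {
    abort("not a spatialfda study directory", class = "sfda_io_error")
  }
  cells <- readr::read_csv(file.path(dir, manifest$cells),
                           show_col_types = FALSE)
  metadata <- readr::read_csv(file.path(dir, manifest$metadata),
                              show_col_types = FALSE)
  study <- make_study(cells, metadata,
                      phenotypes = unlist(manifest$phenotypes))
  for (key in names(manifest$summaries)) {
    sset <- read_curves(file.path(dir, manifest$summaries[[key]]))
    study$summaries[[key]] <- sset
  }
  study
}
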