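#' Plot a summary function set
#'
#' Spaghetti plot of the per-sample curves (one line per sample), optionally
#' against the CSR baseline.
#'
#' @param object A `summary_set`.
#' @param value Curve column to draw (default `"observed"`).
#' @param baseline Draw the CSR baseline of the set (default `TRUE`; drawn
#'   dashed, averaged across samples).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot summary_set
#' @export
autoplot.summary_set <- function(object, value = "observed",
                                 baseline = TRUE, ...) {
  if (!nrow(object)) abort("empty summary set")
  metric <- attr(object, "metric")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$r, y = .data[[value]],
                                    group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(
      x = "radius r", y = sprintf("%s(r)", metric),
      title = sprintf("%s (%s, marks %s)", metric, attr(object, "variate"),
                      paste(attr(object, "marks"), collapse = " vs "))) +
    ggplot2::theme_minimal()
  if (baseline && value == "observed") {
    base_col <- if (identical(attr(object, "baseline"), "permutation")) {
      "csr_permuted"
    } else "csr_theoretical"
    if (any(is.finite(object[[base_col]]))) {
      base_df <- dplyr::summarise(
        dplyr::group_by(tibble::as_tibble(object), .data$r),
        baseline = mean(.data[[base_col]], na.rm = TRUE), .groups = "drop")
      p <- p + ggplot2::geom_line(
        data = base_df,
        ggplot2::aes(x = .data$r, y = .data$baseline, group = 1),
        linetype = "dashed", color = "red", linewidth = 0.6)
    }
  }
  p
}

#' @rdname autoplot.summary_set
#' @param x,y See [autoplot.summary_set()].
#' @export
plot.summary_set <- function(x, y, ...) print(autoplot(x, ...))

#' Plot FPCA components as mean +/- one standard deviation
#'
#' One panel per retained component, each showing the mean curve (solid)
#' and \eqn{\mu \pm \sqrt{\lambda_k}\phi_k} (dotted), the standard display
#' of what curve pattern a component encodes.
#'
#' @param object An `sfda_fpca`.
#' @param components Which components to show (default all retained).
#' @param ... Unused.
#' @return A ggplot object (facetted by component).
#' @method autoplot sfda_fpca
#' @export
autoplot.sfda_fpca <- function(object, components = seq_len(object$npc),
                               ...) {
  bands <- purrr::map_dfr(components, function(k) {
    b <- fpca_component_band(object, k)
    b$component <- sprintf("PC%d (%.0f%%)", k,
                           100 * object$evalues[k] / object$total_variance)
    b
  })
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dotted",
                       color = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dotted",
                       color = "red") +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "radius r", y = "curve value",
                  title = "FPCA: mean ± 1 SD of each component") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sfda_fpca
#' @param x,y See [autoplot.sfda_fpca()].
#' @export
plot.sfda_fpca <- function(x, y, ...) print(autoplot(x, ...))

#' Plot a functional Cox hazard-ratio curve with confidence bands
#'
#' Solid line: \eqn{\exp\hat\beta(r)}; dotted lines: pointwise confidence
#' band; horizontal reference at HR = 1. Radii where the band excludes 1 are
#' the significant range.
#'
#' @param object An `sfda_fcox`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfda_fcox
#' @export
autoplot.sfda_fcox <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_hline(yintercept = 1, color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_low), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_high), linetype = "dotted") +
    ggplot2::labs(x = "radius r", y = "hazard ratio exp(β(r))",
                  title = "functional Cox: pointwise hazard ratio") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sfda_fcox
#' @param x,y See [autoplot.sfda_fcox()].
#' @export
plot.sfda_fcox <- function(x, y, ...) print(autoplot(x, ...))

#' @rdname autoplot.sfda_fcox
#' @method autoplot sfda_sofr
#' @export
autoplot.sfda_sofr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$beta)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_low), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_high), linetype = "dotted") +
    ggplot2::labs(x = "radius r", y = "β(r)",
                  title = "scalar-on-function coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sfda_fcox
#' @export
plot.sfda_sofr <- function(x, y, ...) print(autoplot(x, ...))

#' Save any of the pipeline plots to a file
#'
#' Thin wrapper over [ggplot2::ggsave()] that creates the directory and
#' returns the path, used by scripted pipelines.
#'
#' @param plot A ggplot object (e.g. from `autoplot()`).
#' @param path Output file (extension selects the device).
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 7, height = 4) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ggplot2::ggsave(path, plot = plot, width = width, height = height)
  invisible(path)
}
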