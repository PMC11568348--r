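# registry for user-defined summary metrics
.sfda_plugins <- new.env(parent = emptyenv())

#' Register a user-defined spatial summary metric
#'
#' A plugin makes a custom summary function usable everywhere a builtin
#' metric is, including batch extraction and the permutation baseline. The
#' callable receives the full marked pattern, the target mark (or mark pair)
#' and the radius grid, and must return one numeric value per grid point.
#'
#' @param name Metric name; must not collide with the builtins `K`, `L`, `G`
#'   or a previously registered plugin (re-register by removing first with
#'   [remove_summary_plugin()]).
#' @param fn `function(pattern, marks, grid) -> numeric`.
#' @return `name`, invisibly.
#' @examples
#' register_summary_plugin("const1", function(pattern, marks, grid) {
#'   rep(1, length(grid))
#' })
#' remove_summary_plugin("const1")
#' @export
register_summary_plugin <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (name %in% c("K", "L", "G") || exists(name, envir = .sfda_plugins)) {
    abort(sprintf("metric name '%s' is already taken", name),
          class = "sfda_plugin_error")
  }
  assign(name, fn, envir = .sfda_plugins)
  invisible(name)
}

#' @rdname register_summary_plugin
#' @export
remove_summary_plugin <- function(name) {
  if (exists(name, envir = .sfda_plugins)) rm(list = name, envir = .sfda_plugins)
  invisible(name)
}

get_summary_plugin <- function(name) {
  if (!exists(name, envir = .sfda_plugins)) {
    abort(sprintf("unknown metric '%s' (not a builtin, not a registered plugin)",
                  name),
          class = "sfda_metric_error")
  }
  get(name, envir = .sfda_plugins)
}
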