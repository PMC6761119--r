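#' Run configuration for the screening pipeline
#'
#' Assembles every tunable of a screen run: the expression thresholds,
#' seed-site options, the ChIP window, and the TF correlation switch.
#' Unknown fields are an error so config typos never silently revert
#' to defaults; the defaults themselves are the published screen
#' settings (10,000 TPM; 150 TPM; 2-fold; -0.95).
#'
#' @param thresholds [screen_thresholds()] or a named list of its
#'   fields.
#' @param min_sites Minimum canonical seed sites per UTR; default 1.
#' @param allowed_types Canonical site classes to count; default all
#'   three.
#' @param mask `"soft"` or `"hard"` repeat masking of UTR input.
#' @param window_bp ChIP peak-to-TSS window half-width; default 50000.
#' @param tf_correlation_filter Apply the anti-correlation filter to
#'   the miRNA-TF pair too; default `TRUE`.
#' @param fold_method `"endpoint"` or `"extremum"` fold change.
#' @param expression_stat `"max"` or `"mean"` expression summary.
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param seed Integer seed recorded in output provenance.
#' @return An object of class `run_config`.
#' @export
run_config <- function(thresholds = screen_thresholds(),
                       min_sites = 1L,
                       allowed_types = SITE_TYPES,
                       mask = "soft",
                       window_bp = 50000L,
                       tf_correlation_filter = TRUE,
                       fold_method = "endpoint",
                       expression_stat = "max",
                       correlation_method = "pearson",
                       seed = 1L) {
  stopifnot(min_sites >= 1L, all(allowed_types %in% SITE_TYPES),
            mask %in% c("soft", "hard"), window_bp >= 0,
            is.logical(tf_correlation_filter),
            fold_method %in% c("endpoint", "extremum"),
            expression_stat %in% c("max", "mean"),
            correlation_method %in% c("pearson", "spearman"))
  structure(list(thresholds = as_screen_thresholds(thresholds),
                 min_sites = as.integer(min_sites),
                 allowed_types = allowed_types,
                 mask = mask,
                 window_bp = as.integer(window_bp),
                 tf_correlation_filter = tf_correlation_filter,
                 fold_method = fold_method,
                 expression_stat = expression_stat,
                 correlation_method = correlation_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Top-level keys mirror the [run_config()] arguments; the
#' `thresholds` block mirrors the [screen_thresholds()] field names
#' exactly. Unknown keys at either level are an error.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) return(run_config())
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(y$thresholds))
    y$thresholds <- as_screen_thresholds(y$thresholds)
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  print(x$thresholds)
  cat(sprintf("  seed sites: >= %d of {%s}, %s-masked\n", x$min_sites,
              paste(x$allowed_types, collapse = ", "), x$mask))
  cat(sprintf("  ChIP window: +/- %d bp\n", x$window_bp))
  cat(sprintf("  TF correlation filter: %s; fold: %s; expression: %s; cor: %s\n",
              x$tf_correlation_filter, x$fold_method, x$expression_stat,
              x$correlation_method))
  invisible(x)
}
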