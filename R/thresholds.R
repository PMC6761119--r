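#' Screening thresholds for the feed-forward-loop expression screen
#'
#' Bundles the numeric cut-offs applied by [screen_ffls()]. The defaults
#' are the published screen settings for adipogenesis CAGE/short-RNA
#' data: miRNAs must reach 10,000 TPM, promoters 150 TPM, both must
#' change at least two-fold in the appropriate direction across the
#' course, and miRNA-gene profile correlation must be -0.95 or lower.
#'
#' @param min_mirna_tpm Minimum miRNA expression in tags per million.
#'   A miRNA passes when its replicate-mean profile reaches this value
#'   (see `stat` in [passes_expression()]). Default 10000.
#' @param min_promoter_tpm Minimum promoter/gene expression in TPM.
#'   Default 150.
#' @param min_fold_change Required end-to-end fold change, `>= 1`. Genes
#'   must rise by at least this factor, miRNAs must fall to at most its
#'   reciprocal. Default 2.
#' @param max_correlation Upper bound on the Pearson correlation between
#'   the miRNA and gene profiles; must be `<= 0` for a repression screen.
#'   Default -0.95.
#' @param pseudocount TPM pseudocount added to both ends of the profile
#'   before forming the fold-change ratio, guarding zero denominators.
#'   Default 1.
#'
#' @return An object of class `screen_thresholds`.
#' @examples
#' screen_thresholds()
#' screen_thresholds(max_correlation = -0.85)
#' @export
screen_thresholds <- function(min_mirna_tpm = 10000,
                              min_promoter_tpm = 150,
                              min_fold_change = 2,
                              max_correlation = -0.95,
                              pseudocount = 1) {
  for (nm in c("min_mirna_tpm", "min_promoter_tpm", "min_fold_change",
               "max_correlation", "pseudocount")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (min_mirna_tpm < 0 || min_promoter_tpm < 0)
    stop("TPM thresholds must be non-negative", call. = FALSE)
  if (min_fold_change < 1)
    stop("`min_fold_change` must be >= 1", call. = FALSE)
  if (max_correlation < -1 || max_correlation > 0)
    stop("`max_correlation` must lie in [-1, 0] for a repression screen",
         call. = FALSE)
  if (pseudocount < 0)
    stop("`pseudocount` must be >= 0", call. = FALSE)
  structure(
    list(min_mirna_tpm = as.numeric(min_mirna_tpm),
         min_promoter_tpm = as.numeric(min_promoter_tpm),
         min_fold_change = as.numeric(min_fold_change),
         max_correlation = as.numeric(max_correlation),
         pseudocount = as.numeric(pseudocount)),
    class = "screen_thresholds"
  )
}

#' Build thresholds from a named list (e.g. a parsed YAML block)
#'
#' Unknown field names are an error so that config typos never silently
#' fall back to defaults.
#'
#' @param x Named list with a subset of the [screen_thresholds()] fields.
#' @return A `screen_thresholds` object.
#' @export
as_screen_thresholds <- function(x) {
  if (inherits(x, "screen_thresholds")) return(x)
  if (is.null(x)) return(screen_thresholds())
  if (!is.list(x)) stop("thresholds must be a named list", call. = FALSE)
  known <- names(formals(screen_thresholds))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown threshold field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(screen_thresholds, x)
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat("FFL screen thresholds:\n")
  cat(sprintf("  miRNA expression  >= %g TPM\n", x$min_mirna_tpm))
  cat(sprintf("  gene expression   >= %g TPM\n", x$min_promoter_tpm))
  cat(sprintf("  fold change       >= %g (genes up, miRNA down)\n",
              x$min_fold_change))
  cat(sprintf("  correlation       <= %g\n", x$max_correlation))
  cat(sprintf("  pseudocount       %g TPM\n", x$pseudocount))
  invisible(x)
}
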