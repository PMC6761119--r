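#' Partial correlations between a phenotype and two gene-expression
#' regressors
#'
#' Fits the multiple regression `phenotype ~ intercept + regressor1 +
#' regressor2` (after applying any log10 flags) on complete cases and
#' reports, for each regressor, the partial correlation with the
#' phenotype given the other regressor, together with the two-sided
#' p-value of the regression coefficient's t-test at `df = n - 3`.
#' A negative partial r indicates an inverse relationship between
#' regressor and phenotype.
#'
#' The partial correlation is computed by residualization — the
#' correlation between the phenotype residualized on the other
#' regressor(s) and this regressor residualized on the other
#' regressor(s) — and cross-checked on every fit against the
#' t-statistic identity `|r| = |t| / sqrt(t^2 + df)`.
#'
#' @param cohort Data frame with one row per subject; any `subject_id`
#'   column is ignored for fitting.
#' @param phenotype Name of the phenotype column.
#' @param regressors Character vector of regressor column names
#'   (typically two).
#' @param log10_cols Columns (phenotype or regressors) to log10
#'   transform before fitting; values must be strictly positive.
#' @return Data frame with one row per regressor and columns
#'   `phenotype`, `regressor`, `partial_r`, `p_value`, `df`, `n`.
#' @export
partial_correlations <- function(cohort, phenotype, regressors,
                                 log10_cols = character(0)) {
  stopifnot(is.data.frame(cohort), length(regressors) >= 2L)
  cols <- c(phenotype, regressors)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("column(s) not in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- cohort[, cols, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- length(regressors)
  df_resid <- n - k - 1L
  if (df_resid < 1L)
    stop("insufficient complete rows (n = ", n, ") for ", k,
         " regressors", call. = FALSE)
  for (cn in intersect(log10_cols, cols)) {
    if (any(d[[cn]] <= 0))
      stop("column '", cn, "' has non-positive values; cannot log10 ",
           "transform", call. = FALSE)
    d[[cn]] <- log10(d[[cn]])
  }
  if (sd(d[[phenotype]]) == 0)
    stop("phenotype '", phenotype, "' has zero variance", call. = FALSE)
  for (r in regressors)
    if (sd(d[[r]]) == 0)
      stop("regressor '", r, "' has zero variance", call. = FALSE)
  if (k == 2L && abs(cor(d[[regressors[1L]]], d[[regressors[2L]]])) >
      1 - 1e-12)
    stop("collinear regressors: ", regressors[1L], ", ", regressors[2L],
         call. = FALSE)

  y <- d[[phenotype]]
  X <- as.matrix(d[, regressors, drop = FALSE])
  fit <- lm(y ~ X)
  if (anyNA(coef(fit)))
    stop("collinear regressors: ", paste(regressors, collapse = ", "),
         call. = FALSE)
  tstats <- summary(fit)$coefficients[-1L, "t value"]

  out <- lapply(seq_len(k), function(i) {
    others <- X[, -i, drop = FALSE]
    ry <- residuals(lm(y ~ others))
    rx <- residuals(lm(X[, i] ~ others))
    pr <- cor(ry, rx)
    t_i <- tstats[[i]]
    # residualization and t-statistic routes must agree
    if (abs(abs(pr) - abs(t_i) / sqrt(t_i^2 + df_resid)) > 1e-8)
      warning("partial correlation routes disagree for ", regressors[i],
              call. = FALSE)
    data.frame(phenotype = phenotype, regressor = regressors[i],
               partial_r = pr,
               p_value = 2 * pt(-abs(t_i), df_resid),
               df = df_resid, n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Phenotype-by-regressor partial-correlation table
#'
#' Runs [partial_correlations()] for each phenotype against the same
#' regressor pair and stacks the results — the shape of a clinical
#' gene-expression association table (one row per phenotype x
#' regressor, partial r and p side by side). Phenotypes that cannot be
#' fitted (zero variance, insufficient rows) are skipped with a
#' warning.
#'
#' @param cohort Data frame, one row per subject.
#' @param phenotypes Character vector of phenotype column names.
#' @param regressors Character vector of (typically two) regressor
#'   columns.
#' @param log10_cols Columns to log10 transform before fitting.
#' @return Data frame as in [partial_correlations()], rows stacked over
#'   phenotypes.
#' @export
phenotype_table <- function(cohort, phenotypes, regressors,
                            log10_cols = character(0)) {
  out <- lapply(phenotypes, function(ph) {
    tryCatch(
      partial_correlations(cohort, ph, regressors, log10_cols),
      error = function(e) {
        warning("phenotype '", ph, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(phenotype = character(0), regressor = character(0),
                      partial_r = numeric(0), p_value = numeric(0),
                      df = integer(0), n = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Write a phenotype association table
#'
#' Partial r at 4 decimals, p-values at 2 significant digits.
#'
#' @param tab Result of [phenotype_table()].
#' @param path Output TSV path.
#' @param header Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(tab, path, header = NULL) {
  stopifnot(is.data.frame(tab))
  out <- tab
  out$partial_r <- sprintf("%.4f", out$partial_r)
  out$p_value <- signif(out$p_value, 2)
  write_tsv_atomic(out, path, header = header)
}

#' Read a cohort table
#'
#' Tab-delimited, header row, `subject_id` first column, remaining
#' columns numeric phenotype and expression measures.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (names(df)[1L] != "subject_id")
    stop("cohort table must start with a subject_id column", call. = FALSE)
  df
}
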