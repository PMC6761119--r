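#' Time-course expression matrix with replicates
#'
#' Container for TPM expression of a set of entities (miRNAs or
#' genes/promoters) over an ordered series of timepoints, each measured
#' in a fixed number of replicates. Values are stored as an entities x
#' (timepoint x replicate) matrix whose columns are named
#' `<timepoint>__rep<k>` in timepoint-major order.
#'
#' Invariants enforced at construction: all values are non-negative and
#' finite, timepoints are strictly increasing in numeric time, entity
#' ids are unique, and every (entity, timepoint) carries exactly the
#' declared replicate count — ragged replicate structure is an input
#' error, never silently imputed.
#'
#' @param values Numeric matrix, rows = entities (rownames = entity
#'   ids), columns in timepoint-major order (all replicates of the first
#'   timepoint, then the second, ...).
#' @param timepoints Data frame with columns `label` (character) and
#'   `time` (numeric, strictly increasing).
#' @param n_replicates Single positive integer, replicates per timepoint.
#'
#' @return An object of class `time_course_matrix` with elements
#'   `values`, `timepoints`, `n_replicates`.
#' @export
time_course_matrix <- function(values, timepoints, n_replicates) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)))
    stop("`values` must carry entity ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate entity_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must all be finite (no missing cells)",
         call. = FALSE)
  if (any(values < 0))
    stop("negative TPM value found; expression must be >= 0",
         call. = FALSE)
  if (!is.data.frame(timepoints) ||
      !all(c("label", "time") %in% names(timepoints)))
    stop("`timepoints` must be a data frame with columns label, time",
         call. = FALSE)
  if (nrow(timepoints) < 1L || anyNA(timepoints$time))
    stop("timepoints must have numeric times", call. = FALSE)
  if (any(diff(timepoints$time) <= 0))
    stop("timepoints must be strictly increasing in numeric time",
         call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) != 1L || is.na(n_replicates) || n_replicates < 1L)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  expected <- nrow(timepoints) * n_replicates
  if (ncol(values) != expected)
    stop("ragged replicate structure: expected ",
         nrow(timepoints), " timepoints x ", n_replicates,
         " replicates = ", expected, " columns, got ", ncol(values),
         call. = FALSE)
  colnames(values) <- tc_column_names(timepoints$label, n_replicates)
  structure(
    list(values = values,
         timepoints = data.frame(label = as.character(timepoints$label),
                                 time = as.numeric(timepoints$time),
                                 stringsAsFactors = FALSE),
         n_replicates = n_replicates),
    class = "time_course_matrix"
  )
}

tc_column_names <- function(labels, n_replicates) {
  as.vector(vapply(labels, function(l)
    paste0(l, "__rep", seq_len(n_replicates)), character(n_replicates)))
}

#' @export
print.time_course_matrix <- function(x, ...) {
  cat(sprintf("time_course_matrix: %d entities x %d timepoints x %d replicates\n",
              nrow(x$values), nrow(x$timepoints), x$n_replicates))
  cat("  timepoints:", paste(x$timepoints$label, collapse = ", "), "\n")
  cat("  entities:", paste(head(rownames(x$values), 6), collapse = ", "),
      if (nrow(x$values) > 6) "..." else "", "\n")
  invisible(x)
}

#' Entity identifiers of a time-course matrix
#' @param m A `time_course_matrix`.
#' @return Character vector of entity ids in file order.
#' @export
entity_ids <- function(m) {
  stopifnot(inherits(m, "time_course_matrix"))
  rownames(m$values)
}

#' Read a tab-delimited TPM expression table
#'
#' The expected layout is one `entity_id` column followed by value
#' columns named `<timepoint>__rep<k>` (e.g. `day0__rep1`). Lines
#' starting with `#` are provenance comments and are skipped. Numeric
#' time is parsed from the first number embedded in each timepoint
#' label (`day0` -> 0, `day2.5` -> 2.5); when no label contains a
#' number, timepoints are ordered as they appear.
#'
#' @param path Path to a UTF-8 tab-delimited file with `.` decimals and
#'   no missing cells.
#' @param timepoint_spec Optional data frame overriding header parsing,
#'   with columns `column`, `timepoint`, `time`, `replicate` mapping
#'   each value column to its timepoint label, numeric time and
#'   replicate index.
#'
#' @return A validated [time_course_matrix()]; entity order is
#'   preserved from the file.
#' @export
read_expression_table <- function(path, timepoint_spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression table needs an entity_id column plus value columns",
         call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate entity_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  value_cols <- names(df)[-1L]
  spec <- if (is.null(timepoint_spec)) {
    parse_timepoint_columns(value_cols)
  } else {
    validate_timepoint_spec(timepoint_spec, value_cols)
  }

  num <- suppressWarnings(
    vapply(value_cols, function(cn) as.numeric(df[[cn]]), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, value_cols))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("malformed numeric cell at row '", ids[bad[1L]],
         "', column '", value_cols[bad[2L]], "' in ", path, call. = FALSE)
  }

  tp <- unique(spec[, c("timepoint", "time")])
  tp <- tp[order(tp$time), , drop = FALSE]
  reps <- sort(unique(spec$replicate))
  n_rep <- length(reps)
  if (!identical(reps, seq_len(n_rep)))
    stop("replicate indices must be 1..k; got: ",
         paste(reps, collapse = ", "), call. = FALSE)
  # ragged structure check: every timepoint must have each replicate once
  for (lab in tp$timepoint) {
    have <- sort(spec$replicate[spec$timepoint == lab])
    if (!identical(have, seq_len(n_rep)))
      stop("ragged replicate structure at timepoint '", lab,
           "': found replicates {", paste(have, collapse = ","),
           "}, expected 1..", n_rep, call. = FALSE)
  }

  ordered_cols <- unlist(lapply(tp$timepoint, function(lab)
    vapply(seq_len(n_rep), function(k)
      spec$column[spec$timepoint == lab & spec$replicate == k],
      character(1L))))
  time_course_matrix(num[, ordered_cols, drop = FALSE],
                     data.frame(label = tp$timepoint, time = tp$time),
                     n_rep)
}

parse_timepoint_columns <- function(cols) {
  m <- regmatches(cols, regexec("^(.*)__rep([0-9]+)$", cols))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad))
    stop("cannot parse value column name(s) as <timepoint>__rep<k>: ",
         paste(cols[bad], collapse = ", "), call. = FALSE)
  labels <- vapply(m, `[[`, character(1L), 2L)
  reps <- as.integer(vapply(m, `[[`, character(1L), 3L))
  times <- label_times(unique(labels))
  data.frame(column = cols, timepoint = labels,
             time = times[labels], replicate = reps,
             stringsAsFactors = FALSE)
}

label_times <- function(labels) {
  hits <- regmatches(labels, regexpr("-?[0-9]+\\.?[0-9]*", labels))
  if (length(hits) == length(labels) && !anyNA(suppressWarnings(as.numeric(hits)))) {
    times <- as.numeric(hits)
  } else {
    times <- seq_along(labels)  # fall back to order of appearance
  }
  if (anyDuplicated(times))
    stop("timepoint labels do not yield distinct numeric times: ",
         paste(labels, collapse = ", "), call. = FALSE)
  setNames(times, labels)
}

validate_timepoint_spec <- function(spec, cols) {
  need <- c("column", "timepoint", "time", "replicate")
  if (!is.data.frame(spec) || !all(need %in% names(spec)))
    stop("timepoint_spec needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!setequal(spec$column, cols))
    stop("timepoint_spec columns do not match the file's value columns",
         call. = FALSE)
  data.frame(column = as.character(spec$column),
             timepoint = as.character(spec$timepoint),
             time = as.numeric(spec$time),
             replicate = as.integer(spec$replicate),
             stringsAsFactors = FALSE)
}

#' Write a time-course matrix as a tab-delimited TPM table
#'
#' Inverse of [read_expression_table()]; round-tripping preserves all
#' values and the entity order.
#'
#' @param m A `time_course_matrix`.
#' @param path Output file path.
#' @param header Optional character vector of provenance lines written
#'   as `#` comments before the table.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, header = NULL) {
  stopifnot(inherits(m, "time_course_matrix"))
  df <- data.frame(entity_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path, header = header)
}

#' Replicate-mean expression profile of one entity
#'
#' Collapses the replicates of a single entity to one arithmetic mean
#' per timepoint — the per-entity trajectory that all downstream
#' filters (expression level, fold change, correlation) operate on.
#'
#' @param m A `time_course_matrix`.
#' @param entity Entity identifier present in `m`.
#' @return An object of class `tc_profile` with elements `entity_id`,
#'   `timepoints` and `means`.
#' @export
replicate_mean <- function(m, entity) {
  stopifnot(inherits(m, "time_course_matrix"))
  if (!entity %in% rownames(m$values))
    stop("unknown entity: ", entity, call. = FALSE)
  v <- m$values[entity, ]
  nt <- nrow(m$timepoints)
  means <- vapply(seq_len(nt), function(i) {
    mean(v[((i - 1L) * m$n_replicates + 1L):(i * m$n_replicates)])
  }, numeric(1L))
  new_profile(entity, m$timepoints, means)
}

new_profile <- function(entity_id, timepoints, means) {
  stopifnot(length(means) == nrow(timepoints), all(means >= 0))
  structure(list(entity_id = entity_id,
                 timepoints = timepoints,
                 means = as.numeric(means)),
            class = "tc_profile")
}

#' @export
print.tc_profile <- function(x, ...) {
  cat("profile", x$entity_id, ":",
      paste(sprintf("%s=%.4g", x$timepoints$label, x$means), collapse = " "),
      "\n")
  invisible(x)
}

#' Replicate-mean profiles for all entities
#'
#' @param m A `time_course_matrix`.
#' @return Numeric matrix entities x timepoints of replicate means.
#' @export
replicate_means <- function(m) {
  stopifnot(inherits(m, "time_course_matrix"))
  nt <- nrow(m$timepoints)
  out <- vapply(seq_len(nt), function(i) {
    rowMeans(m$values[, ((i - 1L) * m$n_replicates + 1L):(i * m$n_replicates),
                      drop = FALSE])
  }, numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), m$timepoints$label))
  out
}

profile_from_means <- function(entity, m, mean_matrix) {
  new_profile(entity, m$timepoints, mean_matrix[entity, ])
}

#' End-to-end fold change of an expression profile
#'
#' Signed fold change across the differentiation course, computed as
#' `(last + pseudocount) / (first + pseudocount)` on the replicate-mean
#' profile. Values above 1 indicate upregulation, below 1
#' downregulation; downregulation by at least k-fold corresponds to a
#' returned value `<= 1/k`. The alternative `"extremum"` method uses the
#' course minimum and maximum instead of the endpoints, oriented by
#' which occurs later.
#'
#' @param profile A `tc_profile` with at least two timepoints.
#' @param thresholds A [screen_thresholds()] object supplying the
#'   pseudocount.
#' @param method `"endpoint"` (default) or `"extremum"`.
#' @return A single positive number.
#' @export
fold_change <- function(profile, thresholds = screen_thresholds(),
                        method = c("endpoint", "extremum")) {
  stopifnot(inherits(profile, "tc_profile"))
  method <- match.arg(method)
  m <- profile$means
  if (length(m) < 2L)
    stop("fold change needs at least two timepoints", call. = FALSE)
  pc <- as_screen_thresholds(thresholds)$pseudocount
  if (method == "endpoint") {
    (m[length(m)] + pc) / (m[1L] + pc)
  } else {
    i_max <- which.max(m); i_min <- which.min(m)
    if (i_max >= i_min) (m[i_max] + pc) / (m[i_min] + pc)
    else                (m[i_min] + pc) / (m[i_max] + pc)
  }
}

#' Correlation between two expression profiles
#'
#' Pearson product-moment correlation (or Spearman rank correlation) of
#' the two replicate-mean vectors over a shared time course. Profiles
#' with zero variance have no defined correlation: the function warns
#' and returns `NA`, and callers are expected to exclude the entity
#' rather than treat it as uncorrelated.
#'
#' @param a,b `tc_profile` objects over identical timepoints, at least
#'   three timepoints each.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning for a
#'   zero-variance profile.
#' @export
pearson_r <- function(a, b, method = c("pearson", "spearman")) {
  stopifnot(inherits(a, "tc_profile"), inherits(b, "tc_profile"))
  method <- match.arg(method)
  if (!identical(a$timepoints$label, b$timepoints$label) ||
      !isTRUE(all.equal(a$timepoints$time, b$timepoints$time)))
    stop("profiles are over different timepoints", call. = FALSE)
  if (length(a$means) < 3L)
    stop("correlation needs at least three timepoints", call. = FALSE)
  if (sd(a$means) == 0 || sd(b$means) == 0) {
    warning("undefined correlation: zero-variance profile (",
            if (sd(a$means) == 0) a$entity_id else b$entity_id, ")",
            call. = FALSE)
    return(NA_real_)
  }
  r <- cor(a$means, b$means, method = method)
  # exactly (anti-)linear profiles must report exactly +/-1; cor() can
  # leave a one-ulp residue from its summation order
  if (1 - abs(r) < 1e-12) r <- sign(r)
  r
}

#' Does a profile reach an expression threshold?
#'
#' "Highly expressed" is evaluated on the replicate-mean profile.
#' With `stat = "max"` (default) the entity passes when any timepoint
#' mean reaches `min_tpm`, so genes induced only late in the course can
#' qualify; `stat = "mean"` requires the course average to reach it.
#' The comparison is inclusive (`>=`).
#'
#' @param profile A non-empty `tc_profile`.
#' @param min_tpm Threshold in TPM.
#' @param stat `"max"` (default) or `"mean"`.
#' @return Logical scalar.
#' @export
passes_expression <- function(profile, min_tpm, stat = c("max", "mean")) {
  stopifnot(inherits(profile, "tc_profile"), length(profile$means) >= 1L)
  stat <- match.arg(stat)
  s <- if (stat == "max") max(profile$means) else mean(profile$means)
  s >= min_tpm
}

#' Relative expression by the 2^-dCt method
#'
#' qPCR relative quantification: `2^-(ct_target - ct_reference)`.
#' Equal Ct values give 1; each extra cycle of the target halves the
#' result.
#'
#' @param ct_target,ct_reference Finite threshold-cycle values
#'   (vectorized).
#' @return Non-negative relative expression.
#' @examples
#' relative_expression_2dct(25, 20)  # 2^-5 = 0.03125
#' @export
relative_expression_2dct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  2^(-(ct_target - ct_reference))
}

# -- shared atomic TSV writer ------------------------------------------------

write_tsv_atomic <- function(df, path, header = NULL, col.names = TRUE) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  if (!is.null(header) && length(header))
    writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  close(con)
  if (!file.rename(tmp, path))
    stop("cannot write output file: ", path, call. = FALSE)
  invisible(path)
}

provenance_header <- function(command, seed = NULL) {
  c(paste0("ffloop ", as.character(utils::packageVersion("ffloop"))),
    paste0("command: ", command),
    if (!is.null(seed)) paste0("seed: ", seed),
    paste0("date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}
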