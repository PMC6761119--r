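#' Screen for coherent type-2 feed-forward loops
#'
#' The core screen behind the candidate-loop table. A coherent type-2
#' feed-forward loop is a three-node motif in which a miRNA represses
#' both a transcription factor (TF) and one of the TF's positively
#' regulated targets. A loop `(miRNA, TF, target)` is emitted when ALL
#' of the following hold under `thresholds`:
#'
#' * the miRNA is highly expressed (`>= min_mirna_tpm`) and
#'   downregulated at least `min_fold_change`-fold end to end;
#' * the TF and the target are expressed (`>= min_promoter_tpm`) and
#'   upregulated at least `min_fold_change`-fold;
#' * the miRNA profile is anti-correlated with the target profile
#'   (`r <= max_correlation`), and — by default — with the TF profile
#'   too (`tf_correlation_filter`);
#' * the TF and target 3'UTRs each carry at least `min_sites` canonical
#'   seed sites for the miRNA;
#' * the target is a TF target by ChIP-peak proximity to its TSS or by
#'   membership in a supplied target list; and `target != tf`.
#'
#' Entities with zero-variance profiles have no defined correlation and
#' are excluded at the correlation stage with a logged warning. Output
#' order is deterministic: by miRNA name, then target name.
#'
#' @param mirna_matrix,gene_matrix [time_course_matrix()] objects over
#'   identical timepoints (small-RNA and promoter/gene TPM).
#' @param mirnas A [mirna_record()] or list of them; each is screened
#'   against the fixed TF.
#' @param tf_id Identifier of the transcription factor; must be present
#'   in `gene_matrix` and in `utrs`.
#' @param utrs 3'UTR sequences (named `DNAStringSet`, named character
#'   vector, or FASTA path); ids must match `gene_matrix` entities.
#' @param tf_targets Optional precomputed TF-target gene ids (character
#'   vector or file path); bypasses peak assignment.
#' @param peaks,annotation,window_bp ChIP evidence for the TF-target
#'   edge, passed to [assign_chip_targets()] when `tf_targets` is not
#'   given.
#' @param thresholds A [screen_thresholds()] object.
#' @param tf_correlation_filter Apply the anti-correlation requirement
#'   to the miRNA-TF pair as well (default `TRUE`).
#' @param fold_method,expression_stat,correlation_method Passed through
#'   to [fold_change()], [passes_expression()] and [pearson_r()].
#' @param min_sites,allowed_types,mask Seed-site options, see
#'   [predict_mirna_targets()].
#'
#' @return List with `loops` (data frame, one row per candidate loop,
#'   columns `mirna`, `tf`, `target`, `mirna_fold`, `tf_fold`,
#'   `target_fold`, `r_mirna_tf`, `r_mirna_target`, `n_sites_tf`,
#'   `n_sites_target`, `tf_target_evidence`) and `report` (a
#'   `screen_report` of the filter funnel).
#' @export
screen_ffls <- function(mirna_matrix, gene_matrix, mirnas, tf_id, utrs,
                        tf_targets = NULL, peaks = NULL, annotation = NULL,
                        window_bp = 50000L,
                        thresholds = screen_thresholds(),
                        tf_correlation_filter = TRUE,
                        fold_method = "endpoint",
                        expression_stat = "max",
                        correlation_method = "pearson",
                        min_sites = 1L, allowed_types = SITE_TYPES,
                        mask = "soft") {
  stopifnot(inherits(mirna_matrix, "time_course_matrix"),
            inherits(gene_matrix, "time_course_matrix"))
  thresholds <- as_screen_thresholds(thresholds)
  if (inherits(mirnas, "mirna_record")) mirnas <- list(mirnas)
  stopifnot(length(mirnas) >= 1L,
            all(vapply(mirnas, inherits, logical(1L), "mirna_record")))
  if (!identical(mirna_matrix$timepoints$label, gene_matrix$timepoints$label))
    stop("miRNA and gene matrices are over different timepoints",
         call. = FALSE)
  if (!tf_id %in% entity_ids(gene_matrix))
    stop("TF '", tf_id, "' is absent from the gene expression matrix",
         call. = FALSE)
  utr_seqs <- as_utr_set(utrs)
  if (!tf_id %in% names(utr_seqs))
    stop("TF '", tf_id, "' has no UTR record; the miRNA-TF edge cannot ",
         "be evaluated", call. = FALSE)
  if (is.null(tf_targets) && (is.null(peaks) || is.null(annotation)))
    stop("supply either `tf_targets` or both `peaks` and `annotation`",
         call. = FALSE)

  # TF -> target evidence channel
  if (!is.null(tf_targets)) {
    evidence_set <- if (is.character(tf_targets) && length(tf_targets) == 1L &&
                        file.exists(tf_targets)) read_target_list(tf_targets)
                    else as.character(tf_targets)
    evidence_kind <- "target_list"
  } else {
    evidence_set <- assign_chip_targets(peaks, annotation, window_bp)
    evidence_kind <- "chip_peak"
  }

  log <- list()
  note <- function(entity, stage, reason, value = NA_real_) {
    log[[length(log) + 1L]] <<- data.frame(
      entity = entity, stage = stage, reason = reason,
      value = as.numeric(value), stringsAsFactors = FALSE)
  }

  mir_means <- replicate_means(mirna_matrix)
  gene_means <- replicate_means(gene_matrix)
  mir_profile <- function(id) profile_from_means(id, mirna_matrix, mir_means)
  gene_profile <- function(id) profile_from_means(id, gene_matrix, gene_means)

  # --- miRNA cascade: expression, then fold -------------------------------
  mirna_names <- vapply(mirnas, `[[`, character(1L), "name")
  if (anyDuplicated(mirna_names))
    stop("duplicate miRNA names in `mirnas`", call. = FALSE)
  missing_m <- setdiff(mirna_names, entity_ids(mirna_matrix))
  if (length(missing_m))
    stop("miRNA(s) absent from the miRNA expression matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)

  mir_expressed <- character(0); mir_regulated <- character(0)
  for (id in mirna_names) {
    p <- mir_profile(id)
    if (!passes_expression(p, thresholds$min_mirna_tpm, stat = expression_stat)) {
      note(id, "mirna_expression", "below min_mirna_tpm", max(p$means))
      next
    }
    mir_expressed <- c(mir_expressed, id)
    fc <- fold_change(p, thresholds, method = fold_method)
    if (fc > 1 / thresholds$min_fold_change) {
      note(id, "mirna_fold", "not downregulated min_fold_change-fold", fc)
      next
    }
    mir_regulated <- c(mir_regulated, id)
  }

  # --- gene cascade: expression, then fold (TF handled like any gene) -----
  gene_names <- entity_ids(gene_matrix)
  gene_expressed <- character(0); gene_regulated <- character(0)
  gene_fold_v <- setNames(rep(NA_real_, length(gene_names)), gene_names)
  for (id in gene_names) {
    p <- gene_profile(id)
    if (!passes_expression(p, thresholds$min_promoter_tpm,
                           stat = expression_stat)) {
      note(id, "gene_expression", "below min_promoter_tpm", max(p$means))
      next
    }
    gene_expressed <- c(gene_expressed, id)
    fc <- fold_change(p, thresholds, method = fold_method)
    gene_fold_v[id] <- fc
    if (fc < thresholds$min_fold_change) {
      note(id, "gene_fold", "not upregulated min_fold_change-fold", fc)
      next
    }
    gene_regulated <- c(gene_regulated, id)
  }

  # --- per-miRNA: TF edge, then targets -----------------------------------
  site_count <- function(mirna, gid) {
    if (!gid %in% names(utr_seqs)) return(NA_integer_)
    h <- find_seed_sites(gid, utr_seqs[[gid]], mirna, mask = mask)
    sum(h$site_type %in% allowed_types)
  }

  loops <- list()
  n_pairs_anticorrelated <- 0L
  for (mi in mirnas) {
    id <- mi$name
    if (!id %in% mir_regulated) next
    mp <- mir_profile(id)
    mfc <- fold_change(mp, thresholds, method = fold_method)

    # TF edge: must survive the gene cascade, carry seed sites, and
    # (by default) anti-correlate with the miRNA
    if (!tf_id %in% gene_regulated) {
      note(paste(id, tf_id, sep = "~"), "tf_check",
           "TF failed the expression/fold cascade")
      next
    }
    tf_sites <- site_count(mi, tf_id)
    if (is.na(tf_sites) || tf_sites < min_sites) {
      note(paste(id, tf_id, sep = "~"), "tf_check",
           "TF UTR lacks the required seed sites", tf_sites)
      next
    }
    r_tf <- suppressWarnings(pearson_r(mp, gene_profile(tf_id),
                                       method = correlation_method))
    if (tf_correlation_filter &&
        (is.na(r_tf) || r_tf > thresholds$max_correlation)) {
      note(paste(id, tf_id, sep = "~"), "tf_check",
           "miRNA-TF correlation above max_correlation", r_tf)
      next
    }

    for (gid in setdiff(gene_regulated, tf_id)) {
      gp <- gene_profile(gid)
      r <- suppressWarnings(pearson_r(mp, gp, method = correlation_method))
      if (is.na(r)) {
        note(paste(id, gid, sep = "~"), "correlation",
             "undefined correlation (zero-variance profile)")
        next
      }
      if (r > thresholds$max_correlation) {
        note(paste(id, gid, sep = "~"), "correlation",
             "correlation above max_correlation", r)
        next
      }
      n_pairs_anticorrelated <- n_pairs_anticorrelated + 1L
      ns <- site_count(mi, gid)
      if (is.na(ns)) {
        note(paste(id, gid, sep = "~"), "seed_site", "gene has no UTR record")
        next
      }
      if (ns < min_sites) {
        note(paste(id, gid, sep = "~"), "seed_site",
             "too few canonical seed sites", ns)
        next
      }
      if (!gid %in% evidence_set) {
        note(paste(id, gid, sep = "~"), "chip_evidence",
             paste0("no TF->target evidence (", evidence_kind, ")"))
        next
      }
      loops[[length(loops) + 1L]] <- data.frame(
        mirna = id, tf = tf_id, target = gid,
        mirna_fold = mfc, tf_fold = gene_fold_v[[tf_id]],
        target_fold = gene_fold_v[[gid]],
        r_mirna_tf = r_tf, r_mirna_target = r,
        n_sites_tf = tf_sites, n_sites_target = ns,
        tf_target_evidence = evidence_kind,
        stringsAsFactors = FALSE)
    }
  }

  loops <- if (length(loops)) do.call(rbind, loops) else empty_loop_table()
  loops <- loops[order(loops$mirna, loops$target), , drop = FALSE]
  rownames(loops) <- NULL

  report <- new_screen_report(
    counts = c(n_mirnas_input = length(mirna_names),
               n_mirnas_expressed = length(mir_expressed),
               n_mirnas_regulated = length(mir_regulated),
               n_genes_input = length(gene_names),
               n_genes_expressed = length(gene_expressed),
               n_genes_regulated = length(gene_regulated),
               n_pairs_anticorrelated = n_pairs_anticorrelated,
               n_loops = nrow(loops)),
    log = if (length(log)) do.call(rbind, log) else empty_screen_log(),
    thresholds = thresholds)
  list(loops = loops, report = report)
}

empty_loop_table <- function() {
  data.frame(mirna = character(0), tf = character(0), target = character(0),
             mirna_fold = numeric(0), tf_fold = numeric(0),
             target_fold = numeric(0), r_mirna_tf = numeric(0),
             r_mirna_target = numeric(0), n_sites_tf = integer(0),
             n_sites_target = integer(0), tf_target_evidence = character(0),
             stringsAsFactors = FALSE)
}

empty_screen_log <- function() {
  data.frame(entity = character(0), stage = character(0),
             reason = character(0), value = numeric(0),
             stringsAsFactors = FALSE)
}

new_screen_report <- function(counts, log, thresholds) {
  structure(list(counts = counts, log = log, thresholds = thresholds),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(funnel_report(x), sep = "\n")
  invisible(x)
}

#' Render the screen's filter funnel as text
#'
#' One line per cascade stage with the number of surviving entities,
#' followed by the per-entity exclusion log.
#'
#' @param report A `screen_report` from [screen_ffls()].
#' @return Character vector of report lines.
#' @export
funnel_report <- function(report) {
  stopifnot(inherits(report, "screen_report"))
  cnt <- report$counts
  lines <- c(
    "FFL screen funnel",
    sprintf("  miRNAs: %d input -> %d expressed -> %d downregulated",
            cnt[["n_mirnas_input"]], cnt[["n_mirnas_expressed"]],
            cnt[["n_mirnas_regulated"]]),
    sprintf("  genes:  %d input -> %d expressed -> %d upregulated",
            cnt[["n_genes_input"]], cnt[["n_genes_expressed"]],
            cnt[["n_genes_regulated"]]),
    sprintf("  miRNA-gene pairs anti-correlated: %d",
            cnt[["n_pairs_anticorrelated"]]),
    sprintf("  candidate loops emitted: %d", cnt[["n_loops"]]))
  if (nrow(report$log)) {
    lines <- c(lines, "  exclusions:")
    lines <- c(lines, sprintf("    %-24s %-16s %s%s",
                              report$log$entity, report$log$stage,
                              report$log$reason,
                              ifelse(is.na(report$log$value), "",
                                     sprintf(" (%.4g)", report$log$value))))
  }
  lines
}

#' Write the candidate-loop table
#'
#' One row per loop; real-valued columns are written with 4 decimals.
#' Row order is already deterministic (miRNA, then target).
#'
#' @param loops Loop data frame from [screen_ffls()].
#' @param path Output TSV path.
#' @param header Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_ffl_table <- function(loops, path, header = NULL) {
  stopifnot(is.data.frame(loops))
  out <- loops
  for (cn in c("mirna_fold", "tf_fold", "target_fold",
               "r_mirna_tf", "r_mirna_target"))
    out[[cn]] <- sprintf("%.4f", out[[cn]])
  if (nrow(out) == 0L) out <- out[0L, , drop = FALSE]
  write_tsv_atomic(out, path, header = header)
}

#' Read back a candidate-loop table
#'
#' @param path TSV written by [write_ffl_table()].
#' @return Loop data frame (reals at the written 4-decimal precision).
#' @export
read_ffl_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_loop_table())
  df
}

#' Re-check every emitted loop against the thresholds it was screened
#' under
#'
#' Self-consistency audit: verifies that the evidence values stored on
#' each loop satisfy the screen's predicates. Used by the test suite;
#' returns `TRUE` invisibly or stops with the first violation.
#'
#' @param loops Loop data frame from [screen_ffls()].
#' @param thresholds The [screen_thresholds()] the screen ran with.
#' @param min_sites Minimum seed-site count used.
#' @return `TRUE` (invisibly) when every loop is consistent.
#' @export
audit_loops <- function(loops, thresholds = screen_thresholds(),
                        min_sites = 1L) {
  thresholds <- as_screen_thresholds(thresholds)
  for (i in seq_len(nrow(loops))) {
    l <- loops[i, ]
    ok <- l$mirna_fold <= 1 / thresholds$min_fold_change &&
      l$tf_fold >= thresholds$min_fold_change &&
      l$target_fold >= thresholds$min_fold_change &&
      l$r_mirna_target <= thresholds$max_correlation &&
      l$n_sites_tf >= min_sites && l$n_sites_target >= min_sites &&
      l$target != l$tf
    if (!ok)
      stop("loop ", l$mirna, " -> ", l$target,
           " violates the thresholds it was screened under", call. = FALSE)
  }
  invisible(TRUE)
}
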