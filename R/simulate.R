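#' Configuration for the synthetic study generator
#'
#' Describes a synthetic adipogenesis-style study: a differentiation
#' time course (day 0 to day 12) measured in replicates, one screened
#' miRNA driving a configurable number of planted coherent type-2
#' loops, and one decoy gene per screen filter. TPM scales default to
#' the regimes the screen thresholds address: loop miRNAs start at
#' 20,000 TPM (comfortably above the 10,000 TPM filter) and fall
#' `down_fold`-fold; loop genes start at 300 TPM and rise
#' `up_fold`-fold.
#'
#' @param n_timepoints Number of timepoints, `>= 3`; default 6 spanning
#'   day 0-12.
#' @param n_replicates Replicates per timepoint; default 3.
#' @param n_mirnas Total miRNAs (first drives the loops, the rest are
#'   dim flat background); default 2.
#' @param n_genes Total genes including the TF; default 9 = TF + 3 loop
#'   targets + 5 decoys.
#' @param n_planted_loops Loops planted for the first miRNA; must be
#'   `<= n_genes - 1` (the TF occupies one slot). Default 3.
#' @param mirna_base_tpm Loop-miRNA expression at day 0; default 20000.
#' @param gene_base_tpm Loop-gene expression at day 0; default 300.
#' @param down_fold,up_fold End-to-end fold changes of loop miRNAs
#'   (down) and loop genes (up); default 4.
#' @param noise_cv Replicate coefficient of variation (multiplicative
#'   Gaussian noise, truncated at zero); default 0.05.
#' @param utr_length Length of generated 3'UTRs in nt; default 2000.
#' @param decoy_fraction Fraction of the non-TF, non-target gene slots
#'   filled with per-filter decoys (the rest are dim flat background
#'   genes); default 1.
#' @param rng_seed Base seed for all generator randomness.
#' @param mirna Optional [mirna_record()] used as the loop miRNA;
#'   defaults to hsa-miR-27b-3p from the packaged reference records.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_timepoints = 6L, n_replicates = 3L,
                             n_mirnas = 2L, n_genes = 9L,
                             n_planted_loops = 3L,
                             mirna_base_tpm = 20000, gene_base_tpm = 300,
                             down_fold = 4, up_fold = 4,
                             noise_cv = 0.05, utr_length = 2000L,
                             decoy_fraction = 1, rng_seed = 1L,
                             mirna = NULL) {
  cfg <- list(n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes),
              n_planted_loops = as.integer(n_planted_loops),
              mirna_base_tpm = as.numeric(mirna_base_tpm),
              gene_base_tpm = as.numeric(gene_base_tpm),
              down_fold = as.numeric(down_fold),
              up_fold = as.numeric(up_fold),
              noise_cv = as.numeric(noise_cv),
              utr_length = as.integer(utr_length),
              decoy_fraction = as.numeric(decoy_fraction),
              rng_seed = as.integer(rng_seed),
              mirna = mirna)
  with(cfg, {
    if (n_timepoints < 3L) stop("need at least 3 timepoints", call. = FALSE)
    if (n_replicates < 1L || n_mirnas < 1L || n_genes < 2L ||
        n_planted_loops < 1L)
      stop("all generator counts must be positive", call. = FALSE)
    if (n_planted_loops > n_genes - 1L)
      stop("n_planted_loops must be <= n_genes - 1 (the TF occupies ",
           "one gene slot)", call. = FALSE)
    if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
    if (decoy_fraction < 0 || decoy_fraction > 1)
      stop("decoy_fraction must lie in [0, 1]", call. = FALSE)
    if (utr_length < 200L) stop("utr_length too short", call. = FALSE)
    if (down_fold < 1 || up_fold < 1)
      stop("fold parameters must be >= 1", call. = FALSE)
  })
  if (is.null(cfg$mirna)) cfg$mirna <- mir27_records()[["hsa-miR-27b-3p"]]
  stopifnot(inherits(cfg$mirna, "mirna_record"))
  structure(cfg, class = "generator_config")
}

DECOY_CLASSES <- c("flat", "dim", "bump", "no_site", "no_peak")

# which screen stage each decoy class is designed to fail
DECOY_FAILURE_STAGE <- c(flat = "gene_fold", dim = "gene_expression",
                         bump = "correlation", no_site = "seed_site",
                         no_peak = "chip_evidence")

# roles whose UTRs carry a planted seed site / whose TSS gets a peak
roles_with_sites <- function() c("tf", "target", "flat", "dim", "bump", "no_peak")
roles_with_peaks <- function() c("target", "flat", "dim", "bump", "no_site")

#' Generate miRNA and gene time-course matrices with planted loops
#'
#' Builds the two expression matrices of a synthetic study. The loop
#' miRNA decays geometrically from `mirna_base_tpm` by `down_fold` end
#' to end; loop genes (and the TF) are negative affine transforms of
#' the miRNA profile rising from about `gene_base_tpm` by exactly
#' `up_fold`, so that in the noise-free limit their correlation with
#' the miRNA is exactly -1, the profiles are monotone, and endpoint
#' and extremum fold changes coincide. Replicate values are the
#' timepoint mean times `1 + N(0, noise_cv)`, truncated at zero.
#'
#' Decoy genes cover the screen's filters one each: `flat` (high but
#' unchanging, fails the fold filter), `dim` (rising but below the
#' expression threshold), `bump` (rising and expressed but with a
#' non-monotone bump calibrated to correlation about -0.90 with the
#' miRNA), `no_site` (passes all expression filters but its UTR will
#' carry no seed site), `no_peak` (passes everything but gets no ChIP
#' peak).
#'
#' @param config A [generator_config()].
#' @return List with `mirna_matrix`, `gene_matrix`
#'   ([time_course_matrix()] objects) and `truth` (a `planted_truth`
#'   object listing the planted loops and per-gene roles).
#' @export
generate_time_courses <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$rng_seed)
  nt <- config$n_timepoints
  times <- seq(0, 12, length.out = nt)
  tp <- data.frame(label = paste0("day", formatC(times, format = "g")),
                   time = times)

  # loop miRNA: geometric decay, exact end-to-end fold 1/down_fold
  mir_mean <- config$mirna_base_tpm *
    config$down_fold^(-(seq_len(nt) - 1) / (nt - 1))

  anti_affine <- function(base, fold) {
    # negative affine transform of the miRNA profile: exact fold 'fold'
    # up end-to-end, correlation with the miRNA exactly -1
    b <- (base * fold - base) / (mir_mean[nt] - mir_mean[1L])
    base + b * (mir_mean - mir_mean[1L])
  }

  # gene roles: TF, loop targets, decoys (cycling), background
  n_free <- config$n_genes - 1L - config$n_planted_loops
  n_decoys <- round(config$decoy_fraction * n_free)
  roles <- c("tf",
             rep("target", config$n_planted_loops),
             DECOY_CLASSES[(seq_len(n_decoys) - 1L) %% length(DECOY_CLASSES) + 1L],
             rep("background", n_free - n_decoys))
  gene_ids <- c("TF1",
                sprintf("G%02d", seq_len(config$n_planted_loops)),
                if (n_decoys) sprintf("D%02d", seq_len(n_decoys)),
                if (n_free - n_decoys)
                  sprintf("B%02d", seq_len(n_free - n_decoys)))
  gene_roles <- data.frame(gene = gene_ids, role = roles,
                           designed_failure =
                             unname(DECOY_FAILURE_STAGE[roles]),
                           stringsAsFactors = FALSE)

  gene_means <- matrix(0, nrow = length(gene_ids), ncol = nt,
                       dimnames = list(gene_ids, tp$label))
  scale_i <- 0L
  for (i in seq_along(gene_ids)) {
    role <- roles[i]
    if (role %in% c("tf", "target", "no_site", "no_peak")) {
      scale_i <- scale_i + 1L
      base <- config$gene_base_tpm * (1 + 0.05 * (scale_i - 1L))
      gene_means[i, ] <- anti_affine(base, config$up_fold)
    } else if (role == "flat") {
      gene_means[i, ] <- rep(config$gene_base_tpm * config$up_fold, nt)
    } else if (role == "dim") {
      gene_means[i, ] <- anti_affine(config$gene_base_tpm * 0.05,
                                     config$up_fold)
    } else if (role == "bump") {
      gene_means[i, ] <- bump_profile(anti_affine(config$gene_base_tpm,
                                                  config$up_fold),
                                      mir_mean, target_r = -0.90)
    } else { # background
      gene_means[i, ] <- rep(config$gene_base_tpm * 0.1, nt)
    }
  }

  # background miRNAs: dim and flat, fail the expression filter; each
  # gets a random mature sequence so it can be screened like any other
  mirna_records <- c(list(config$mirna),
                     lapply(seq_len(config$n_mirnas - 1L), function(i)
                       mirna_record(sprintf("bg-miR-%02d", i),
                                    paste(sample(c("a", "c", "g", "u"), 21L,
                                                 replace = TRUE),
                                          collapse = ""))))
  mirna_ids <- vapply(mirna_records, `[[`, character(1L), "name")
  mir_means <- rbind(mir_mean,
                     matrix(rep(500, (config$n_mirnas - 1L) * nt),
                            ncol = nt))
  rownames(mir_means) <- mirna_ids
  colnames(mir_means) <- tp$label

  add_noise <- function(means) {
    nr <- config$n_replicates
    vals <- matrix(0, nrow = nrow(means), ncol = nt * nr,
                   dimnames = list(rownames(means),
                                   tc_column_names(tp$label, nr)))
    for (j in seq_len(nt)) for (k in seq_len(nr)) {
      noise <- if (config$noise_cv > 0)
        rnorm(nrow(means), 0, config$noise_cv) else 0
      vals[, (j - 1L) * nr + k] <- pmax(0, means[, j] * (1 + noise))
    }
    vals
  }

  mirna_matrix <- time_course_matrix(add_noise(mir_means), tp,
                                     config$n_replicates)
  gene_matrix <- time_course_matrix(add_noise(gene_means), tp,
                                    config$n_replicates)

  truth <- structure(
    list(loops = data.frame(mirna = config$mirna$name, tf = "TF1",
                            target = gene_ids[roles == "target"],
                            stringsAsFactors = FALSE),
         tf_id = "TF1",
         mirna = config$mirna,
         mirna_records = setNames(mirna_records, mirna_ids),
         mirna_ids = mirna_ids,
         gene_roles = gene_roles,
         mean_profiles = list(mirna = mir_means, gene = gene_means),
         sites = NULL, peaks = NULL,
         config = unclass(config)[setdiff(names(config), "mirna")]),
    class = "planted_truth")
  list(mirna_matrix = mirna_matrix, gene_matrix = gene_matrix,
       truth = truth)
}

# add a bump to the middle timepoint of a rising profile until its
# Pearson correlation with the miRNA profile reaches target_r;
# endpoints are untouched so the end-to-end fold change is preserved
bump_profile <- function(gene_mean, mir_mean, target_r = -0.90) {
  mid <- ceiling(length(gene_mean) / 2)
  if (mid == 1L || mid == length(gene_mean)) mid <- 2L
  r_at <- function(b) {
    g <- gene_mean; g[mid] <- g[mid] + b
    cor(g, mir_mean)
  }
  span <- diff(range(gene_mean))
  hi <- span
  while (r_at(hi) < target_r && hi < 1e6 * span) hi <- hi * 2
  b <- stats::uniroot(function(b) r_at(b) - target_r,
                      lower = 0, upper = hi, tol = 1e-10)$root
  out <- gene_mean
  out[mid] <- out[mid] + b
  out
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth: %d loop(s), TF %s, miRNA %s\n",
              nrow(x$loops), x$tf_id, x$mirna$name))
  cat("  targets:", paste(x$loops$target, collapse = ", "), "\n")
  decoys <- x$gene_roles[x$gene_roles$role %in% DECOY_CLASSES, ]
  if (nrow(decoys))
    cat("  decoys: ", paste(sprintf("%s(%s)", decoys$gene, decoys$role),
                            collapse = ", "), "\n")
  invisible(x)
}

#' TSS annotation for the synthetic genes
#'
#' Places every gene on one chromosome with TSSs spaced five windows
#' apart, so peak-to-gene windows never collide.
#'
#' @param truth A `planted_truth` object.
#' @param window_bp Window half-width the study will be screened with.
#' @return Annotation data frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
generate_tss_annotation <- function(truth, window_bp = 50000L) {
  stopifnot(inherits(truth, "planted_truth"))
  n <- nrow(truth$gene_roles)
  data.frame(gene_id = truth$gene_roles$gene,
             chrom = "chr1",
             tss = 2L * as.integer(window_bp) +
               (seq_len(n) - 1L) * 5L * as.integer(window_bp),
             strand = "+", stringsAsFactors = FALSE)
}

#' Generate 3'UTR sequences with planted seed sites
#'
#' Each gene receives a random background sequence resampled until it
#' contains no occurrence of any of the loop miRNA's three canonical
#' site patterns; genes whose role requires a miRNA repression edge
#' (the TF, the loop targets, and the flat/dim/bump/no-peak decoys)
#' then get one 8mer site written in at a recorded position. `no_site`
#' decoys and background genes keep the pattern-free background. The
#' planting is re-verified so that each planted UTR carries exactly one
#' canonical site.
#'
#' @param truth A `planted_truth` object.
#' @param mirna The loop [mirna_record()]; defaults to the one recorded
#'   in `truth`.
#' @param config The [generator_config()] (for `utr_length` and the
#'   RNG seed).
#' @return List with `utrs` (a named `Biostrings::DNAStringSet`) and
#'   `sites` (data frame `gene`, `start`, `end`, `site_type` of planted
#'   sites, 0-based half-open).
#' @export
generate_utrs <- function(truth, mirna = truth$mirna,
                          config = do.call(generator_config, truth$config)) {
  stopifnot(inherits(truth, "planted_truth"),
            inherits(mirna, "mirna_record"))
  set.seed(config$rng_seed + 101L)
  L <- config$utr_length
  patterns <- site_patterns(mirna)
  pat7 <- patterns[c("7mer-m8", "7mer-A1")]  # absence of both implies no 8mer

  pattern_free <- function() {
    for (try in seq_len(1000L)) {
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      subj <- Biostrings::DNAString(s)
      if (all(vapply(pat7, function(p)
        Biostrings::countPattern(p, subj) == 0L, logical(1L))))
        return(s)
    }
    stop("could not draw a pattern-free background UTR in 1000 attempts; ",
         "pathological configuration", call. = FALSE)
  }

  plant <- function(s) {
    p8 <- patterns[["8mer"]]
    for (try in seq_len(1000L)) {
      pos <- sample(50:(L - nchar(p8) - 50L), 1L)  # 0-based start
      cand <- paste0(substr(s, 1L, pos), p8,
                     substr(s, pos + nchar(p8) + 1L, L))
      subj <- Biostrings::DNAString(cand)
      # junctions must not create extra matches: exactly one of each 7mer
      if (all(vapply(pat7, function(p)
        Biostrings::countPattern(p, subj) == 1L, logical(1L))))
        return(list(seq = cand, start = pos))
      s <- pattern_free()
    }
    stop("could not plant a clean seed site in 1000 attempts", call. = FALSE)
  }

  seqs <- character(nrow(truth$gene_roles))
  names(seqs) <- truth$gene_roles$gene
  sites <- list()
  for (i in seq_len(nrow(truth$gene_roles))) {
    g <- truth$gene_roles$gene[i]
    role <- truth$gene_roles$role[i]
    s <- pattern_free()
    if (role %in% roles_with_sites()) {
      pl <- plant(s)
      s <- pl$seq
      sites[[length(sites) + 1L]] <- data.frame(
        gene = g, start = pl$start, end = pl$start + 8L,
        site_type = "8mer", stringsAsFactors = FALSE)
    }
    seqs[i] <- s
  }
  list(utrs = Biostrings::DNAStringSet(seqs),
       sites = if (length(sites)) do.call(rbind, sites) else
         data.frame(gene = character(0), start = integer(0),
                    end = integer(0), site_type = character(0),
                    stringsAsFactors = FALSE))
}

#' Generate ChIP peaks around target TSSs
#'
#' One 200 bp peak is centered within `window_bp/2` of the TSS of every
#' loop target and of the decoys designed to pass the ChIP filter;
#' `no_peak` decoys and background genes receive none. Background
#' peaks are placed midway between consecutive TSSs, at least
#' `2 * window_bp` from every TSS, so they enter no gene's evidence at
#' the generating window.
#'
#' @param truth A `planted_truth` object.
#' @param annotation TSS annotation from [generate_tss_annotation()].
#' @param window_bp Window half-width; peaks land within `window_bp/2`
#'   of their TSS. Must be at least 200.
#' @param config The [generator_config()] (RNG seed).
#' @return Data frame of peaks (`chrom`, `start`, `end`, 0-based
#'   half-open) with an attribute-free extra column `peak_for` naming
#'   the gene a peak was planted for (`NA` for background peaks).
#' @export
generate_peaks <- function(truth, annotation, window_bp = 50000L,
                           config = do.call(generator_config, truth$config)) {
  stopifnot(inherits(truth, "planted_truth"), window_bp >= 200L)
  set.seed(config$rng_seed + 202L)
  window_bp <- as.integer(window_bp)
  ann <- as_tss_table(annotation)
  peaked <- truth$gene_roles$gene[truth$gene_roles$role %in% roles_with_peaks()]
  peaks <- list()
  for (g in peaked) {
    tss <- ann$tss[ann$gene_id == g]
    if (!length(tss)) stop("gene missing from annotation: ", g, call. = FALSE)
    offset <- sample(seq(-window_bp %/% 2L, window_bp %/% 2L), 1L)
    center <- tss + offset
    if (center < 100L)
      stop("chromosome too short to place a peak for ", g, call. = FALSE)
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = "chr1", start = center - 100L, end = center + 100L,
      peak_for = g, stringsAsFactors = FALSE)
  }
  # background peaks midway between consecutive TSSs (2.5 windows away)
  tss_sorted <- sort(ann$tss)
  if (length(tss_sorted) > 1L) {
    mids <- head(tss_sorted, -1L) + diff(tss_sorted) %/% 2L
    for (m in mids[seq_len(min(3L, length(mids)))]) {
      stopifnot(all(abs(m - ann$tss) >= 2L * window_bp))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = "chr1", start = m - 100L, end = m + 100L,
        peak_for = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, peaks)
}

#' Default planted effects for the synthetic clinical cohort
#'
#' Three phenotypes with opposed-sign standardized effects of the two
#' expression regressors, echoing the pattern of clinical adipose
#' phenotype tables (one log10-scaled measure included).
#'
#' @return Data frame with columns `phenotype`, `beta1`, `beta2`,
#'   `noise_sd`, `log10`.
#' @export
default_cohort_effects <- function() {
  data.frame(
    phenotype = c("bmi", "body_fat", "insulin_sensitivity"),
    beta1 = c(-0.8, -0.72, 0.43),
    beta2 = c(0.7, 0.73, -0.56),
    noise_sd = c(0.5, 0.5, 0.8),
    log10 = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic clinical cohort with planted expression effects
#'
#' Two expression regressors are drawn standard normal (optionally
#' correlated by `rho`); each phenotype is `beta1 * x1 + beta2 * x2 +
#' N(0, noise_sd)`. Phenotypes flagged `log10` are exponentiated base
#' 10 after generation, so the analysis's log10 transform recovers the
#' linear model.
#'
#' @param n_subjects Number of rows, `>= 10`; default 56.
#' @param effects Data frame as [default_cohort_effects()].
#' @param rho Correlation between the two regressors, in `(-1, 1)`.
#' @param rng_seed RNG seed.
#' @param regressor_names Names of the two expression columns.
#' @return List with `cohort` (data frame: `subject_id`, phenotype
#'   columns, regressor columns) and `effects` (the ground truth,
#'   including `log10_cols`).
#' @export
generate_cohort <- function(n_subjects = 56L,
                            effects = default_cohort_effects(),
                            rho = 0, rng_seed = 1L,
                            regressor_names = c("PPARG", "SCAMP3")) {
  if (n_subjects < 10L) stop("n_subjects must be >= 10", call. = FALSE)
  if (rho <= -1 || rho >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  stopifnot(is.data.frame(effects),
            all(c("phenotype", "beta1", "beta2", "noise_sd", "log10") %in%
                  names(effects)),
            length(regressor_names) == 2L)
  set.seed(rng_seed)
  x1 <- rnorm(n_subjects)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n_subjects)
  cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)))
  for (i in seq_len(nrow(effects))) {
    y <- effects$beta1[i] * x1 + effects$beta2[i] * x2 +
      rnorm(n_subjects, 0, effects$noise_sd[i])
    if (effects$log10[i]) y <- 10^y
    cohort[[effects$phenotype[i]]] <- y
  }
  cohort[[regressor_names[1L]]] <- x1
  cohort[[regressor_names[2L]]] <- x2
  eff <- effects
  eff$regressor1 <- regressor_names[1L]
  eff$regressor2 <- regressor_names[2L]
  list(cohort = cohort, effects = eff,
       log10_cols = effects$phenotype[effects$log10])
}

#' Generate one complete synthetic study
#'
#' Convenience wrapper running the whole generator chain: time
#' courses, TSS annotation, UTRs with planted sites, ChIP peaks and a
#' clinical cohort, all deterministic under `config$rng_seed`.
#'
#' @param config A [generator_config()].
#' @param window_bp ChIP window half-width used for TSS spacing and
#'   peak placement.
#' @param n_subjects Cohort size.
#' @return List with `mirna_matrix`, `gene_matrix`, `utrs`, `annotation`,
#'   `peaks`, `cohort`, `cohort_effects`, `cohort_log10_cols`, and the
#'   completed `truth` (now including planted `sites` and `peaks`).
#' @export
simulate_ffl_study <- function(config = generator_config(),
                               window_bp = 50000L, n_subjects = 56L) {
  tc <- generate_time_courses(config)
  annotation <- generate_tss_annotation(tc$truth, window_bp)
  utr <- generate_utrs(tc$truth, config = config)
  peaks <- generate_peaks(tc$truth, annotation, window_bp, config = config)
  coh <- generate_cohort(n_subjects = n_subjects,
                         rng_seed = config$rng_seed + 303L)
  truth <- tc$truth
  truth$sites <- utr$sites
  truth$peaks <- peaks
  list(mirna_matrix = tc$mirna_matrix, gene_matrix = tc$gene_matrix,
       utrs = utr$utrs, annotation = annotation,
       peaks = peaks[, c("chrom", "start", "end")],
       cohort = coh$cohort, cohort_effects = coh$effects,
       cohort_log10_cols = coh$log10_cols,
       truth = truth, window_bp = as.integer(window_bp))
}

#' Write a simulated study to disk
#'
#' Emits the file set a real screen would consume: `mirna_expr.tsv`,
#' `gene_expr.tsv`, `utrs.fa`, `peaks.bed`, `tss.tsv`, `cohort.tsv`,
#' plus machine-readable ground truth in `truth.json`.
#'
#' @param sim Result of [simulate_ffl_study()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header("simulate", seed = sim$truth$config$rng_seed)
  write_expression_table(sim$mirna_matrix, file.path(outdir, "mirna_expr.tsv"),
                         header = hdr)
  write_expression_table(sim$gene_matrix, file.path(outdir, "gene_expr.tsv"),
                         header = hdr)
  Biostrings::writeXStringSet(sim$utrs, file.path(outdir, "utrs.fa"))
  write_tsv_atomic(sim$peaks, file.path(outdir, "peaks.bed"),
                   col.names = FALSE)
  write_tsv_atomic(sim$annotation, file.path(outdir, "tss.tsv"), header = hdr)
  write_tsv_atomic(sim$cohort, file.path(outdir, "cohort.tsv"), header = hdr)
  truth <- sim$truth
  truth$mirna <- unclass(truth$mirna)
  truth$mirna_records <- lapply(truth$mirna_records, unclass)
  jsonlite::write_json(unclass(truth), file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(outdir)
}
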