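# Independent oracles and small fixture builders shared across tests.

# Pearson correlation by the closed-form product-moment formula,
# independent of stats::cor.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Reverse complement by explicit character operations.
oracle_revcomp <- function(s) {
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Exhaustive substring-comparison site scanner: every window of length
# 7 and 8 is compared to every pattern, then the canonical priority
# rule (8mer > 7mer-m8 > 7mer-A1, left to right, no double counting)
# is applied.
oracle_find_sites <- function(seq, patterns) {
  s <- toupper(chartr("uU", "tT", seq))
  hits <- NULL
  for (ty in c("8mer", "7mer-m8", "7mer-A1")) {
    p <- patterns[[ty]]
    w <- nchar(p)
    if (nchar(s) < w) next
    subs <- substring(s, 1:(nchar(s) - w + 1), w:nchar(s))
    at <- which(subs == p)
    if (length(at))
      hits <- rbind(hits, data.frame(start = at - 1L, end = at - 1L + w,
                                     site_type = ty,
                                     stringsAsFactors = FALSE))
  }
  if (is.null(hits)) return(hits)
  hits$priority <- match(hits$site_type, c("8mer", "7mer-m8", "7mer-A1"))
  hits <- hits[order(hits$priority, hits$start), ]
  keep <- logical(nrow(hits))
  acc <- NULL
  for (i in seq_len(nrow(hits))) {
    ok <- is.null(acc) ||
      !any(hits$start[i] < acc$end & hits$end[i] > acc$start)
    if (ok) {
      keep[i] <- TRUE
      acc <- rbind(acc, hits[i, c("start", "end")])
    }
  }
  out <- hits[keep, c("start", "end", "site_type")]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One-replicate noise-free time-course matrix from a named list of
# per-entity mean vectors.
toy_matrix <- function(profiles, times = NULL) {
  nt <- length(profiles[[1]])
  if (is.null(times)) times <- seq(0, 12, length.out = nt)
  tp <- data.frame(label = paste0("day", formatC(times, format = "g")),
                   time = times)
  vals <- do.call(rbind, profiles)
  rownames(vals) <- names(profiles)
  time_course_matrix(vals, tp, 1L)
}

toy_profile <- function(means, times = NULL, id = "x") {
  m <- toy_matrix(setNames(list(means), id), times)
  replicate_mean(m, id)
}

mir27a <- function() mir27_records()[["hsa-miR-27a-3p"]]
mir27b <- function() mir27_records()[["hsa-miR-27b-3p"]]

# Hand-built single-loop screen fixture: one miRNA 4-fold down from
# 20000 TPM, TF and target 4-fold up above 150 TPM, all profiles
# affine in time (hence exactly anti-correlated), 8mer sites planted
# in both UTRs, one peak at the target TSS.
single_loop_fixture <- function(target_means = seq(300, 1200, length.out = 6)) {
  mirna <- mir27a()
  pats <- site_patterns(mirna)
  p8 <- pats[["8mer"]]
  bg <- function(seed) {
    set.seed(seed)
    repeat {
      s <- random_dna(300)
      # no 7mer-m8 and no 7mer-A1 implies no 8mer either
      if (!grepl(pats[["7mer-m8"]], s, fixed = TRUE) &&
          !grepl(pats[["7mer-A1"]], s, fixed = TRUE))
        return(s)
    }
  }
  utrs <- c(TF1 = paste0(bg(11), p8, bg(12)),
            GENE1 = paste0(bg(13), p8, bg(14)))
  list(
    mirna = mirna,
    mirna_matrix = toy_matrix(list(`hsa-miR-27a-3p` =
                                     seq(20000, 5000, length.out = 6))),
    gene_matrix = toy_matrix(list(TF1 = seq(200, 800, length.out = 6),
                                  GENE1 = target_means)),
    utrs = utrs,
    annotation = data.frame(gene_id = c("TF1", "GENE1"), chrom = "chr1",
                            tss = c(100000L, 600000L), strand = "+",
                            stringsAsFactors = FALSE),
    peaks = data.frame(chrom = "chr1", start = 599900L, end = 600100L,
                       stringsAsFactors = FALSE))
}
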