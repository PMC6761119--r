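test_that("the miR-27 family records carry the expected seed", {
  recs <- mir27_records()
  expect_identical(seed_of(recs[["hsa-miR-27a-3p"]]), "ucacagu")
  expect_identical(seed_of(recs[["hsa-miR-27b-3p"]]), "ucacagu")
  expect_error(seed_of(mirna_record("x", "ucacagu")), "at least 8")
  expect_error(mirna_record("x", "ucacagtu"), "RNA")
})

test_that("canonical site patterns are the reverse complements of the seed", {
  pats <- site_patterns(mir27a())
  expect_identical(pats[["8mer"]], "ACTGTGAA")
  expect_identical(pats[["7mer-m8"]], "ACTGTGA")
  expect_identical(pats[["7mer-A1"]], "CTGTGAA")
  # against an independent reverse-complement oracle
  expect_identical(pats[["7mer-m8"]],
                   oracle_revcomp(toupper(chartr("u", "t", "ucacagu"))))
  expect_identical(oracle_revcomp(oracle_revcomp(pats[["7mer-m8"]])),
                   pats[["7mer-m8"]])

  homo <- site_patterns(mirna_record("homo", "aaaaaaaaaa"))
  expect_identical(unname(homo), c("TTTTTTTA", "TTTTTTT", "TTTTTTA"))

  # structural identities hold for arbitrary miRNAs
  set.seed(9)
  for (i in 1:25) {
    seq <- paste(sample(c("a", "c", "g", "u"), 12, replace = TRUE),
                 collapse = "")
    p <- site_patterns(mirna_record("r", seq))
    expect_identical(p[["8mer"]], paste0(p[["7mer-m8"]], "A"))
    expect_identical(substring(p[["8mer"]], 2), p[["7mer-A1"]])
  }
})

test_that("find_seed_sites locates and classifies canonical sites", {
  h <- find_seed_sites("u1", "GGACTGTGAACC", mir27a())
  expect_equal(nrow(h), 1L)
  expect_identical(h$site_type, "8mer")
  expect_equal(c(h$start, h$end), c(2L, 10L))

  expect_equal(nrow(find_seed_sites("u2", "GGGGGGGG", mir27a())), 0L)

  # U/T equivalence and soft-mask matching
  expect_equal(find_seed_sites("u3", "ggacugugaacc", mir27a())$site_type,
               "8mer")
  # hard masking turns lowercase into N, which never matches
  expect_equal(nrow(find_seed_sites("u3", "ggactgtgaacc", mir27a(),
                                    mask = "hard")), 0L)
  expect_equal(nrow(find_seed_sites("u4", "GGACTGNGAACC", mir27a())), 0L)
  expect_error(find_seed_sites("u5", "GGACTXTGAACC", mir27a()),
               "invalid character")

  # 7mer classification when the 8mer A is absent
  expect_identical(find_seed_sites("u6", "GGACTGTGACC", mir27a())$site_type,
                   "7mer-m8")
  expect_identical(find_seed_sites("u7", "GGCTGTGAACC", mir27a())$site_type,
                   "7mer-A1")
})

test_that("overlapping classifications resolve to the highest-priority type", {
  # an 8mer locus also contains a 7mer-m8 and a 7mer-A1: one hit only
  h <- find_seed_sites("u", "TTACTGTGAATT", mir27a())
  expect_identical(h$site_type, "8mer")
  # two tandem non-overlapping 8mers are both kept
  h2 <- find_seed_sites("u", "ACTGTGAAACTGTGAA", mir27a())
  expect_equal(h2$start, c(0L, 8L))
  expect_identical(h2$site_type, c("8mer", "8mer"))
})

test_that("scanner agrees with the exhaustive substring oracle", {
  pats <- site_patterns(mir27a())
  set.seed(101)
  for (i in 1:60) {
    # AT-rich alphabet makes seed-like matches much more frequent
    s <- paste(sample(c("A", "C", "G", "T", "A", "T"), 2000,
                      replace = TRUE), collapse = "")
    got <- find_seed_sites("u", s, mir27a())
    want <- oracle_find_sites(s, pats)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("start", "end", "site_type")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("planting a pattern in pattern-free background yields exactly one hit", {
  pats <- site_patterns(mir27b())
  set.seed(77)
  for (i in 1:25) {
    repeat {
      bg <- random_dna(500)
      if (!grepl(pats[["7mer-m8"]], bg, fixed = TRUE) &&
          !grepl(pats[["7mer-A1"]], bg, fixed = TRUE)) break
    }
    pos <- sample(10:480, 1)  # 0-based
    planted <- paste0(substr(bg, 1, pos), pats[["8mer"]],
                      substr(bg, pos + 9, 500))
    h <- find_seed_sites("u", planted, mir27b())
    h8 <- h[h$site_type == "8mer", ]
    expect_true(any(h8$start == pos))
  }
})

test_that("miR-27a-3p and miR-27b-3p give identical sites on any UTR", {
  set.seed(13)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T", "A", "T"), 1500,
                      replace = TRUE), collapse = "")
    expect_identical(find_seed_sites("u", s, mir27a()),
                     find_seed_sites("u", s, mir27b()))
  }
})

test_that("predict_mirna_targets applies site count and class filters", {
  pats <- site_patterns(mir27a())
  with_site <- paste0("GGGGGGGGGG", pats[["8mer"]], "GGGGGGGGGG")
  without <- "GGGGGGGGGGGGGGGGGGGGGGGGGGGG"
  utrs <- c(hit = with_site, miss = without)
  res <- predict_mirna_targets(mir27a(), utrs)
  expect_identical(res$targets, "hit")
  expect_identical(unique(res$hits$mirna_name), "hsa-miR-27a-3p")

  expect_length(predict_mirna_targets(mir27a(), utrs,
                                      min_sites = 2)$targets, 0L)

  only_a1 <- paste0("GGGGGGGGGG", pats[["7mer-A1"]], "GGGGGGGGGG")
  expect_length(predict_mirna_targets(mir27a(), c(g = only_a1),
                                      allowed_types = "8mer")$targets, 0L)

  expect_warning(empty <- predict_mirna_targets(mir27a(),
                                                character(0)),
                 "empty UTR")
  expect_length(empty$targets, 0L)

  # FASTA path input
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hit extra description", with_site, ">miss", without), fa)
  expect_identical(predict_mirna_targets(mir27a(), fa)$targets, "hit")
})

test_that("ChIP peaks assign targets within a TSS window", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chrom = c("chr1", "chr2", "chr1"),
                    tss = c(1100L, 1100L, 150L), strand = "+",
                    stringsAsFactors = FALSE)
  pk <- data.frame(chrom = "chr1", start = 1000L, end = 1200L,
                   stringsAsFactors = FALSE)
  expect_identical(assign_chip_targets(pk, ann, 0L), "g1")
  expect_identical(assign_chip_targets(pk, ann, 1000L), c("g1", "g3"))
  # chromosome mismatch excludes regardless of window
  expect_false("g2" %in% assign_chip_targets(pk, ann, 10000000L))
  # half-open peak [0,100) reaches TSSs at 50 and 150 under a 50 kb
  # window; at window 0 only the contained TSS qualifies
  pk2 <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  ann2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     tss = c(50L, 150L), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  expect_identical(assign_chip_targets(pk2, ann2, 50000L), c("a", "b"))
  expect_identical(assign_chip_targets(pk2, ann2, 0L), "a")
  expect_error(assign_chip_targets(data.frame(chrom = "c", start = 5,
                                              end = 5), ann, 0L),
               "start < end")
})

test_that("target assignment is monotone in the window size", {
  set.seed(55)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:15), chrom = "chr1",
                    tss = sort(sample.int(1e6, 15)), strand = "+",
                    stringsAsFactors = FALSE)
  pk <- data.frame(chrom = "chr1",
                   start = sort(sample.int(1e6, 10)))
  pk$end <- pk$start + 200L
  prev <- character(0)
  for (w in c(0L, 100L, 1000L, 10000L, 100000L)) {
    cur <- assign_chip_targets(pk, ann, w)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("target lists are read, deduplicated and whitespace-tolerant", {
  genes <- mir27b_candidate_targets()
  expect_length(genes, 10L)
  expect_true(all(c("PPARG", "SCAMP3", "ABCA1") %in% genes))

  path <- withr::local_tempfile()
  writeLines(c("gene_id", "A", "B", "  ", "A", "", "C "), path)
  expect_identical(read_target_list(path), c("A", "B", "C"))
  writeLines(c("", "   "), path)
  expect_warning(empty <- read_target_list(path), "empty target list")
  expect_length(empty, 0L)
})

test_that("BED peak files round-trip into the assignment step", {
  sim <- simulate_ffl_study(generator_config(noise_cv = 0, rng_seed = 21))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  assigned <- assign_chip_targets(file.path(dir, "peaks.bed"),
                                  file.path(dir, "tss.tsv"),
                                  sim$window_bp)
  roles <- sim$truth$gene_roles
  expect_setequal(assigned,
                  roles$gene[roles$role %in% c("target", "flat", "dim",
                                               "bump", "no_site")])
})
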