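test_that("generators are deterministic under a fixed seed", {
  cfg <- generator_config(rng_seed = 123)
  a <- simulate_ffl_study(cfg)
  b <- simulate_ffl_study(cfg)
  expect_identical(a$mirna_matrix$values, b$mirna_matrix$values)
  expect_identical(a$gene_matrix$values, b$gene_matrix$values)
  expect_identical(as.character(a$utrs), as.character(b$utrs))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$cohort, b$cohort)
  c <- simulate_ffl_study(generator_config(rng_seed = 124))
  expect_false(identical(a$gene_matrix$values, c$gene_matrix$values))
})

test_that("noise-free replicates are identical and planted r is exactly -1", {
  sim <- generate_time_courses(generator_config(noise_cv = 0, rng_seed = 2))
  v <- sim$gene_matrix$values
  for (t in seq_len(6)) {
    block <- v[, (3 * t - 2):(3 * t)]
    expect_true(all(block == block[, 1]))
  }
  mp <- replicate_mean(sim$mirna_matrix, sim$truth$mirna$name)
  tfp <- replicate_mean(sim$gene_matrix, "TF1")
  expect_identical(pearson_r(mp, tfp), -1)
  expect_true(all(sim$mirna_matrix$values >= 0))
  expect_true(all(sim$gene_matrix$values >= 0))
})

test_that("planted fold changes hit the configured magnitudes exactly", {
  cfg <- generator_config(noise_cv = 0, down_fold = 4, up_fold = 4,
                          rng_seed = 6)
  sim <- generate_time_courses(cfg)
  th0 <- screen_thresholds(pseudocount = 0)
  mp <- replicate_mean(sim$mirna_matrix, sim$truth$mirna$name)
  expect_equal(fold_change(mp, th0), 0.25, tolerance = 1e-12)
  # monotone profiles: endpoint and extremum definitions coincide
  expect_equal(fold_change(mp, th0, method = "extremum"),
               fold_change(mp, th0), tolerance = 1e-12)
  for (g in c(sim$truth$loops$target, "TF1")) {
    gp <- replicate_mean(sim$gene_matrix, g)
    expect_equal(fold_change(gp, th0), 4, tolerance = 1e-12)
    expect_equal(fold_change(gp, th0, method = "extremum"), 4,
                 tolerance = 1e-12)
  }
})

test_that("each decoy class fails exactly its designated filter noise-free", {
  cfg <- generator_config(noise_cv = 0, rng_seed = 17)
  sim <- simulate_ffl_study(cfg)
  th <- screen_thresholds()
  mp <- replicate_mean(sim$mirna_matrix, sim$truth$mirna$name)
  roles <- sim$truth$gene_roles
  decoys <- roles[roles$role %in% c("flat", "dim", "bump", "no_site",
                                    "no_peak"), ]
  evidence <- assign_chip_targets(sim$peaks, sim$annotation, sim$window_bp)
  predicates <- function(g) {
    gp <- replicate_mean(sim$gene_matrix, g)
    r <- suppressWarnings(pearson_r(mp, gp))
    sites <- find_seed_sites(g, as.character(sim$utrs[[g]]),
                             sim$truth$mirna)
    c(expression = passes_expression(gp, th$min_promoter_tpm),
      fold = fold_change(gp, th) >= th$min_fold_change,
      correlation = !is.na(r) && r <= th$max_correlation,
      sites = nrow(sites) >= 1,
      chip = g %in% evidence)
  }
  expected_fail <- c(flat = "fold", dim = "expression",
                     bump = "correlation", no_site = "sites",
                     no_peak = "chip")
  for (i in seq_len(nrow(decoys))) {
    p <- predicates(decoys$gene[i])
    fail <- expected_fail[[decoys$role[i]]]
    expect_false(p[[fail]], label = paste(decoys$gene[i], fail))
    other <- setdiff(names(p), fail)
    if (decoys$role[i] == "flat") {
      # a constant profile has no defined correlation at all; the
      # screen excludes it at the fold stage before correlation is
      # evaluated
      expect_false(p[["correlation"]])
      other <- setdiff(other, "correlation")
    }
    expect_true(all(p[other]),
                label = paste(decoys$gene[i], "passes the rest"))
  }
  # and every planted loop target passes all five
  for (g in sim$truth$loops$target)
    expect_true(all(predicates(g)))
})

test_that("planted UTR sites are found exactly where they were planted", {
  sim <- simulate_ffl_study(generator_config(noise_cv = 0, rng_seed = 23))
  sites <- sim$truth$sites
  expect_setequal(sites$gene,
                  sim$truth$gene_roles$gene[
                    sim$truth$gene_roles$role %in%
                      c("tf", "target", "flat", "dim", "bump", "no_peak")])
  for (i in seq_len(nrow(sites))) {
    h <- find_seed_sites(sites$gene[i],
                         as.character(sim$utrs[[sites$gene[i]]]),
                         sim$truth$mirna)
    expect_equal(nrow(h), 1L)
    expect_identical(h$site_type, "8mer")
    expect_equal(h$start, sites$start[i])
  }
  # no-site decoys and background genes carry nothing
  bare <- setdiff(sim$truth$gene_roles$gene, sites$gene)
  for (g in bare)
    expect_equal(nrow(find_seed_sites(g, as.character(sim$utrs[[g]]),
                                      sim$truth$mirna)), 0L)
})

test_that("peaks land inside the generating window; background peaks nowhere", {
  sim <- simulate_ffl_study(generator_config(rng_seed = 29))
  truth_peaks <- sim$truth$peaks
  ann <- sim$annotation
  planted <- truth_peaks[!is.na(truth_peaks$peak_for), ]
  for (i in seq_len(nrow(planted))) {
    tss <- ann$tss[ann$gene_id == planted$peak_for[i]]
    center <- (planted$start[i] + planted$end[i]) / 2
    expect_lte(abs(center - tss), sim$window_bp / 2)
  }
  bg <- truth_peaks[is.na(truth_peaks$peak_for), ]
  expect_gt(nrow(bg), 0)
  assigned_with_bg_only <- assign_chip_targets(
    bg[, c("chrom", "start", "end")], ann, sim$window_bp)
  expect_length(assigned_with_bg_only, 0L)
  # halving the window below the planted offset can drop targets,
  # never add them (monotonicity downwards)
  full <- assign_chip_targets(sim$peaks, ann, sim$window_bp)
  half <- assign_chip_targets(sim$peaks, ann, sim$window_bp %/% 4L)
  expect_true(all(half %in% full))
})

test_that("the screen recovers exactly the planted loops end to end", {
  cfg <- generator_config(noise_cv = 0, n_planted_loops = 3, rng_seed = 41)
  sim <- simulate_ffl_study(cfg)
  res <- screen_ffls(sim$mirna_matrix, sim$gene_matrix, sim$truth$mirna,
                     "TF1", sim$utrs, peaks = sim$peaks,
                     annotation = sim$annotation)
  expect_identical(res$loops$target, sort(sim$truth$loops$target))
  expect_identical(res$loops$mirna,
                   rep(sim$truth$mirna$name, nrow(sim$truth$loops)))
})

test_that("generator configuration invariants are enforced", {
  expect_error(generator_config(n_timepoints = 2), "3 timepoints")
  expect_error(generator_config(n_planted_loops = 9, n_genes = 9),
               "n_genes - 1")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(decoy_fraction = 1.5), "decoy_fraction")
  expect_error(generate_cohort(n_subjects = 5), ">= 10")
  expect_error(generate_cohort(rho = 1), "rho")
})

test_that("a written simulation is a complete, readable study", {
  sim <- simulate_ffl_study(generator_config(noise_cv = 0, rng_seed = 47))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  files <- c("mirna_expr.tsv", "gene_expr.tsv", "utrs.fa", "peaks.bed",
             "tss.tsv", "cohort.tsv", "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$loops$target, sim$truth$loops$target)
  res <- screen_ffls(read_expression_table(file.path(dir, "mirna_expr.tsv")),
                     read_expression_table(file.path(dir, "gene_expr.tsv")),
                     sim$truth$mirna, "TF1",
                     file.path(dir, "utrs.fa"),
                     peaks = file.path(dir, "peaks.bed"),
                     annotation = file.path(dir, "tss.tsv"))
  expect_identical(res$loops$target, sort(sim$truth$loops$target))
})
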