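---
title: "Screening time-course expression data for coherent type-2 feed-forward loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening time-course expression data for coherent type-2 feed-forward loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffloop)
```

## The motif and the screening model

A coherent type-2 feed-forward loop (FFL) is a three-node regulatory
motif in which a repressor — here a miRNA — suppresses both a
transcription factor (TF) and a gene the TF activates. Both paths from
the miRNA to the target are repressive (direct repression, and
repression of the activator), which is what makes the motif
"coherent". Its proposed biological function is to sharpen temporal
boundaries: while the miRNA is high, the TF and target are held down
together; when the miRNA falls — as miR-27a/b-3p does during
adipogenesis — the TF (PPARG) and its targets rise together.

`ffloop` turns that picture into a conjunction of testable predicates
on observable data. Each candidate edge is evidenced separately:

* **miRNA ⊣ TF** and **miRNA ⊣ target**: canonical seed
  complementarity in the 3'UTR *and* strong anti-correlation of the
  expression profiles over the time course;
* **TF → target**: a ChIP-seq peak near the target's TSS (or
  membership in a published TF-target list) *and* concordant
  up-regulation of both genes.

The screen is deliberately a transparent filter cascade rather than a
scored model: each stage removes entities for one auditable reason,
and the funnel report records every exclusion with the offending
value. No significance is attached to an emitted loop — the output is
a candidate list for experimental follow-up, exactly as such screens
are used in practice.

## Thresholds and their defaults

`screen_thresholds()` bundles the cut-offs. The defaults are the
published screen settings for FANTOM5-style adipogenesis CAGE and
short-RNA data, and are deliberately strict — they were chosen to
yield a follow-up-sized candidate list, not to control an error rate:

| parameter          | default | unit | meaning |
|--------------------|---------|------|---------|
| `min_mirna_tpm`    | 10000   | TPM  | miRNA "highly expressed" level |
| `min_promoter_tpm` | 150     | TPM  | gene/promoter expression level |
| `min_fold_change`  | 2       | —    | end-to-end regulation magnitude |
| `max_correlation`  | −0.95   | —    | miRNA–gene profile anti-correlation |
| `pseudocount`      | 1       | TPM  | added to both fold-change endpoints |

Three interpretation choices were genuinely open and are resolved as
follows (each has a configuration switch):

* **"Highly expressed" at which timepoint?** Evaluated as the *maximum*
  replicate-mean TPM across the course (`stat = "max"`). A target
  induced only late in differentiation must be allowed to pass; a
  course-mean alternative is available (`stat = "mean"`).
* **Fold change of what?** The endpoint ratio `(last + pc) / (first +
  pc)` (`fold_method = "endpoint"`), reading "regulated during
  differentiation" as start-versus-end; an extremum ratio is available
  (`"extremum"`). The synthetic generator uses monotone trajectories,
  on which the two definitions coincide.
* **Which correlation, on what?** Pearson correlation on replicate-mean
  profiles. Rank (Spearman) correlation is available behind
  `correlation_method`; pooling replicates instead of averaging them is
  not offered, since replicate-level pairing across the two libraries
  is not meaningful.
* **Does the anti-correlation filter apply to the TF?** Yes by default
  (`tf_correlation_filter = TRUE`): the TF is required to behave like
  any repressed target of the miRNA. The requirement is stated
  explicitly only for targets in the motif definition, so a switch
  turns it off.

The pseudocount (1 TPM) guards zero denominators at the fold-change
stage; at the screen's expression scales (≥ 150 TPM survivors) it
perturbs fold changes by well under 1%.

## Target prediction

Only the three canonical seed-site classes are matched, on the
UTR sense strand in DNA space:

* `7mer-m8` — reverse complement of miRNA seed positions 2–8;
* `7mer-A1` — reverse complement of positions 2–7 followed by `A`;
* `8mer` — the 7mer-m8 match followed by the A1 adenosine.

No context scoring, conservation weighting, or 3'-supplementary
pairing is attempted: those rank sites, whereas this screen only asks
whether a canonical site exists. Overlapping classifications at one
locus are resolved to the single highest-priority type (8mer >
7mer-m8 > 7mer-A1), assigned left to right without double counting,
so a planted 8mer is never additionally counted as its embedded
7mers. `N` never matches; `U` is accepted as `T`; soft-masked
(lowercase) sequence matches by default with a hard-mask option.

The ChIP evidence rule — peak within ±50 kb of the TSS,
strand-independent, BED half-open arithmetic — is a conventional
promoter-proximal assignment; published peak-to-gene assignments vary,
so the window is a parameter and a precomputed target list can bypass
assignment entirely.

## The phenotype stage

For each phenotype the model is a two-regressor multiple regression
(typically the TF and one candidate target):

`phenotype ~ intercept + expr1 + expr2`

after log10-transforming any flagged columns (flags are explicit
configuration, never auto-detected; the transform refuses non-positive
values). Per regressor the package reports the partial correlation —
computed by double residualization on the other regressor — and the
coefficient's two-sided t-test p-value at `df = n − 3`. The identity
`|r| = |t| / √(t² + df)` links the two routes and is verified on every
fit; raw p-values are reported without multiplicity correction, as is
conventional for descriptive clinical association tables. Missing
data are handled by complete-case filtering.

## What the synthetic generator emulates

`simulate_ffl_study()` produces every input the screen consumes, with
ground truth recorded:

* **Trajectories.** The loop miRNA decays geometrically from 20,000
  TPM by 4-fold over a 6-timepoint day-0→12 course; loop genes are
  negative affine transforms of the miRNA profile rising from ~300 TPM
  by exactly 4-fold. The affine construction makes the noise-free
  miRNA–gene correlation exactly −1 and keeps profiles monotone, so
  endpoint and extremum fold definitions agree on planted entities.
* **Replicates.** Three per timepoint; replicate value = mean ×
  (1 + N(0, `noise_cv`)), truncated at zero. The multiplicative
  (CV-based) form keeps noise scale-free across the 150 vs 10,000 TPM
  regimes. The default CV of 5% reflects the reproducibility of
  deeply sequenced CAGE libraries.
* **Decoys, one per filter.** `flat` (high, unchanging → fails fold),
  `dim` (rising but sub-threshold → fails expression), `bump` (rising
  and expressed, middle-timepoint bump calibrated by root-finding to
  r = −0.90 against the miRNA → fails correlation at −0.95 but passes
  at −0.85), `no_site` (perfect profile, pattern-free UTR), `no_peak`
  (perfect profile and UTR, no ChIP peak). Each is a dedicated
  negative control for exactly one predicate.
* **UTRs.** Random background rejection-sampled until free of all
  three site patterns, then a single 8mer written in at a recorded
  position, with junction re-checks guaranteeing exactly one canonical
  site per planted UTR.
* **Peaks.** One 200 bp peak within half a window of each evidenced
  TSS; TSSs are spaced five windows apart and background peaks sit
  midway between TSSs (≥ 2 windows from any gene).
* **Cohort.** Two standard-normal expression regressors (optionally
  correlated) and phenotypes `β1·x1 + β2·x2 + noise`, with log-flagged
  phenotypes exponentiated base-10 so the analysis's log10 recovers
  linearity. The default cohort size of 56 matches the scale of the
  clinical cohorts such screens are paired with.

What the generator does **not** emulate: realistic TPM distributions
beyond the threshold-relevant scales, promoter multiplicity per gene,
correlated (batch) noise across entities, hairpin processing of
miRNAs, peak width/affinity variation, or non-canonical target sites.
Passing recovery tests therefore demonstrates that the pipeline's
logic is correct and its filters are calibrated to their stated
meanings — not that the thresholds are optimal for any particular
real dataset.

## Numerical choices

* Correlations within 10⁻¹² of ±1 are snapped to exactly ±1:
  construction-grade anti-correlated profiles must report −1, and
  `cor()`'s summation order can leave a one-ulp residue.
* Zero-variance profiles have *undefined* correlation: the screen
  logs and excludes them rather than assigning r = 0. (The flat decoy
  is nonetheless excluded earlier, at the fold stage.)
* Site-overlap ties break by class priority then leftmost position —
  deterministic for any input.
* Output tables round reals to 4 decimals and sort loops by (miRNA,
  target), so repeated runs diff cleanly; all writes are atomic
  (tempfile + rename) and provenance lives in `#` comment headers.
* Replicate structure is declared in the column headers
  (`<timepoint>__rep<k>`), never inferred; ragged or missing cells are
  errors, not imputation targets.

## Validation scale

The shipped test-and-acceptance runs use study sizes chosen to make
every property checkable by construction or brute force: the default
9-gene/2-miRNA layout with 3 planted loops; 100 generator seeds for
noisy recall (300 loop recoveries); 1,000 random UTRs up to 10 kb
against an exhaustive substring-comparison scanner oracle; 200 random
UTRs for the miR-27a/b-3p seed-identity property; 50 random instances
for threshold-relaxation monotonicity; 200 cohorts of n = 56 for
planted-sign recovery plus 500 null simulations for p-value
calibration, with a 10⁶-row cohort as the large-sample oracle for the
analytic partial correlation.

## Known limitations

* The screen is per-TF: one transcription factor per run, loops
  emitted per (miRNA, target) pair. Multi-TF screening is a loop over
  runs.
* Only the coherent type-2 topology is addressed; other FFL types
  (e.g. a miRNA repressing an activator of itself) need different
  predicate sets.
* No motif-enrichment statistics are computed: the output is a
  filtered candidate list, and any claim about over-representation
  requires a null model this package does not provide.
* Seed matching is sequence-only; expression context (site
  accessibility, AU content) is out of scope.
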