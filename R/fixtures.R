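#' Packaged miR-27a/b-3p mature records
#'
#' The two miR-27 family members share an identical seed (`ucacagu`,
#' positions 2-8), differing only at position 18, so they predict the
#' same canonical target sets. Sequences and miRBase mature accessions
#' (MIMAT0000084, MIMAT0000419) ship with the package.
#'
#' @return Named list of two [mirna_record()] objects
#'   (`hsa-miR-27a-3p`, `hsa-miR-27b-3p`).
#' @examples
#' seed_of(mir27_records()[["hsa-miR-27b-3p"]])
#' @export
mir27_records <- function() {
  path <- system.file("extdata", "mir27_mature.tsv", package = "ffloop",
                      mustWork = TRUE)
  recs <- read_mirnas(path)
  setNames(recs, vapply(recs, `[[`, character(1L), "name"))
}

#' Packaged candidate miR-27b-3p/PPARG loop target genes
#'
#' The ten genes reported by the adipogenesis feed-forward-loop screen
#' of FANTOM5 CAGE/short-RNA data as candidate miR-27b-3p targets that
#' are also PPARG targets (PPARG itself among them).
#'
#' @return Character vector of ten gene symbols.
#' @export
mir27b_candidate_targets <- function() {
  read_target_list(system.file("extdata", "mir27b_adipogenesis_targets.txt",
                               package = "ffloop", mustWork = TRUE))
}
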