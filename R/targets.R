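#' Mature miRNA record
#'
#' Holds a mature miRNA name and its 5'->3' RNA sequence. The seed
#' region — nucleotides 2-8 — drives all canonical target prediction,
#' so the sequence must be at least 8 nt long.
#'
#' @param name miRNA identifier, e.g. `"hsa-miR-27a-3p"`.
#' @param sequence RNA-alphabet string (`a`/`c`/`g`/`u`, case
#'   insensitive), length >= 8.
#' @param mirbase_id Optional miRBase mature accession (`MIMAT...`).
#' @return An object of class `mirna_record`.
#' @export
mirna_record <- function(name, sequence, mirbase_id = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- tolower(as.character(sequence))
  if (nchar(sequence) < 8L)
    stop("miRNA sequence must be at least 8 nt (seed positions 2-8): ",
         name, call. = FALSE)
  if (grepl("[^acgu]", sequence))
    stop("miRNA sequence must be RNA (a/c/g/u only): ", name,
         call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 mirbase_id = as.character(mirbase_id)),
            class = "mirna_record")
}

#' @export
print.mirna_record <- function(x, ...) {
  cat(sprintf("%s  %s  (%s)\n", x$name, x$sequence,
              if (is.na(x$mirbase_id)) "no accession" else x$mirbase_id))
  invisible(x)
}

#' Read mature miRNAs from a TSV table or FASTA file
#'
#' TSV input needs columns `name`, `sequence` and optionally
#' `mirbase_id`; FASTA input (`.fa`/`.fasta`) is read with
#' `Biostrings::readRNAStringSet()` and record ids become names.
#'
#' @param path Input file path.
#' @return A list of [mirna_record()] objects.
#' @export
read_mirnas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readRNAStringSet(path)
    nms <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
    return(lapply(seq_along(seqs), function(i)
      mirna_record(nms[i], as.character(seqs[[i]]))))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(df)))
    stop("miRNA table needs columns: name, sequence", call. = FALSE)
  if (!"mirbase_id" %in% names(df)) df$mirbase_id <- NA_character_
  lapply(seq_len(nrow(df)), function(i)
    mirna_record(df$name[i], df$sequence[i], df$mirbase_id[i]))
}

#' Seed region of a mature miRNA
#'
#' Nucleotides 2-8 of the mature sequence (1-based), lowercased RNA.
#'
#' @param mirna A [mirna_record()].
#' @return A 7-character RNA string.
#' @examples
#' seed_of(mirna_record("hsa-miR-27a-3p", "uucacaguggcuaaguuccgc"))
#' # "ucacagu"
#' @export
seed_of <- function(mirna) {
  stopifnot(inherits(mirna, "mirna_record"))
  substr(mirna$sequence, 2L, 8L)
}

#' Canonical seed-site DNA patterns for a miRNA
#'
#' The three canonical site classes matched on a 3'UTR (sense strand,
#' DNA alphabet):
#' * `7mer-m8` — perfect Watson-Crick complement of seed positions 2-8;
#' * `7mer-A1` — complement of positions 2-7 followed by an `A`
#'   opposite miRNA position 1;
#' * `8mer` — the 7mer-m8 match followed by the A1 adenosine.
#'
#' Structurally, `8mer == 7mer-m8 + "A"` and the last 7 characters of
#' the 8mer equal the 7mer-A1 pattern.
#'
#' @param mirna A [mirna_record()].
#' @return Named character vector with elements `"8mer"`, `"7mer-m8"`,
#'   `"7mer-A1"`.
#' @export
site_patterns <- function(mirna) {
  seed <- seed_of(mirna)
  seed_dna <- Biostrings::DNAString(chartr("uU", "tT", seed))
  m8 <- as.character(Biostrings::reverseComplement(seed_dna))
  c("8mer" = paste0(m8, "A"),
    "7mer-m8" = m8,
    "7mer-A1" = paste0(substr(m8, 2L, 7L), "A"))
}

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

normalize_utr <- function(utr_seq, mask = c("soft", "hard")) {
  mask <- match.arg(mask)
  s <- chartr("uU", "tT", as.character(utr_seq))
  if (mask == "hard") s <- gsub("[acgtn]", "N", s)
  s <- toupper(s)
  if (grepl("[^ACGTN]", s))
    stop("invalid character in UTR sequence (allowed: A/C/G/T/U/N)",
         call. = FALSE)
  s
}

#' Find canonical seed sites on a 3'UTR
#'
#' Scans the sense strand of a 3'UTR for the miRNA's three canonical
#' site patterns. All match positions are located (including
#' overlapping occurrences of the same pattern); where classifications
#' overlap at the same locus the single highest-priority type wins
#' (8mer > 7mer-m8 > 7mer-A1), assigned left to right without double
#' counting. `N` bases never match. `U` is accepted and treated as `T`;
#' soft-masked (lowercase) sequence matches by default, or is masked to
#' `N` with `mask = "hard"`.
#'
#' @param utr_id UTR/gene identifier attached to the hits.
#' @param utr_seq DNA (or RNA) string over `A/C/G/T/U/N`, case
#'   insensitive.
#' @param mirna A [mirna_record()].
#' @param mask `"soft"` (default: lowercase matches) or `"hard"`
#'   (lowercase excluded).
#' @return Data frame with columns `utr_id`, `start`, `end` (0-based,
#'   half-open, sense strand), `site_type`; zero rows when nothing
#'   matches, sorted by `start`.
#' @export
find_seed_sites <- function(utr_id, utr_seq, mirna, mask = "soft") {
  s <- normalize_utr(utr_seq, mask)
  patterns <- site_patterns(mirna)
  subject <- Biostrings::DNAString(s)
  hits <- do.call(rbind, lapply(SITE_TYPES, function(ty) {
    p <- patterns[[ty]]
    if (nchar(s) < nchar(p)) return(NULL)
    m <- Biostrings::matchPattern(p, subject, fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(utr_id = utr_id,
               start = Biostrings::start(m) - 1L,     # to 0-based
               end = Biostrings::end(m),              # half-open
               site_type = ty,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) return(empty_site_table())
  # priority resolution: 8mer > 7mer-m8 > 7mer-A1, then left to right,
  # greedily keeping hits that do not overlap an accepted hit
  hits$priority <- match(hits$site_type, SITE_TYPES)
  hits <- hits[order(hits$priority, hits$start), , drop = FALSE]
  kept <- logical(nrow(hits))
  acc_start <- integer(0); acc_end <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (!any(hits$start[i] < acc_end & hits$end[i] > acc_start)) {
      kept[i] <- TRUE
      acc_start <- c(acc_start, hits$start[i])
      acc_end <- c(acc_end, hits$end[i])
    }
  }
  hits <- hits[kept, c("utr_id", "start", "end", "site_type"), drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_site_table <- function() {
  data.frame(utr_id = character(0), start = integer(0), end = integer(0),
             site_type = character(0), stringsAsFactors = FALSE)
}

#' Predict miRNA target genes by canonical seed matching
#'
#' A gene is called a predicted target when its 3'UTR carries at least
#' `min_sites` canonical sites of the allowed classes.
#'
#' @param mirna A [mirna_record()].
#' @param utrs A named `Biostrings::DNAStringSet`, a named character
#'   vector of UTR sequences, or a FASTA file path. Record ids must
#'   equal the gene ids used elsewhere.
#' @param min_sites Minimum number of qualifying sites, `>= 1`.
#' @param allowed_types Subset of `c("8mer", "7mer-m8", "7mer-A1")`.
#' @param mask Passed to [find_seed_sites()].
#' @return List with `targets` (character vector of predicted gene
#'   ids, UTR input order) and `hits` (site table for all scanned UTRs,
#'   with a `mirna_name` column).
#' @export
predict_mirna_targets <- function(mirna, utrs, min_sites = 1L,
                                  allowed_types = SITE_TYPES,
                                  mask = "soft") {
  stopifnot(min_sites >= 1L, length(allowed_types) >= 1L,
            all(allowed_types %in% SITE_TYPES))
  seqs <- as_utr_set(utrs)
  if (length(seqs) == 0L) {
    warning("empty UTR collection: no targets predicted", call. = FALSE)
    return(list(targets = character(0),
                hits = cbind(empty_site_table(),
                             mirna_name = character(0))))
  }
  hit_list <- lapply(names(seqs), function(id)
    find_seed_sites(id, seqs[[id]], mirna, mask = mask))
  hits <- do.call(rbind, hit_list)
  hits$mirna_name <- rep(mirna$name, nrow(hits))
  counts <- vapply(hit_list, function(h)
    sum(h$site_type %in% allowed_types), integer(1L))
  list(targets = names(seqs)[counts >= min_sites], hits = hits)
}

as_utr_set <- function(utrs) {
  if (inherits(utrs, "DNAStringSet")) {
    seqs <- as.character(utrs)
  } else if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs)) {
    seqs <- as.character(Biostrings::readDNAStringSet(utrs))
  } else if (is.character(utrs)) {
    seqs <- utrs
  } else {
    stop("`utrs` must be a DNAStringSet, named character vector, ",
         "or FASTA path", call. = FALSE)
  }
  if (length(seqs) == 0L) return(list())
  if (is.null(names(seqs)))
    stop("UTR sequences must be named with gene ids", call. = FALSE)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`,
                        character(1L), 1L)
  as.list(seqs)
}

#' Assign TF target genes from ChIP peaks near transcription start sites
#'
#' A gene is called a TF target when at least one peak interval
#' overlaps the window `[tss - window_bp, tss + window_bp]` on the same
#' chromosome. Peaks use BED convention (0-based, half-open); the
#' window is strand-independent.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a BED file path.
#' @param annotation Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based), `strand`, or a TSV path ([read_tss_table()]).
#' @param window_bp Non-negative window half-width in bp; default 50000.
#' @return Character vector of target gene ids (annotation order).
#' @export
assign_chip_targets <- function(peaks, annotation, window_bp = 50000L) {
  stopifnot(window_bp >= 0)
  peaks <- as_peak_table(peaks)
  annotation <- as_tss_table(annotation)
  if (nrow(peaks) == 0L || nrow(annotation) == 0L) return(character(0))
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  win <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = pmax(1L, annotation$tss - as.integer(window_bp) + 1L),
                     end = annotation$tss + as.integer(window_bp) + 1L))
  ov <- GenomicRanges::findOverlaps(win, pk, ignore.strand = TRUE)
  annotation$gene_id[sort(unique(S4Vectors::queryHits(ov)))]
}

as_peak_table <- function(peaks) {
  if (is.character(peaks) && length(peaks) == 1L) {
    if (!file.exists(peaks)) stop("file not found: ", peaks, call. = FALSE)
    gr <- rtracklayer::import(peaks, format = "BED")
    peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,  # to BED 0-based
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) && (any(peaks$start < 0) || any(peaks$start >= peaks$end)))
    stop("peak intervals must satisfy 0 <= start < end (BED convention)",
         call. = FALSE)
  peaks
}

as_tss_table <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- read_tss_table(annotation)
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(annotation)))
  if (nrow(annotation) && (any(annotation$tss < 0) ||
                           !all(annotation$strand %in% c("+", "-"))))
    stop("annotation needs tss >= 0 and strand in {+, -}", call. = FALSE)
  annotation
}

#' Read a TSS annotation table
#'
#' Tab-delimited with header columns `gene_id`, `chrom`, `tss`
#' (0-based), `strand`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  as_tss_table(df)
}

#' Read a precomputed TF-target gene list
#'
#' One identifier per line; an optional single header line (`gene_id`,
#' `gene`, `target` or `id`, case insensitive) and `#` comments are
#' skipped, whitespace-only lines are ignored, duplicates are removed
#' (first occurrence kept).
#'
#' @param path Text file path.
#' @return Character vector of gene ids; empty with a warning for an
#'   empty file.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) &&
      grepl("^(gene_id|gene|target|id)$", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  if (length(lines) == 0L) {
    warning("empty target list: ", path, call. = FALSE)
    return(character(0))
  }
  unique(lines)
}

#' Write a seed-site table
#'
#' @param hits Site table as returned by [predict_mirna_targets()]
#'   (`$hits`), with columns `utr_id`, `start`, `end`, `site_type`,
#'   `mirna_name`.
#' @param path Output TSV path.
#' @param header Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(hits, path, header = NULL) {
  cols <- c("utr_id", "start", "end", "site_type", "mirna_name")
  stopifnot(is.data.frame(hits), all(cols %in% names(hits)))
  write_tsv_atomic(hits[, cols, drop = FALSE], path, header = header)
}
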