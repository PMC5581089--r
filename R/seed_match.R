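# miRNA seed handling: seed extraction (nucleotides 2-8 of the mature
# 5' end), seed-family grouping, and detection of seed-complementary
# target sites in 3'-UTRs with the canonical site-type taxonomy
# (6mer < 7mer-A1 < 7mer-m8 < 8mer).

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Construct a miRNA sequence record
#'
#' Sequences are given 5' to 3'; T is accepted and normalized to U. The
#' seed is nucleotides 2-8 (1-based, inclusive).
#'
#' @param id miRNA identifier (e.g. `"hsa-let-7d-5p"`).
#' @param sequence RNA (or DNA) string, length >= 8.
#' @return A `mirna_sequence` with fields `id`, `sequence` (RNA), `seed`.
#' @export
mirna_sequence <- function(id, sequence) {
  seq <- chartr("tu", "TU", toupper(sequence))
  seq <- chartr("T", "U", seq)
  bad <- regmatches(seq, regexpr("[^ACGU]", seq))
  if (length(bad)) {
    stop("invalid base '", bad, "' at offset ",
         regexpr("[^ACGU]", seq), " in miRNA ", id)
  }
  if (nchar(seq) < 8L) stop("miRNA ", id, " shorter than 8 nt; no seed")
  structure(list(id = id, sequence = seq, seed = substr(seq, 2L, 8L)),
            class = "mirna_sequence")
}

#' Extract the seed (nucleotides 2-8) of a miRNA
#'
#' @param mirna A `mirna_sequence`, or a raw sequence string (length >= 8).
#' @return The 7-nt seed as an RNA string.
#' @export
extract_seed <- function(mirna) {
  if (!inherits(mirna, "mirna_sequence")) {
    mirna <- mirna_sequence("mirna", mirna)
  }
  mirna$seed
}

#' Target-site pattern of a seed (7mer-m8 site, DNA alphabet)
#'
#' The 7mer-m8 site is the reverse complement of the seed, read 5' to 3'
#' on the target, reported in DNA alphabet (U -> T).
#'
#' @param seed A 7-nt seed (RNA or DNA alphabet).
#' @return The 7-nt DNA pattern.
#' @export
seed_site_pattern <- function(seed) {
  s <- chartr("u", "U", toupper(seed))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) stop("invalid base in seed '", seed, "'")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Find seed-complementary sites of a miRNA in a 3'-UTR
#'
#' Site classes follow the canonical taxonomy. With the seed being miRNA
#' nucleotides 2-8:
#' \itemize{
#' \item 8mer: match to the reverse complement of the full seed,
#'   immediately followed (3' on the target) by an A;
#' \item 7mer-m8: match to the reverse complement of the full seed;
#' \item 7mer-A1: match to the reverse complement of seed nucleotides 2-7
#'   followed by an A;
#' \item 6mer: match to the reverse complement of seed nucleotides 2-7 only.
#' }
#' Each core-match locus is reported once with its maximal type;
#' overlapping loci are all reported. Coordinates are 1-based inclusive on
#' the UTR read 5' to 3'.
#'
#' @param utr UTR sequence (DNA or RNA; normalized to DNA), or a named
#'   length-1 character vector whose name is used as `utr_id`.
#' @param mirna A `mirna_sequence` (or raw miRNA sequence string).
#' @param min_type Least specific site type to report; default
#'   `"7mer-m8"` (set `"6mer"` to report marginal sites too).
#' @param utr_id Identifier for the UTR in the output.
#' @return Data frame `utr_id`, `mirna_id`, `seed`, `start`, `end`,
#'   `site_type` (ordered factor), one row per reported site.
#' @export
find_seed_sites <- function(utr, mirna, min_type = "7mer-m8",
                            utr_id = NULL) {
  if (is.null(utr_id)) utr_id <- names(utr) %||% "utr"
  utr <- unname(utr)
  if (!inherits(mirna, "mirna_sequence")) mirna <- mirna_sequence("mirna", mirna)
  min_type <- match.arg(min_type, SITE_TYPES)
  useq <- chartr("u", "U", toupper(utr))
  useq <- chartr("U", "T", useq)
  off <- regexpr("[^ACGT]", useq)
  if (off > 0) {
    stop("invalid character in UTR ", utr_id, " at offset ", off)
  }
  if (nchar(useq) < 6L) stop("UTR shorter than 6 nt")
  seed <- mirna$seed
  # seed = s1..s7 (miRNA nt 2..8); the 7mer-m8 pattern is comp(s7) + core6
  core6 <- seed_site_pattern(substr(seed, 1L, 6L))       # revcomp of nt 2-7
  m8base <- substr(seed_site_pattern(seed), 1L, 1L)      # complement of nt 8
  starts <- unlist(gregexpr(paste0("(?=", core6, ")"), useq, perl = TRUE))
  starts <- starts[starts > 0]
  if (length(starts) == 0L) {
    return(empty_site_table())
  }
  chars <- strsplit(useq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  rows <- lapply(starts, function(q) {
    has_m8 <- q > 1L && chars[q - 1L] == m8base
    has_a1 <- q + 6L <= n && chars[q + 6L] == "A"
    if (has_m8 && has_a1) {
      type <- "8mer"; s <- q - 1L; e <- q + 6L
    } else if (has_m8) {
      type <- "7mer-m8"; s <- q - 1L; e <- q + 5L
    } else if (has_a1) {
      type <- "7mer-A1"; s <- q; e <- q + 6L
    } else {
      type <- "6mer"; s <- q; e <- q + 5L
    }
    data.frame(utr_id = utr_id, mirna_id = mirna$id, seed = seed,
               start = s, end = e, site_type = type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$site_type <- factor(out$site_type, levels = SITE_TYPES, ordered = TRUE)
  out <- out[out$site_type >= min_type, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
empty_site_table <- function() {
  data.frame(utr_id = character(), mirna_id = character(),
             seed = character(), start = integer(), end = integer(),
             site_type = factor(character(), levels = SITE_TYPES,
                                ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Group miRNAs into families by exact seed identity
#'
#' Family members share nucleotides 2-8 and are expected to have largely
#' overlapping target repertoires (the let-7 family is the canonical
#' example).
#'
#' @param mirnas List of `mirna_sequence` objects (or raw sequences, which
#'   are then identified by their position).
#' @return Named list, one element per distinct seed (lexical order),
#'   each a character vector of miRNA ids.
#' @export
group_families <- function(mirnas) {
  if (length(mirnas) == 0L) return(stats::setNames(list(), character()))
  mirnas <- lapply(seq_along(mirnas), function(i) {
    m <- mirnas[[i]]
    if (inherits(m, "mirna_sequence")) m else mirna_sequence(paste0("mirna_", i), m)
  })
  seeds <- vapply(mirnas, `[[`, "", "seed")
  ids <- vapply(mirnas, `[[`, "", "id")
  groups <- split(ids, seeds)
  groups[order(names(groups), method = "radix")]
}

#' Read miRNA sequences from a FASTA file
#'
#' @param path FASTA path (RNA or DNA alphabet).
#' @return List of `mirna_sequence` objects keyed by record id.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i)
    mirna_sequence(ids[i], as.character(set[[i]])))
  stats::setNames(out, ids)
}

#' Read 3'-UTR sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (DNA alphabet).
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  stats::setNames(unname(seqs), sub("\\s.*$", "", names(set)))
}

#' Seed-site scan of many miRNAs against many UTRs
#'
#' @param mirnas List of `mirna_sequence` (e.g. [read_mirna_fasta()]).
#' @param utrs Named character vector of UTR sequences.
#' @param min_type Least specific site type to report.
#' @return Combined site table (see [find_seed_sites()]).
#' @export
scan_seed_sites <- function(mirnas, utrs, min_type = "7mer-m8") {
  tabs <- list()
  for (u in names(utrs)) {
    for (m in mirnas) {
      tabs[[length(tabs) + 1L]] <-
        find_seed_sites(utrs[[u]], m, min_type = min_type, utr_id = u)
    }
  }
  out <- do.call(rbind, c(tabs, list(empty_site_table())))
  rownames(out) <- NULL
  out
}
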