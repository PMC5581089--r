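# The positional enrichment scan: per-cytoband 2x2 contingency tables of
# downregulated probes, one-sided Fisher exact p-values (hypergeometric
# upper tail), Manhattan-table construction, and miRNA/mRNA concordance.

#' Build the 2x2 contingency table for one region
#'
#' Rows are in-region / out-of-region, columns downregulated / not.
#'
#' @param region_probe_ids Probe ids assigned to the region.
#' @param down_ids Probe ids flagged downregulated.
#' @param universe_ids All probe ids in the scan universe (assigned probes).
#' @return A `contingency_table` list with integer counts `a` (in-region
#'   down), `b` (in-region not down), `c` (out down), `d` (out not down).
#' @export
build_region_table <- function(region_probe_ids, down_ids, universe_ids) {
  if (length(setdiff(region_probe_ids, universe_ids))) {
    stop("region probes are not a subset of the scan universe")
  }
  down_ids <- intersect(down_ids, universe_ids)
  a <- length(intersect(region_probe_ids, down_ids))
  b <- length(region_probe_ids) - a
  c <- length(down_ids) - a
  d <- length(universe_ids) - length(region_probe_ids) - c
  structure(list(a = a, b = b, c = c, d = d), class = "contingency_table")
}

#' One-sided Fisher exact p-value (hypergeometric upper tail)
#'
#' For a 2x2 table (a, b; c, d) the p-value is the probability of observing
#' at least `a` downregulated probes in the region under the null of no
#' association, i.e. the upper tail `P(X >= a)` of
#' `Hypergeometric(N = a+b+c+d, K = a+c, n = a+b)`. Tail terms are summed
#' in log space for numerical stability.
#'
#' @param tab A `contingency_table`, or the count `a` when `b`, `c`, `d`
#'   are also given.
#' @param b,c,d Optional counts when `tab` is the scalar `a`.
#' @return The one-sided p-value in (0, 1].
#' @export
fisher_exact_one_sided <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (inherits(tab, "contingency_table")) {
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  } else {
    a <- tab
  }
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  N <- a + b + c + d
  K <- a + c        # downregulated in universe
  n <- a + b        # region size
  if (N == 0L) return(1.0)
  hi <- min(K, n)
  if (a > hi) stop("impossible table: a exceeds min(K, n)")
  support <- a:hi
  logp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  p <- exp(logsumexp(logp))
  min(max(p, .Machine$double.xmin), 1.0)
}

#' Scan all cytoband regions for enrichment of downregulated probes
#'
#' The scan universe is the set of probes of one molecule type that carry a
#' region assignment and a fold-change record. Each band with at least
#' `min_probes` assigned probes is tested with the one-sided Fisher exact
#' test for enrichment of probes with `fc < 1/fold_threshold`. Significance
#' is `p <= alpha` (inclusive). Benjamini-Hochberg q-values are added as an
#' extra column; the significance call itself uses the fixed threshold.
#'
#' @param records A `fold_change` data frame ([compute_fold_changes()]).
#' @param probes A region-assigned `probe_annotation` restricted (or
#'   restrictable via `molecule`) to one molecule type.
#' @param alpha Significance threshold on the one-sided p-value
#'   (default 2e-3).
#' @param min_probes Minimum assigned probes for a band to be tested
#'   (default 2).
#' @param fold_threshold Fold threshold defining "downregulated"
#'   (default 2, i.e. fc < 0.5).
#' @param molecule Optional molecule filter applied to `probes`.
#' @param sided `"one"` (default, enrichment of downregulated probes) or
#'   `"two"` (classic two-sided Fisher via [stats::fisher.test()]).
#' @return A `scan_result` list: `molecule`, `alpha`, `results` (one row
#'   per tested region: `region_id`, `chrom`, `start`, `end`,
#'   `midpoint_bp`, `a`, `b`, `c`, `d`, `p`, `neg_log10_p`, `q_bh`,
#'   `significant`), `universe_size`, `down_total`.
#' @export
scan_regions <- function(records, probes, alpha = 2e-3, min_probes = 2L,
                         fold_threshold = 2.0, molecule = NULL,
                         sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha <= 1, min_probes >= 1)
  if (!is.null(molecule)) probes <- probes[probes$molecule == molecule, , drop = FALSE]
  if (!is.null(molecule)) {
    mols <- molecule
  } else {
    mols <- unique(probes$molecule)
  }
  ann <- probes[!is.na(probes$region_id), , drop = FALSE]
  dropped <- sum(!records$probe_id %in% ann$probe_id)
  if (dropped > 0L) {
    msg("scan_regions: dropped %d record(s) without region assignment", dropped)
  }
  ann <- ann[ann$probe_id %in% records$probe_id, , drop = FALSE]
  if (nrow(ann) == 0L) stop("empty scan universe: no assigned probes with records")
  universe <- ann$probe_id
  rec <- records[match(universe, records$probe_id), , drop = FALSE]
  down_ids <- rec$probe_id[rec$fc < 1 / fold_threshold]
  down_total <- length(down_ids)

  sizes <- table(ann$region_id)
  region_ids <- names(sizes)[sizes >= min_probes]
  meta <- ann[!duplicated(ann$region_id), c("region_id", "chrom"), drop = FALSE]

  if (length(region_ids) == 0L) {
    res <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      midpoint_bp = numeric(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p = numeric(),
                      neg_log10_p = numeric(), q_bh = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    return(structure(list(molecule = if (length(mols) == 1L) mols else "mixed",
                          alpha = alpha, fold_threshold = fold_threshold,
                          min_probes = as.integer(min_probes), sided = sided,
                          results = res, universe_size = length(universe),
                          down_total = down_total),
                     class = "scan_result"))
  }
  rows <- lapply(region_ids, function(rid) {
    in_region <- ann$probe_id[ann$region_id == rid]
    tab <- build_region_table(in_region, down_ids, universe)
    p <- if (sided == "one") {
      fisher_exact_one_sided(tab)
    } else {
      stats::fisher.test(matrix(c(tab$a, tab$b, tab$c, tab$d), 2L,
                                byrow = TRUE))$p.value
    }
    data.frame(region_id = rid,
               chrom = meta$chrom[meta$region_id == rid][1L],
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # band coordinates from the probe annotation extent (refined by
  # manhattan_table when a cytoband map is supplied)
  res$start <- vapply(res$region_id, function(rid)
    min(ann$start[ann$region_id == rid]), numeric(1L))
  res$end <- vapply(res$region_id, function(rid)
    max(ann$end[ann$region_id == rid]), numeric(1L))
  res$midpoint_bp <- floor((res$start + res$end) / 2)
  res$neg_log10_p <- -log10(res$p)
  res$q_bh <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p <= alpha
  uch <- unique(res$chrom)
  chrom_rank <- match(res$chrom, uch[chrom_order(uch)])
  res <- res[order(chrom_rank, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("region_id", "chrom", "start", "end", "midpoint_bp",
                 "a", "b", "c", "d", "p", "neg_log10_p", "q_bh", "significant")]
  structure(list(molecule = if (length(mols) == 1L) mols else "mixed",
                 alpha = alpha,
                 fold_threshold = fold_threshold,
                 min_probes = as.integer(min_probes),
                 sided = sided,
                 results = res,
                 universe_size = length(universe),
                 down_total = down_total),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result (%s): %d regions tested, universe %d, %d down, alpha %g\n",
              x$molecule, nrow(x$results), x$universe_size, x$down_total, x$alpha))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant regions:\n")
    print(sig[, c("region_id", "a", "b", "p", "neg_log10_p")], row.names = FALSE)
  } else {
    cat("no significant regions\n")
  }
  invisible(x)
}

#' Manhattan table for a scan result
#'
#' Projects each tested region onto a single cumulative genomic axis
#' (chromosomes in order 1..22, X, Y laid end to end; x = preceding
#' chromosome lengths + band midpoint). The significance threshold line
#' `-log10(alpha)` is attached as the `threshold` attribute.
#'
#' @param scan A `scan_result`.
#' @param bands The `cytoband_map` used for the scan; band coordinates
#'   define chromosome lengths and band midpoints.
#' @return Data frame with `region_id`, `chrom`, `cumulative_x_bp`,
#'   `neg_log10_p`, `significant`; attribute `threshold`.
#' @export
manhattan_table <- function(scan, bands) {
  res <- scan$results
  missing <- setdiff(res$region_id, bands$region_id)
  if (length(missing)) {
    stop("scanned region(s) without band coordinates: ",
         paste(missing, collapse = ", "))
  }
  chroms <- unique(bands$chrom)[chrom_order(unique(bands$chrom))]
  lens <- vapply(chroms, function(ch) max(bands$end[bands$chrom == ch]),
                 numeric(1L))
  offsets <- stats::setNames(c(0, cumsum(lens))[seq_along(chroms)], chroms)
  b <- bands[match(res$region_id, bands$region_id), , drop = FALSE]
  x <- offsets[b$chrom] + floor((b$start + b$end) / 2)
  out <- data.frame(region_id = res$region_id,
                    chrom = res$chrom,
                    cumulative_x_bp = unname(x),
                    neg_log10_p = res$neg_log10_p,
                    significant = res$significant,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cumulative_x_bp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- -log10(scan$alpha)
  out
}

#' Regions significant in both the miRNA and the mRNA scan
#'
#' @param scan_mirna,scan_mrna `scan_result` objects over the same band
#'   vocabulary.
#' @return Character vector of region ids significant in both scans,
#'   ordered by the larger of the two p-values (most concordantly
#'   significant first).
#' @export
concordant_regions <- function(scan_mirna, scan_mrna) {
  a <- scan_mirna$results
  b <- scan_mrna$results
  ids <- intersect(a$region_id[a$significant], b$region_id[b$significant])
  if (length(ids) == 0L) return(character())
  pmaxv <- pmax(a$p[match(ids, a$region_id)], b$p[match(ids, b$region_id)])
  ids[order(pmaxv, ids)]
}

#' Write a scan result table
#'
#' @param scan A `scan_result`.
#' @param path Output TSV path.
#' @export
write_scan_result <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# molecule=%s alpha=%g fold_threshold=%g min_probes=%d sided=%s universe=%d down_total=%d",
                     scan$molecule, scan$alpha, scan$fold_threshold,
                     scan$min_probes, scan$sided, scan$universe_size,
                     scan$down_total), con)
  utils::write.table(scan$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Manhattan table
#'
#' @param mt Output of [manhattan_table()].
#' @param path Output TSV path.
#' @export
write_manhattan_table <- function(mt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold_neg_log10_p=%s",
                     format_full(attr(mt, "threshold"))), con)
  utils::write.table(as.data.frame(mt), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
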