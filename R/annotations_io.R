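# Readers, writers and validators for the tabular inputs of the positional
# scan: cytoband maps, probe annotations and expression matrices.
#
# Coordinates are 0-based half-open internally (as in BED); reports render
# 1-based inclusive positions.

MOLECULES <- c("miRNA", "mRNA")
CONDITIONS <- c("parental", "resistant")

#' Read a UCSC-style cytoband table
#'
#' Parses a tab-separated cytoband file with columns `chrom`, `start`, `end`,
#' `band` and optionally `stain` (ignored). Bands are validated to be
#' non-overlapping within each chromosome and returned sorted by chromosome
#' and start.
#'
#' @param path Path to a cytoBand-style TSV (no header; `#` comments allowed).
#' @return A `cytoband_map` data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `band`, and `region_id` (e.g. `"9q22.32"`).
#' @export
read_cytoband_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty cytoband table: ", path)
    return(cytoband_map(data.frame(chrom = character(), start = integer(),
                                   end = integer(), band = character(),
                                   stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad)) {
    stop("malformed cytoband row at line ", which(keep)[bad[1L]],
         ": expected >= 4 tab-separated fields")
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end   = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    band  = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stop("malformed cytoband row at line ", which(keep)[bad[1L]],
         ": non-numeric coordinate")
  }
  cytoband_map(df)
}

#' Construct and validate a cytoband map
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `band`.
#' @return Validated `cytoband_map`, sorted by chromosome then start.
#' @export
cytoband_map <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "band") %in% names(df)))
  if (nrow(df)) {
    if (any(df$start >= df$end)) {
      i <- which(df$start >= df$end)[1L]
      stop("cytoband with start >= end: ", df$chrom[i], ":", df$start[i],
           "-", df$end[i], " (", df$band[i], ")")
    }
    if (anyDuplicated(paste(df$chrom, df$band))) {
      stop("duplicate band name within a chromosome")
    }
    df <- df[order(match(df$chrom, unique(df$chrom)[chrom_order(unique(df$chrom))]),
                   df$start), , drop = FALSE]
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      if (nrow(sub) > 1L) {
        ov <- which(sub$start[-1L] < sub$end[-nrow(sub)])
        if (length(ov)) {
          i <- ov[1L]
          stop("overlapping cytobands on ", ch, ": ",
               sub$band[i], " [", sub$start[i], ",", sub$end[i], ") and ",
               sub$band[i + 1L], " [", sub$start[i + 1L], ",", sub$end[i + 1L], ")")
        }
      }
    }
  }
  df$region_id <- if (nrow(df)) region_label(df$chrom, df$band) else character()
  rownames(df) <- NULL
  class(df) <- c("cytoband_map", "data.frame")
  df
}

#' Coarsen a cytoband map to major bands
#'
#' Merges sub-bands (e.g. q22.31, q22.32, q22.33) into their major band
#' (q22) by dropping the suffix after the dot and unioning extents.
#' Sub-bands of a major band must be contiguous within the chromosome,
#' which holds for conventional cytoband tables.
#'
#' @param bands A `cytoband_map` at sub-band granularity.
#' @return A `cytoband_map` at major-band granularity.
#' @export
coarsen_bands <- function(bands) {
  major <- sub("\\..*$", "", bands$band)
  key <- paste(bands$chrom, major, sep = "\r")
  merged <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- bands[key == k, , drop = FALSE]
    data.frame(chrom = sub$chrom[1L], start = min(sub$start),
               end = max(sub$end), band = sub("^.*\r", "", k),
               stringsAsFactors = FALSE)
  }))
  cytoband_map(merged)
}

#' Read a BED-like probe annotation table
#'
#' Columns (tab-separated, no header, `#` comments allowed): `chrom`,
#' `start`, `end`, `probe_id`, `molecule` (miRNA or mRNA), `strand`
#' (`+`, `-` or `.`), `symbol` (optional).
#'
#' @param path Path to the annotation TSV.
#' @return A `probe_annotation` data frame; `region_id` is `NA` until
#'   [assign_regions()] is applied.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6L || ncol(df) > 8L) {
    stop("probe annotation must have 6-8 tab-separated columns, found ",
         ncol(df))
  }
  names(df) <- c("chrom", "start", "end", "probe_id", "molecule", "strand",
                 "symbol", "region_id")[seq_len(ncol(df))]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyNA(df$start) || anyNA(df$end)) stop("non-numeric probe coordinate")
  if ("region_id" %in% names(df)) df$region_id[df$region_id == "."] <- NA
  if ("symbol" %in% names(df)) df$symbol[df$symbol == "."] <- NA
  probe_annotation(df)
}

#' Construct and validate a probe annotation
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `probe_id`,
#'   `molecule`, `strand`, and optionally `symbol` and `region_id`.
#' @return Validated `probe_annotation` data frame.
#' @export
probe_annotation <- function(df) {
  req <- c("chrom", "start", "end", "probe_id", "molecule", "strand")
  stopifnot(all(req %in% names(df)))
  if (!"symbol" %in% names(df)) df$symbol <- NA_character_
  if (!"region_id" %in% names(df)) df$region_id <- NA_character_
  if (nrow(df)) {
    if (any(df$start >= df$end)) {
      i <- which(df$start >= df$end)[1L]
      stop("probe with start >= end: ", df$probe_id[i])
    }
    if (anyDuplicated(df$probe_id)) {
      stop("duplicate probe_id: ",
           df$probe_id[duplicated(df$probe_id)][1L])
    }
    bad <- setdiff(unique(df$molecule), MOLECULES)
    if (length(bad)) stop("unknown molecule token: ", bad[1L])
    badstr <- setdiff(unique(df$strand), c("+", "-", "."))
    if (length(badstr)) stop("unknown strand token: ", badstr[1L])
  }
  for (m in MOLECULES) {
    msg("probe annotation: %d %s probes", sum(df$molecule == m), m)
  }
  rownames(df) <- NULL
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Assign each probe to the cytoband containing its midpoint
#'
#' Membership uses the probe midpoint and the half-open `[start, end)` band
#' convention, so a midpoint equal to a band's end coordinate falls in the
#' next band. Probes whose midpoint is not covered by any band (or whose
#' chromosome is absent from the map) are left unassigned; they are excluded
#' from region scans.
#'
#' @param probes A `probe_annotation` data frame.
#' @param bands A `cytoband_map`.
#' @return The probes with `region_id` filled in (NA when unassigned).
#' @export
assign_regions <- function(probes, bands) {
  probes$region_id <- NA_character_
  if (nrow(probes) == 0L) return(probes)
  mid <- floor((probes$start + probes$end) / 2)
  for (ch in unique(probes$chrom)) {
    b <- bands[bands$chrom == ch, , drop = FALSE]
    idx <- which(probes$chrom == ch)
    if (nrow(b) == 0L) next
    # bands are sorted and non-overlapping within a chromosome
    j <- findInterval(mid[idx], b$start)
    hit <- j >= 1L & j <= nrow(b)
    hit[hit] <- mid[idx][hit] < b$end[j[hit]]
    probes$region_id[idx[hit]] <- b$region_id[j[hit]]
  }
  n_un <- sum(is.na(probes$region_id))
  if (n_un > 0L) msg("assign_regions: %d probe(s) left unassigned", n_un)
  probes
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is a TSV whose header row holds sample ids and whose
#' first column is `probe_id`; intensities are linear and non-negative.
#' The metadata file maps `sample_id` to `cell_line`, `condition`
#' (parental/resistant) and `molecule` (miRNA/mRNA).
#'
#' @param path Path to the expression TSV.
#' @param meta_path Path to the sample metadata TSV (with header).
#' @return An `expr_matrix` object.
#' @export
read_expression_matrix <- function(path, meta_path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, header = TRUE, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- tab[[1L]]
  expr_matrix(vals, meta)
}

#' Construct and validate an expression matrix
#'
#' @param values Numeric matrix, probes x samples, with probe ids as
#'   rownames and sample ids as colnames; linear non-negative intensities.
#' @param sample_meta Data frame with columns `sample_id`, `cell_line`,
#'   `condition`, `molecule`.
#' @return An `expr_matrix`: a list with `values`, `probe_ids`,
#'   `sample_ids`, `sample_meta`.
#' @export
expr_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values),
            all(c("sample_id", "cell_line", "condition", "molecule") %in%
                  names(sample_meta)))
  if (anyNA(values)) stop("expression matrix contains NA values")
  if (any(values < 0)) stop("negative intensity in expression matrix")
  missing <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing)) {
    stop("sample(s) in matrix missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(sample_meta$condition), CONDITIONS)
  if (length(bad)) stop("unknown condition: ", bad[1L])
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values,
                 probe_ids = rownames(values),
                 sample_ids = colnames(values),
                 sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_meta$molecule), collapse = "/")))
  invisible(x)
}

#' Write an expression matrix and its metadata
#'
#' Values are rendered at full double precision so that a write/read cycle
#' reproduces the matrix bit-identically.
#'
#' @param expr An `expr_matrix`.
#' @param path Output path for the value TSV.
#' @param meta_path Output path for the metadata TSV.
#' @export
write_expression_matrix <- function(expr, path, meta_path) {
  vals <- expr$values
  out <- cbind(probe_id = rownames(vals),
               as.data.frame(apply(vals, 2L, format_full),
                             stringsAsFactors = FALSE))
  names(out) <- c("probe_id", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a probe annotation table (with region assignments)
#'
#' @param probes A `probe_annotation`.
#' @param path Output TSV path.
#' @export
write_probe_annotation <- function(probes, path) {
  df <- as.data.frame(probes)
  df <- df[, c("chrom", "start", "end", "probe_id", "molecule", "strand",
               "symbol", "region_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = ".")
  invisible(path)
}

#' Write a cytoband map
#'
#' @param bands A `cytoband_map`.
#' @param path Output TSV path.
#' @export
write_cytoband_table <- function(bands, path) {
  df <- as.data.frame(bands)[, c("chrom", "start", "end", "band")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
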