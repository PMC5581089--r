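# Internal helpers shared across modules.

#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Round half away from zero, the convention used for printed resistance
# ratios (round() in R rounds half to even, which would print 0.5 -> 0).
#' @noRd
round_half_away <- function(x, decimals = 0L) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Max-precision decimal rendering so that write -> read round-trips are
# bit-identical for doubles.
#' @noRd
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Chromosome sort order for reports and Manhattan x-offsets: 1..22, X, Y,
# then anything else alphabetically.
#' @noRd
chrom_order <- function(chroms) {
  nm <- sub("^chr", "", chroms)
  rank <- suppressWarnings(as.integer(nm))
  rank[nm == "X"] <- 100L
  rank[nm == "Y"] <- 101L
  rank[is.na(rank)] <- 102L
  order(rank, nm)
}

# Human-readable region label: chromosome number + band, e.g. "9q22.32".
#' @noRd
region_label <- function(chrom, band) {
  paste0(sub("^chr", "", chrom), band)
}

# Deterministic sub-seed per generator stage, kept inside 32-bit range.
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + h * 1299721) %% 2147483647
}

#' @noRd
msg <- function(...) message("[resistscan] ", sprintf(...))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
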