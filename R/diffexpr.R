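# Resistant-vs-parental fold changes per probe and the 2-fold
# deregulation rule ("downregulated" = fold change < 50%).

#' Per-probe fold changes between resistant and parental samples
#'
#' Computes, for one cell line, the ratio of mean resistant intensity to
#' mean parental intensity on the linear scale. Replicates are aggregated
#' by arithmetic mean (geometric optional) and the aggregated means are
#' floored at `floor_intensity` before the ratio so that fold changes are
#' always finite and positive. Probes that are all-zero in both conditions
#' are uninformative and get `fc = 1`.
#'
#' Flags use strict inequalities: `down_flag` iff `fc < 0.5`, `up_flag`
#' iff `fc > 2`.
#'
#' @param expr An [expr_matrix()].
#' @param cell_line Cell line whose parental/resistant pair to compare.
#' @param molecule Optional molecule filter ("miRNA" or "mRNA").
#' @param floor_intensity Detection floor applied to condition means before
#'   the ratio (linear intensity units). Default 1.
#' @param aggregate Replicate aggregation, `"arithmetic"` (default) or
#'   `"geometric"` mean.
#' @return A `fold_change` data frame: `probe_id`, `fc`, `log2fc`,
#'   `down_flag`, `up_flag`, `uninformative`.
#' @export
compute_fold_changes <- function(expr, cell_line,
                                 molecule = NULL,
                                 floor_intensity = 1.0,
                                 aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  meta <- expr$sample_meta
  sel <- meta$cell_line == cell_line
  if (!is.null(molecule)) sel <- sel & meta$molecule == molecule
  par_ids <- meta$sample_id[sel & meta$condition == "parental"]
  res_ids <- meta$sample_id[sel & meta$condition == "resistant"]
  if (length(par_ids) == 0L || length(res_ids) == 0L) {
    stop("cell line '", cell_line, "' needs at least one parental and one ",
         "resistant sample", if (!is.null(molecule)) paste0(" (", molecule, ")"))
  }
  agg <- function(m) {
    if (aggregate == "arithmetic") rowMeans(m) else exp(rowMeans(log(pmax(m, .Machine$double.xmin))))
  }
  par_mean <- agg(expr$values[, par_ids, drop = FALSE])
  res_mean <- agg(expr$values[, res_ids, drop = FALSE])
  uninformative <- par_mean == 0 & res_mean == 0
  fc <- pmax(res_mean, floor_intensity) / pmax(par_mean, floor_intensity)
  fc[uninformative] <- 1.0
  out <- data.frame(probe_id = expr$probe_ids,
                    fc = unname(fc),
                    log2fc = unname(log2(fc)),
                    down_flag = unname(fc < 0.5),
                    up_flag = unname(fc > 2.0),
                    uninformative = unname(uninformative),
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_change", "data.frame")
  out
}

#' Split probes into down- and up-regulated sets at a fold threshold
#'
#' @param records A `fold_change` data frame from [compute_fold_changes()].
#' @param threshold Fold threshold (> 1); down means `fc < 1/threshold`,
#'   up means `fc > threshold`, both strict.
#' @return List with character vectors `down_ids` and `up_ids`.
#' @export
flag_deregulated <- function(records, threshold = 2.0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1) {
    stop("threshold must be a single number > 1")
  }
  down_ids <- records$probe_id[records$fc < 1 / threshold]
  up_ids <- records$probe_id[records$fc > threshold]
  msg("flag_deregulated: %d down, %d up of %d probes (threshold %g)",
      length(down_ids), length(up_ids), nrow(records), threshold)
  list(down_ids = down_ids, up_ids = up_ids)
}

#' Write a fold-change table
#'
#' @param records A `fold_change` data frame.
#' @param path Output TSV path.
#' @export
write_fold_changes <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
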