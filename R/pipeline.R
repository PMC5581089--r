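# End-to-end orchestration: read inputs -> assign regions -> fold changes
# -> region scans per platform -> Manhattan tables -> concordance; and the
# dose-response branch (plates -> fits -> resistance ratios). Every stage
# writes its TSV and the run manifest records parameters, input checksums
# and stage counts.

#' Run configuration for the scan pipeline
#'
#' @param cytobands,annotation Paths to the cytoband and probe-annotation
#'   TSVs.
#' @param expression Named list (by molecule) of expression TSV paths.
#' @param metadata Named list (by molecule) of sample-metadata TSV paths.
#' @param outdir Output directory.
#' @param cell_line Cell line to compare.
#' @param alpha Fisher significance threshold (default 2e-3).
#' @param fold_threshold Fold threshold defining deregulation (default 2).
#' @param min_probes Minimum probes per tested band (default 2).
#' @param sided Test sidedness, `"one"` or `"two"`.
#' @return A `run_config` list.
#' @export
run_config <- function(cytobands, annotation, expression, metadata, outdir,
                       cell_line, alpha = 2e-3, fold_threshold = 2.0,
                       min_probes = 2L, sided = "one") {
  for (f in c(cytobands, annotation, unlist(expression), unlist(metadata))) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  stopifnot(alpha > 0, alpha <= 1, fold_threshold > 1, min_probes >= 1)
  structure(list(cytobands = cytobands, annotation = annotation,
                 expression = expression, metadata = metadata,
                 outdir = outdir, cell_line = cell_line, alpha = alpha,
                 fold_threshold = fold_threshold,
                 min_probes = as.integer(min_probes), sided = sided),
            class = "run_config")
}

#' Run the positional enrichment scan end to end
#'
#' For each platform (miRNA, mRNA): reads the expression matrix, computes
#' resistant/parental fold changes, flags probes downregulated below
#' `1/fold_threshold`, tests every cytoband with the one-sided Fisher
#' exact test, and writes fold-change, scan and Manhattan TSVs. Regions
#' significant on both platforms are written to `concordant.tsv`. A
#' `manifest.tsv` records parameters, input MD5 checksums, per-stage
#' counts and output checksums; rerunning an identical configuration
#' reproduces all outputs byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a report list: `scans` (per molecule), `manhattan`
#'   tables, `concordant` region ids, `manifest` data frame.
#' @export
run_scan_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(config$outdir, ...)
  manifest <- list()
  note <- function(key, value) manifest[[length(manifest) + 1L]] <<-
    data.frame(key = key, value = as.character(value), stringsAsFactors = FALSE)

  note("alpha", config$alpha)
  note("fold_threshold", config$fold_threshold)
  note("min_probes", config$min_probes)
  note("sided", config$sided)
  note("cell_line", config$cell_line)
  for (f in c(config$cytobands, config$annotation,
              unlist(config$expression), unlist(config$metadata))) {
    note(paste0("md5_input_", basename(f)), unname(tools::md5sum(f)))
  }

  bands <- read_cytoband_table(config$cytobands)
  probes <- suppressMessages(read_probe_annotation(config$annotation))
  probes <- suppressMessages(assign_regions(probes, bands))
  note("probes_total", nrow(probes))
  note("probes_assigned", sum(!is.na(probes$region_id)))
  note("probes_unassigned", sum(is.na(probes$region_id)))

  scans <- list(); mts <- list(); outputs <- character()
  for (mol in names(config$expression)) {
    expr <- read_expression_matrix(config$expression[[mol]],
                                   config$metadata[[mol]])
    fc <- compute_fold_changes(expr, config$cell_line, molecule = mol)
    write_fold_changes(fc, o(sprintf("fold_changes_%s.tsv", mol)))
    outputs <- c(outputs, o(sprintf("fold_changes_%s.tsv", mol)))
    down <- suppressMessages(flag_deregulated(fc, config$fold_threshold))
    note(sprintf("%s_down", mol), length(down$down_ids))
    note(sprintf("%s_up", mol), length(down$up_ids))
    scan <- suppressMessages(
      scan_regions(fc, probes, alpha = config$alpha,
                   min_probes = config$min_probes,
                   fold_threshold = config$fold_threshold,
                   molecule = mol, sided = config$sided))
    note(sprintf("%s_universe", mol), scan$universe_size)
    note(sprintf("%s_regions_tested", mol), nrow(scan$results))
    note(sprintf("%s_significant", mol), sum(scan$results$significant))
    write_scan_result(scan, o(sprintf("scan_%s.tsv", mol)))
    outputs <- c(outputs, o(sprintf("scan_%s.tsv", mol)))
    mt <- manhattan_table(scan, bands)
    write_manhattan_table(mt, o(sprintf("manhattan_%s.tsv", mol)))
    outputs <- c(outputs, o(sprintf("manhattan_%s.tsv", mol)))
    scans[[mol]] <- scan
    mts[[mol]] <- mt
  }

  concordant <- if (all(c("miRNA", "mRNA") %in% names(scans))) {
    concordant_regions(scans$miRNA, scans$mRNA)
  } else character()
  utils::write.table(data.frame(region_id = concordant),
                     o("concordant.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, o("concordant.tsv"))
  note("concordant_regions", length(concordant))
  for (f in outputs) {
    note(paste0("md5_output_", basename(f)), unname(tools::md5sum(f)))
  }
  man <- do.call(rbind, manifest)
  utils::write.table(man, o("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(scans = scans, manhattan = mts, concordant = concordant,
                 manifest = man))
}

#' Run the dose-response branch: fits and resistance ratios
#'
#' Reads a plate TSV, fits an IC50 per drug/sample dataset, and computes
#' the requested resistance ratios. The pairs table needs columns
#' `numerator_label`, `denominator_label` and optionally `decimals`
#' (default 1) and `drug`; in printed-values mode it may instead carry
#' `ic50_num` and `ic50_den` columns, bypassing fitting. Censored ratios
#' are rendered `"> x"`.
#'
#' @param plates Path to the plate TSV (may be `NULL` in printed-values
#'   mode).
#' @param pairs Path to the ratio pairs TSV.
#' @param outdir Output directory.
#' @param method Fit method for [fit_ic50()].
#' @return Invisibly, list with `fits` and `ratios` data frames.
#' @export
run_doseresponse <- function(plates, pairs, outdir,
                             method = "loglinear_interp") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pair_tab <- utils::read.delim(pairs, header = TRUE,
                                stringsAsFactors = FALSE, comment.char = "#")
  fits <- NULL
  fit_lookup <- list()
  if (!is.null(plates)) {
    datasets <- read_plate_table(plates)
    fits <- fit_plate_ic50s(datasets, method = method)
    utils::write.table(fits[, setdiff(names(fits), "fit")],
                       file.path(outdir, "fits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (i in seq_len(nrow(fits))) {
      fit_lookup[[paste(fits$drug[i], fits$sample_label[i], sep = ":")]] <-
        fits$fit[[i]]
    }
  }
  printed_mode <- all(c("ic50_num", "ic50_den") %in% names(pair_tab))
  rows <- lapply(seq_len(nrow(pair_tab)), function(i) {
    decimals <- if ("decimals" %in% names(pair_tab)) pair_tab$decimals[i] else 1L
    if (printed_mode) {
      rr <- resistance_ratio(pair_tab$ic50_num[i], pair_tab$ic50_den[i],
                             decimals = decimals,
                             numerator_label = pair_tab$numerator_label[i],
                             denominator_label = pair_tab$denominator_label[i])
    } else {
      drug <- if ("drug" %in% names(pair_tab)) pair_tab$drug[i] else
        fits$drug[1L]
      fn <- fit_lookup[[paste(drug, pair_tab$numerator_label[i], sep = ":")]]
      fd <- fit_lookup[[paste(drug, pair_tab$denominator_label[i], sep = ":")]]
      if (is.null(fn) || is.null(fd)) {
        stop("unpaired ratio labels: ", pair_tab$numerator_label[i], " / ",
             pair_tab$denominator_label[i])
      }
      rr <- resistance_ratio(fn, fd, decimals = decimals,
                             numerator_label = pair_tab$numerator_label[i],
                             denominator_label = pair_tab$denominator_label[i])
    }
    data.frame(numerator_label = rr$numerator_label,
               denominator_label = rr$denominator_label,
               ratio = rr$label, censored = rr$censored,
               stringsAsFactors = FALSE)
  })
  ratios <- if (length(rows)) do.call(rbind, rows) else
    data.frame(numerator_label = character(), denominator_label = character(),
               ratio = character(), censored = logical())
  utils::write.table(ratios, file.path(outdir, "ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fits = fits, ratios = ratios))
}
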