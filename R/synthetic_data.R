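# Deterministic generator for every input the pipeline consumes, with
# machine-readable planted ground truth: a banded genome with probe
# annotations, paired parental/resistant expression with one coordinately
# downregulated band, dose-response plates with known IC50s, and UTRs with
# planted seed sites.

# Sub-band names given to consecutive bands of each chromosome; with the
# default 10 bands per chromosome the planted default locus "9q22.32"
# exists by construction.
BAND_NAMES_10 <- c("p21.3", "p21.2", "p21.1", "p13.3", "q21.1",
                   "q21.3", "q22.31", "q22.32", "q22.33", "q31.1")

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a
#' 10-chromosome genome of 100 cytobands carrying 1000 probes per
#' platform (miRNA and mRNA), one parental and one resistant array per
#' platform, log-normal intensities with multiplicative replicate noise, a
#' planted band ("9q22.32") whose probes are all downregulated 4-fold in
#' the resistant condition on both platforms, and a 5% background rate of
#' spurious 4-fold downregulation elsewhere. Dose-response defaults plant
#' a ten-fold resistant/parental IC50 pair (76 vs 7.6 uM) on an 8-point
#' half-log concentration grid with 3 replicates and absorbance noise
#' sd 0.05.
#'
#' @param rng_seed Integer master seed; every generator stage derives its
#'   own sub-seed from it.
#' @param n_chroms,bands_per_chrom,band_length_bp Genome layout.
#' @param probes_per_band Named vector, probes per band per platform.
#' @param baseline_log2_mean,baseline_log2_sd Log2 parameters of the
#'   log-normal baseline intensity.
#' @param background_down_rate Fraction of non-planted probes spuriously
#'   downregulated in the resistant condition.
#' @param background_down_effect Fold applied to spurious probes.
#' @param planted List of planted signals: each a list with `band`
#'   (region id), `molecules`, `effect_fold` (>= 2), `fraction_affected`.
#' @param replicates Named vector: arrays per condition.
#' @param replicate_noise_log2_sd Multiplicative (log2) replicate noise.
#' @param cell_line Cell-line label used in sample metadata.
#' @param dose List: `ic50_um` (named planted IC50s), `hill`, `top`,
#'   `bottom`, `noise_sd` (viability-fraction scale), `concentrations`
#'   (uM), `replicates`, `drug`, `gain`, `blank`.
#' @param utr List: `length` (nt), `n_sites`, `site_type`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_chroms = 10L,
                       bands_per_chrom = 10L,
                       band_length_bp = 1e7,
                       probes_per_band = c(miRNA = 10L, mRNA = 10L),
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 2,
                       background_down_rate = 0.05,
                       background_down_effect = 4,
                       planted = list(list(band = "9q22.32",
                                           molecules = c("miRNA", "mRNA"),
                                           effect_fold = 4,
                                           fraction_affected = 1)),
                       replicates = c(parental = 1L, resistant = 1L),
                       replicate_noise_log2_sd = 0.25,
                       cell_line = "DLD-1",
                       dose = list(ic50_um = c(parental = 7.6, resistant = 76),
                                   hill = 1, top = 1, bottom = 0,
                                   noise_sd = 0.05,
                                   concentrations = 10^seq(-1, 2.5, by = 0.5),
                                   replicates = 3L, drug = "FTD",
                                   gain = 0.8, blank = 0.1),
                       utr = list(length = 300L, n_sites = 3L,
                                  site_type = "7mer-m8")) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_chroms = n_chroms,
              bands_per_chrom = bands_per_chrom,
              band_length_bp = band_length_bp,
              probes_per_band = probes_per_band,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              background_down_rate = background_down_rate,
              background_down_effect = background_down_effect,
              planted = planted, replicates = replicates,
              replicate_noise_log2_sd = replicate_noise_log2_sd,
              cell_line = cell_line, dose = dose, utr = utr)
  stopifnot(cfg$n_chroms >= 1, cfg$bands_per_chrom >= 1,
            cfg$band_length_bp >= 1e4, all(cfg$probes_per_band >= 1),
            cfg$background_down_rate >= 0, cfg$background_down_rate < 1,
            all(cfg$replicates >= 1))
  for (pl in cfg$planted) {
    if (pl$effect_fold < 2) stop("planted effect_fold must be >= 2 to cross the 0.5 rule")
    if (pl$fraction_affected <= 0 || pl$fraction_affected > 1) {
      stop("fraction_affected must be in (0, 1]")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a banded genome with probe annotations
#'
#' Bands tile each chromosome contiguously; probes are placed uniformly at
#' random within their band. Chromosome names are chr1..chrN; band names
#' cycle through a fixed sub-band vocabulary so region ids look like real
#' cytobands (with defaults, "9q22.32" exists).
#'
#' @param config A [sim_config()].
#' @return List with `bands` (a `cytoband_map`) and `probes` (a
#'   region-assigned `probe_annotation`).
#' @export
gen_genome <- function(config) {
  set.seed(stage_seed(config$rng_seed, "genome"))
  nb <- config$bands_per_chrom
  band_names <- if (nb == 10L) BAND_NAMES_10 else
    sprintf("q%d.%d", 11L + (seq_len(nb) - 1L) %/% 4L, (seq_len(nb) - 1L) %% 4L + 1L)
  L <- config$band_length_bp
  bands <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    data.frame(chrom = paste0("chr", ci),
               start = (seq_len(nb) - 1L) * L,
               end = seq_len(nb) * L,
               band = band_names,
               stringsAsFactors = FALSE)
  }))
  bands <- cytoband_map(bands)
  widths <- c(miRNA = 80L, mRNA = 60L)
  rows <- list()
  for (mol in names(config$probes_per_band)) {
    k <- config$probes_per_band[[mol]]
    for (bi in seq_len(nrow(bands))) {
      pos <- floor(stats::runif(k, bands$start[bi], bands$end[bi] - widths[[mol]]))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = bands$chrom[bi],
        start = pos,
        end = pos + widths[[mol]],
        probe_id = sprintf("%s_%s_%02d", sub("RNA", "R", mol),
                           bands$region_id[bi], seq_len(k)),
        molecule = mol,
        strand = sample(c("+", "-"), k, replace = TRUE),
        symbol = sprintf("%s%s.%02d", if (mol == "miRNA") "MIR" else "GENE",
                         gsub("[^0-9A-Za-z]", "", bands$region_id[bi]),
                         seq_len(k)),
        stringsAsFactors = FALSE)
    }
  }
  probes <- suppressMessages(probe_annotation(do.call(rbind, rows)))
  probes <- suppressMessages(assign_regions(probes, bands))
  list(bands = bands, probes = probes)
}

#' Generate paired parental/resistant expression with planted signal
#'
#' Baseline probe intensity is log-normal (`2^N(mean, sd)` in log2
#' units); each array adds multiplicative log-normal replicate noise.
#' Resistant arrays divide planted probes by their `effect_fold` and an
#' independent Bernoulli(`background_down_rate`) subset of the remaining
#' probes by `background_down_effect`.
#'
#' @param config A [sim_config()].
#' @param genome Output of [gen_genome()].
#' @return List with one `expr_matrix` per platform (named by molecule)
#'   and `truth`: a data frame `probe_id`, `molecule`, `status`
#'   (planted/spurious), `effect_fold`.
#' @export
gen_expression_pair <- function(config, genome) {
  out <- list()
  truth <- list()
  for (mol in names(config$probes_per_band)) {
    set.seed(stage_seed(config$rng_seed, paste0("expr_", mol)))
    probes <- genome$probes[genome$probes$molecule == mol, , drop = FALSE]
    np <- nrow(probes)
    baseline <- 2^stats::rnorm(np, config$baseline_log2_mean,
                               config$baseline_log2_sd)
    effect <- rep(1, np)
    status <- rep("null", np)
    for (pl in config$planted) {
      if (!mol %in% pl$molecules) next
      in_band <- which(probes$region_id == pl$band)
      if (length(in_band) == 0L) stop("planted band ", pl$band, " has no ", mol, " probes")
      n_aff <- max(1L, round(length(in_band) * pl$fraction_affected))
      aff <- in_band[seq_len(n_aff)]
      effect[aff] <- pl$effect_fold
      status[aff] <- "planted"
    }
    spur_pool <- which(status == "null")
    spur <- spur_pool[stats::runif(length(spur_pool)) < config$background_down_rate]
    effect[spur] <- config$background_down_effect
    status[spur] <- "spurious"

    n_par <- config$replicates[["parental"]]
    n_res <- config$replicates[["resistant"]]
    samp_noise <- function(n) {
      matrix(2^stats::rnorm(np * n, 0, config$replicate_noise_log2_sd), np, n)
    }
    par_vals <- baseline * samp_noise(n_par)
    res_vals <- (baseline / effect) * samp_noise(n_res)
    vals <- cbind(par_vals, res_vals)
    sids <- c(sprintf("%s_parental_%s_r%d", config$cell_line, mol, seq_len(n_par)),
              sprintf("%s_resistant_%s_r%d", config$cell_line, mol, seq_len(n_res)))
    colnames(vals) <- sids
    rownames(vals) <- probes$probe_id
    meta <- data.frame(sample_id = sids,
                       cell_line = config$cell_line,
                       condition = rep(c("parental", "resistant"),
                                       c(n_par, n_res)),
                       molecule = mol, stringsAsFactors = FALSE)
    out[[mol]] <- expr_matrix(vals, meta)
    truth[[mol]] <- data.frame(probe_id = probes$probe_id, molecule = mol,
                               status = status, effect_fold = effect,
                               stringsAsFactors = FALSE)
  }
  out$truth <- do.call(rbind, truth)
  rownames(out$truth) <- NULL
  out
}

#' Generate dose-response plates with known IC50s
#'
#' Viability follows a 4-parameter logistic
#' `v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)`, with Gaussian
#' noise of sd `noise_sd` added per replicate on the viability-fraction
#' scale; absorbances are `blank + gain * (v + noise)`, with untreated
#' control and blank rows included.
#'
#' @param config A [sim_config()].
#' @return List with `datasets` (list of `viability_dataset`, one per
#'   planted IC50) and `truth` (data frame `sample_label`, `drug`,
#'   `ic50_um`).
#' @export
gen_dose_response <- function(config) {
  d <- config$dose
  set.seed(stage_seed(config$rng_seed, "dose"))
  datasets <- list()
  for (lab in names(d$ic50_um)) {
    ic50 <- d$ic50_um[[lab]]
    conc <- c(0, d$concentrations)
    v <- d$bottom + (d$top - d$bottom) / (1 + (conc / ic50)^d$hill)
    v[conc == 0] <- d$top
    od <- lapply(v, function(vi) {
      d$blank + d$gain * (vi + stats::rnorm(d$replicates, 0, d$noise_sd))
    })
    label <- paste(config$cell_line, lab, sep = "/")
    datasets[[label]] <- viability_dataset(d$drug, label, conc, od, d$blank)
  }
  truth <- data.frame(sample_label = names(datasets), drug = d$drug,
                      ic50_um = unname(d$ic50_um[sub("^.*/", "", names(datasets))]),
                      stringsAsFactors = FALSE)
  list(datasets = datasets, truth = truth)
}

#' Generate a 3'-UTR with planted seed sites
#'
#' Background bases are drawn uniformly and rejection-sampled so that no
#' accidental occurrence of the seed's core match survives outside the
#' planted loci; sites of the configured type are inserted at
#' non-overlapping random positions with a guard base preventing
#' accidental upgrade to a longer site type.
#'
#' @param config A [sim_config()].
#' @param seed_7mer The miRNA seed (nt 2-8) whose sites to plant.
#' @param utr_id Identifier used in the truth table.
#' @return List with `sequence` (DNA string) and `sites` (data frame
#'   `utr_id`, `start`, `end`, `site_type`).
#' @export
gen_utr_with_sites <- function(config, seed_7mer, utr_id = "utr_1") {
  u <- config$utr
  len <- u$length
  n_sites <- u$n_sites
  site_type <- match.arg(u$site_type, SITE_TYPES)
  core6 <- seed_site_pattern(substr(seed_7mer, 1L, 6L))
  m8base <- substr(seed_site_pattern(seed_7mer), 1L, 1L)
  site_seq <- switch(site_type,
    "6mer" = core6,
    "7mer-A1" = paste0(core6, "A"),
    "7mer-m8" = paste0(m8base, core6),
    "8mer" = paste0(m8base, core6, "A"))
  slot <- nchar(site_seq) + 2L  # flanking guard positions
  if (n_sites > 0 && len < n_sites * 10L) stop("UTR too short to pack planted sites")
  set.seed(stage_seed(config$rng_seed, paste0("utr_", utr_id)))
  for (attempt in seq_len(50L)) {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (n_sites > 0) {
      # choose non-overlapping slots
      ok <- FALSE
      for (try in seq_len(200L)) {
        starts <- sort(sample.int(len - slot + 1L, n_sites))
        if (n_sites == 1L || all(diff(starts) >= slot)) { ok <- TRUE; break }
      }
      if (!ok) stop("infeasible site packing: ", n_sites, " sites in ", len, " nt")
      site_starts <- starts + 1L  # site begins after the leading guard base
      for (s in starts) {
        # leading guard: never the m8 base; trailing guard: never A and
        # never able to extend a core match
        chars[s] <- setdiff(c("C", "G", "T", "A"), m8base)[1L]
        substr_chars <- strsplit(site_seq, "", fixed = TRUE)[[1L]]
        chars[(s + 1L):(s + nchar(site_seq))] <- substr_chars
        chars[s + nchar(site_seq) + 1L] <- "C"
      }
    } else {
      site_starts <- integer()
    }
    seqstr <- paste(chars, collapse = "")
    found <- unlist(gregexpr(paste0("(?=", core6, ")"), seqstr, perl = TRUE))
    found <- found[found > 0]
    expected_core <- site_starts + (nchar(site_seq) - 6L) -
      (if (site_type %in% c("7mer-A1", "8mer")) 1L else 0L)
    if (setequal(found, expected_core)) break
    if (attempt == 50L) stop("could not generate a clean UTR background")
  }
  sites <- if (n_sites > 0) {
    data.frame(utr_id = utr_id,
               start = site_starts,
               end = site_starts + nchar(site_seq) - 1L,
               site_type = site_type, stringsAsFactors = FALSE)
  } else {
    data.frame(utr_id = character(), start = integer(), end = integer(),
               site_type = character(), stringsAsFactors = FALSE)
  }
  list(sequence = seqstr, sites = sites)
}

#' Write a full synthetic run to a directory
#'
#' Emits every input the pipeline consumes plus machine-readable ground
#' truth: cytobands, probe annotation, expression matrices and metadata
#' per platform, dose-response plates, miRNA/UTR FASTA, and truth TSVs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param mirna Optional `mirna_sequence` whose sites to plant in the UTR
#'   (default: the let-7d-5p sequence).
#' @return Invisibly, a named list of written paths.
#' @export
write_simulation <- function(config, outdir,
                             mirna = mirna_sequence("hsa-let-7d-5p",
                                                    "AGAGGUAGUAGGUUGCAUAGUU")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  genome <- gen_genome(config)
  write_cytoband_table(genome$bands, p("cytobands.tsv"))
  write_probe_annotation(genome$probes, p("annotation.tsv"))
  expr <- gen_expression_pair(config, genome)
  paths <- list(cytobands = p("cytobands.tsv"), annotation = p("annotation.tsv"))
  for (mol in names(config$probes_per_band)) {
    paths[[paste0("expr_", mol)]] <- p(sprintf("expression_%s.tsv", mol))
    paths[[paste0("meta_", mol)]] <- p(sprintf("samples_%s.tsv", mol))
    write_expression_matrix(expr[[mol]], paths[[paste0("expr_", mol)]],
                            paths[[paste0("meta_", mol)]])
  }
  utils::write.table(expr$truth, p("truth_expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dr <- gen_dose_response(config)
  plate_rows <- lapply(dr$datasets, function(ds) {
    odm <- do.call(rbind, ds$absorbances)
    reps <- ncol(odm)
    rbind(
      data.frame(drug = ds$drug, sample_label = ds$sample_label,
                 concentration_um = "blank",
                 matrix(rep(ds$blank, reps), 1L,
                        dimnames = list(NULL, sprintf("od595_%d", seq_len(reps)))),
                 check.names = FALSE, stringsAsFactors = FALSE),
      data.frame(drug = ds$drug, sample_label = ds$sample_label,
                 concentration_um = format_full(ds$concentrations),
                 matrix(format_full(odm), nrow(odm),
                        dimnames = list(NULL, sprintf("od595_%d", seq_len(reps)))),
                 check.names = FALSE, stringsAsFactors = FALSE))
  })
  plates <- do.call(rbind, plate_rows)
  utils::write.table(plates, p("plates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dr$truth, p("truth_ic50.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utr <- gen_utr_with_sites(config, mirna$seed, utr_id = "utr_1")
  writeLines(c(paste0(">", mirna$id), mirna$sequence), p("mirnas.fa"))
  writeLines(c(">utr_1", utr$sequence), p("utrs.fa"))
  utils::write.table(utr$sites, p("truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$plates <- p("plates.tsv")
  paths$mirnas <- p("mirnas.fa")
  paths$utrs <- p("utrs.fa")
  paths$truth_expression <- p("truth_expression.tsv")
  paths$truth_ic50 <- p("truth_ic50.tsv")
  paths$truth_sites <- p("truth_sites.tsv")
  invisible(paths)
}
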