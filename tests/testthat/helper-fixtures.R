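# Shared in-code fixtures: tiny genomes, matrices, and the independent
# hypergeometric enumeration oracle used against the Fisher implementation.

# Upper-tail hypergeometric probability by direct enumeration of the pmf
# over the whole support (independent of the log-space implementation).
enum_upper_tail <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(pmf[support >= a])
}

tiny_bands <- function() {
  cytoband_map(data.frame(
    chrom = c("chr1", "chr1", "chr9"),
    start = c(0, 1e6, 0),
    end = c(1e6, 2e6, 1e6),
    band = c("p11.1", "q11.1", "q22.32"),
    stringsAsFactors = FALSE))
}

tiny_probes <- function() {
  suppressMessages(probe_annotation(data.frame(
    chrom = c("chr1", "chr1", "chr9", "chrUn"),
    start = c(100, 1.5e6, 5e5, 10),
    end = c(180, 1.5e6 + 80, 5e5 + 60, 90),
    probe_id = c("p1", "p2", "p3", "p4"),
    molecule = c("miRNA", "miRNA", "mRNA", "mRNA"),
    strand = c("+", "-", "+", "."),
    symbol = c("A", "B", "C", "D"),
    stringsAsFactors = FALSE)))
}

# Expression matrix with explicit per-condition intensities for one
# cell line; `par` and `res` are named vectors of probe intensities.
tiny_expr <- function(par, res, molecule = "miRNA", cell_line = "CL") {
  vals <- cbind(par, res)
  colnames(vals) <- c("s_par", "s_res")
  expr_matrix(vals, data.frame(
    sample_id = c("s_par", "s_res"),
    cell_line = cell_line,
    condition = c("parental", "resistant"),
    molecule = molecule, stringsAsFactors = FALSE))
}

let7d <- function() mirna_sequence("hsa-let-7d-5p", "AGAGGUAGUAGGUUGCAUAGUU")

# Small fast simulation used where full defaults are unnecessary.
small_config <- function(seed = 1L,
                         planted = list(list(band = "2q12.1",
                                             molecules = c("miRNA", "mRNA"),
                                             effect_fold = 4,
                                             fraction_affected = 1)),
                         ...) {
  sim_config(rng_seed = seed, n_chroms = 4L, bands_per_chrom = 5L,
             probes_per_band = c(miRNA = 5L, mRNA = 5L),
             planted = planted, ...)
}
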