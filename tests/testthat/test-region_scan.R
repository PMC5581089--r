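# The per-cytoband enrichment test and its Manhattan/concordance outputs.

test_that("contingency tables count region/universe margins correctly", {
  universe <- sprintf("p%04d", 1:1000)
  region <- universe[1:10]
  down <- c(universe[1:6], universe[101:144])  # 6 in-region of 50 total
  tab <- build_region_table(region, down, universe)
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 6L, b = 4L, c = 44L, d = 946L))
  # empty region
  tab0 <- build_region_table(character(), down, universe)
  expect_equal(tab0$a + tab0$b, 0L)
  expect_equal(tab0$c, 50L)
  # region = universe
  tabU <- build_region_table(universe, down, universe)
  expect_equal(tabU$c + tabU$d, 0L)
  expect_error(build_region_table(c("nope"), down, universe), "subset")
})

test_that("one-sided Fisher p matches hand-enumerated values", {
  # only one table consistent with margins when nothing is down
  expect_equal(fisher_exact_one_sided(0, 10, 0, 90), 1.0)
  # (3,0;0,3): P(X = 3) = C(3,3)C(3,0)/C(6,3) = 1/20
  expect_equal(fisher_exact_one_sided(3, 0, 0, 3), 0.05, tolerance = 1e-12)
  # balanced table: observed equals its null expectation, so p > 0.5
  p_bal <- fisher_exact_one_sided(5, 5, 5, 5)
  expect_equal(p_bal, enum_upper_tail(5, 5, 5, 5), tolerance = 1e-12)
  expect_gt(p_bal, 0.5)
})

test_that("one-sided Fisher p agrees with independent implementations", {
  # random tables vs both the enumeration oracle and stats::fisher.test
  set.seed(99)
  for (i in 1:50) {
    a <- rpois(1, 3); b <- rpois(1, 8); c <- rpois(1, 20); d <- rpois(1, 300)
    p <- fisher_exact_one_sided(a, b, c, d)
    expect_equal(p, enum_upper_tail(a, b, c, d), tolerance = 1e-10)
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      alternative = "greater")$p.value
    expect_equal(p, ft, tolerance = 1e-10)
  }
})

test_that("enumerated hypergeometric pmf over the support sums to 1", {
  for (N in 2:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        support <- max(0, n - (N - K)):min(K, n)
        pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
        expect_equal(sum(pmf), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value is non-increasing in the observed in-region count", {
  # fixed margins N = 100, K = 20, n = 10; slide a over the support
  for (a in 1:10) {
    p_lo <- fisher_exact_one_sided(a - 1, 10 - (a - 1), 20 - (a - 1),
                                   100 - 10 - 20 + (a - 1))
    p_hi <- fisher_exact_one_sided(a, 10 - a, 20 - a, 100 - 10 - 20 + a)
    expect_lte(p_hi, p_lo + 1e-15)
  }
})

test_that("scan recovers a planted band and is permutation invariant", {
  cfg <- sim_config(rng_seed = 2024)
  g <- gen_genome(cfg)
  e <- gen_expression_pair(cfg, g)
  fc <- compute_fold_changes(e$miRNA, "DLD-1", molecule = "miRNA")
  scan <- suppressMessages(scan_regions(fc, g$probes, molecule = "miRNA"))
  expect_s3_class(scan, "scan_result")
  expect_equal(scan$universe_size, 1000L)
  best <- scan$results[which.min(scan$results$p), ]
  expect_equal(best$region_id, "9q22.32")
  expect_lte(best$p, 2e-3)
  expect_true(best$significant)
  # margins identical across regions
  expect_true(all(scan$results$a + scan$results$c == scan$down_total))
  # permutation invariance over probe input order
  set.seed(1)
  perm <- sample(nrow(fc))
  scan2 <- suppressMessages(scan_regions(fc[perm, ], g$probes,
                                         molecule = "miRNA"))
  expect_equal(scan2$results$p[match(scan$results$region_id,
                                     scan2$results$region_id)],
               scan$results$p)
})

test_that("a null scan has unit p-values; alpha = 1 makes all significant", {
  em <- tiny_expr(par = setNames(rep(100, 4), c("p1", "p2", "p3", "p4")),
                  res = setNames(rep(100, 4), c("p1", "p2", "p3", "p4")))
  probes <- suppressMessages(probe_annotation(data.frame(
    chrom = "chr1", start = c(0, 10, 1e6 + 0, 1e6 + 10) + 100,
    end = c(0, 10, 1e6, 1e6 + 10) + 180,
    probe_id = c("p1", "p2", "p3", "p4"), molecule = "miRNA",
    strand = "+", symbol = NA, stringsAsFactors = FALSE)))
  probes <- suppressMessages(assign_regions(probes, cytoband_map(data.frame(
    chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
    band = c("p11", "q11"), stringsAsFactors = FALSE))))
  fc <- compute_fold_changes(em, "CL")
  scan <- suppressMessages(scan_regions(fc, probes))
  expect_true(all(scan$results$p == 1))
  expect_false(any(scan$results$significant))
  scan_all <- suppressMessages(scan_regions(fc, probes, alpha = 1))
  expect_true(all(scan_all$results$significant))
})

test_that("min_probes excludes degenerate single-probe regions", {
  cfg <- small_config(5)
  g <- gen_genome(cfg)
  e <- gen_expression_pair(cfg, g)
  fc <- compute_fold_changes(e$miRNA, "DLD-1", molecule = "miRNA")
  scan_all <- suppressMessages(scan_regions(fc, g$probes, molecule = "miRNA",
                                            min_probes = 1))
  scan_high <- suppressMessages(scan_regions(fc, g$probes, molecule = "miRNA",
                                             min_probes = 6))
  expect_equal(nrow(scan_all$results), 20L)   # every band has 5 probes
  expect_equal(nrow(scan_high$results), 0L)
})

test_that("Manhattan table offsets chromosomes cumulatively", {
  cfg <- small_config(6)
  g <- gen_genome(cfg)
  e <- gen_expression_pair(cfg, g)
  fc <- compute_fold_changes(e$miRNA, "DLD-1", molecule = "miRNA")
  scan <- suppressMessages(scan_regions(fc, g$probes, molecule = "miRNA"))
  mt <- manhattan_table(scan, g$bands)
  expect_equal(attr(mt, "threshold"), -log10(2e-3))
  expect_equal(round(attr(mt, "threshold"), 5), 2.69897)
  # p = 1 regions sit at ordinate 0
  expect_true(all(mt$neg_log10_p[scan$results$p[match(mt$region_id,
    scan$results$region_id)] == 1] == 0))
  # chromosome lengths: 5 bands x 1e7 per chromosome
  L <- 5 * 1e7
  chr2 <- mt[mt$chrom == "chr2", ]
  expect_true(all(chr2$cumulative_x_bp >= L))
  expect_true(all(mt$cumulative_x_bp == sort(mt$cumulative_x_bp)))
  # region missing from the band map is an error
  expect_error(manhattan_table(scan, g$bands[g$bands$chrom != "chr2", ]),
               "without band coordinates")
})

test_that("concordant regions are the intersection, ordered by max p", {
  mk <- function(ids, ps, sig) {
    structure(list(results = data.frame(region_id = ids, p = ps,
                                        significant = sig,
                                        stringsAsFactors = FALSE)),
              class = "scan_result")
  }
  a <- mk(c("9q22.32", "1p11"), c(1e-5, 0.5), c(TRUE, FALSE))
  b <- mk(c("9q22.32", "3p21.1", "1p11"), c(1e-4, 1e-3, 1e-3),
          c(TRUE, TRUE, TRUE))
  expect_equal(concordant_regions(a, b), "9q22.32")
  a2 <- mk("2q11", 1e-4, TRUE)
  expect_equal(concordant_regions(a2, b), character())
})

test_that("the same band planted in both layers is returned as concordant", {
  cfg <- sim_config(rng_seed = 31)
  g <- gen_genome(cfg)
  e <- gen_expression_pair(cfg, g)
  scans <- lapply(c(miRNA = "miRNA", mRNA = "mRNA"), function(mol) {
    fc <- compute_fold_changes(e[[mol]], "DLD-1", molecule = mol)
    suppressMessages(scan_regions(fc, g$probes, molecule = mol))
  })
  expect_true("9q22.32" %in% concordant_regions(scans$miRNA, scans$mRNA))
})
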