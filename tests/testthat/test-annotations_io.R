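# Parsing, validation and region assignment of the scan's spatial inputs.

test_that("cytoband tables parse, sort, and reject overlaps", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr9\t90000000\t91000000\tq22.32\tgpos50",
               "chr9\t89000000\t90000000\tq22.31"), f)
  bands <- read_cytoband_table(f)
  expect_s3_class(bands, "cytoband_map")
  expect_equal(nrow(bands), 2L)
  expect_equal(bands$band, c("q22.31", "q22.32"))  # sorted by start
  expect_equal(bands$region_id, c("9q22.31", "9q22.32"))
  expect_equal(bands$start[2], 90000000)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t1000\tp1", "chr1\t500\t1500\tp2"), f2)
  expect_error(read_cytoband_table(f2), "overlapping.*p1.*p2")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\tabc\tp1"), f3)
  expect_error(read_cytoband_table(f3), "line 1")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f4)
  expect_warning(bands0 <- read_cytoband_table(f4), "empty")
  expect_equal(nrow(bands0), 0L)
})

test_that("probe annotations validate coordinates, molecules, uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "chr9\t90100000\t90100080\tlet-7d\tmiRNA\t+\tMIRLET7D"), f)
  probes <- suppressMessages(read_probe_annotation(f))
  expect_equal(probes$probe_id, "let-7d")
  expect_equal(probes$molecule, "miRNA")
  expect_true(is.na(probes$region_id))

  dup <- probes[c(1, 1), ]
  expect_error(probe_annotation(dup), "duplicate probe_id")
  bad <- probes; bad$start <- bad$end
  expect_error(probe_annotation(bad), "start >= end")
  bad2 <- probes; bad2$molecule <- "protein"
  expect_error(probe_annotation(bad2), "unknown molecule")
})

test_that("region assignment uses the midpoint and half-open bands", {
  bands <- tiny_bands()
  probes <- tiny_probes()
  out <- suppressMessages(assign_regions(probes, bands))
  expect_equal(out$region_id, c("1p11.1", "1q11.1", "9q22.32", NA))

  # midpoint exactly at a band's end falls in the next band
  edge <- suppressMessages(probe_annotation(data.frame(
    chrom = "chr1", start = 1e6 - 40, end = 1e6 + 40, probe_id = "edge",
    molecule = "miRNA", strand = "+", symbol = "E",
    stringsAsFactors = FALSE)))
  out2 <- suppressMessages(assign_regions(edge, bands))
  expect_equal(out2$region_id, "1q11.1")

  # idempotent and order-independent
  twice <- suppressMessages(assign_regions(out, bands))
  expect_identical(twice$region_id, out$region_id)
  shuf <- probes[c(3, 1, 4, 2), ]
  out3 <- suppressMessages(assign_regions(shuf, bands))
  expect_identical(out3$region_id[match(out$probe_id, out3$probe_id)],
                   out$region_id)
})

test_that("every probe is assigned to at most one band", {
  cfg <- small_config(11)
  g <- gen_genome(cfg)
  reassigned <- suppressMessages(assign_regions(g$probes, g$bands))
  expect_false(anyNA(reassigned$region_id))
  # generating band and assigned band agree (round-trip consistency)
  expect_identical(reassigned$region_id, g$probes$region_id)
})

test_that("coarsening merges sub-bands into contiguous major bands", {
  bands <- cytoband_map(data.frame(
    chrom = c("chr9", "chr9", "chr9", "chr9"),
    start = c(0, 10, 20, 30) * 1e6,
    end = c(10, 20, 30, 40) * 1e6,
    band = c("q22.31", "q22.32", "q22.33", "q31.1"),
    stringsAsFactors = FALSE))
  major <- coarsen_bands(bands)
  expect_equal(nrow(major), 2L)
  expect_equal(major$band, c("q22", "q31"))
  expect_equal(major$end[major$band == "q22"], 3e7)
  expect_equal(major$region_id, c("9q22", "9q31"))
  # region assignment works identically on the coarser map
  probes <- suppressMessages(probe_annotation(data.frame(
    chrom = "chr9", start = 15e6, end = 15e6 + 60, probe_id = "p1",
    molecule = "mRNA", strand = "+", symbol = NA,
    stringsAsFactors = FALSE)))
  out <- suppressMessages(assign_regions(probes, major))
  expect_equal(out$region_id, "9q22")
})

test_that("expression matrices validate metadata and reject negatives", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), cell_line = "CL",
                     condition = c("parental", "resistant"),
                     molecule = "miRNA", stringsAsFactors = FALSE)
  em <- expr_matrix(vals, meta)
  expect_equal(dim(em$values), c(3L, 2L))

  expect_error(expr_matrix(vals, meta[1, , drop = FALSE]),
               "missing from metadata")
  vals2 <- vals; vals2[1, 1] <- -5
  expect_error(expr_matrix(vals2, meta), "negative intensity")
})

test_that("expression matrices round-trip bit-identically through TSV", {
  set.seed(42)
  vals <- matrix(rlnorm(60, 5, 2), nrow = 20,
                 dimnames = list(sprintf("p%02d", 1:20),
                                 c("s1", "s2", "s3")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), cell_line = "CL",
                     condition = c("parental", "parental", "resistant"),
                     molecule = "mRNA", stringsAsFactors = FALSE)
  em <- expr_matrix(vals, meta)
  f <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, f, fm)
  back <- read_expression_matrix(f, fm)
  expect_identical(back$values, em$values)
  expect_identical(back$sample_meta, em$sample_meta)
})

test_that("probe annotations round-trip through TSV", {
  bands <- tiny_bands()
  probes <- suppressMessages(assign_regions(tiny_probes(), bands))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(probes, f)
  back <- suppressMessages(read_probe_annotation(f))
  expect_identical(back$probe_id, probes$probe_id)
  expect_identical(back$start, probes$start)
  expect_identical(back$molecule, probes$molecule)
})
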