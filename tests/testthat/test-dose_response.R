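# Viability normalization, IC50 fitting, censoring, and resistance ratios.

test_that("viability normalizes against blank and untreated control", {
  ds <- viability_dataset("FTD", "CL", c(0, 1, 3, 10, 30),
                         list(0.9, 0.8, 0.7, 0.5, 0.3), blank = 0.1)
  nv <- normalize_viability(ds)
  expect_equal(nv$viability[nv$concentration_um == 0], 1.0)
  expect_equal(nv$viability[nv$concentration_um == 10], 0.5)
  expect_equal(nv$viability[nv$concentration_um == 30], 0.25)
  # OD equal to blank maps to viability 0
  ds2 <- viability_dataset("FTD", "CL", c(0, 1, 3, 10, 30),
                          list(0.9, 0.9, 0.5, 0.3, 0.1), blank = 0.1)
  nv2 <- normalize_viability(ds2)
  expect_equal(nv2$viability[nv2$concentration_um == 1], 1.0)
  expect_equal(nv2$viability[nv2$concentration_um == 30], 0.0)
  expect_error(viability_dataset("FTD", "CL", c(0, 1, 3, 10, 30),
                                 list(0.1, 0.2, 0.2, 0.2, 0.2), blank = 0.1),
               "exceed the blank")
})

test_that("an exactly sampled 50% point is returned as the IC50", {
  cc <- c(1, 3, 10, 30, 100)
  vv <- 1 / (1 + cc / 10)   # v(10) = 0.5 exactly
  fit <- fit_ic50(cc, vv)
  expect_equal(fit$ic50_um, 10.0)
  expect_true(is.na(fit$censored))
})

test_that("the local regression line predicts 50% at the fitted IC50", {
  cc <- 10^seq(-1, 2.5, by = 0.5)
  vv <- 1 / (1 + (cc / 12)^1.3)
  fit <- fit_ic50(cc, vv)
  pred <- fit$coef$intercept + fit$coef$slope * log10(fit$ic50_um)
  expect_equal(pred, 0.5, tolerance = 1e-6)
  expect_gte(fit$ic50_um, fit$cmin)
  expect_lte(fit$ic50_um, fit$cmax)
})

test_that("viability above 50% at Cmax censors the IC50 as >Cmax", {
  fit <- fit_ic50(c(1, 10, 100, 400), c(0.98, 0.95, 0.9, 0.8))
  expect_true(is.na(fit$ic50_um))
  expect_equal(fit$censored, ">")
  expect_equal(ic50_label(fit), ">400")
  fit2 <- fit_ic50(c(1, 10, 100, 400), c(0.45, 0.3, 0.2, 0.1))
  expect_equal(fit2$censored, "<")
  expect_equal(ic50_label(fit2), "<1")
})

test_that("noiseless 4PL data is recovered within 1% by the logistic fit", {
  cc <- 10^seq(-1, 2.5, by = 0.5)
  vv <- 1 / (1 + (cc / 7.6)^1.2)
  fit <- fit_ic50(cc, vv, method = "logistic4p")
  expect_lt(abs(fit$ic50_um - 7.6) / 7.6, 0.01)
})

test_that("loglinear and 4PL agree within 15% on noiseless logistic data", {
  cc <- 10^seq(-1, 2.5, by = 0.5)
  for (hill in c(0.8, 1, 1.5, 2)) {
    vv <- 1 / (1 + (cc / 7.6)^hill)
    ll <- fit_ic50(cc, vv)$ic50_um
    lg <- fit_ic50(cc, vv, method = "logistic4p")$ic50_um
    expect_lt(abs(ll - lg) / lg, 0.15)
  }
})

test_that("median relative IC50 error under noise stays below 10%", {
  cc <- 10^seq(-1, 2.5, by = 0.5)
  truth <- 7.6
  errs <- vapply(1:40, function(s) {
    set.seed(s)
    vm <- vapply(cc, function(ci)
      mean(1 / (1 + ci / truth) + rnorm(3, 0, 0.05)), numeric(1))
    abs(fit_ic50(cc, vm)$ic50_um - truth) / truth
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("multiple 50% crossings warn and use the lowest", {
  cc <- c(1, 3, 10, 30, 100, 300)
  vv <- c(0.9, 0.4, 0.6, 0.55, 0.3, 0.1)  # crosses at 1-3, 3-10, 30-100
  expect_warning(fit <- fit_ic50(cc, vv), "lowest")
  expect_lt(fit$ic50_um, 10)
})

test_that("resistance ratios reproduce printed fold changes", {
  expect_equal(resistance_ratio(16.8, 7.6, 1)$ratio, 2.2)
  expect_equal(resistance_ratio(3.7, 13.9, 2)$ratio, 0.27)
  expect_equal(resistance_ratio(15.7, 82.7, 2)$ratio, 0.19)
  expect_equal(resistance_ratio(7.6, 7.6, 1)$ratio, 1.0)
})

test_that("censored numerators give '> bound' ratios, denominators error", {
  cens <- fit_ic50(c(1, 10, 100, 400), c(0.98, 0.95, 0.9, 0.8))
  rr <- resistance_ratio(cens, 10, 0)
  expect_true(rr$censored)
  expect_equal(rr$ratio, 40)
  expect_equal(rr$label, "> 40")
  expect_error(resistance_ratio(10, cens), "censored denominator")
})

test_that("ratio is reciprocal and invariant to concentration units", {
  cc <- 10^seq(-1, 2.5, by = 0.5)
  v1 <- 1 / (1 + (cc / 5)^1.1)
  v2 <- 1 / (1 + (cc / 20)^0.9)
  f1 <- fit_ic50(cc, v1); f2 <- fit_ic50(cc, v2)
  r12 <- f1$ic50_um / f2$ic50_um
  r21 <- f2$ic50_um / f1$ic50_um
  expect_equal(r12 * r21, 1, tolerance = 1e-12)
  # scaling concentrations by k scales IC50 by k, ratio unchanged
  k <- 1000
  f1k <- fit_ic50(cc * k, v1); f2k <- fit_ic50(cc * k, v2)
  expect_equal(f1k$ic50_um, f1$ic50_um * k, tolerance = 1e-9)
  expect_equal(f1k$ic50_um / f2k$ic50_um, r12, tolerance = 1e-9)
})

test_that("plate tables round-trip through the fitting front end", {
  cfg <- sim_config(rng_seed = 12)
  dir <- withr::local_tempdir()
  write_simulation(cfg, dir)
  datasets <- read_plate_table(file.path(dir, "plates.tsv"))
  expect_length(datasets, 2L)
  fits <- fit_plate_ic50s(datasets)
  truth <- read.delim(file.path(dir, "truth_ic50.tsv"))
  m <- match(fits$sample_label, truth$sample_label)
  expect_true(all(abs(fits$ic50_um - truth$ic50_um[m]) /
                    truth$ic50_um[m] < 0.25))
})
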