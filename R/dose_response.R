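# Viability normalization, IC50 estimation from regression of viability on
# log10 concentration, and resistance ratios (resistant / parental IC50),
# with ">Cmax" censoring when 50% inhibition is never reached.

#' Construct a viability dataset from plate readings
#'
#' @param drug Drug name (e.g. "FTD", "5-FU").
#' @param sample_label Cell line / treatment arm.
#' @param concentrations Concentrations in uM, including 0 for the
#'   untreated control; strictly increasing, >= 4 non-zero values.
#' @param absorbances List (or matrix rows) of OD595 replicate readings,
#'   one entry per concentration.
#' @param blank Blank OD595.
#' @return A `viability_dataset` object.
#' @export
viability_dataset <- function(drug, sample_label, concentrations,
                              absorbances, blank) {
  if (is.matrix(absorbances)) {
    absorbances <- lapply(seq_len(nrow(absorbances)),
                          function(i) absorbances[i, ])
  }
  stopifnot(length(concentrations) == length(absorbances),
            all(lengths(absorbances) >= 1L))
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  absorbances <- absorbances[ord]
  if (any(diff(concentrations) <= 0)) stop("concentrations must be strictly increasing")
  if (!any(concentrations == 0)) stop("an untreated control (concentration 0) is required")
  if (sum(concentrations > 0) < 4L) stop("need >= 4 non-zero concentrations")
  od0 <- mean(absorbances[[which(concentrations == 0)]])
  if (od0 <= blank) stop("untreated absorbance must exceed the blank")
  structure(list(drug = drug, sample_label = sample_label,
                 concentrations = concentrations,
                 absorbances = absorbances, blank = blank),
            class = "viability_dataset")
}

#' Normalize absorbances to viability fractions
#'
#' `viability(c) = (OD(c) - blank) / (OD(0) - blank)`; the untreated
#' control maps to 1 by construction. Values above 1 (growth stimulation)
#' are kept, not clipped.
#'
#' @param dataset A `viability_dataset`.
#' @return Data frame with `concentration_um`, `viability` (mean across
#'   replicates) and a `replicates` list-column of per-replicate fractions.
#' @export
normalize_viability <- function(dataset) {
  stopifnot(inherits(dataset, "viability_dataset"))
  od0 <- mean(dataset$absorbances[[which(dataset$concentrations == 0)]])
  denom <- od0 - dataset$blank
  reps <- lapply(dataset$absorbances, function(od) (od - dataset$blank) / denom)
  out <- data.frame(concentration_um = dataset$concentrations,
                    viability = vapply(reps, mean, numeric(1L)))
  out$replicates <- reps
  out
}

#' Fit an IC50 from viability versus log10 concentration
#'
#' Two estimators:
#' \describe{
#' \item{`loglinear_interp`}{(default) A local regression line of viability
#'   on log10 concentration over the two points bracketing the 50%
#'   crossing plus their immediate neighbours (4 points when available),
#'   solved for viability = 0.5. If viability never reaches 0.5 by the
#'   highest concentration the IC50 is censored `">Cmax"`; if it is
#'   already below 0.5 at the lowest concentration it is `"<Cmin"`. If a
#'   sampled point sits exactly at 50% that concentration is returned.}
#' \item{`logistic4p`}{A 4-parameter logistic
#'   `v = bottom + (top - bottom) / (1 + (c/ic50)^hill)` fitted by
#'   Levenberg-Marquardt least squares; the IC50 is the curve midpoint on
#'   the concentration axis.}
#' }
#'
#' @param concentrations Concentrations in uM (the untreated 0 is ignored
#'   for fitting).
#' @param viability Viability fractions paired with `concentrations`.
#' @param method `"loglinear_interp"` or `"logistic4p"`.
#' @return A `dose_response_fit`: `ic50_um` (NA when censored), `censored`
#'   (`NA`, `">"` or `"<"`), `cmin`/`cmax`, `method`, `coef`, `r2`.
#' @export
fit_ic50 <- function(concentrations, viability,
                     method = c("loglinear_interp", "logistic4p")) {
  method <- match.arg(method)
  if (length(concentrations) != length(viability)) {
    stop("concentrations and viability must have equal length")
  }
  keep <- concentrations > 0
  cc <- concentrations[keep]
  vv <- viability[keep]
  ord <- order(cc)
  cc <- cc[ord]; vv <- vv[ord]
  if (length(cc) < 4L) stop("need >= 4 non-zero concentrations")
  cmin <- cc[1L]; cmax <- cc[length(cc)]

  new_fit <- function(ic50, censored = NA_character_, coef = NULL, r2 = NA_real_) {
    structure(list(ic50_um = ic50, censored = censored, cmin = cmin,
                   cmax = cmax, method = method, coef = coef, r2 = r2),
              class = "dose_response_fit")
  }

  if (method == "logistic4p") {
    dat <- data.frame(c = cc, v = vv)
    # starting values from a logit-log regression of the scaled response
    top0 <- max(vv); bot0 <- min(min(vv), 0)
    sc <- pmin(pmax((vv - bot0) / (top0 - bot0), 1e-4), 1 - 1e-4)
    mid <- sc > 0.01 & sc < 0.99
    if (sum(mid) < 2L) mid <- rep(TRUE, length(sc))
    ll <- stats::lm(log(sc[mid] / (1 - sc[mid])) ~ log(cc[mid]))
    hill0 <- min(4, max(0.2, -unname(stats::coef(ll)[2L])))
    ic500 <- exp(unname(stats::coef(ll)[1L]) / hill0)
    if (!is.finite(ic500) || ic500 <= 0) ic500 <- exp(stats::median(log(cc)))
    do_fit <- function(start) {
      minpack.lm::nlsLM(v ~ bottom + (top - bottom) / (1 + (c / ic50)^hill),
                        data = dat, start = start,
                        lower = c(top = -Inf, bottom = -Inf,
                                  ic50 = 1e-12, hill = 0.05),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
    fit <- tryCatch(
      do_fit(list(top = top0, bottom = bot0, ic50 = ic500, hill = hill0)),
      error = function(e)
        do_fit(list(top = top0, bottom = bot0,
                    ic50 = exp(stats::median(log(cc))), hill = 1)))
    cf <- stats::coef(fit)
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((vv - mean(vv))^2)
    ic50 <- unname(cf["ic50"])
    if (vv[length(vv)] > 0.5 && ic50 > cmax) return(new_fit(NA_real_, ">", as.list(cf), r2))
    if (vv[1L] < 0.5 && ic50 < cmin) return(new_fit(NA_real_, "<", as.list(cf), r2))
    return(new_fit(ic50, NA_character_, as.list(cf), r2))
  }

  # loglinear_interp
  exact <- which(abs(vv - 0.5) < 1e-9)
  if (length(exact)) {
    return(new_fit(cc[exact[1L]], NA_character_,
                   list(slope = NA_real_, intercept = NA_real_), 1.0))
  }
  s <- sign(vv - 0.5)
  crossings <- which(s[-length(s)] != s[-1L])
  if (length(crossings) == 0L) {
    if (vv[length(vv)] > 0.5) return(new_fit(NA_real_, ">"))
    if (vv[1L] < 0.5) return(new_fit(NA_real_, "<"))
  }
  if (length(crossings) > 1L) {
    warning("multiple 50% crossings; using the lowest concentration crossing")
  }
  i <- crossings[1L]
  idx <- intersect((i - 1L):(i + 2L), seq_along(cc))
  x <- log10(cc[idx]); y <- vv[idx]
  lmfit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(lmfit)[2L])
  intercept <- unname(stats::coef(lmfit)[1L])
  if (!is.finite(slope) || slope == 0) stop("degenerate regression window (flat viability)")
  ic50 <- 10^((0.5 - intercept) / slope)
  r2 <- if (length(idx) > 2L) summary(lmfit)$r.squared else 1.0
  new_fit(ic50, NA_character_, list(slope = slope, intercept = intercept), r2)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose_response_fit (%s): IC50 = %s uM\n", x$method, ic50_label(x)))
  invisible(x)
}

#' Render an IC50 (possibly censored) as the conventional label
#'
#' @param fit A `dose_response_fit`.
#' @param decimals Decimal places for uncensored values (default 1).
#' @return A string such as `"7.6"`, `">400"` or `"<0.1"`.
#' @export
ic50_label <- function(fit, decimals = 1L) {
  if (is.na(fit$censored)) {
    format(round_half_away(fit$ic50_um, decimals), nsmall = decimals,
           scientific = FALSE, trim = TRUE)
  } else if (fit$censored == ">") {
    paste0(">", format(fit$cmax, scientific = FALSE, trim = TRUE))
  } else {
    paste0("<", format(fit$cmin, scientific = FALSE, trim = TRUE))
  }
}

#' Resistance ratio of two IC50 fits
#'
#' The resistance (or sensitization) fold change is the numerator IC50
#' divided by the denominator IC50, rounded half away from zero to
#' `decimals`. A numerator censored above (`">Cmax"`) yields the lower
#' bound `"> Cmax/ic50_den"`, mirroring "> 40-fold" style reporting; a
#' censored denominator is an error because the ratio is then undefined.
#'
#' Bare numbers are accepted in place of fits (printed-values mode).
#'
#' @param fit_num,fit_den `dose_response_fit` objects or plain positive
#'   numbers (IC50s in the same units).
#' @param decimals Decimal places for the reported ratio.
#' @param numerator_label,denominator_label Optional labels for reporting.
#' @return A `resistance_ratio`: `ratio` (numeric; for a censored
#'   numerator the lower bound), `censored` (logical), `label`,
#'   `decimals`, plus the two labels.
#' @export
resistance_ratio <- function(fit_num, fit_den, decimals = 1L,
                             numerator_label = NULL, denominator_label = NULL) {
  as_fit <- function(x) {
    if (inherits(x, "dose_response_fit")) return(x)
    stopifnot(is.numeric(x), length(x) == 1L, x > 0)
    structure(list(ic50_um = as.numeric(x), censored = NA_character_,
                   cmin = NA_real_, cmax = NA_real_, method = "given",
                   coef = NULL, r2 = NA_real_),
              class = "dose_response_fit")
  }
  fit_num <- as_fit(fit_num); fit_den <- as_fit(fit_den)
  if (!is.na(fit_den$censored)) stop("censored denominator IC50: ratio undefined")
  if (!is.na(fit_num$censored) && fit_num$censored == "<") {
    stop("numerator censored below Cmin: only an upper bound would be defined")
  }
  if (!is.na(fit_num$censored)) {
    bound <- round_half_away(fit_num$cmax / fit_den$ic50_um, decimals)
    out <- list(ratio = bound, censored = TRUE,
                label = paste0("> ", format(bound, nsmall = decimals,
                                            scientific = FALSE, trim = TRUE)),
                decimals = as.integer(decimals))
  } else {
    r <- round_half_away(fit_num$ic50_um / fit_den$ic50_um, decimals)
    out <- list(ratio = r, censored = FALSE,
                label = format(r, nsmall = decimals, scientific = FALSE,
                               trim = TRUE),
                decimals = as.integer(decimals))
  }
  out$numerator_label <- numerator_label
  out$denominator_label <- denominator_label
  class(out) <- "resistance_ratio"
  out
}

#' @export
print.resistance_ratio <- function(x, ...) {
  cat(sprintf("resistance_ratio: %s%s\n", x$label,
              if (!is.null(x$numerator_label))
                sprintf(" (%s / %s)", x$numerator_label, x$denominator_label)
              else ""))
  invisible(x)
}

#' Read a plate table of dose-response absorbances
#'
#' Long-format TSV with header `drug`, `sample_label`, `concentration_um`,
#' then one or more `od595_*` replicate columns. The blank for each
#' drug/sample pair is given on a row whose `concentration_um` field is the
#' word `blank`; a row with concentration 0 is the untreated control.
#'
#' @param path Plate TSV path.
#' @return A list of `viability_dataset` objects, one per
#'   drug x sample_label combination.
#' @export
read_plate_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#", colClasses = "character")
  odcols <- grep("^od595", names(tab), value = TRUE)
  if (length(odcols) == 0L) stop("plate table has no od595 replicate columns")
  out <- list()
  for (key in unique(paste(tab$drug, tab$sample_label, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- tab[tab$drug == parts[1L] & tab$sample_label == parts[2L], , drop = FALSE]
    is_blank <- tolower(sub$concentration_um) == "blank"
    if (!any(is_blank)) stop("no blank row for ", parts[1L], "/", parts[2L])
    odmat <- function(rows) {
      lapply(seq_len(nrow(rows)), function(i) {
        v <- suppressWarnings(as.numeric(unlist(rows[i, odcols])))
        v[!is.na(v)]
      })
    }
    blank <- mean(unlist(odmat(sub[is_blank, , drop = FALSE])))
    doses <- sub[!is_blank, , drop = FALSE]
    conc <- as.numeric(doses$concentration_um)
    if (anyNA(conc)) stop("non-numeric concentration for ", parts[1L], "/", parts[2L])
    out[[paste(parts, collapse = ":")]] <-
      viability_dataset(parts[1L], parts[2L], conc, odmat(doses), blank)
  }
  out
}

#' Fit IC50s for every dataset of a plate table
#'
#' @param datasets List of `viability_dataset` (e.g. [read_plate_table()]).
#' @param method Fitting method passed to [fit_ic50()].
#' @return Data frame: `sample_label`, `drug`, `method`, `ic50`
#'   (label, censoring rendered as `>x`/`<x`), `ic50_um` (numeric, NA if
#'   censored), `r2`; the fits themselves in a list-column `fit`.
#' @export
fit_plate_ic50s <- function(datasets, method = "loglinear_interp") {
  rows <- lapply(datasets, function(ds) {
    nv <- normalize_viability(ds)
    fit <- fit_ic50(nv$concentration_um, nv$viability, method = method)
    data.frame(sample_label = ds$sample_label, drug = ds$drug,
               method = method, ic50 = ic50_label(fit),
               ic50_um = if (is.na(fit$censored)) fit$ic50_um else NA_real_,
               r2 = fit$r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fit <- lapply(datasets, function(ds) {
    nv <- normalize_viability(ds)
    fit_ic50(nv$concentration_um, nv$viability, method = method)
  })
  rownames(out) <- NULL
  out
}
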