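# qPCR relative quantification by the Ct-based calibrated standard-curve
# method: Ct -> quantity via the curve, normalization against a reference
# assay (U6 for miRNA, GAPDH for mRNA), and calibration against a
# calibrator sample.

#' Construct a qPCR standard curve
#'
#' Ct is modelled as linear in log10 quantity: `Ct = intercept +
#' slope * log10(Q)`, slope negative. Amplification efficiency is
#' `10^(-1/slope) - 1`; a perfectly efficient reaction (doubling per
#' cycle) has slope `-1/log10(2) ~= -3.3219` and efficiency 1.
#'
#' @param slope Ct change per log10 quantity (must be negative).
#' @param intercept Ct at quantity 1.
#' @return A `standard_curve` with fields `slope`, `intercept`,
#'   `efficiency`.
#' @export
standard_curve <- function(slope, intercept) {
  if (!is.numeric(slope) || slope >= 0) stop("standard-curve slope must be negative")
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.5) {
    stop("implausible amplification efficiency ", signif(eff, 3),
         " (allowed (0, 1.5])")
  }
  if (eff < 0.8 || eff > 1.1) {
    warning("amplification efficiency ", signif(eff, 3),
            " outside the usual (0.8, 1.1) band")
  }
  structure(list(slope = slope, intercept = intercept, efficiency = eff),
            class = "standard_curve")
}

#' Standard curve of a perfectly efficient reaction
#'
#' @param intercept Ct at quantity 1 (default 0; relative quantities are
#'   insensitive to the intercept).
#' @return A `standard_curve` with slope `-1/log10(2)`.
#' @export
perfect_efficiency_curve <- function(intercept = 0) {
  standard_curve(-1 / log10(2), intercept)
}

#' Convert a Ct value to a relative quantity via a standard curve
#'
#' `Q = 10^((ct - intercept) / slope)`, strictly decreasing in Ct.
#'
#' @param ct Threshold cycle(s).
#' @param curve A `standard_curve`.
#' @return Positive quantity (vectorized over `ct`).
#' @export
quantity_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Construct a qPCR sample of replicate Ct values
#'
#' @param sample_id Sample identifier.
#' @param ct_target Replicate Ct values of the target assay.
#' @param ct_reference Replicate Ct values of the reference assay
#'   (U6 for miRNA, GAPDH for mRNA).
#' @param role `"test"` or `"calibrator"`.
#' @return A `qpcr_sample`.
#' @export
qpcr_sample <- function(sample_id, ct_target, ct_reference,
                        role = c("test", "calibrator")) {
  role <- match.arg(role)
  stopifnot(length(ct_target) >= 1L, length(ct_reference) >= 1L,
            all(ct_target > 0), all(ct_reference > 0))
  structure(list(sample_id = sample_id, ct_target = ct_target,
                 ct_reference = ct_reference, role = role),
            class = "qpcr_sample")
}

#' Relative expression of a test sample versus a calibrator
#'
#' Replicate Cts are averaged on the Ct scale, converted to quantities
#' through the assay standard curves, normalized against the reference
#' assay, and calibrated:
#' `(Qt/Qr)_test / (Qt/Qr)_calibrator`. With perfectly efficient curves
#' this reduces to the classic `2^(-ddCt)`.
#'
#' @param test,calibrator `qpcr_sample` objects.
#' @param curve_target,curve_reference `standard_curve`s for the target and
#'   reference assays; when omitted, perfect-efficiency curves are assumed
#'   (with a logged notice).
#' @return Positive relative expression; 1 for the calibrator vs itself.
#' @export
relative_expression <- function(test, calibrator,
                                curve_target = NULL, curve_reference = NULL) {
  stopifnot(inherits(test, "qpcr_sample"), inherits(calibrator, "qpcr_sample"))
  if (is.null(curve_target) || is.null(curve_reference)) {
    msg("relative_expression: assuming perfect-efficiency standard curves")
  }
  curve_target <- curve_target %||% perfect_efficiency_curve()
  curve_reference <- curve_reference %||% perfect_efficiency_curve()
  norm_q <- function(s) {
    qt <- quantity_from_ct(mean(s$ct_target), curve_target)
    qr <- quantity_from_ct(mean(s$ct_reference), curve_reference)
    qt / qr
  }
  norm_q(test) / norm_q(calibrator)
}

#' Read a Ct table and compute relative expression per assay
#'
#' TSV with header `sample_id`, `assay`, `role` (test/calibrator) and one
#' or more `ct_*` replicate columns. For each target assay, every test
#' sample is calibrated against the (single) calibrator sample, normalized
#' by the `reference` assay.
#'
#' @param path Ct TSV path.
#' @param reference Name of the reference assay (e.g. `"U6"`, `"GAPDH"`).
#' @param curves Optional data frame `assay`, `slope`, `intercept`; assays
#'   absent from it use perfect-efficiency curves.
#' @return Data frame `sample_id`, `assay`, `relative_expression`.
#' @export
read_ct_table <- function(path, reference, curves = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  ctcols <- grep("^ct", names(tab), value = TRUE)
  if (length(ctcols) == 0L) stop("Ct table has no ct_* replicate columns")
  if (!reference %in% tab$assay) stop("reference assay '", reference, "' absent")
  curve_for <- function(assay) {
    if (!is.null(curves) && assay %in% curves$assay) {
      i <- match(assay, curves$assay)
      standard_curve(curves$slope[i], curves$intercept[i])
    } else {
      perfect_efficiency_curve()
    }
  }
  cts <- function(row) {
    v <- suppressWarnings(as.numeric(unlist(row[ctcols])))
    v[!is.na(v)]
  }
  ref <- tab[tab$assay == reference, , drop = FALSE]
  targets <- setdiff(unique(tab$assay), reference)
  out <- list()
  for (assay in targets) {
    sub <- tab[tab$assay == assay, , drop = FALSE]
    samples <- lapply(seq_len(nrow(sub)), function(i) {
      r <- ref[ref$sample_id == sub$sample_id[i], , drop = FALSE]
      if (nrow(r) == 0L) stop("no reference Cts for sample ", sub$sample_id[i])
      qpcr_sample(sub$sample_id[i], cts(sub[i, ]), cts(r[1L, ]),
                  role = sub$role[i])
    })
    cal <- Filter(function(s) s$role == "calibrator", samples)
    if (length(cal) != 1L) stop("assay ", assay, " needs exactly one calibrator")
    rel <- vapply(samples, relative_expression, numeric(1L),
                  calibrator = cal[[1L]],
                  curve_target = curve_for(assay),
                  curve_reference = curve_for(reference))
    out[[assay]] <- data.frame(sample_id = sub$sample_id, assay = assay,
                               relative_expression = rel,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
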