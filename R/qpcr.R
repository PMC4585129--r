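# qPCR absolute quantification of ANME subclades (ANME-1, ANME-2a/b,
# ANME-2c) from 16S rRNA gene assays: standard-curve calibration, copy-number
# back-calculation, and fold-change growth calls.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(copies) over a dilution series.
#' Amplification efficiency is `10^(-1/slope) - 1` (a slope of -3.3219
#' corresponds to perfect doubling, 100%).
#'
#' @param copies_per_ul Known standard copies per microlitre (> 0).
#' @param cq Measured quantification cycles, same length.
#' @return An object of class `qpcr_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, the calibrated `range` of log10 copies, and
#'   the underlying `lm` fit.
#' @export
#' @examples
#' copies <- rep(10^(5:1), each = 3)
#' cq <- 38 - 3.3219 * log10(copies) + rnorm(15, sd = 0.1)
#' fit_standard_curve(copies, cq)
fit_standard_curve <- function(copies_per_ul, cq) {
  stopifnot(length(copies_per_ul) == length(cq))
  if (any(copies_per_ul <= 0))
    stop("standard copies must be > 0", call. = FALSE)
  lx <- log10(copies_per_ul)
  if (length(unique(lx)) < 3L)
    stop("degenerate standard series: need >= 3 distinct dilution levels",
         call. = FALSE)
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # direct R^2: summary.lm warns on the exact fits used for calibration QC
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 range = range(lx), fit = fit),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat("qPCR standard curve: Cq =", format(x$intercept, digits = 6), "+",
      format(x$slope, digits = 6), "* log10(copies)\n")
  cat(sprintf("  efficiency %.1f%%, R^2 %.4f, calibrated range 10^%.1f-10^%.1f copies/ul\n",
              100 * x$efficiency, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.qpcr_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted Cq for known copy numbers
#'
#' @param object A `qpcr_curve`.
#' @param copies_per_ul Copy numbers to predict Cq for.
#' @param ... Unused.
#' @return Predicted Cq values.
#' @export
predict.qpcr_curve <- function(object, copies_per_ul, ...) {
  object$intercept + object$slope * log10(copies_per_ul)
}

#' Absolute quantification from a Cq value
#'
#' Copies in the reaction are `10^((cq - intercept)/slope)`; dividing by the
#' template DNA mass gives copies per ng DNA, and scaling by the total
#' extracted DNA over the sample mass gives copies per gram wet weight. Both
#' normalizations are reported because fold changes are invariant between
#' them only when DNA yield is constant across samples.
#'
#' @param curve A `qpcr_curve`.
#' @param cq Observed Cq values (vectorized).
#' @param template_ng Template DNA in the reaction, ng (assay default 5 ng).
#' @param extract_ng_per_ul DNA concentration of the extract, ng/ul.
#' @param elution_ul Elution volume of the extract, ul.
#' @param sample_g_wet Wet mass of the extracted sample, g.
#' @return A data.frame with `cq`, `copies`, `copies_per_ng_dna`,
#'   `copies_per_g_wet`, and a logical `extrapolated` flag (with a warning)
#'   for Cq values outside the calibrated range.
#' @export
quantify <- function(curve, cq, template_ng = 5, extract_ng_per_ul,
                     elution_ul, sample_g_wet) {
  stopifnot(inherits(curve, "qpcr_curve"),
            template_ng > 0, extract_ng_per_ul > 0, elution_ul > 0,
            sample_g_wet > 0)
  copies <- 10^((cq - curve$intercept) / curve$slope)
  lx <- log10(copies)
  extrap <- lx < curve$range[1] - 1e-9 | lx > curve$range[2] + 1e-9
  if (any(extrap))
    warning(sum(extrap), " Cq value(s) outside the calibrated range; ",
            "quantification is an extrapolation", call. = FALSE)
  per_ng <- copies / template_ng
  per_g <- per_ng * (extract_ng_per_ul * elution_ul) / sample_g_wet
  data.frame(cq = cq, copies = copies, copies_per_ng_dna = per_ng,
             copies_per_g_wet = per_g, extrapolated = extrap)
}

#' Fold change between two abundance measurements
#'
#' @param final,initial Abundances of the same clade in the same bottle
#'   lineage (any common normalization). Vectorized.
#' @return A data.frame with `ratio` and the `growth` call (strictly
#'   ratio > 1).
#' @export
fold_change <- function(final, initial) {
  if (any(final < 0) || any(initial < 0))
    stop("abundances must be >= 0", call. = FALSE)
  if (any(initial == 0))
    stop("fold change undefined: initial abundance is zero", call. = FALSE)
  ratio <- final / initial
  data.frame(ratio = ratio, growth = ratio > 1)
}
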