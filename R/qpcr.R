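#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct = intercept + slope * log10(copies)` over a
#' dilution series.  Wells with no amplification (`NA` Ct) are excluded from
#' the fit.  The amplification efficiency is `E = 10^(-1/slope) - 1`
#' (`E = 1` means perfect doubling per cycle, i.e. slope `-1/log10(2)
#' = -3.3219`).
#'
#' @param copies template copies of each standard (> 0).
#' @param Ct measured Ct values (`NA` = no amplification).
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `dynamic_range` (min/max copies used),
#'   `n_used`, `n_dropped`.
#' @export
fit_standard_curve <- function(copies, Ct) {
  if (length(copies) != length(Ct)) stop("copies and Ct lengths differ")
  if (any(copies <= 0)) stop("standard copies must be > 0")
  use <- !is.na(Ct)
  copies <- copies[use]; Ct2 <- Ct[use]
  if (length(unique(copies)) < 2L) {
    stop("need at least two distinct copy levels with amplification")
  }
  fit <- lm(Ct2 ~ log10(copies))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((Ct2 - mean(Ct2))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1, r_squared = r2,
                 dynamic_range = range(copies),
                 n_used = length(Ct2), n_dropped = sum(!use)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Ct = %.4f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.4f, r^2 %.6f, dynamic range %.3g-%.3g copies (%d wells, %d dropped)\n",
              x$efficiency, x$r_squared, x$dynamic_range[1],
              x$dynamic_range[2], x$n_used, x$n_dropped))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted Ct for given template copies
#'
#' @param object a `standard_curve`.
#' @param copies template copies.
#' @param ... ignored.
#' @return predicted Ct values.
#' @export
predict.standard_curve <- function(object, copies, ...) {
  object$intercept + object$slope * log10(copies)
}

#' Convert Ct values to absolute copies
#'
#' Inverts the standard curve: `copies = 10^((Ct - intercept) / slope)`.
#' `NA` Ct (no amplification) yields `NA` copies flagged below detection;
#' copies outside the curve's dynamic range are flagged out of range.
#'
#' @param Ct numeric Ct values.
#' @param curve a [fit_standard_curve()] object.
#' @return data.frame `Ct`, `copies`, `below_detection`, `out_of_range`.
#' @export
ct_to_copies <- function(Ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((Ct - curve$intercept) / curve$slope)
  below <- is.na(Ct)
  oor <- !below & (copies < curve$dynamic_range[1] |
                     copies > curve$dynamic_range[2])
  data.frame(Ct = Ct, copies = copies, below_detection = below,
             out_of_range = oor)
}

#' Species mixture shares and predicted read yield from marker copies
#'
#' Normalises per-species marker (5.8S rRNA analogue) copy numbers to
#' shares, predicts the read yield of each species for a planned sequencing
#' depth, and reports all pairwise copy ratios.
#'
#' @param copies named numeric: marker copies per species (>= 0, at least
#'   one > 0).
#' @param planned_total_reads optional planned total fragments for the
#'   sample (e.g. 100e6 for a mixed culture); predicted per-species reads
#'   are `share * planned_total_reads`.
#' @return object of class `mixture_estimate`: `copies`, `shares` (sum to
#'   1), `predicted_reads` (or `NULL`), `ratios` (matrix,
#'   `ratios[i, j] = copies_i / copies_j`).
#' @export
mixture_shares <- function(copies, planned_total_reads = NULL) {
  if (any(copies < 0)) stop("copies must be >= 0")
  if (sum(copies) <= 0) stop("all species have zero copies")
  if (is.null(names(copies))) names(copies) <- paste0("sp", seq_along(copies))
  shares <- copies / sum(copies)
  ratios <- outer(copies, copies, "/")
  pred <- if (!is.null(planned_total_reads)) {
    shares * planned_total_reads
  }
  structure(list(copies = copies, shares = shares, predicted_reads = pred,
                 ratios = ratios), class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("mixture_estimate shares:\n")
  print(round(x$shares, 4))
  if (!is.null(x$predicted_reads)) {
    cat("predicted reads:\n"); print(round(x$predicted_reads))
  }
  invisible(x)
}

#' Fold change of species-pair marker ratios between two time points
#'
#' E.g. a species pair at ratio 1.0 at 0 h and 4.0 at 24 h has a 4.0-fold
#' change in its marker ratio.
#'
#' @param mix_t0,mix_t1 [mixture_shares()] objects at the two time points
#'   (same species).
#' @return matrix of `ratios_t1 / ratios_t0`.
#' @export
mixture_ratio_fold <- function(mix_t0, mix_t1) {
  stopifnot(identical(names(mix_t0$copies), names(mix_t1$copies)))
  mix_t1$ratios / mix_t0$ratios
}

#' Fit a gDNA biomass standard curve
#'
#' Fits `Ct = intercept + slope * log10(dry weight mg)` on standards of
#' known dry weight measured at a fixed gDNA dilution (default 1/500); the
#' dilution is recorded so samples measured at a different dilution can be
#' rescaled.
#'
#' @param weights_mg known dry weights of the standards (mg).
#' @param Ct measured Ct values.
#' @param dilution_factor gDNA dilution at which the standards were run.
#' @return a `biomass_curve` (inherits `standard_curve`) with
#'   `dilution_factor`.
#' @export
fit_biomass_curve <- function(weights_mg, Ct, dilution_factor = 500) {
  curve <- fit_standard_curve(weights_mg, Ct)
  curve$dilution_factor <- dilution_factor
  class(curve) <- c("biomass_curve", class(curve))
  curve
}

#' Estimate mycelial biomass from gDNA qPCR
#'
#' Inverts the biomass standard curve to the dry weight of mycelium in the
#' extracted aliquot, rescaling when the sample's gDNA dilution differs from
#' the standards', then scales to the whole flask by the fraction of
#' recovered solids used for the extraction.
#'
#' @param Ct sample Ct values (`NA` = below detection).
#' @param biomass_curve a [fit_biomass_curve()] object.
#' @param dilution_factor gDNA dilution of the samples (default 500, the
#'   study's standard dilution).
#' @param aliquot_fraction fraction of recovered solids extracted, in
#'   (0, 1].
#' @return object of class `biomass_estimate`: data.frame `Ct`,
#'   `aliquot_mg`, `flask_mg`, `below_detection`.  Always
#'   `flask_mg = aliquot_mg / aliquot_fraction`.
#' @export
estimate_biomass <- function(Ct, biomass_curve, dilution_factor = 500,
                             aliquot_fraction = 1) {
  stopifnot(inherits(biomass_curve, "biomass_curve"))
  if (aliquot_fraction <= 0 || aliquot_fraction > 1) {
    stop("aliquot_fraction must be in (0, 1]")
  }
  raw_mg <- 10^((Ct - biomass_curve$intercept) / biomass_curve$slope)
  # a more dilute sample template means proportionally more gDNA per mg
  aliquot_mg <- raw_mg * dilution_factor / biomass_curve$dilution_factor
  out <- data.frame(Ct = Ct, aliquot_mg = aliquot_mg,
                    flask_mg = aliquot_mg / aliquot_fraction,
                    below_detection = is.na(Ct))
  class(out) <- c("biomass_estimate", "data.frame")
  out
}

#' Normalise a transcript level to the species-specific rRNA abundance
#'
#' @param target_abundance per-species transcript abundance (copies).
#' @param rrna_abundance matching species-specific 5.8S rRNA abundance
#'   (> 0).
#' @return `target_abundance / rrna_abundance`.
#' @export
normalize_to_rrna <- function(target_abundance, rrna_abundance) {
  if (any(rrna_abundance <= 0)) stop("rRNA abundance must be > 0")
  target_abundance / rrna_abundance
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors (length >= 3, nonzero variance).
#' @return `cor(x, y)^2`.
#' @export
squared_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  cor(x, y)^2
}
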