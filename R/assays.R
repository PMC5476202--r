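# Deterministic enzyme-assay arithmetic: pNP activity rates, DNS sugar
# release with background correction, per-biomass normalisation.

#' pNP enzyme activity
#'
#' Activity in rho-mol pNP per minute per microlitre of culture filtrate:
#' `released / (minutes * filtrate_ul)`.  The default incubation time is
#' 180 min (3 h at 37 C).
#'
#' @param released_pnp_rho_mol pNP released over the incubation (rho-mol).
#' @param minutes incubation time (> 0; default 180).
#' @param filtrate_ul filtrate volume assayed (> 0).
#' @return activity in rho-mol pNP min^-1 ul^-1.
#' @export
pnp_activity <- function(released_pnp_rho_mol, minutes = 180, filtrate_ul) {
  if (any(minutes <= 0)) stop("incubation time must be > 0")
  if (any(filtrate_ul <= 0)) stop("filtrate volume must be > 0")
  released_pnp_rho_mol / (minutes * filtrate_ul)
}

#' Fit a linear (non-log) assay standard curve
#'
#' Least-squares line `signal = intercept + slope * amount`, used for
#' colorimetric standards that respond linearly in concentration (glucose
#' standards for the DNS assay, pNP standards).
#'
#' @param amounts standard amounts (>= 2 distinct values).
#' @param signals measured signals (e.g. absorbance).
#' @return object of class `linear_curve`: `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_linear_curve <- function(amounts, signals) {
  if (length(unique(amounts)) < 2L) stop("need >= 2 distinct standard amounts")
  fit <- lm(signals ~ amounts)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((signals - mean(signals))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "linear_curve")
}

#' Convert assay signals to amounts via a linear standard curve
#'
#' @param signals measured signals.
#' @param curve a [fit_linear_curve()] object.
#' @return amounts `(signals - intercept) / slope`.
#' @export
signal_to_amount <- function(signals, curve) {
  stopifnot(inherits(curve, "linear_curve"))
  if (curve$slope == 0) stop("degenerate standard curve (zero slope)")
  (signals - curve$intercept) / curve$slope
}

#' Background-corrected reducing sugars (DNS assay)
#'
#' Converts sample and control signals to glucose equivalents via the
#' glucose standard curve (or uses them directly when `glucose_curve` is
#' `NULL`, i.e. inputs are already in glucose units), then subtracts both
#' the straw control and the filtrate control.  Values below the combined
#' background are reported as negative with a flag, never clamped.
#'
#' @param sample,straw_ctrl,filtrate_ctrl signals (or glucose equivalents).
#' @param glucose_curve a [fit_linear_curve()] object fitted on glucose
#'   standards, or `NULL` when inputs are already converted.
#' @return data.frame `glucose_equivalents` (corrected) and
#'   `below_background`.
#' @export
dns_corrected_sugars <- function(sample, straw_ctrl, filtrate_ctrl,
                                 glucose_curve = NULL) {
  if (!is.null(glucose_curve)) {
    if (!inherits(glucose_curve, "linear_curve")) {
      stop("glucose_curve must be a fitted linear_curve")
    }
    sample <- signal_to_amount(sample, glucose_curve)
    straw_ctrl <- signal_to_amount(straw_ctrl, glucose_curve)
    filtrate_ctrl <- signal_to_amount(filtrate_ctrl, glucose_curve)
  }
  corrected <- sample - straw_ctrl - filtrate_ctrl
  data.frame(glucose_equivalents = corrected,
             below_background = corrected < 0)
}

#' Normalise a released amount to mycelial dry weight
#'
#' @param amount released amount (e.g. nmol reducing ends).
#' @param dry_weight_mg mycelial dry weight (> 0), typically a gDNA-based
#'   [estimate_biomass()] prediction.
#' @return amount per mg dry weight.
#' @export
per_biomass_release <- function(amount, dry_weight_mg) {
  if (any(dry_weight_mg <= 0)) stop("dry weight must be > 0")
  amount / dry_weight_mg
}
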