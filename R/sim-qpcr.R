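#' Copies of the default qPCR standard dilution series
#'
#' Ten five-fold dilutions starting from 5e7 target copies, the scheme used
#' to build plasmid standard curves for absolute quantification.
#'
#' @param start_copies copies in the most concentrated standard.
#' @param dilution_factor fold dilution between consecutive standards.
#' @param n number of standards.
#' @return numeric vector `start_copies * dilution_factor^-(0:(n-1))`.
#' @export
qpcr_standard_series <- function(start_copies = 5e7, dilution_factor = 5,
                                 n = 10) {
  stopifnot_scalar_number(start_copies, "start_copies", positive = TRUE)
  stopifnot_scalar_number(dilution_factor, "dilution_factor", positive = TRUE)
  start_copies * dilution_factor^-(seq_len(n) - 1)
}

#' Simulate a qPCR plate from true template copies
#'
#' Ct values follow the log-linear model
#' `Ct = intercept + slope * log10(copies) + Normal(0, noise_sd)`.
#' Wells whose effective template is zero (or negative) report no
#' amplification (`NA` Ct).  Probe specificity is modelled by a boolean
#' cross-reactivity matrix: the effective template for assay `a` in a sample
#' is the sum of copies over the template species that assay amplifies
#' (default: perfectly specific assays, identity matrix).
#'
#' @param true_copies numeric matrix, template species x samples (row/col
#'   names used), or a named vector treated as a one-sample matrix.
#' @param curve numeric `c(slope, intercept)`; default slope
#'   `-1/log10(2)` (perfect doubling, efficiency 1) and intercept 40.
#' @param noise_sd Gaussian Ct noise standard deviation.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param cross_reactivity logical matrix assays x template species;
#'   default `diag(nrow(true_copies))` (each assay amplifies its own
#'   species only).
#' @return data.frame with `assay`, `sample`, `copies` (effective template)
#'   and `Ct` (`NA` = no amplification).
#' @export
simulate_qpcr_plate <- function(true_copies,
                                curve = c(slope = -1 / log10(2),
                                          intercept = 40),
                                noise_sd = 0, seed = NULL,
                                cross_reactivity = NULL) {
  if (is.null(dim(true_copies))) {
    true_copies <- matrix(true_copies, ncol = 1,
                          dimnames = list(names(true_copies), "s1"))
  }
  nt <- nrow(true_copies)
  if (is.null(rownames(true_copies))) {
    rownames(true_copies) <- paste0("t", seq_len(nt))
  }
  if (is.null(colnames(true_copies))) {
    colnames(true_copies) <- paste0("s", seq_len(ncol(true_copies)))
  }
  if (is.null(cross_reactivity)) {
    cross_reactivity <- diag(nt) == 1
    dimnames(cross_reactivity) <- list(rownames(true_copies),
                                       rownames(true_copies))
  }
  eff <- cross_reactivity %*% true_copies  # assays x samples
  slope <- unname(curve[1]); intercept <- unname(curve[2])
  with_seed(seed, {
    ct <- intercept + slope * log10(ifelse(eff > 0, eff, NA))
    if (noise_sd > 0) {
      ct <- ct + matrix(rnorm(length(ct), 0, noise_sd), nrow(ct))
    }
    ct[eff <= 0] <- NA_real_
    data.frame(
      assay = rep(rownames(eff), ncol(eff)),
      sample = rep(colnames(eff), each = nrow(eff)),
      copies = as.vector(eff), Ct = as.vector(ct),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a standard dilution series on a plate
#'
#' @param curve,noise_sd,seed as in [simulate_qpcr_plate()].
#' @param start_copies,dilution_factor,n as in [qpcr_standard_series()].
#' @return data.frame with `copies` and `Ct`.
#' @export
simulate_standard_series <- function(curve = c(slope = -1 / log10(2),
                                               intercept = 40),
                                     noise_sd = 0, seed = NULL,
                                     start_copies = 5e7, dilution_factor = 5,
                                     n = 10) {
  copies <- qpcr_standard_series(start_copies, dilution_factor, n)
  m <- matrix(copies, nrow = 1, dimnames = list("std", paste0("d", seq_len(n))))
  plate <- simulate_qpcr_plate(m, curve = curve, noise_sd = noise_sd,
                               seed = seed)
  data.frame(copies = plate$copies, Ct = plate$Ct)
}

#' Simulate gDNA biomass samples with their weight standards
#'
#' Single-copy-locus template copies are proportional to the dry weight of
#' mycelium in the extracted aliquot.  Standards are generated from known
#' dry weights spanning the 2-50 mg range; both standards and samples are
#' measured at the same gDNA dilution (default 1/500) so the standard curve
#' inverts Ct directly to aliquot dry weight.
#'
#' @param dry_weights_mg named numeric: true aliquot dry weight per sample
#'   (mg).  Zero weights give zero copies (no amplification).
#' @param copies_per_mg single-copy locus copies per mg dry weight.
#' @param aliquot_fraction fraction of the recovered solids used for the
#'   extraction, in (0, 1]; flask totals are aliquot / aliquot_fraction.
#' @param seed RNG seed.
#' @param curve,noise_sd qPCR model as in [simulate_qpcr_plate()].
#' @param dilution_factor gDNA dilution applied before the plate (default
#'   500).
#' @param standard_weights_mg dry weights of the standards.
#' @return list of class `gdna_sim`: `standards` (data.frame `weight_mg`,
#'   `copies_well`, `Ct`), `samples` (data.frame `sample`,
#'   `aliquot_weight_mg`, `flask_weight_mg`, `copies_well`, `Ct`),
#'   `dilution_factor`, `aliquot_fraction`, `copies_per_mg`.
#' @export
simulate_gdna_biomass <- function(dry_weights_mg, copies_per_mg = 2e5,
                                  aliquot_fraction = 1, seed = NULL,
                                  curve = c(slope = -1 / log10(2),
                                            intercept = 40),
                                  noise_sd = 0, dilution_factor = 500,
                                  standard_weights_mg = c(2, 5, 10, 20,
                                                          35, 50)) {
  if (any(dry_weights_mg < 0)) stop("dry weights must be >= 0")
  if (aliquot_fraction <= 0 || aliquot_fraction > 1) {
    stop("aliquot_fraction must be in (0, 1]")
  }
  if (is.null(names(dry_weights_mg))) {
    names(dry_weights_mg) <- paste0("s", seq_along(dry_weights_mg))
  }
  all_w <- c(standard_weights_mg, dry_weights_mg)
  copies_well <- all_w * copies_per_mg / dilution_factor
  m <- matrix(copies_well, nrow = 1,
              dimnames = list("scl", paste0("w", seq_along(all_w))))
  plate <- simulate_qpcr_plate(m, curve = curve, noise_sd = noise_sd,
                               seed = seed)
  ns <- length(standard_weights_mg)
  structure(list(
    standards = data.frame(weight_mg = standard_weights_mg,
                           copies_well = plate$copies[seq_len(ns)],
                           Ct = plate$Ct[seq_len(ns)]),
    samples = data.frame(sample = names(dry_weights_mg),
                         aliquot_weight_mg = unname(dry_weights_mg),
                         flask_weight_mg =
                           unname(dry_weights_mg) / aliquot_fraction,
                         copies_well = plate$copies[-seq_len(ns)],
                         Ct = plate$Ct[-seq_len(ns)],
                         stringsAsFactors = FALSE),
    dilution_factor = dilution_factor, aliquot_fraction = aliquot_fraction,
    copies_per_mg = copies_per_mg
  ), class = "gdna_sim")
}
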