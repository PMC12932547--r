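#' Halo-to-colony index (solubilization / siderophore production)
#'
#' Ratio of halo diameter to colony diameter on a plate assay. The same
#' formula serves both the phosphate solubilization index (SI, clear halo)
#' and the siderophore production index (SPI, orange halo); the assay label
#' is carried along for reporting only.
#'
#' @param halo halo diameter (any length unit).
#' @param colony colony diameter (same unit); must be positive.
#' @param assay label, \code{"SI"} or \code{"SPI"}.
#' @return the index, with attribute \code{assay}.
#' @export
halo_index <- function(halo, colony, assay = c("SI", "SPI")) {
  assay <- match.arg(assay)
  if (!all(is.finite(halo)) || !all(is.finite(colony))) {
    stop_validation("diameters must be finite")
  }
  if (any(colony <= 0)) stop_validation("colony diameter must be positive")
  if (any(halo < 0)) stop_validation("halo diameter must be non-negative")
  structure(halo / colony, assay = assay)
}

#' Percent inhibition of pathogen growth
#'
#' \code{(1 - treated/control) * 100}. Covers both the dual-culture
#' inhibition efficiency (treated = pathogen radius toward the antagonist,
#' control = radius in solo culture) and the culture-filtrate inhibition
#' rate (treated/control colony sizes on amended vs. plain media); the
#' measurements only need a consistent convention (radius or diameter)
#' within each pair. Negative values — the pathogen grew faster under
#' treatment — are allowed and flagged with attribute
#' \code{growth_promotion}.
#'
#' @param treated treated-growth measurement (>= 0).
#' @param control control-growth measurement (> 0).
#' @return percent inhibition.
#' @export
inhibition_percent <- function(treated, control) {
  if (!all(is.finite(treated)) || !all(is.finite(control))) {
    stop_validation("measurements must be finite")
  }
  if (any(control <= 0)) stop_validation("control measurement must be positive")
  if (any(treated < 0)) stop_validation("treated measurement must be non-negative")
  out <- (1 - treated / control) * 100
  structure(out, growth_promotion = out < 0)
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a treated sample relative to a control
#' sample, each normalized to a reference gene:
#' \code{2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))}.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   qPCR cycle-threshold values.
#' @return the fold change.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(is.finite(vals))) stop_validation("cycle values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
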