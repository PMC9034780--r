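# Peters'-rule overlap predictions.

#' Predict an input profile from axo-dendritic overlap
#'
#' Resamples the axon-density and (pia-aligned, total) dendritic-length
#' profiles onto a common depth grid, peak-normalizes each factor to 1,
#' and multiplies bin-wise: large predicted input where both axons and
#' dendrites are present (Peters' rule). Invariant to positive rescaling
#' of either factor.
#'
#' @param axon an `axon_profile`.
#' @param dendrite a pia-aligned `morph_profile` (compartments are summed).
#' @param bin_um depth bin of the prediction, um (quadrant pitch).
#' @return An object of class `predicted_input`: `values` in `[0, 1]`,
#'   `position_um` (bin depth, multiples of `bin_um`), and the normalized
#'   factors. Disjoint supports give an all-zero prediction with a warning.
#' @export
predict_input <- function(axon, dendrite, bin_um = QUADRANT_UM) {
  stopifnot(inherits(axon, "axon_profile"),
            inherits(dendrite, "morph_profile"))
  dmax <- max(axon$breaks[length(axon$breaks)],
              dendrite$breaks[length(dendrite$breaks)])
  k <- ceiling(dmax / bin_um)
  dst <- seq(0, k * bin_um, by = bin_um)
  ax <- rebin_mass(axon$breaks, axon$density * diff(axon$breaks), dst)
  dd <- rebin_mass(dendrite$breaks, rowSums(dendrite$L), dst)
  if (max(ax) <= 0 || max(dd) <= 0)
    stop("a factor profile is all zero", call. = FALSE)
  ax <- ax / max(ax); dd <- dd / max(dd)
  pred <- ax * dd
  if (all(pred == 0))
    warning("axon and dendrite profiles have disjoint depth support; ",
            "prediction is all zero")
  structure(list(values = pred, position_um = dst[-1L],
                 axis = "depth-from-pia", pitch_um = bin_um,
                 axon_norm = ax, dendrite_norm = dd,
                 area = axon$area),
            class = c("predicted_input", "scracm_profile"))
}

#' Compare a predicted with a measured input profile
#'
#' Cosine similarity and Pearson correlation across depth bins shared by
#' the two profiles, plus the per-bin difference (both profiles are
#' peak-normalized before comparison).
#'
#' @param predicted a `predicted_input` (or any `scracm_profile`).
#' @param measured a `scracm_profile` on the same axis/pitch.
#' @return List with `cosine`, `pearson`, `n_bins`, `difference` (data
#'   frame of position and predicted - measured), and `defined` (FALSE
#'   when either profile is all zero).
#' @export
compare_profiles <- function(predicted, measured) {
  stopifnot(inherits(predicted, "scracm_profile"),
            inherits(measured, "scracm_profile"))
  if (abs(predicted$pitch_um - measured$pitch_um) > 1e-6)
    stop("profiles must share the same bin pitch", call. = FALSE)
  pos <- intersect(round(predicted$position_um, 6),
                   round(measured$position_um, 6))
  if (!length(pos))
    stop("profiles have no common depth bins", call. = FALSE)
  a <- predicted$values[match(pos, round(predicted$position_um, 6))]
  b <- measured$values[match(pos, round(measured$position_um, 6))]
  if (max(a) <= 0 || max(b) <= 0) {
    warning("a profile is all zero on the common grid; similarity undefined")
    return(list(cosine = NA_real_, pearson = NA_real_, n_bins = length(pos),
                difference = data.frame(position_um = pos,
                                        difference = a - b),
                defined = FALSE))
  }
  a <- a / max(a); b <- b / max(b)
  cosine <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  pearson <- if (stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::cor(a, b) else NA_real_
  list(cosine = cosine, pearson = pearson, n_bins = length(pos),
       difference = data.frame(position_um = pos, difference = a - b),
       defined = TRUE)
}
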