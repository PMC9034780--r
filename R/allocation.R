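# Compartment-level allocation of measured input.

#' Allocate a vertical input profile among dendritic compartments
#'
#' Deconvolves a measured, pia-aligned vertical charge profile with a
#' dendritic length profile: in each depth bin the input charge is
#' apportioned to basal / oblique / tuft in proportion to each
#' compartment's share of the dendritic length in that bin. Bins carrying
#' input where the morphology has no dendrite are apportioned using the
#' nearest bin with dendrite (to conserve measured charge), or dropped.
#'
#' @param input_profile a depth-from-pia `scracm_profile` (from
#'   [vertical_profile()] of a pia-aligned map).
#' @param morph a `morph_profile`; it is rescaled to `soma_depth_um` (when
#'   given) and re-binned onto the input profile's 20.83 um grid.
#' @param soma_depth_um the recorded cell's soma-pia distance, um; NULL
#'   uses the morphology profile's own scale.
#' @param zero_bins `"nearest"` (default) or `"drop"`.
#' @return An object of class `compartment_alloc`: `proportions` (basal,
#'   oblique, tuft, summing to 1), `charges_pc`, `total_pc`, and the
#'   per-bin allocation matrix.
#' @export
allocate_input <- function(input_profile, morph, soma_depth_um = NULL,
                           zero_bins = c("nearest", "drop")) {
  stopifnot(inherits(input_profile, "scracm_profile"),
            inherits(morph, "morph_profile"))
  zero_bins <- match.arg(zero_bins)
  if (input_profile$axis != "depth-from-pia")
    stop("'input_profile' must be on the depth-from-pia axis", call. = FALSE)
  if (sum(morph$L) <= 0)
    stop("morphology profile is all zero", call. = FALSE)
  if (!is.null(soma_depth_um))
    morph <- rescale_profile(morph, soma_depth_um)
  p <- input_profile$pitch_um
  pos <- input_profile$position_um
  dst_breaks <- c(pos - p, pos[length(pos)])
  L <- vapply(colnames(morph$L), function(cc)
    rebin_mass(morph$breaks, morph$L[, cc], dst_breaks),
    numeric(length(pos)))
  tot_len <- rowSums(L)
  q <- input_profile$values
  alloc <- matrix(0, length(q), 3L, dimnames = list(NULL, colnames(L)))
  with_dend <- which(tot_len > 0)
  for (k in seq_along(q)) {
    if (q[k] <= 0) next
    src <- k
    if (tot_len[k] <= 0) {
      if (zero_bins == "drop" || !length(with_dend)) next
      src <- with_dend[order(abs(with_dend - k), with_dend)][1L]
    }
    alloc[k, ] <- q[k] * L[src, ] / tot_len[src]
  }
  charges <- colSums(alloc)
  total <- sum(charges)
  props <- if (total > 0) charges / total else charges * 0
  structure(list(proportions = props, charges_pc = charges,
                 total_pc = total, alloc = alloc,
                 dendrite_um = L, position_um = pos),
            class = "compartment_alloc")
}

#' @export
print.compartment_alloc <- function(x, ...) {
  cat(sprintf(
    "compartment allocation: basal %.1f%%, oblique %.1f%%, tuft %.1f%% of %.3g pC\n",
    100 * x$proportions[1], 100 * x$proportions[2], 100 * x$proportions[3],
    x$total_pc))
  invisible(x)
}

#' Convert proportions into absolute compartment charges
#'
#' Scales compartment proportions by a total (full-field) charge.
#'
#' @param proportions length-3 non-negative fractions (basal, oblique,
#'   tuft); need not be exactly normalized (they are renormalized when
#'   their sum is positive).
#' @param full_field_total_pc total charge in pC (>= 0).
#' @return An object of class `compartment_split` with `proportions`,
#'   `charges_pc` (exact, `proportion * total`) and `total_pc`.
#' @examples
#' s <- proportional_charge(c(0.08, 0.17, 0.75), 2.48)
#' round(s$charges_pc[["tuft"]], 2)  # 1.86
#' @export
proportional_charge <- function(proportions, full_field_total_pc) {
  proportions <- as.numeric(proportions)
  if (length(proportions) != 3L || any(!is.finite(proportions)) ||
      any(proportions < 0))
    stop("'proportions' must be 3 non-negative fractions", call. = FALSE)
  if (!is.finite(full_field_total_pc) || full_field_total_pc < 0)
    stop("'full_field_total_pc' must be non-negative", call. = FALSE)
  if (sum(proportions) > 0)
    proportions <- proportions / sum(proportions)
  names(proportions) <- c("basal", "oblique", "tuft")
  charges <- proportions * full_field_total_pc
  structure(list(proportions = proportions, charges_pc = charges,
                 total_pc = full_field_total_pc),
            class = "compartment_split")
}

#' Build a compartment split from absolute charges
#'
#' @param charges_pc length-3 non-negative charges (basal, oblique, tuft)
#'   in pC.
#' @return A `compartment_split` whose total is the sum of the charges.
#' @export
compartment_split <- function(charges_pc) {
  charges_pc <- as.numeric(charges_pc)
  if (length(charges_pc) != 3L || any(!is.finite(charges_pc)) ||
      any(charges_pc < 0))
    stop("'charges_pc' must be 3 non-negative charges", call. = FALSE)
  names(charges_pc) <- c("basal", "oblique", "tuft")
  total <- sum(charges_pc)
  props <- if (total > 0) charges_pc / total else charges_pc * 0
  structure(list(proportions = props, charges_pc = charges_pc,
                 total_pc = total), class = "compartment_split")
}

#' @export
print.compartment_split <- function(x, ...) {
  cat(sprintf(
    "compartment split: total %.2f pC; basal %.2f, oblique %.2f, tuft %.2f pC (%d/%d/%d%%)\n",
    x$total_pc, x$charges_pc[1], x$charges_pc[2], x$charges_pc[3],
    round_half_up(100 * x$proportions[1]),
    round_half_up(100 * x$proportions[2]),
    round_half_up(100 * x$proportions[3])))
  invisible(x)
}

#' Aggregate per-area compartment splits
#'
#' Pools splits across input areas: the grand total is the sum of area
#' totals, and each overall compartment proportion is the summed
#' compartment charge divided by the grand total.
#'
#' @param splits list of `compartment_split` objects.
#' @return A `compartment_split` holding the pooled charges, grand total
#'   and overall proportions.
#' @export
aggregate_splits <- function(splits) {
  if (inherits(splits, "compartment_split")) splits <- list(splits)
  if (!length(splits)) stop("need at least one split", call. = FALSE)
  stopifnot(all(vapply(splits, inherits, logical(1), "compartment_split")))
  charges <- Reduce(`+`, lapply(splits, `[[`, "charges_pc"))
  grand <- sum(vapply(splits, `[[`, numeric(1), "total_pc"))
  props <- if (grand > 0) charges / grand else charges * 0
  structure(list(proportions = props, charges_pc = charges,
                 total_pc = grand, n_areas = length(splits)),
            class = "compartment_split")
}
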