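# Per-area summaries and anatomical-vs-functional comparisons.

# compartment-share-weighted profiles of an averaged map
compartment_profiles <- function(map, morph, soma_depth_um) {
  ms <- rescale_profile(morph, soma_depth_um)
  pv <- vertical_profile(map, align = "pia")
  p <- map$pitch_um
  dst <- c(pv$position_um - p, pv$position_um[length(pv$position_um)])
  L <- vapply(colnames(ms$L), function(cc)
    rebin_mass(ms$breaks, ms$L[, cc], dst), numeric(length(pv$values)))
  tot <- rowSums(L)
  share <- L
  share[tot > 0, ] <- L[tot > 0, ] / tot[tot > 0]
  share[tot <= 0, ] <- 0
  list(share = share, pv = pv, morph_scaled = ms)
}

#' Summarize an input area across recorded cells
#'
#' Builds the per-area summary record: cell counts, mean +/- SEM of
#' full-field totals and soma depths, mean compartment proportions and the
#' corresponding absolute charges, per-compartment peak locations and
#' horizontal biases measured on the aligned average map (tuft reported
#' as depth from the pia, basal and oblique as signed distance from the
#' soma, positive toward the pia / medial), and the fraction of cells
#' whose input peak falls in the tuft (peak shallower than the cell's
#' scaled main-bifurcation depth).
#'
#' @param fits list of `scracm_fit` objects for one area; cells failing
#'   QC or flagged for direct photocurrent are dropped.
#' @param area area label.
#' @param n_animals optional number of animals.
#' @return An object of class `area_summary`.
#' @export
summarize_area <- function(fits, area = "area", n_animals = NA_integer_) {
  if (inherits(fits, "scracm_fit")) fits <- list(fits)
  keep <- vapply(fits, function(f) f$qc_pass && !f$direct_photocurrent,
                 logical(1))
  fits <- fits[keep]
  n <- length(fits)
  if (!n) stop("no cells survive QC for area ", area, call. = FALSE)
  sem <- function(x) if (length(x) > 1L)
    stats::sd(x) / sqrt(length(x)) else NA_real_

  totals <- vapply(fits, `[[`, numeric(1), "total_pc")
  depths <- vapply(fits, `[[`, numeric(1), "soma_depth_um")
  props <- rowMeans(vapply(fits, function(f) f$alloc$proportions,
                           numeric(3)))
  if (sum(props) > 0) props <- props / sum(props)
  split <- proportional_charge(props, mean(totals))

  # aligned average of the normalized maps
  avg_pia <- align_and_average(lapply(fits, `[[`, "map_norm"), mode = "pia")
  avg_soma <- align_and_average(lapply(fits, `[[`, "map_norm"), mode = "soma")

  # per-compartment peaks on the average map, weighted by length share
  morph <- fits[[1]]$morph_scaled
  cp <- compartment_profiles(avg_pia, morph, mean(depths))
  peak <- bias <- c(basal = NA_real_, oblique = NA_real_, tuft = NA_real_)
  soma_row <- avg_pia$soma_anchor[["row"]]
  for (cc in names(peak)) {
    w <- structure(list(values = cp$pv$values * cp$share[, cc],
                        position_um = cp$pv$position_um,
                        axis = "depth-from-pia",
                        pitch_um = avg_pia$pitch_um),
                   class = "scracm_profile")
    if (cc != "tuft") {  # basal and oblique reported from the soma
      w$position_um <- (soma_row - seq_along(w$values)) * avg_pia$pitch_um
      w$axis <- "depth-from-soma"
    }
    peak[cc] <- suppressWarnings(as.numeric(peak_location(w)))
    hv <- colSums(avg_pia$grid * cp$share[, cc])
    hprof <- structure(list(
      values = hv,
      position_um = (seq_along(hv) - avg_pia$soma_anchor[["col"]]) *
        avg_pia$pitch_um * avg_pia$medial_sign,
      axis = "horizontal-from-soma", pitch_um = avg_pia$pitch_um),
      class = "scracm_profile")
    bias[cc] <- suppressWarnings(as.numeric(horizontal_bias(hprof)))
  }

  # per-cell peak-in-tuft test against the cell's scaled bifurcation depth
  in_tuft <- vapply(fits, function(f) {
    pk <- suppressWarnings(peak_location(f$profile_v, round = FALSE))
    !is.na(pk) && is.finite(f$morph_scaled$bifurcation_depth_um) &&
      pk < f$morph_scaled$bifurcation_depth_um
  }, logical(1))

  structure(list(
    area = area, n_cells = n, n_animals = n_animals,
    soma_depth_um = mean(depths), soma_depth_sem = sem(depths),
    total_pc = mean(totals), total_sem = sem(totals),
    proportions = props, charges_pc = split$charges_pc,
    peak_location_um = peak, horizontal_bias_um = bias,
    cells_with_peak_in_tuft = sum(in_tuft),
    map_pia = avg_pia, map_soma = avg_soma
  ), class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d cells, total %.2f +/- %s pC\n", x$area, x$n_cells,
              x$total_pc,
              if (is.na(x$total_sem)) "NA" else sprintf("%.2f", x$total_sem)))
  cat(sprintf("  proportions b/o/t: %d/%d/%d%%; peaks %s um; tuft peaks %d/%d\n",
              round_half_up(100 * x$proportions[1]),
              round_half_up(100 * x$proportions[2]),
              round_half_up(100 * x$proportions[3]),
              paste(x$peak_location_um, collapse = "/"),
              x$cells_with_peak_in_tuft, x$n_cells))
  invisible(x)
}

#' Anatomical vs functional connectivity comparison
#'
#' Spearman rank correlation between per-area presynaptic (rabies) input
#' cell counts and total synaptic charge.
#'
#' @param counts data frame with columns `area` and `count` (one row per
#'   experiment; counts are averaged per area).
#' @param summaries list of `area_summary` objects, or a data frame with
#'   columns `area` and `total_pc`.
#' @return List with `rho`, `p`, `n_areas`, `data`, and `defined` (FALSE
#'   when either ranking is degenerate).
#' @export
anatomy_vs_function <- function(counts, summaries) {
  if (!all(c("area", "count") %in% names(counts)))
    stop("'counts' needs columns area and count", call. = FALSE)
  if (is.data.frame(summaries)) {
    tot <- summaries[, c("area", "total_pc")]
  } else {
    if (inherits(summaries, "area_summary")) summaries <- list(summaries)
    tot <- data.frame(
      area = vapply(summaries, `[[`, character(1), "area"),
      total_pc = vapply(summaries, `[[`, numeric(1), "total_pc"))
  }
  cmean <- stats::aggregate(count ~ area, counts, mean)
  d <- merge(cmean, tot, by = "area")
  if (nrow(d) < 3L) stop("need at least 3 paired areas", call. = FALSE)
  if (length(unique(d$count)) == 1L || length(unique(d$total_pc)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n_areas = nrow(d), data = d,
                defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(d$count, d$total_pc,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_areas = nrow(d),
       data = d, defined = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: adjusted p-values via
#' [stats::p.adjust()] plus accept/reject decisions at the given FDR.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param fdr false-discovery rate for the decisions (default 0.1).
#' @return List with `adjusted` and logical `reject`.
#' @export
bh_adjust <- function(p_values, fdr = 0.1) {
  if (!is.numeric(p_values) || !length(p_values) ||
      any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("'p_values' must be numbers in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= fdr, fdr = fdr)
}
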