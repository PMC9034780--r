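# Per-cell sCRACM estimation: the fitting front-end.

#' Fit the sCRACM input model for one cell
#'
#' Runs the whole per-cell pipeline: series-resistance QC, baselining and
#' trial-averaging, per-spot peak/charge measurement with the 7x-SD
#' inclusion criterion, direct-photocurrent screening, charge-map
#' construction at quadrant resolution, vertical/horizontal projections,
#' compartment allocation against the average morphology profile (rescaled
#' to the cell's soma-pia distance), and conversion to absolute
#' compartment charges via the full-field total.
#'
#' @param session a `recording_session`.
#' @param morph a `morph_profile` (typically the average across
#'   reconstructed cells, see [average_profiles()]).
#' @param cfg an [analysis_config()].
#' @return An object of class `scracm_fit` with components `qc_pass`,
#'   `direct_photocurrent`, `responses`, `map`, `map_norm`, `profile_v`
#'   (pia-aligned vertical), `profile_v_soma`, `profile_h`, `alloc`,
#'   `split`, `total_pc`, `morph_scaled`, `soma_depth_um`, `config`.
#' @seealso [coef.scracm_fit()], [summarize_area()]
#' @export
fit_scracm <- function(session, morph, cfg = analysis_config()) {
  stopifnot(inherits(session, "recording_session"),
            inherits(morph, "morph_profile"))
  qc <- qc_filter(session, cfg)
  segs <- baseline_and_average(session, cfg)
  responses <- measure_responses(segs, cfg)
  direct <- flag_direct_photocurrent(responses, cfg)
  map <- build_map(responses, session)
  map_norm <- suppressWarnings(normalize_map(map))
  pv <- vertical_profile(map, align = "pia")
  pvs <- vertical_profile(map, align = "soma")
  ph <- horizontal_profile(map)
  total <- full_field_charge(session, cfg)
  morph_scaled <- rescale_profile(morph, session$soma_depth_um)
  alloc <- allocate_input(pv, morph_scaled)
  split <- proportional_charge(alloc$proportions, max(0, total))
  structure(list(
    qc_pass = qc, direct_photocurrent = direct, responses = responses,
    map = map, map_norm = map_norm, profile_v = pv, profile_v_soma = pvs,
    profile_h = ph, alloc = alloc, split = split, total_pc = total,
    morph_scaled = morph_scaled, soma_depth_um = session$soma_depth_um,
    series_resistance_mohm = session$series_resistance_mohm,
    medial_sign = session$medial_sign, config = cfg
  ), class = "scracm_fit")
}

#' @export
print.scracm_fit <- function(x, ...) {
  cat("sCRACM fit\n")
  cat(sprintf("  QC: %s; direct photocurrent: %s\n",
              if (x$qc_pass) "pass" else
                "FAIL (series resistance too high)",
              if (x$direct_photocurrent) "FLAGGED" else "no"))
  cat(sprintf("  significant spots: %d / %d; full-field charge %.3g pC\n",
              sum(x$responses$significant), nrow(x$responses), x$total_pc))
  print(x$split)
  invisible(x)
}

#' Compartment input proportions of a fit
#'
#' @param object an `scracm_fit`.
#' @param ... unused.
#' @return Named numeric (basal, oblique, tuft) summing to 1 when any
#'   input was detected.
#' @export
coef.scracm_fit <- function(object, ...) object$alloc$proportions

#' @export
summary.scracm_fit <- function(object, ...) {
  pk_pia <- suppressWarnings(peak_location(object$profile_v))
  pk_h <- suppressWarnings(horizontal_bias(object$profile_h))
  out <- list(
    qc_pass = object$qc_pass,
    direct_photocurrent = object$direct_photocurrent,
    n_significant = sum(object$responses$significant),
    total_pc = object$total_pc,
    proportions = object$alloc$proportions,
    charges_pc = object$split$charges_pc,
    peak_depth_um = as.numeric(pk_pia),
    horizontal_bias_um = as.numeric(pk_h),
    soma_depth_um = object$soma_depth_um
  )
  class(out) <- "summary.scracm_fit"
  out
}

#' @export
print.summary.scracm_fit <- function(x, ...) {
  cat(sprintf(
    "sCRACM fit: total %.3g pC, %d significant spots, peak %.0f um from pia\n",
    x$total_pc, x$n_significant, x$peak_depth_um))
  cat(sprintf(
    "  proportions b/o/t: %.2f/%.2f/%.2f; horizontal bias %+.0f um\n",
    x$proportions[1], x$proportions[2], x$proportions[3],
    x$horizontal_bias_um))
  invisible(x)
}

#' Heatmap of a fitted input map
#'
#' @param x an `scracm_fit`.
#' @param normalized plot the peak-normalized map (default) or raw pC.
#' @param ... passed to [graphics::image()].
#' @export
plot.scracm_fit <- function(x, normalized = TRUE, ...) {
  m <- if (normalized) x$map_norm else x$map
  g <- m$grid
  graphics::image(
    x = seq_len(ncol(g)) * m$pitch_um,
    y = seq_len(nrow(g)) * m$pitch_um,
    z = t(g[rev(seq_len(nrow(g))), , drop = FALSE]),
    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
    xlab = "mediolateral (um)", ylab = "depth from pia (um)",
    useRaster = TRUE, ...)
  graphics::points(m$soma_anchor[["col"]] * m$pitch_um,
                   (nrow(g) - m$soma_anchor[["row"]] + 1) * m$pitch_um,
                   pch = 17, cex = 1.2)
  invisible(x)
}
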