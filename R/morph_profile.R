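# Depth-binned dendritic length profiles.

#' Depth-binned dendritic length profile
#'
#' Quantifies total dendritic length per compartment in bins along the
#' apical-dendrite (depth) axis. Each segment's length is apportioned to
#' bins by linear overlap of its depth span; horizontal structure is
#' collapsed.
#'
#' @param morph a labeled `scracm_morphology`.
#' @param bin_um bin width in um (default 10).
#' @param align axis convention attached to the result: `"pia"` (depth
#'   from pia) or `"soma"` (origin at the soma, positive toward the pia).
#'   Binning is always performed in absolute depth; `align` only sets how
#'   positions are reported.
#' @return A `morph_profile`: list with `L` (bins x 3 matrix of length in
#'   um, columns basal/oblique/tuft), `breaks` (depth bin edges from the
#'   pia), `bin_um`, `soma_depth_um`, `bifurcation_depth_um`, `align`.
#' @export
length_profile <- function(morph, bin_um = 10, align = c("pia", "soma")) {
  stopifnot(inherits(morph, "scracm_morphology"))
  align <- match.arg(align)
  if (!is.numeric(bin_um) || length(bin_um) != 1L || bin_um <= 0)
    stop("'bin_um' must be a positive bin width", call. = FALSE)
  ed <- morph_edges(morph)
  ed <- ed[ed$compartment %in% c("basal", "oblique", "tuft") & ed$length > 0, ]
  if (!nrow(ed)) stop("morphology has no labeled dendritic length",
                      call. = FALSE)
  kmax <- ceiling(max(ed$d1) / bin_um)
  breaks <- seq(0, kmax * bin_um, by = bin_um)
  L <- matrix(0, nrow = kmax, ncol = 3,
              dimnames = list(NULL, c("basal", "oblique", "tuft")))
  for (i in seq_len(nrow(ed))) {
    cc <- ed$compartment[i]
    d0 <- ed$d0[i]; d1 <- ed$d1[i]
    if (d1 - d0 < 1e-9) {
      k <- min(kmax, max(1L, ceiling(d0 / bin_um)))
      L[k, cc] <- L[k, cc] + ed$length[i]
    } else {
      k0 <- max(1L, floor(d0 / bin_um) + 1L)
      k1 <- min(kmax, floor((d1 - 1e-12) / bin_um) + 1L)
      for (k in k0:k1) {
        ov <- min(d1, breaks[k + 1L]) - max(d0, breaks[k])
        L[k, cc] <- L[k, cc] + ed$length[i] * ov / (d1 - d0)
      }
    }
  }
  structure(list(L = L, breaks = breaks, bin_um = bin_um,
                 soma_depth_um = morph$soma_depth_um,
                 bifurcation_depth_um = morph$bifurcation_depth_um,
                 align = align, n_cells = 1L),
            class = "morph_profile")
}

#' @export
print.morph_profile <- function(x, ...) {
  cat(sprintf(
    "morph_profile: %d x %g um bins, soma %.0f um, %d cell(s), %s-aligned\n",
    nrow(x$L), x$bin_um, x$soma_depth_um, x$n_cells, x$align))
  tot <- colSums(x$L)
  cat(sprintf("  length (um): basal %.0f, oblique %.0f, tuft %.0f\n",
              tot[1], tot[2], tot[3]))
  invisible(x)
}

# Redistribute bin masses from src edges onto dst edges by fractional
# overlap. Conserves the total exactly for covering dst grids.
rebin_mass <- function(src_breaks, values, dst_breaks) {
  out <- numeric(length(dst_breaks) - 1L)
  for (i in seq_along(values)) {
    v <- values[i]
    if (v == 0) next
    a <- src_breaks[i]; b <- src_breaks[i + 1L]
    j0 <- findInterval(a, dst_breaks, rightmost.closed = TRUE)
    j1 <- findInterval(b - 1e-12, dst_breaks, rightmost.closed = TRUE)
    j0 <- max(1L, j0); j1 <- min(length(out), max(j0, j1))
    for (j in j0:j1) {
      ov <- min(b, dst_breaks[j + 1L]) - max(a, dst_breaks[j])
      if (ov > 0) out[j] <- out[j] + v * ov / (b - a)
    }
  }
  out
}

# Linearly rescale a profile along depth so that its soma-pia distance
# maps to `target` (pia anchored at 0), re-binned onto `bin_um` bins.
rescale_profile <- function(prof, target, bin_um = prof$bin_um) {
  if (!is.finite(prof$soma_depth_um) || prof$soma_depth_um <= 0)
    stop("profile has zero or unknown soma-pia distance", call. = FALSE)
  s <- target / prof$soma_depth_um
  src <- prof$breaks * s
  kmax <- ceiling(max(src) / bin_um)
  dst <- seq(0, kmax * bin_um, by = bin_um)
  L <- apply(prof$L, 2L, function(v) rebin_mass(src, v, dst))
  structure(list(L = L, breaks = dst, bin_um = bin_um,
                 soma_depth_um = target,
                 bifurcation_depth_um = prof$bifurcation_depth_um * s,
                 align = prof$align, n_cells = prof$n_cells),
            class = "morph_profile")
}

#' Average morphology profiles scaled to a common soma-pia distance
#'
#' Each profile is linearly rescaled along depth (pia anchored at 0) so
#' that its soma maps to `target_soma_pia_um`, re-binned onto common bins
#' (length conserved), and the per-compartment length profiles averaged
#' across cells. Because pia and soma are both anchored by the rescaling,
#' pia- and soma-alignment coincide; `align` sets the reported convention.
#'
#' @param profiles list of `morph_profile` objects.
#' @param target_soma_pia_um soma-pia distance of the averaged profile, um.
#' @param align axis convention of the result.
#' @param bin_um bin width of the result, um.
#' @return A `morph_profile` averaged across cells (`n_cells` recorded).
#' @export
average_profiles <- function(profiles, target_soma_pia_um,
                             align = c("pia", "soma"), bin_um = 10) {
  align <- match.arg(align)
  if (inherits(profiles, "morph_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  stopifnot_scalar(target_soma_pia_um, "target_soma_pia_um")
  scaled <- lapply(profiles, rescale_profile, target = target_soma_pia_um,
                   bin_um = bin_um)
  kmax <- max(vapply(scaled, function(p) nrow(p$L), integer(1)))
  acc <- matrix(0, kmax, 3, dimnames = list(NULL, colnames(scaled[[1]]$L)))
  for (p in scaled) acc[seq_len(nrow(p$L)), ] <- acc[seq_len(nrow(p$L)), ] + p$L
  bif <- vapply(scaled, function(p) p$bifurcation_depth_um, numeric(1))
  structure(list(L = acc / length(scaled),
                 breaks = seq(0, kmax * bin_um, by = bin_um),
                 bin_um = bin_um, soma_depth_um = target_soma_pia_um,
                 bifurcation_depth_um = mean(bif, na.rm = TRUE),
                 align = align, n_cells = length(scaled)),
            class = "morph_profile")
}
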