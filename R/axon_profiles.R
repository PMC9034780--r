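# Laminar axon-density profiles.

#' Generate a canonical laminar axon-density profile
#'
#' Stylized depth profiles of long-range axons in visual cortex,
#' peak-normalized to 1 over `n_bins` bins spanning the full 1000 um
#' cortical depth:
#' * `FF` (feedforward, e.g. VISp/ORB-like): densest in L2/3 and L5,
#'   near-absent in L1;
#' * `FB_thalamic` (LP/ATN-like): global peak in outer L1 with a
#'   secondary peak in L3;
#' * `FB_cortical` (RSPg/ACA-like): superficial L1 peak plus diffuse
#'   deep density.
#'
#' @param pattern one of `"FF"`, `"FB_cortical"`, `"FB_thalamic"`.
#' @param n_bins number of depth bins (>= 10).
#' @param depth_um full cortical depth spanned, um.
#' @param area optional area label carried on the result.
#' @return An object of class `axon_profile`: `density` (peak-normalized),
#'   `depth_um` (bin centers), `breaks`, `area`, `pattern`.
#' @export
generate_axon_profile <- function(pattern = c("FF", "FB_cortical",
                                              "FB_thalamic"),
                                  n_bins = 48L, depth_um = GRID_DEPTH_UM,
                                  area = NULL) {
  pattern <- match.arg(pattern)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 10)
    stop("'n_bins' must be at least 10", call. = FALSE)
  n_bins <- as.integer(n_bins)
  u <- (seq_len(n_bins) - 0.5) / n_bins
  g <- function(mu, sd) exp(-((u - mu) / sd)^2 / 2)
  d <- switch(pattern,
    FF = g(0.30, 0.08) + 0.9 * g(0.65, 0.10),
    FB_thalamic = g(0.04, 0.035) + 0.55 * g(0.35, 0.08),
    FB_cortical = g(0.08, 0.05) + 0.35 * g(0.60, 0.28)
  )
  d <- d / max(d)
  structure(list(density = d,
                 depth_um = u * depth_um,
                 breaks = seq(0, depth_um, length.out = n_bins + 1L),
                 area = area %||% pattern, pattern = pattern),
            class = "axon_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write axon-density profiles as CSV
#'
#' Two-column CSV (`depth_um`, `density`): `depth_um` are bin centers on a
#' uniform grid from the pia downward.
#'
#' @param x an `axon_profile`.
#' @param path CSV path.
#' @param area optional area label attached on read.
#' @export
write_axon_profile <- function(x, path) {
  stopifnot(inherits(x, "axon_profile"))
  utils::write.csv(data.frame(depth_um = x$depth_um, density = x$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_axon_profile
#' @export
read_axon_profile <- function(path, area = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("depth_um", "density") %in% names(d)))
    stop("axon CSV needs columns depth_um, density", call. = FALSE)
  if (any(d$density < 0) || all(d$density <= 0))
    stop("axon densities must be non-negative with at least one positive bin",
         call. = FALSE)
  w <- diff(d$depth_um)
  bw <- if (length(w)) stats::median(w) else d$depth_um[1] * 2
  structure(list(density = d$density, depth_um = d$depth_um,
                 breaks = c(d$depth_um - bw / 2, d$depth_um[length(d$depth_um)]
                            + bw / 2),
                 area = area %||% "axon", pattern = NA_character_),
            class = "axon_profile")
}
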