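# 2D input-map construction, alignment, averaging, and projections.

#' Construct an input map
#'
#' @param grid quadrant-resolution charge matrix (rows = depth from the
#'   pia downward, cols = mediolateral).
#' @param soma_anchor `(row, col)` of the soma at quadrant resolution.
#' @param pia_row row index of the pia.
#' @param medial_sign +1 if increasing column index points medially.
#' @param pitch_um pixel pitch, um.
#' @param counts optional matrix of contributing-cell counts (for
#'   averaged maps).
#' @return An object of class `input_map`.
#' @export
input_map <- function(grid, soma_anchor, pia_row = 1L, medial_sign = 1L,
                      pitch_um = QUADRANT_UM, counts = NULL) {
  if (!is.matrix(grid) || any(!is.finite(grid)))
    stop("'grid' must be a finite numeric matrix", call. = FALSE)
  if (any(grid < 0)) stop("map charges must be non-negative", call. = FALSE)
  if (soma_anchor[1] < 1 || soma_anchor[1] > nrow(grid) ||
      soma_anchor[2] < 1 || soma_anchor[2] > ncol(grid))
    stop("'soma_anchor' outside the grid", call. = FALSE)
  structure(list(grid = grid,
                 soma_anchor = c(row = as.integer(round(soma_anchor[1])),
                                 col = as.integer(round(soma_anchor[2]))),
                 pia_row = as.integer(pia_row),
                 medial_sign = as.integer(medial_sign),
                 pitch_um = pitch_um, counts = counts),
            class = "input_map")
}

#' @export
print.input_map <- function(x, ...) {
  cat(sprintf(
    "input_map: %d x %d px (%.2f um), total %.3g pC, soma (%d, %d), pia row %d\n",
    nrow(x$grid), ncol(x$grid), x$pitch_um, sum(x$grid),
    x$soma_anchor[1], x$soma_anchor[2], x$pia_row))
  invisible(x)
}

#' Build a charge map from spot responses
#'
#' Places per-spot charges on the native stimulation grid (zero for
#' non-significant spots and for negative noise charges), then upsamples
#' 2x to quadrant resolution by splitting each spot's charge equally over
#' its four quadrants, conserving total charge.
#'
#' @param responses response table from [measure_responses()].
#' @param session the `recording_session` the responses came from.
#' @param pia_row quadrant row of the pia (the simulated grid starts at
#'   the pia, row 1).
#' @return An `input_map` at quadrant resolution.
#' @export
build_map <- function(responses, session, pia_row = 1L) {
  n_rows <- session$n_rows; n_cols <- session$n_cols
  if (nrow(responses) != n_rows * n_cols)
    stop(sprintf("expected %d spot responses, got %d", n_rows * n_cols,
                 nrow(responses)), call. = FALSE)
  q <- numeric(n_rows * n_cols)
  keep <- responses$significant
  q[responses$spot_index[keep]] <- pmax(0, responses$charge_pc[keep])
  native <- matrix(0, n_rows, n_cols)
  native[cbind(spot_row(seq_along(q), n_cols), spot_col(seq_along(q), n_cols))] <- q
  up <- native[rep(seq_len(n_rows), each = 2L),
               rep(seq_len(n_cols), each = 2L), drop = FALSE] / 4
  input_map(up, soma_anchor = session$soma_position, pia_row = pia_row,
            medial_sign = session$medial_sign)
}

#' Peak-normalize a map
#'
#' @param map an `input_map`.
#' @return The map divided by its maximum pixel; an all-zero map is
#'   returned unchanged with a warning.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "input_map"))
  mx <- max(map$grid)
  if (mx <= 0) {
    warning("all-zero map: nothing to normalize")
    return(map)
  }
  map$grid <- map$grid / mx
  map
}

#' Align maps on a common anchor and average
#'
#' Shifts each map at quadrant resolution so the chosen vertical anchor
#' (pia or soma row) and the soma column coincide, then averages
#' pixel-wise over the union canvas; each canvas pixel is divided by the
#' number of cells contributing there.
#'
#' @param maps an `input_map` or list of them (same pitch).
#' @param mode vertical anchor: `"pia"` or `"soma"`.
#' @return An averaged `input_map` carrying a `counts` matrix; its
#'   `soma_anchor`/`pia_row` are the (rounded mean) anchor positions on
#'   the canvas.
#' @export
align_and_average <- function(maps, mode = c("pia", "soma")) {
  mode <- match.arg(mode)
  if (inherits(maps, "input_map")) maps <- list(maps)
  if (!length(maps)) stop("need at least one map", call. = FALSE)
  pitch <- maps[[1]]$pitch_um
  if (any(vapply(maps, function(m) abs(m$pitch_um - pitch) > 1e-9, logical(1))))
    stop("maps must share the same pixel pitch", call. = FALSE)
  a_row <- vapply(maps, function(m)
    if (mode == "pia") m$pia_row else m$soma_anchor[["row"]], numeric(1))
  a_col <- vapply(maps, function(m) m$soma_anchor[["col"]], numeric(1))
  nr <- vapply(maps, function(m) nrow(m$grid), numeric(1))
  nc <- vapply(maps, function(m) ncol(m$grid), numeric(1))
  rmin <- min(1 - a_row); rmax <- max(nr - a_row)
  cmin <- min(1 - a_col); cmax <- max(nc - a_col)
  H <- rmax - rmin + 1L; W <- cmax - cmin + 1L
  acc <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  soma_r <- soma_c <- pia_r <- numeric(length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    rr <- seq_len(nrow(m$grid)) - a_row[i] - rmin + 1
    cc <- seq_len(ncol(m$grid)) - a_col[i] - cmin + 1
    acc[rr, cc] <- acc[rr, cc] + m$grid
    cnt[rr, cc] <- cnt[rr, cc] + 1L
    soma_r[i] <- m$soma_anchor[["row"]] - a_row[i] - rmin + 1
    soma_c[i] <- m$soma_anchor[["col"]] - a_col[i] - cmin + 1
    pia_r[i] <- m$pia_row - a_row[i] - rmin + 1
  }
  avg <- acc
  avg[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  input_map(avg,
            soma_anchor = c(round(mean(soma_r)), round(mean(soma_c))),
            pia_row = round(mean(pia_r)),
            medial_sign = maps[[1]]$medial_sign,
            pitch_um = pitch, counts = cnt)
}

#' Project a map onto the depth or horizontal axis
#'
#' Sums the map across the orthogonal axis per pixel row/column (sums, not
#' means, so projections conserve total charge).
#'
#' @param map an `input_map`.
#' @param align axis convention for the vertical profile: depth from the
#'   pia (`"pia"`, positions are positive multiples of the pitch) or
#'   signed distance from the soma (`"soma"`, positive toward the pia).
#' @return An object of class `scracm_profile` with `values`,
#'   `position_um` (on the 1000/48 um lattice), `axis`, `pitch_um`.
#' @export
vertical_profile <- function(map, align = c("pia", "soma")) {
  stopifnot(inherits(map, "input_map"))
  align <- match.arg(align)
  v <- rowSums(map$grid)
  pos <- if (align == "pia")
    (seq_along(v) - map$pia_row + 1) * map$pitch_um
  else
    (map$soma_anchor[["row"]] - seq_along(v)) * map$pitch_um
  structure(list(values = v, position_um = pos,
                 axis = if (align == "pia") "depth-from-pia" else
                   "depth-from-soma",
                 pitch_um = map$pitch_um),
            class = "scracm_profile")
}

#' @rdname vertical_profile
#' @export
horizontal_profile <- function(map) {
  stopifnot(inherits(map, "input_map"))
  v <- colSums(map$grid)
  pos <- (seq_along(v) - map$soma_anchor[["col"]]) * map$pitch_um *
    map$medial_sign
  structure(list(values = v, position_um = pos,
                 axis = "horizontal-from-soma", pitch_um = map$pitch_um),
            class = "scracm_profile")
}

#' Peak location of a profile
#'
#' Position of the maximum bin in the profile's axis convention. Ties are
#' broken toward the anchor (the position closest to zero). The raw value
#' is an integer multiple of the 1000/48 um pixel pitch; the reported
#' value is rounded half-up to integer um (the published 21/42/63/83/104
#' lattice).
#'
#' @param profile a `scracm_profile`.
#' @param round round the result to integer um (default); the unrounded
#'   lattice value is attached as attribute `raw_um` either way.
#' @return Signed distance in um, or NA (with a warning) for an all-zero
#'   profile.
#' @export
peak_location <- function(profile, round = TRUE) {
  stopifnot(inherits(profile, "scracm_profile"))
  if (all(profile$values <= 0)) {
    warning("profile has no positive values: no peak")
    return(NA_real_)
  }
  cand <- which(profile$values == max(profile$values))
  i <- cand[which.min(abs(profile$position_um[cand]))]
  raw <- profile$position_um[i]
  out <- if (round) round_half_up(raw) else raw
  attr(out, "raw_um") <- raw
  out
}

#' Horizontal bias of an input profile
#'
#' Signed mediolateral offset of the profile peak from the soma column
#' (positive medial, negative lateral), quantized to the 1000/48 um pixel
#' lattice and rounded half-up to integer um.
#'
#' @inheritParams peak_location
#' @export
horizontal_bias <- function(profile, round = TRUE) {
  stopifnot(inherits(profile, "scracm_profile"))
  if (profile$axis != "horizontal-from-soma")
    stop("'profile' must be a horizontal (from-soma) profile", call. = FALSE)
  peak_location(profile, round = round)
}

#' @export
print.scracm_profile <- function(x, ...) {
  cat(sprintf("scracm_profile (%s): %d bins of %.2f um, total %.3g\n",
              x$axis, length(x$values), x$pitch_um, sum(x$values)))
  invisible(x)
}
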