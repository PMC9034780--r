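# Stimulation-grid geometry.
#
# The photostimulation grid covers 1000 um of cortical depth by 500 um
# mediolaterally, divided into 24 x 12 square spots of 1000/24 = 41.67 um.
# Somata are localized to one quadrant of a spot, so maps are worked at
# quadrant resolution: 48 x 24 pixels of 1000/48 = 20.83 um. All reported
# peak locations and horizontal biases live on this 20.83-um lattice.
#
# Matrix convention used throughout: rows index cortical depth (row 1 at
# the pia, increasing downward), columns index the mediolateral axis;
# `medial_sign = +1` means increasing column index points medially.

GRID_DEPTH_UM <- 1000
GRID_HORIZ_UM <- 500
N_ROWS_NATIVE <- 24L  # spots along the depth axis
N_COLS_NATIVE <- 12L  # spots along the mediolateral axis
SPOT_UM <- GRID_DEPTH_UM / N_ROWS_NATIVE      # 41.67 um square spots
QUADRANT_UM <- SPOT_UM / 2                    # 20.83 um working pixel

#' Stimulation grid geometry and irradiance
#'
#' Constants of the patterned-stimulation protocol: a 1000 x 500 um grid of
#' 24 x 12 light spots aligned to the apical-dendrite axis, worked at
#' quadrant (half-spot) resolution after soma localization.
#'
#' @param spot_power_uw laser power delivered per spot, in microwatts.
#' @return A list with `grid_depth_um`, `grid_horiz_um`, `n_rows`, `n_cols`
#'   (native spot counts along depth and mediolateral axes), `spot_um`
#'   (spot side), `quadrant_um` (working pixel), and `irradiance_mw_mm2`
#'   (spot power divided by spot area).
#' @examples
#' g <- grid_geometry()
#' round(g$spot_um, 1)            # 41.7
#' round(g$quadrant_um, 1)        # 20.8
#' round(g$irradiance_mw_mm2)     # 173
#' @export
grid_geometry <- function(spot_power_uw = 300) {
  stopifnot_scalar(spot_power_uw, "spot_power_uw")
  spot_mm <- SPOT_UM / 1000
  list(
    grid_depth_um = GRID_DEPTH_UM,
    grid_horiz_um = GRID_HORIZ_UM,
    n_rows = N_ROWS_NATIVE,
    n_cols = N_COLS_NATIVE,
    n_spots = N_ROWS_NATIVE * N_COLS_NATIVE,
    spot_um = SPOT_UM,
    quadrant_um = QUADRANT_UM,
    spot_power_uw = spot_power_uw,
    irradiance_mw_mm2 = (spot_power_uw / 1000) / (spot_mm^2)
  )
}
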