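#' Simulation specification for synthetic sCRACM sessions
#'
#' Bundles the stimulation-protocol constants with the free parameters of
#' the synthetic recording generator. Protocol constants follow the
#' published sCRACM design (24 x 12 spots over 1000 x 500 um, 1 ms stimuli
#' at 10 Hz, 20 kHz acquisition at -70 mV); the remaining defaults describe
#' a strong input pathway recorded under low-noise voltage clamp (see the
#' methods vignette for the choices).
#'
#' @param n_trials number of repetitions of the full 288-spot sequence.
#' @param noise_sd_pa standard deviation of the additive Gaussian baseline
#'   noise, in pA, per raw sweep sample.
#' @param epsc_rise_ms,epsc_decay_ms time constants of the
#'   difference-of-exponentials EPSC kernel, in ms.
#' @param epsc_latency_ms synaptic latency between the light pulse and
#'   EPSC onset, in ms (direct photocurrents, by contrast, begin almost
#'   immediately; the analysis uses a 2 ms onset bound to separate them).
#' @param targeting length-3 non-negative weights (basal, oblique, tuft)
#'   summing to 1: the fraction of the total charge contributed by synapses
#'   on each dendritic compartment. This is the simulation's ground truth.
#' @param total_charge_pc total synaptic charge across all spots, in pC.
#' @param soma_depth_um depth of the soma below the pia, in um; must lie in
#'   (200, 800) so the dendritic tree fits the grid.
#' @param sample_rate_hz acquisition rate in Hz.
#' @param stim_rate_hz stimulus rate in Hz (one spot per 1/rate seconds).
#' @param stim_dur_ms light-pulse duration in ms (metadata only; responses
#'   are modeled at the synaptic-current level).
#' @param seed integer seed controlling all randomness of the generator.
#' @return An object of class `sim_spec`.
#' @seealso [simulate_session()], [generate_morphology()]
#' @export
sim_spec <- function(n_trials = 10L,
                     noise_sd_pa = 0.5,
                     epsc_rise_ms = 2,
                     epsc_decay_ms = 15,
                     epsc_latency_ms = 3,
                     targeting = c(basal = 0.25, oblique = 0.50, tuft = 0.25),
                     total_charge_pc = 10,
                     soma_depth_um = 500,
                     sample_rate_hz = 20000,
                     stim_rate_hz = 10,
                     stim_dur_ms = 1,
                     seed = 1L) {
  stopifnot_scalar(n_trials, "n_trials")
  stopifnot_scalar(noise_sd_pa, "noise_sd_pa", positive = FALSE)
  if (noise_sd_pa < 0) stop("'noise_sd_pa' must be >= 0", call. = FALSE)
  stopifnot_scalar(epsc_rise_ms, "epsc_rise_ms")
  stopifnot_scalar(epsc_decay_ms, "epsc_decay_ms")
  if (epsc_decay_ms <= epsc_rise_ms)
    stop("'epsc_decay_ms' must exceed 'epsc_rise_ms'", call. = FALSE)
  if (!is.numeric(epsc_latency_ms) || epsc_latency_ms < 0 ||
      epsc_latency_ms >= 40)
    stop("'epsc_latency_ms' must be in [0, 40) ms", call. = FALSE)
  stopifnot_scalar(total_charge_pc, "total_charge_pc", positive = FALSE)
  if (total_charge_pc < 0) stop("'total_charge_pc' must be >= 0", call. = FALSE)
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz")
  stopifnot_scalar(stim_rate_hz, "stim_rate_hz")
  stopifnot_scalar(stim_dur_ms, "stim_dur_ms")
  stopifnot_scalar(soma_depth_um, "soma_depth_um")
  if (soma_depth_um <= 200 || soma_depth_um >= 800)
    stop("'soma_depth_um' must lie strictly between 200 and 800 um",
         call. = FALSE)
  targeting <- as.numeric(targeting)
  if (length(targeting) != 3L || any(!is.finite(targeting)) ||
      any(targeting < 0))
    stop("'targeting' must be 3 non-negative weights (basal, oblique, tuft)",
         call. = FALSE)
  if (abs(sum(targeting) - 1) > 1e-9)
    stop("'targeting' weights must sum to 1 (within 1e-9)", call. = FALSE)
  names(targeting) <- c("basal", "oblique", "tuft")

  structure(list(
    grid_depth_um = GRID_DEPTH_UM, grid_horiz_um = GRID_HORIZ_UM,
    n_rows = N_ROWS_NATIVE, n_cols = N_COLS_NATIVE,
    sample_rate_hz = sample_rate_hz, stim_rate_hz = stim_rate_hz,
    stim_dur_ms = stim_dur_ms, n_trials = as.integer(n_trials),
    noise_sd_pa = noise_sd_pa, epsc_rise_ms = epsc_rise_ms,
    epsc_decay_ms = epsc_decay_ms, epsc_latency_ms = epsc_latency_ms,
    targeting = targeting,
    total_charge_pc = total_charge_pc, soma_depth_um = soma_depth_um,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("sCRACM simulation spec\n")
  cat(sprintf("  grid: %d x %d spots (%g x %g um), %g kHz, %g Hz stimuli\n",
              x$n_rows, x$n_cols, x$grid_depth_um, x$grid_horiz_um,
              x$sample_rate_hz / 1000, x$stim_rate_hz))
  cat(sprintf("  trials: %d, noise %.3g pA, EPSC rise/decay %g/%g ms\n",
              x$n_trials, x$noise_sd_pa, x$epsc_rise_ms, x$epsc_decay_ms))
  cat(sprintf("  total charge %.3g pC, targeting b/o/t = %.2f/%.2f/%.2f\n",
              x$total_charge_pc, x$targeting[1], x$targeting[2],
              x$targeting[3]))
  cat(sprintf("  soma depth %g um, seed %d\n", x$soma_depth_um, x$seed))
  invisible(x)
}
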