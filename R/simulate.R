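# Synthetic sCRACM recording sessions with known ground truth.

spot_row <- function(idx, n_cols = N_COLS_NATIVE) (idx - 1L) %/% n_cols + 1L
spot_col <- function(idx, n_cols = N_COLS_NATIVE) (idx - 1L) %% n_cols + 1L

#' Unit-charge EPSC kernel
#'
#' Difference-of-exponentials inward-current kernel sampled on the
#' acquisition grid and windowed to the 50 ms response-quantification
#' window. The sampled kernel is normalized so its trapezoidal integral is
#' exactly 1 (per ms), so a scaled copy deposits exactly the requested
#' charge as measured by the analysis quadrature.
#'
#' @param rise_ms,decay_ms time constants in ms (decay > rise).
#' @param sample_rate_hz sampling rate in Hz.
#' @param window_ms kernel support in ms (the response window).
#' @return Numeric vector of kernel samples (1/ms units), covering
#'   `[0, window_ms]` inclusive.
#' @export
epsc_kernel <- function(rise_ms = 2, decay_ms = 15, sample_rate_hz = 20000,
                        window_ms = 50) {
  dt <- 1000 / sample_rate_hz
  t <- seq(0, window_ms, by = dt)
  k <- exp(-t / decay_ms) - exp(-t / rise_ms)
  k / trapz(k, dt)
}

# pseudo-random spot order: no two consecutive spots are 8-neighbors
stim_order <- function(n_rows = N_ROWS_NATIVE, n_cols = N_COLS_NATIVE,
                       max_tries = 50000L) {
  n <- n_rows * n_cols
  adjacent <- function(a, b) {
    abs(spot_row(a, n_cols) - spot_row(b, n_cols)) <= 1L &
      abs(spot_col(a, n_cols) - spot_col(b, n_cols)) <= 1L
  }
  for (i in seq_len(max_tries)) {
    ord <- sample.int(n)
    if (!any(adjacent(ord[-n], ord[-1L]))) return(ord)
  }
  # greedy repair of the last draw: swap offending successors away
  for (rep_i in seq_len(10000L)) {
    bad <- which(adjacent(ord[-n], ord[-1L]))
    if (!length(bad)) return(ord)
    i <- bad[1L] + 1L
    for (j in sample.int(n)) {
      if (j == i) next
      cand <- ord; tmp <- cand[i]; cand[i] <- cand[j]; cand[j] <- tmp
      touch <- unique(pmax(1L, pmin(n - 1L, c(i - 1L, i, j - 1L, j))))
      if (!any(adjacent(cand[touch], cand[touch + 1L]))) { ord <- cand; break }
    }
  }
  stop("could not construct a non-adjacent stimulus sequence", call. = FALSE)
}

# dendritic length per native grid spot and compartment; edges are cut
# into <=5 um pieces and assigned by midpoint
morph_spot_lengths <- function(morph, n_rows = N_ROWS_NATIVE,
                               n_cols = N_COLS_NATIVE) {
  nd <- morph$nodes
  ed <- morph_edges(morph)
  ed <- ed[ed$compartment %in% c("basal", "oblique", "tuft"), ]
  spot <- SPOT_UM
  x_min <- -GRID_HORIZ_UM / 2
  out <- list(basal = matrix(0, n_rows, n_cols),
              oblique = matrix(0, n_rows, n_cols),
              tuft = matrix(0, n_rows, n_cols))
  for (i in seq_len(nrow(ed))) {
    ci <- ed$child[i]; pid <- ed$parent[i]
    n_sub <- max(1L, ceiling(ed$length[i] / 5))
    f <- (seq_len(n_sub) - 0.5) / n_sub
    xm <- nd$x[pid] + f * (nd$x[ci] - nd$x[pid])
    ym <- nd$y[pid] + f * (nd$y[ci] - nd$y[pid])
    r <- floor(ym / spot) + 1L
    cc <- floor((xm - x_min) / spot) + 1L
    ok <- r >= 1L & r <= n_rows & cc >= 1L & cc <= n_cols
    if (!any(ok)) next
    m <- out[[ed$compartment[i]]]
    piece <- ed$length[i] / n_sub
    for (j in which(ok)) m[r[j], cc[j]] <- m[r[j], cc[j]] + piece
    out[[ed$compartment[i]]] <- m
  }
  out
}

#' Simulate an sCRACM recording session
#'
#' Generates per-trial voltage-clamp sweeps for the full 288-spot grid
#' protocol plus one full-field stimulus per trial. Each spot's noiseless
#' EPSC integrates, over the 50 ms response window, to a ground-truth
#' charge proportional to the dendritic length of the targeted
#' compartments under that spot: `q(spot) = total *
#' sum_c w_c * len_c(spot) / len_c(grid)`, so per-compartment charge sums
#' equal `total * w_c` and the full-field charge equals the sum of all
#' per-spot charges. Additive white Gaussian noise models the recording
#' baseline.
#'
#' @param spec a [sim_spec()].
#' @param morph a `scracm_morphology` (defaults to a tree generated at the
#'   spec's soma depth and seed).
#' @param seed overrides `spec$seed` when given.
#' @return A list with `session` (a `recording_session`) and `truth`
#'   (a `ground_truth`: per-spot charge matrix, compartment split,
#'   per-spot compartment lengths).
#' @export
simulate_session <- function(spec, morph = NULL, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (is.null(morph))
    morph <- generate_morphology(spec$soma_depth_um, seed = seed)
  stopifnot(inherits(morph, "scracm_morphology"))

  lens <- morph_spot_lengths(morph, spec$n_rows, spec$n_cols)
  tot_len <- vapply(lens, sum, numeric(1))
  w <- spec$targeting
  bad <- w > 0 & tot_len[names(w)] <= 0
  if (any(bad))
    stop("targeting weight positive for compartment(s) with no dendritic ",
         "length inside the grid: ", paste(names(w)[bad], collapse = ", "),
         call. = FALSE)
  q <- matrix(0, spec$n_rows, spec$n_cols)
  for (cc in names(w)) {
    if (w[[cc]] > 0) q <- q + w[[cc]] * lens[[cc]] / tot_len[[cc]]
  }
  q <- q * spec$total_charge_pc  # pC per native spot

  fs <- spec$sample_rate_hz
  dt <- 1000 / fs
  isi <- 1000 / spec$stim_rate_hz
  n_spots <- spec$n_rows * spec$n_cols
  t0 <- 50  # ms of pre-protocol baseline
  stim_t <- t0 + (seq_len(n_spots) - 1L) * isi
  ff_t <- t0 + n_spots * isi
  n_samp <- round((ff_t + isi) / dt)
  # kernel support: [latency, 50 ms] after the stimulus, so the full
  # deposited charge falls inside the response-quantification window
  lat_samp <- round(spec$epsc_latency_ms / dt)
  kern <- epsc_kernel(spec$epsc_rise_ms, spec$epsc_decay_ms, fs,
                      window_ms = 50 - spec$epsc_latency_ms)
  klen <- length(kern)

  with_seed(seed, {
    sched <- vector("list", spec$n_trials)
    sweeps <- vector("list", spec$n_trials)
    for (tr in seq_len(spec$n_trials)) {
      ord <- stim_order(spec$n_rows, spec$n_cols)
      x <- if (spec$noise_sd_pa > 0)
        stats::rnorm(n_samp, 0, spec$noise_sd_pa) else numeric(n_samp)
      for (k in seq_len(n_spots)) {
        sp <- ord[k]
        ch_fc <- q[spot_row(sp), spot_col(sp)] * 1000  # pC -> pA*ms
        if (ch_fc > 0) {
          i0 <- round(stim_t[k] / dt) + 1L + lat_samp
          idx <- i0:(i0 + klen - 1L)
          x[idx] <- x[idx] - ch_fc * kern
        }
      }
      i0 <- round(ff_t / dt) + 1L + lat_samp
      idx <- i0:(i0 + klen - 1L)
      x[idx] <- x[idx] - sum(q) * 1000 * kern
      sweeps[[tr]] <- x
      sched[[tr]] <- data.frame(
        trial = tr,
        spot_index = c(ord, NA_integer_),
        t_ms = c(stim_t, ff_t),
        is_full_field = c(rep(FALSE, n_spots), TRUE)
      )
    }
    session <- recording_session(
      sweeps = sweeps, schedule = do.call(rbind, sched),
      sample_rate_hz = fs,
      soma_position = c(
        row = max(1L, min(2L * spec$n_rows,
                          ceiling(morph$soma_depth_um / QUADRANT_UM))),
        col = spec$n_cols  # soma at the grid's horizontal center
      ),
      soma_depth_um = morph$soma_depth_um, medial_sign = 1L,
      series_resistance_mohm = stats::runif(1, 10, 30),
      n_rows = spec$n_rows, n_cols = spec$n_cols
    )
    truth <- structure(list(
      per_spot_charge_pc = q,
      compartment_split = w,
      spot_lengths_um = lens,
      total_charge_pc = spec$total_charge_pc,
      soma_depth_um = morph$soma_depth_um
    ), class = "ground_truth")
    list(session = session, truth = truth)
  })
}
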