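# Per-spot response measurement from raw sweeps.

#' Analysis configuration
#'
#' Detection and QC rules for sCRACM traces: 40 ms pre-stimulus baseline,
#' 50 ms response window, inclusion of responses whose peak exceeds 7x the
#' baseline standard deviation of the trial-averaged trace, exclusion of
#' cells with series resistance above 40 MOhm, and flagging of
#' direct-photocurrent cells by onset latency.
#'
#' @param baseline_window_ms baseline window before each stimulus, ms.
#' @param response_window_ms quantification window after each stimulus, ms.
#' @param detect_sd_mult peak threshold as a multiple of the baseline SD.
#' @param direct_latency_ms onsets faster than this flag direct
#'   photocurrent (onset = first 3x-SD crossing after the stimulus).
#' @param onset_sd_mult SD multiple defining the onset crossing.
#' @param max_series_res_mohm series-resistance QC bound, MOhm (cells with
#'   Rs strictly larger are discarded).
#' @param inward_sign sign of inward currents in the raw traces (-1);
#'   charges are reported positive for inward synaptic currents.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(baseline_window_ms = 40,
                            response_window_ms = 50,
                            detect_sd_mult = 7,
                            direct_latency_ms = 2.0,
                            onset_sd_mult = 3,
                            max_series_res_mohm = 40,
                            inward_sign = -1) {
  for (nm in c("baseline_window_ms", "response_window_ms", "detect_sd_mult",
               "direct_latency_ms", "onset_sd_mult", "max_series_res_mohm"))
    stopifnot_scalar(get(nm), nm)
  if (detect_sd_mult < 1) stop("'detect_sd_mult' must be >= 1", call. = FALSE)
  if (!inward_sign %in% c(-1, 1))
    stop("'inward_sign' must be -1 or +1", call. = FALSE)
  structure(list(baseline_window_ms = baseline_window_ms,
                 response_window_ms = response_window_ms,
                 detect_sd_mult = detect_sd_mult,
                 direct_latency_ms = direct_latency_ms,
                 onset_sd_mult = onset_sd_mult,
                 max_series_res_mohm = max_series_res_mohm,
                 inward_sign = inward_sign),
            class = "analysis_config")
}

#' A single trace segment around one stimulus
#'
#' @param trace numeric samples (pA) spanning the baseline and response
#'   windows; the stimulus occurs at sample `baseline_window_ms` in.
#' @param sample_rate_hz sampling rate, Hz.
#' @param baseline_window_ms length of the pre-stimulus part, ms.
#' @return An object of class `trace_segment`.
#' @export
trace_segment <- function(trace, sample_rate_hz, baseline_window_ms = 40) {
  n_base <- round(baseline_window_ms * sample_rate_hz / 1000)
  if (length(trace) <= n_base + 1L)
    stop("segment shorter than its baseline window", call. = FALSE)
  structure(list(trace = as.numeric(trace), sample_rate_hz = sample_rate_hz,
                 stim_index = n_base + 1L, n_base = n_base),
            class = "trace_segment")
}

#' Baseline-subtract and trial-average all spot segments
#'
#' For every spot, extracts the `[-baseline, +response]` ms window around
#' its stimulus in each trial, subtracts the mean of that trial's own
#' baseline window, and averages across trials. The baseline SD used for
#' detection is computed on the averaged trace's baseline window. The
#' full-field events are processed the same way.
#'
#' @param session a `recording_session`.
#' @param cfg an [analysis_config()].
#' @return An object of class `spot_segments`: averaged segment matrix
#'   (samples x spots), averaged full-field segment, per-spot baseline SD,
#'   and window bookkeeping.
#' @export
baseline_and_average <- function(session, cfg = analysis_config()) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$sample_rate_hz
  dt <- 1000 / fs
  n_base <- round(cfg$baseline_window_ms / dt)
  n_resp <- round(cfg$response_window_ms / dt)
  n_spots <- session$n_rows * session$n_cols
  n_seg <- n_base + n_resp + 1L
  trials <- sort(unique(session$schedule$trial))

  acc <- matrix(0, n_seg, n_spots)
  ff_acc <- numeric(n_seg)
  ff_n <- 0L
  for (tr in trials) {
    x <- session$sweeps[[tr]]
    s <- session$schedule[session$schedule$trial == tr, ]
    sp <- s[!s$is_full_field, ]
    missing <- setdiff(seq_len(n_spots), sp$spot_index)
    if (length(missing))
      stop(sprintf("spot %d missing from trial %d", missing[1], tr),
           call. = FALSE)
    i0 <- round(sp$t_ms / dt) + 1L
    if (any(i0 - n_base < 1L) || any(i0 + n_resp > length(x)))
      stop("analysis windows fall outside the sweep in trial ", tr,
           call. = FALSE)
    idx <- outer(seq.int(-n_base, n_resp), i0, "+")
    seg <- matrix(x[idx], nrow = n_seg)
    seg <- sweep(seg, 2L, colMeans(seg[seq_len(n_base), , drop = FALSE]))
    acc[, sp$spot_index] <- acc[, sp$spot_index] + seg
    for (j in which(s$is_full_field)) {
      i0f <- round(s$t_ms[j] / dt) + 1L
      segf <- x[(i0f - n_base):(i0f + n_resp)]
      ff_acc <- ff_acc + (segf - mean(segf[seq_len(n_base)]))
      ff_n <- ff_n + 1L
    }
  }
  avg <- acc / length(trials)
  base_sd <- apply(avg[seq_len(n_base), , drop = FALSE], 2L, stats::sd)
  structure(list(
    avg = avg, full_field = if (ff_n) ff_acc / ff_n else NULL,
    baseline_sd = base_sd, n_base = n_base, n_resp = n_resp,
    sample_rate_hz = fs, n_trials = length(trials),
    n_rows = session$n_rows, n_cols = session$n_cols
  ), class = "spot_segments")
}

#' Measure one spot response
#'
#' Peak and charge of the evoked current in the response window: the peak
#' is the maximum of the inward-rectified trace; the charge is the
#' trapezoidal integral over the window, reported in pC with inward
#' current as positive charge. A response is significant when its peak
#' exceeds `detect_sd_mult` times the baseline SD. Onset latency is the
#' `onset_sd_mult` x SD crossing attached to the peak: the start of the
#' contiguous supra-threshold run containing the response maximum (NA
#' when the trace never crosses).
#'
#' @param segment a [trace_segment()].
#' @param cfg an [analysis_config()].
#' @param baseline_sd baseline SD in pA; computed from the segment's own
#'   baseline window when NULL.
#' @return One-row data frame: `peak_pa`, `charge_pc`, `baseline_sd_pa`,
#'   `significant`, `onset_latency_ms`.
#' @export
measure_response <- function(segment, cfg = analysis_config(),
                             baseline_sd = NULL) {
  stopifnot(inherits(segment, "trace_segment"))
  dt <- 1000 / segment$sample_rate_hz
  n_resp <- round(cfg$response_window_ms / dt)
  if (n_resp < 1L) stop("response window is empty", call. = FALSE)
  i0 <- segment$stim_index
  if (i0 + n_resp > length(segment$trace))
    stop("segment does not cover the response window", call. = FALSE)
  resp <- segment$trace[i0:(i0 + n_resp)]
  if (is.null(baseline_sd))
    baseline_sd <- stats::sd(segment$trace[seq_len(segment$n_base)])
  rect <- cfg$inward_sign * resp
  peak <- max(rect)
  charge <- trapz(rect, dt) / 1000  # pA*ms -> pC
  sig <- is.finite(baseline_sd) && peak > cfg$detect_sd_mult * baseline_sd
  # onset: the onset_sd_mult x SD crossing attached to the peak (walk back
  # from the peak to the start of its supra-threshold run, so isolated
  # noise excursions earlier in the window are ignored)
  thr <- cfg$onset_sd_mult * baseline_sd
  ipk <- which.max(rect)
  onset <- NA_real_
  if (rect[ipk] > thr) {
    i <- ipk
    while (i > 1L && rect[i - 1L] > thr) i <- i - 1L
    onset <- (i - 1L) * dt
  }
  data.frame(peak_pa = peak, charge_pc = charge,
             baseline_sd_pa = baseline_sd, significant = sig,
             onset_latency_ms = onset)
}

#' Measure all spot responses of a session
#'
#' @param segments a `spot_segments` from [baseline_and_average()].
#' @param cfg an [analysis_config()].
#' @return Data frame with one row per spot (`spot_index`, `peak_pa`,
#'   `charge_pc`, `baseline_sd_pa`, `significant`, `onset_latency_ms`).
#' @export
measure_responses <- function(segments, cfg = analysis_config()) {
  stopifnot(inherits(segments, "spot_segments"))
  n_spots <- ncol(segments$avg)
  out <- lapply(seq_len(n_spots), function(sp) {
    seg <- structure(list(trace = segments$avg[, sp],
                          sample_rate_hz = segments$sample_rate_hz,
                          stim_index = segments$n_base + 1L,
                          n_base = segments$n_base),
                     class = "trace_segment")
    measure_response(seg, cfg, baseline_sd = segments$baseline_sd[sp])
  })
  cbind(spot_index = seq_len(n_spots), do.call(rbind, out))
}

#' Flag direct photocurrent
#'
#' TRUE when any significant spot response begins faster than the
#' direct-photocurrent latency bound; such cells are excluded from
#' averaging (retrogradely infected cells respond to light directly).
#'
#' @param responses response table from [measure_responses()].
#' @param cfg an [analysis_config()].
#' @return Logical flag.
#' @export
flag_direct_photocurrent <- function(responses, cfg = analysis_config()) {
  sig <- responses$significant & !is.na(responses$onset_latency_ms)
  any(sig & responses$onset_latency_ms < cfg$direct_latency_ms)
}

#' Series-resistance QC
#'
#' @param session a `recording_session`.
#' @param cfg an [analysis_config()].
#' @return TRUE (keep) unless the series resistance is strictly larger
#'   than the bound (40 MOhm keeps; 41 discards).
#' @export
qc_filter <- function(session, cfg = analysis_config()) {
  rs <- session$series_resistance_mohm
  if (is.null(rs) || is.na(rs))
    stop("series resistance metadata missing", call. = FALSE)
  rs <= cfg$max_series_res_mohm
}

#' Trial-averaged full-field charge
#'
#' @param session a `recording_session`.
#' @param cfg an [analysis_config()].
#' @return Charge in pC (inward positive) of the baselined, trial-averaged
#'   full-field response.
#' @export
full_field_charge <- function(session, cfg = analysis_config()) {
  stopifnot(inherits(session, "recording_session"))
  if (!any(session$schedule$is_full_field))
    stop("session has no full-field events", call. = FALSE)
  segs <- baseline_and_average(session, cfg)
  dt <- 1000 / segs$sample_rate_hz
  resp <- segs$full_field[(segs$n_base + 1L):(segs$n_base + 1L + segs$n_resp)]
  cfg$inward_sign * trapz(resp, dt) / 1000
}

#' Detection-bias check
#'
#' Tests whether weaker cells have apparently more proximal input (which
#' would indicate distance-dependent detection bias): Pearson correlation
#' between each cell's largest-input-peak depth and its total (full-field)
#' charge.
#'
#' @param cells data frame with columns `peak_depth_um` and `total_pc`,
#'   optionally `area` to split the test per input area.
#' @return Data frame per area: `n`, `r`, `p`, `r_defined` (FALSE when a
#'   variable is degenerate).
#' @export
detection_bias_check <- function(cells) {
  if (!all(c("peak_depth_um", "total_pc") %in% names(cells)))
    stop("'cells' needs columns peak_depth_um and total_pc", call. = FALSE)
  if (is.null(cells$area)) cells$area <- "all"
  out <- lapply(split(cells, cells$area), function(d) {
    if (nrow(d) < 3L)
      stop("need at least 3 cells per area", call. = FALSE)
    if (stats::sd(d$peak_depth_um) == 0 || stats::sd(d$total_pc) == 0)
      return(data.frame(area = d$area[1], n = nrow(d), r = NA_real_,
                        p = NA_real_, r_defined = FALSE))
    ct <- stats::cor.test(d$peak_depth_um, d$total_pc, method = "pearson")
    data.frame(area = d$area[1], n = nrow(d), r = unname(ct$estimate),
               p = ct$p.value, r_defined = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
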