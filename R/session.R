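# RecordingSession container and on-disk layout.

#' Construct a recording session
#'
#' One cell's grid-stimulation voltage-clamp experiment: per-trial sweeps,
#' the stimulus schedule (every spot once per trial plus one full-field
#' event), and cell geometry / QC metadata.
#'
#' @param sweeps list of numeric vectors (pA), one per trial.
#' @param schedule data frame with columns `trial`, `spot_index` (NA for
#'   full-field events), `t_ms`, `is_full_field`.
#' @param sample_rate_hz acquisition rate, Hz.
#' @param soma_position `(row, col)` of the soma at quadrant resolution.
#' @param soma_depth_um pia-to-soma distance along the apical axis, um.
#' @param medial_sign +1 if increasing column index points medially.
#' @param series_resistance_mohm series resistance, MOhm.
#' @param holding_mv holding potential, mV.
#' @param n_rows,n_cols native grid dimensions (depth x mediolateral).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(sweeps, schedule, sample_rate_hz,
                              soma_position, soma_depth_um,
                              medial_sign = 1L,
                              series_resistance_mohm = NA_real_,
                              holding_mv = -70,
                              n_rows = N_ROWS_NATIVE,
                              n_cols = N_COLS_NATIVE) {
  if (!is.list(sweeps) || !length(sweeps))
    stop("'sweeps' must be a non-empty list of numeric vectors", call. = FALSE)
  need <- c("trial", "spot_index", "t_ms", "is_full_field")
  if (!all(need %in% names(schedule)))
    stop("'schedule' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n_spots <- n_rows * n_cols
  for (tr in unique(schedule$trial)) {
    s <- schedule[schedule$trial == tr & !schedule$is_full_field, ]
    if (any(diff(schedule$t_ms[schedule$trial == tr]) <= 0))
      stop("stimulus times must be strictly increasing within trial ", tr,
           call. = FALSE)
    if (!setequal(s$spot_index, seq_len(n_spots)))
      stop("trial ", tr, " does not stimulate every spot exactly once",
           call. = FALSE)
  }
  if (soma_position[1] < 1 || soma_position[1] > 2 * n_rows ||
      soma_position[2] < 1 || soma_position[2] > 2 * n_cols)
    stop("'soma_position' lies outside the quadrant grid", call. = FALSE)
  structure(list(
    sweeps = sweeps, schedule = schedule, sample_rate_hz = sample_rate_hz,
    soma_position = c(row = as.integer(soma_position[1]),
                      col = as.integer(soma_position[2])),
    soma_depth_um = soma_depth_um, medial_sign = as.integer(medial_sign),
    series_resistance_mohm = series_resistance_mohm,
    holding_mv = holding_mv,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
  ), class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "recording_session: %d trials, %d spots, %g kHz, Rs %.1f MOhm\n",
    length(x$sweeps), x$n_rows * x$n_cols, x$sample_rate_hz / 1000,
    x$series_resistance_mohm))
  cat(sprintf("  soma: depth %.0f um, quadrant (%d, %d), medial sign %+d\n",
              x$soma_depth_um, x$soma_position[1], x$soma_position[2],
              x$medial_sign))
  invisible(x)
}

#' Write / read a recording session
#'
#' Directory layout mirroring the documented group structure:
#' `sweeps/trial%03d.csv` (one `current_pa` column per trial),
#' `schedule.csv` (`trial,spot_index,t_ms,is_full_field`), and `meta.json`
#' (sample rate, soma position/depth, medial sign, series resistance,
#' holding potential, grid shape).
#'
#' @param session a `recording_session`.
#' @param dir directory to create/read.
#' @return `write_recording_session` returns `dir` invisibly;
#'   `read_recording_session` returns a `recording_session`.
#' @export
write_recording_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(file.path(dir, "sweeps"), recursive = TRUE, showWarnings = FALSE)
  for (tr in seq_along(session$sweeps)) {
    data.table::fwrite(
      data.table::data.table(current_pa = session$sweeps[[tr]]),
      file.path(dir, "sweeps", sprintf("trial%03d.csv", tr)))
  }
  data.table::fwrite(session$schedule, file.path(dir, "schedule.csv"))
  meta <- session[c("sample_rate_hz", "soma_position", "soma_depth_um",
                    "medial_sign", "series_resistance_mohm", "holding_mv",
                    "n_rows", "n_cols")]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_recording_session
#' @export
read_recording_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(file.path(dir, "sweeps"), pattern = "^trial.*csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no sweep files under ", dir, call. = FALSE)
  sweeps <- lapply(files, function(f) data.table::fread(f)$current_pa)
  schedule <- as.data.frame(data.table::fread(file.path(dir, "schedule.csv")))
  schedule$spot_index <- as.integer(schedule$spot_index)
  schedule$is_full_field <- as.logical(schedule$is_full_field)
  recording_session(
    sweeps = sweeps, schedule = schedule,
    sample_rate_hz = meta$sample_rate_hz,
    soma_position = unlist(meta$soma_position),
    soma_depth_um = meta$soma_depth_um, medial_sign = meta$medial_sign,
    series_resistance_mohm = meta$series_resistance_mohm,
    holding_mv = meta$holding_mv, n_rows = meta$n_rows, n_cols = meta$n_cols
  )
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth` from [simulate_session()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(
    per_spot_charge_pc = truth$per_spot_charge_pc,
    compartment_split = as.list(truth$compartment_split),
    total_charge_pc = truth$total_charge_pc,
    soma_depth_um = truth$soma_depth_um
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
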