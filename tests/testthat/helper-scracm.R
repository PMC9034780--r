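# Shared fixtures, built in code.

PITCH <- 1000 / 48  # quadrant pixel, um

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# a light simulation spec for tests that do not need 20 kHz precision
quick_spec <- function(n_trials = 2L, sample_rate_hz = 2000, ...) {
  sim_spec(n_trials = n_trials, sample_rate_hz = sample_rate_hz, ...)
}

# a zero map at quadrant resolution with soma mid-grid
blank_map <- function(nrow = 48L, ncol = 24L, soma = c(24L, 12L)) {
  input_map(matrix(0, nrow, ncol), soma_anchor = soma, pia_row = 1L)
}

# segment holding a noiseless EPSC-like kernel of given charge (pC),
# delayed by `latency_ms` after the stimulus
kernel_segment <- function(charge_pc, sample_rate_hz = 20000,
                           latency_ms = 0, baseline_ms = 40,
                           response_ms = 50) {
  dt <- 1000 / sample_rate_hz
  n_base <- round(baseline_ms / dt)
  n_resp <- round(response_ms / dt)
  k <- epsc_kernel(sample_rate_hz = sample_rate_hz,
                   window_ms = response_ms - latency_ms)
  tr <- numeric(n_base + n_resp + 1L)
  i0 <- n_base + 1L + round(latency_ms / dt)
  tr[i0:(i0 + length(k) - 1L)] <- -charge_pc * 1000 * k
  trace_segment(tr, sample_rate_hz, baseline_ms)
}

# hand-built morphology: a soma plus explicit labeled segments
# segs: list of list(comp, from = c(x, y), to = c(x, y))
toy_morphology <- function(segs, soma_depth = 400) {
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = soma_depth, z = 0,
                      radius = 8, parent = -1L)
  comp <- "soma"
  nid <- 1L
  for (s in segs) {
    nid <- nid + 1L
    nodes <- rbind(nodes,
      data.frame(id = nid, type = SWC_TYPE_LOOKUP[[s$comp]], x = s$from[1],
                 y = s$from[2], z = 0, radius = 1,
                 parent = if (is.null(s$parent)) 1L else s$parent))
    comp <- c(comp, s$comp)
    nid <- nid + 1L
    nodes <- rbind(nodes,
      data.frame(id = nid, type = SWC_TYPE_LOOKUP[[s$comp]], x = s$to[1],
                 y = s$to[2], z = 0, radius = 1, parent = nid - 1L))
    comp <- c(comp, s$comp)
  }
  structure(list(nodes = nodes,
                 compartment = factor(comp,
                                      levels = c("soma", "basal", "oblique",
                                                 "tuft")),
                 soma_depth_um = soma_depth,
                 bifurcation_depth_um = NA_real_),
            class = "scracm_morphology")
}
SWC_TYPE_LOOKUP <- list(soma = 1L, basal = 3L, oblique = 4L, tuft = 5L)

# morph_profile built directly from a length matrix (10-um bins)
toy_morph_profile <- function(L, bin_um = 10, soma_depth = NULL,
                              bif_depth = NA_real_) {
  colnames(L) <- c("basal", "oblique", "tuft")
  structure(list(L = L, breaks = seq(0, nrow(L) * bin_um, by = bin_um),
                 bin_um = bin_um,
                 soma_depth_um = soma_depth %||% (nrow(L) * bin_um / 2),
                 bifurcation_depth_um = bif_depth, align = "pia",
                 n_cells = 1L), class = "morph_profile")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# depth-from-pia charge profile on the quadrant lattice
toy_profile <- function(values, axis = "depth-from-pia", pitch = PITCH,
                        soma_bin = NULL) {
  pos <- switch(axis,
    "depth-from-pia" = seq_along(values) * pitch,
    "depth-from-soma" = (soma_bin - seq_along(values)) * pitch,
    "horizontal-from-soma" = (seq_along(values) - soma_bin) * pitch)
  structure(list(values = values, position_um = pos, axis = axis,
                 pitch_um = pitch), class = "scracm_profile")
}
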