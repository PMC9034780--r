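# Baselining, response measurement, detection and QC rules.

test_that("baseline subtraction removes constant offsets", {
  m <- generate_morphology(500, seed = 21)
  sim <- simulate_session(quick_spec(noise_sd_pa = 0, total_charge_pc = 0,
                                     n_trials = 1L, seed = 21), m)
  sim$session$sweeps[[1]] <- sim$session$sweeps[[1]] + 5  # +5 pA everywhere
  segs <- baseline_and_average(sim$session)
  expect_equal(max(abs(segs$avg)), 0)
  r <- measure_responses(segs)
  expect_true(all(r$charge_pc == 0))
  expect_true(all(!r$significant))
})

test_that("trial averaging is linear in charge", {
  m <- generate_morphology(500, seed = 22)
  sp <- sim_spec(noise_sd_pa = 0, n_trials = 1L, total_charge_pc = 1,
                 sample_rate_hz = 2000, seed = 22)
  sim <- simulate_session(sp, m)
  s <- sim$session
  # second trial = same protocol at 3x the amplitude
  s$sweeps[[2]] <- s$sweeps[[1]] * 3
  sch2 <- s$schedule; sch2$trial <- 2L
  s$schedule <- rbind(s$schedule, sch2)
  segs <- baseline_and_average(s)
  r <- measure_responses(segs)
  expect_equal(sum(r$charge_pc), 2, tolerance = 1e-6)  # mean of 1 and 3 pC
  expect_equal(full_field_charge(s), 2, tolerance = 1e-6)
})

test_that("baseline SD of the average shrinks like 1/sqrt(n_trials)", {
  m <- generate_morphology(500, seed = 23)
  sim <- simulate_session(sim_spec(noise_sd_pa = 2, n_trials = 5L,
                                   total_charge_pc = 0, seed = 23), m)
  segs <- baseline_and_average(sim$session)
  expect_equal(mean(segs$baseline_sd), 2 / sqrt(5), tolerance = 0.2)
})

test_that("rectangular pulses give the textbook peak and charge", {
  fs <- 20000; dt <- 1000 / fs
  tr <- numeric(round(90 / dt) + 1L)
  i0 <- round(40 / dt) + 1L
  tr[i0:(i0 + round(10 / dt))] <- -10  # 10 ms x -10 pA
  r <- measure_response(trace_segment(tr, fs), baseline_sd = 0.1)
  expect_equal(r$peak_pa, 10)
  expect_equal(r$charge_pc, 0.1, tolerance = 0.005)
  r0 <- measure_response(trace_segment(numeric(2001), fs))
  expect_equal(r0$charge_pc, 0)
  expect_false(r0$significant)
})

test_that("the 7x-SD inclusion criterion is a strict peak threshold", {
  k <- kernel_segment(1)  # arbitrary shape; rescale to target peak
  pk <- max(-k$trace)
  for (mult in c(6.9, 7.1)) {
    seg <- k
    seg$trace <- seg$trace * (mult * 1 / pk)  # peak = mult x SD of 1
    r <- measure_response(seg, baseline_sd = 1)
    expect_identical(r$significant, mult > 7)
  }
})

test_that("charge scales exactly with the sweep gain", {
  m <- generate_morphology(500, seed = 24)
  sim <- simulate_session(quick_spec(seed = 24), m)
  segs1 <- baseline_and_average(sim$session)
  s2 <- sim$session
  s2$sweeps <- lapply(s2$sweeps, function(x) x * 2.5)
  segs2 <- baseline_and_average(s2)
  r1 <- measure_responses(segs1); r2 <- measure_responses(segs2)
  expect_equal(r2$charge_pc, r1$charge_pc * 2.5, tolerance = 1e-12)
  expect_equal(r2$peak_pa, r1$peak_pa * 2.5, tolerance = 1e-12)
})

test_that("onset latency separates synaptic from direct responses", {
  syn <- measure_response(kernel_segment(0.5, latency_ms = 4),
                          baseline_sd = 0.05)
  expect_gte(syn$onset_latency_ms, 4)
  expect_false(flag_direct_photocurrent(syn))
  # step current starting 0.5 ms after the stimulus
  fs <- 20000; dt <- 1000 / fs
  tr <- numeric(round(90 / dt) + 1L)
  i0 <- round(40.5 / dt) + 1L
  tr[i0:length(tr)] <- -30
  direct <- measure_response(trace_segment(tr, fs), baseline_sd = 0.05)
  expect_lt(direct$onset_latency_ms, 2)
  expect_true(flag_direct_photocurrent(direct))
  # no significant spots -> never flagged
  quiet <- measure_response(trace_segment(numeric(2001), fs))
  expect_false(flag_direct_photocurrent(quiet))
})

test_that("series-resistance QC discards strictly above 40 MOhm", {
  m <- generate_morphology(500, seed = 25)
  sim <- simulate_session(quick_spec(n_trials = 1L, seed = 25), m)
  s <- sim$session
  for (rs in c(39, 40, 41)) {
    s$series_resistance_mohm <- rs
    expect_identical(qc_filter(s), rs <= 40)
  }
  s$series_resistance_mohm <- NA_real_
  expect_error(qc_filter(s), "missing")
})

test_that("pure-noise sessions yield almost no significant spots", {
  n_sig <- 0L; n_tot <- 0L
  for (s in 1:3) {
    m <- generate_morphology(500, seed = 300 + s)
    sim <- simulate_session(sim_spec(total_charge_pc = 0, n_trials = 3L,
                                     sample_rate_hz = 4000, seed = 300 + s),
                            m)
    r <- measure_responses(baseline_and_average(sim$session))
    n_sig <- n_sig + sum(r$significant)
    n_tot <- n_tot + nrow(r)
  }
  expect_lt(n_sig / n_tot, 0.01)
})

test_that("detection-bias check reports r, p and degenerate cases", {
  d <- data.frame(peak_depth_um = c(100, 200, 300, 400),
                  total_pc = c(1, 2, 3, 4))
  res <- detection_bias_check(d)
  expect_equal(res$r, 1, tolerance = 1e-12)
  d$peak_depth_um <- rep(250, 4)
  res2 <- detection_bias_check(d)
  expect_false(res2$r_defined)
  expect_true(is.na(res2$r))
  expect_error(detection_bias_check(d[1:2, ]), "at least 3")
  # depth-independent charge: |r| stays small in most draws
  set.seed(99)
  ok <- 0L
  for (i in 1:20) {
    dd <- data.frame(peak_depth_um = runif(20, 50, 900),
                     total_pc = rlnorm(20))
    if (abs(detection_bias_check(dd)$r) < 0.45) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("missing spots are rejected naming spot and trial", {
  m <- generate_morphology(500, seed = 26)
  sim <- simulate_session(quick_spec(n_trials = 1L, seed = 26), m)
  s <- sim$session
  drop <- which(s$schedule$spot_index == 17L)[1]
  s$schedule <- s$schedule[-drop, ]
  expect_error(baseline_and_average(s), "17")
})
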