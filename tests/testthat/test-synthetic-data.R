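# Synthetic-data generator: morphologies, axon profiles, sessions.

test_that("sim_spec validates its invariants", {
  s <- sim_spec()
  expect_equal(s$n_rows * s$n_cols, 288L)
  expect_error(sim_spec(targeting = c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(sim_spec(targeting = c(-0.1, 0.6, 0.5)), "non-negative")
  expect_error(sim_spec(soma_depth_um = 150), "between 200 and 800")
  expect_error(sim_spec(soma_depth_um = 900), "between 200 and 800")
  expect_error(sim_spec(epsc_decay_ms = 1), "exceed")
})

test_that("morphology generation is deterministic and depth-bounded", {
  m1 <- generate_morphology(500, seed = 11)
  m2 <- generate_morphology(500, seed = 11)
  expect_identical(m1, m2)
  f1 <- file.path(tempdir(), "m1.swc"); f2 <- file.path(tempdir(), "m2.swc")
  write_swc(m1, f1); write_swc(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  m3 <- generate_morphology(500, seed = 12)
  expect_false(identical(m1$nodes, m3$nodes))
  expect_error(generate_morphology(150), "between 200 and 800")
})

test_that("generated trees have all compartments, tuft above bifurcation", {
  m <- generate_morphology(500, seed = 1)
  lens <- table(m$compartment)
  expect_true(all(lens[c("basal", "oblique", "tuft")] > 0))
  tuft_depths <- m$nodes$y[m$compartment == "tuft"]
  expect_true(all(tuft_depths < m$bifurcation_depth_um + 1e-9))
})

test_that("averaged morphology shows the superficial-to-deep band order", {
  profs <- lapply(1:11, function(s)
    length_profile(generate_morphology(450 + 10 * (s %% 5), seed = s)))
  avg <- average_profiles(profs, target_soma_pia_um = 500)
  mid <- avg$breaks[-1] - avg$bin_um / 2
  centroid <- function(cc) sum(mid * avg$L[, cc]) / sum(avg$L[, cc])
  expect_lt(centroid("tuft"), centroid("oblique"))
  expect_lt(centroid("oblique"), centroid("basal"))
})

test_that("axon profiles match their laminar patterns", {
  ff <- generate_axon_profile("FF", 100)
  expect_equal(max(ff$density), 1)
  expect_true(all(ff$density[1:10] < 0.1))
  th <- generate_axon_profile("FB_thalamic", 100)
  expect_lte(which.max(th$density), 10)
  # secondary mid-depth peak present
  mid <- th$density[20:60]
  expect_gt(max(mid), 0.3)
  cx <- generate_axon_profile("FB_cortical", 100)
  expect_lte(which.max(cx$density), 15)
  expect_gt(mean(cx$density[50:90]), 0.05)
  for (p in c("FF", "FB_cortical", "FB_thalamic")) {
    d <- generate_axon_profile(p, 50)
    expect_true(all(d$density >= 0))
    expect_true(is.finite(sum(d$density)) && sum(d$density) > 0)
  }
  expect_error(generate_axon_profile("FB"), "arg")
  expect_error(generate_axon_profile("FF", n_bins = 5), "at least 10")
})

test_that("simulated sessions are deterministic and conserve charge", {
  m <- generate_morphology(500, seed = 2)
  sp <- quick_spec(seed = 2)
  a <- simulate_session(sp, m)
  b <- simulate_session(sp, m)
  expect_identical(a$session$sweeps, b$session$sweeps)
  expect_identical(a$session$schedule, b$session$schedule)
  expect_equal(sum(a$truth$per_spot_charge_pc), sp$total_charge_pc,
               tolerance = 1e-12)
})

test_that("ground-truth compartment sums match the targeting split", {
  m <- generate_morphology(500, seed = 4)
  w <- c(0.2, 0.3, 0.5)
  sim <- simulate_session(quick_spec(targeting = w, seed = 4), m)
  q <- sim$truth$per_spot_charge_pc
  lens <- sim$truth$spot_lengths_um
  expected <- Reduce(`+`, lapply(1:3, function(i) {
    cc <- c("basal", "oblique", "tuft")[i]
    w[i] * lens[[cc]] / sum(lens[[cc]]) * 10
  }))
  expect_equal(q, expected, tolerance = 1e-12)
  # per-compartment charge totals are exactly the targeting split
  for (i in 1:3) {
    cc <- c("basal", "oblique", "tuft")[i]
    expect_equal(sum(w[i] * lens[[cc]] / sum(lens[[cc]]) * 10), w[i] * 10,
                 tolerance = 1e-9)
  }
  expect_true(all(q >= 0))
})

test_that("stimulus sequences never stimulate grid neighbors consecutively", {
  m <- generate_morphology(500, seed = 6)
  sim <- simulate_session(quick_spec(n_trials = 3L, seed = 6), m)
  sch <- sim$session$schedule
  for (tr in 1:3) {
    o <- sch$spot_index[sch$trial == tr & !sch$is_full_field]
    expect_setequal(o, 1:288)
    dr <- abs(diff((o - 1L) %/% 12L))
    dc <- abs(diff((o - 1L) %% 12L))
    expect_false(any(dr <= 1 & dc <= 1))
  }
})

test_that("a noiseless single-spot charge is recovered to 1e-6", {
  m <- generate_morphology(500, seed = 5)
  sp <- sim_spec(noise_sd_pa = 0, n_trials = 1L, total_charge_pc = 1,
                 targeting = c(0, 0, 1), seed = 5)
  sim <- simulate_session(sp, m)
  segs <- baseline_and_average(sim$session)
  r <- measure_responses(segs)
  truth <- vapply(seq_len(288), function(s)
    sim$truth$per_spot_charge_pc[(s - 1) %/% 12 + 1, (s - 1) %% 12 + 1],
    numeric(1))
  expect_lt(max(abs(r$charge_pc - truth)), 1e-6)
  expect_equal(sum(r$charge_pc), 1, tolerance = 1e-6)
})

test_that("tuft-only targeting puts charge only in rows overlapping tuft", {
  m <- generate_morphology(500, seed = 7)
  sim <- simulate_session(quick_spec(targeting = c(0, 0, 1), noise_sd_pa = 0,
                                     seed = 7), m)
  q <- sim$truth$per_spot_charge_pc
  tuft_rows <- which(rowSums(sim$truth$spot_lengths_um$tuft) > 0)
  expect_true(all(which(rowSums(q) > 0) %in% tuft_rows))
})

test_that("full-field charge equals the sum of per-spot charges", {
  m <- generate_morphology(500, seed = 8)
  sim <- simulate_session(sim_spec(noise_sd_pa = 0, n_trials = 1L, seed = 8),
                          m)
  ff <- full_field_charge(sim$session)
  expect_equal(ff, sum(sim$truth$per_spot_charge_pc), tolerance = 1e-6)
})

test_that("targeting a compartment absent from the grid is rejected", {
  m <- generate_morphology(500, seed = 9)
  m$compartment[m$compartment == "tuft"] <- "oblique"
  m$nodes$type[m$nodes$type == 5L] <- 4L
  expect_error(simulate_session(quick_spec(targeting = c(0, 0, 1), seed = 9),
                                m),
               "no dendritic length")
})
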