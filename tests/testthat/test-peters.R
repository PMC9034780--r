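# Peters'-rule overlap predictions and profile comparison.

toy_axon <- function(density, bin = 20) {
  structure(list(density = density,
                 depth_um = (seq_along(density) - 0.5) * bin,
                 breaks = seq(0, length(density) * bin, by = bin),
                 area = "toy", pattern = "toy"),
            class = "axon_profile")
}

test_that("predicted input is the hand-computed normalized product", {
  axon <- toy_axon(c(0.2, 1, 0.4, 0, 0.1))
  L <- cbind(basal = c(0, 0, 0, 0, 0), oblique = c(0, 0, 0, 0, 0),
             tuft = c(1, 2, 4, 2, 1))
  dend <- toy_morph_profile(L, bin_um = 20, soma_depth = 50)
  pred <- predict_input(axon, dend, bin_um = 20)
  expect_equal(pred$values, c(0.05, 0.5, 0.4, 0, 0.025), tolerance = 1e-12)
  expect_equal(max(pred$values[pred$values > 0] <= 1), 1)
})

test_that("prediction is invariant to rescaling either factor", {
  axon <- toy_axon(c(0.2, 1, 0.4, 0, 0.1))
  L <- cbind(c(1, 0, 0, 0, 2), c(0, 3, 1, 0, 0), c(2, 2, 0, 1, 0))
  dend <- toy_morph_profile(L, bin_um = 20, soma_depth = 50)
  p1 <- predict_input(axon, dend, bin_um = 20)
  axon10 <- toy_axon(c(0.2, 1, 0.4, 0, 0.1) * 10)
  dend3 <- toy_morph_profile(L * 3, bin_um = 20, soma_depth = 50)
  expect_equal(predict_input(axon10, dend, bin_um = 20)$values, p1$values,
               tolerance = 1e-12)
  expect_equal(predict_input(axon, dend3, bin_um = 20)$values, p1$values,
               tolerance = 1e-12)
})

test_that("coincident peaks predict 1; disjoint supports predict zero", {
  axon <- toy_axon(c(0, 1, 0, 0, 0))
  L <- cbind(numeric(5), numeric(5), c(0, 5, 1, 0, 0))
  dend <- toy_morph_profile(L, bin_um = 20, soma_depth = 50)
  pred <- predict_input(axon, dend, bin_um = 20)
  expect_equal(max(pred$values), 1)
  L2 <- cbind(numeric(5), numeric(5), c(0, 0, 0, 2, 1))
  dend2 <- toy_morph_profile(L2, bin_um = 20, soma_depth = 50)
  expect_warning(p0 <- predict_input(axon, dend2, bin_um = 20), "disjoint")
  expect_true(all(p0$values == 0))
})

test_that("compare_profiles returns cosine 1 / 0 for identical / disjoint", {
  a <- toy_profile(c(0, 1, 2, 1, 0), pitch = 20)
  expect_equal(compare_profiles(a, a)$cosine, 1, tolerance = 1e-12)
  b <- toy_profile(c(2, 0, 0, 0, 1), pitch = 20)
  d <- toy_profile(c(0, 1, 1, 1, 0), pitch = 20)
  expect_equal(compare_profiles(b, d)$cosine, 0)
  expect_warning(res <- compare_profiles(toy_profile(numeric(5), pitch = 20),
                                         a), "undefined")
  expect_false(res$defined)
})

test_that("matched targeting beats a mismatched axon pattern", {
  m <- generate_morphology(500, seed = 71)
  sim <- simulate_session(sim_spec(targeting = c(0, 0, 1), seed = 71), m)
  fit <- fit_scracm(sim$session, length_profile(m))
  measured <- fit$profile_v
  dend <- average_profiles(list(length_profile(m)), 500)
  ff <- predict_input(generate_axon_profile("FF"), dend)
  fb <- predict_input(generate_axon_profile("FB_thalamic"), dend)
  c_ff <- compare_profiles(ff, measured)$cosine
  c_fb <- compare_profiles(fb, measured)$cosine
  expect_lt(c_ff, c_fb)
})

test_that("similarity rises as recording noise falls", {
  m <- generate_morphology(500, seed = 72)
  dend <- average_profiles(list(length_profile(m)), 500)
  cos_at <- vapply(c(2, 0.5, 0), function(noise) {
    sim <- simulate_session(sim_spec(targeting = c(0.25, 0.5, 0.25),
                                     noise_sd_pa = noise, n_trials = 3L,
                                     seed = 72), m)
    fit <- fit_scracm(sim$session, length_profile(m))
    # predictor whose targeting matches the ground truth: the measured
    # noiseless vertical charge profile itself
    truthmap <- input_map(
      sim$truth$per_spot_charge_pc[rep(1:24, each = 2), rep(1:12, each = 2)] / 4,
      soma_anchor = sim$session$soma_position, pia_row = 1L)
    compare_profiles(vertical_profile(truthmap), fit$profile_v)$cosine
  }, numeric(1))
  expect_true(all(diff(cos_at) >= -0.02))  # rising, modulo sampling noise
  expect_gt(cos_at[3], 0.999)
  expect_gt(cos_at[3], cos_at[1])
})
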