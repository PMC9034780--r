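# Map construction, normalization, alignment, projections, peaks.

fake_responses <- function(charges, significant = charges > 0) {
  data.frame(spot_index = seq_along(charges), peak_pa = abs(charges),
             charge_pc = charges, baseline_sd_pa = 0.1,
             significant = significant, onset_latency_ms = 5)
}

fake_session_meta <- function(soma = c(24L, 12L)) {
  structure(list(n_rows = 24L, n_cols = 12L,
                 soma_position = c(row = soma[1], col = soma[2]),
                 medial_sign = 1L), class = "recording_session")
}

test_that("build_map conserves charge through 2x upsampling", {
  ch <- numeric(288); ch[100] <- 1
  map <- build_map(fake_responses(ch), fake_session_meta())
  expect_equal(dim(map$grid), c(48L, 24L))
  expect_equal(sum(map$grid), 1)
  expect_equal(sort(unique(as.vector(map$grid))), c(0, 0.25))
  expect_equal(sum(map$grid > 0), 4L)
  # non-significant spots carry zero
  ch2 <- rep(0.5, 288)
  map2 <- build_map(fake_responses(ch2, significant = rep(FALSE, 288)),
                    fake_session_meta())
  expect_equal(sum(map2$grid), 0)
  # total equals the sum of significant charges exactly
  set.seed(1)
  ch3 <- runif(288); sig <- runif(288) > 0.5
  map3 <- build_map(fake_responses(ch3, sig), fake_session_meta())
  expect_equal(sum(map3$grid), sum(ch3[sig]), tolerance = 1e-12)
  expect_error(build_map(fake_responses(ch3)[1:100, ], fake_session_meta()),
               "288")
})

test_that("normalize_map scales the peak to 1 and warns on empty maps", {
  ch <- numeric(288); ch[10] <- 4; ch[20] <- 2
  map <- build_map(fake_responses(ch), fake_session_meta())
  nm <- normalize_map(map)
  expect_equal(max(nm$grid), 1)
  expect_equal(sum(nm$grid > 0.49 & nm$grid < 0.51), 4L)  # ratios kept
  empty <- blank_map()
  expect_warning(normalize_map(empty), "all-zero")
  uni <- build_map(fake_responses(rep(1, 288)), fake_session_meta())
  expect_true(all(normalize_map(uni)$grid == 1))
})

test_that("align_and_average is an identity for one map and idempotent", {
  ch <- numeric(288); ch[150] <- 2; ch[40] <- 1
  map <- build_map(fake_responses(ch), fake_session_meta())
  avg <- align_and_average(list(map), mode = "pia")
  expect_equal(avg$grid, map$grid)
  avg2 <- align_and_average(list(avg), mode = "pia")
  expect_equal(avg2$grid, avg$grid)
})

test_that("identical maps at a known offset average onto one aligned map", {
  ch <- numeric(288); ch[100] <- 1
  a <- build_map(fake_responses(ch), fake_session_meta())
  # same cell recorded with the grid shifted 3 quadrants down and 2 right:
  # content and anchors both move, so alignment must undo the shift
  b_grid <- matrix(0, 48, 24)
  b_grid[4:48, 3:24] <- a$grid[1:45, 1:22]
  b <- input_map(b_grid, soma_anchor = a$soma_anchor + c(3, 2),
                 pia_row = a$pia_row + 3)
  avg <- align_and_average(list(a, b), mode = "pia")
  core <- avg$counts == 2
  expect_equal(sum(avg$grid[core]), 1, tolerance = 1e-12)
  expect_equal(max(avg$grid), 0.25)
  # averages of normalized maps never exceed 1
  set.seed(2)
  maps <- lapply(1:4, function(i) {
    m <- build_map(fake_responses(runif(288)), fake_session_meta())
    normalize_map(m)
  })
  expect_lte(max(align_and_average(maps, "soma")$grid), 1)
})

test_that("projections conserve total charge and locate deltas", {
  ch <- numeric(288); ch[(8L - 1L) * 12L + 5L] <- 2  # native row 8, col 5
  map <- build_map(fake_responses(ch), fake_session_meta())
  pv <- vertical_profile(map)
  ph <- horizontal_profile(map)
  expect_equal(sum(pv$values), sum(map$grid), tolerance = 1e-12)
  expect_equal(sum(ph$values), sum(map$grid), tolerance = 1e-12)
  expect_equal(sum(pv$values > 0), 2L)  # two quadrant rows
  uni <- build_map(fake_responses(rep(1, 288)), fake_session_meta())
  expect_equal(diff(range(vertical_profile(uni)$values)), 0)
})

test_that("peak locations land on the published micrometre lattice", {
  v <- numeric(48); v[9] <- 1  # 9th quadrant bin below the pia
  p <- toy_profile(v)
  pk <- peak_location(p)
  expect_equal(as.numeric(pk), 188)
  expect_equal(attr(pk, "raw_um"), 9 * 1000 / 48)
  # soma-axis zero at the soma bin
  v2 <- numeric(48); v2[24] <- 1
  p2 <- toy_profile(v2, axis = "depth-from-soma", soma_bin = 24)
  expect_equal(as.numeric(peak_location(p2)), 0)
  # ties break toward the anchor
  v3 <- numeric(48); v3[20] <- 1; v3[30] <- 1
  p3 <- toy_profile(v3, axis = "depth-from-soma", soma_bin = 24)
  expect_equal(attr(peak_location(p3), "raw_um"), (24 - 20) * 1000 / 48)
  expect_warning(pk0 <- peak_location(toy_profile(numeric(10))), "no peak")
  expect_true(is.na(pk0))
})

test_that("horizontal bias is signed by the medial convention", {
  v <- numeric(24); v[13] <- 1  # one quadrant medial of soma col 12
  p <- toy_profile(v, axis = "horizontal-from-soma", soma_bin = 12)
  expect_equal(as.numeric(horizontal_bias(p)), 21)
  v2 <- numeric(24); v2[9] <- 1  # three quadrants lateral
  p2 <- toy_profile(v2, axis = "horizontal-from-soma", soma_bin = 12)
  expect_equal(as.numeric(horizontal_bias(p2)), -63)
  # symmetric profile peaks at the soma
  v3 <- exp(-((1:24) - 12)^2 / 8)
  p3 <- toy_profile(v3, axis = "horizontal-from-soma", soma_bin = 12)
  expect_equal(as.numeric(horizontal_bias(p3)), 0)
})

test_that("soma-aligned outputs are equivariant to anchor shifts", {
  ch <- numeric(288); ch[140] <- 1; ch[60] <- 0.5
  base <- build_map(fake_responses(ch), fake_session_meta(c(24L, 12L)))
  shifted <- build_map(fake_responses(ch), fake_session_meta(c(27L, 12L)))
  pv1 <- vertical_profile(base, align = "soma")
  pv2 <- vertical_profile(shifted, align = "soma")
  expect_equal(pv2$position_um, pv1$position_um + 3 * 1000 / 48)
  expect_equal(pv2$values, pv1$values)
})
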