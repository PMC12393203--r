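test_that("the default-protocol GRE fixture has 256 phase-encode lines per slice", {
  doc <- make_gre_fixture(gre_params())
  expect_equal(sum(doc$blocks$adc > 0), 256L)
  # every readout is preceded by a phase-encode block carrying a gy trapezoid
  adc_blocks <- which(doc$blocks$adc > 0)
  expect_true(all(doc$blocks$gy[adc_blocks - 1L] > 0))
  pe_ids <- doc$blocks$gy[adc_blocks - 1L]
  areas <- vapply(pe_ids, function(id) {
    ev <- doc$gradients[[as.character(id)]]
    ev$amplitude * (ev$rise / 2 + ev$flat + ev$fall / 2)
  }, numeric(1))
  expect_equal(sort(areas), ((1:256) - 1 - 128) / 0.256, tolerance = 1e-9)
  expect_equal(validate_sequence(doc)$status, "ok")
})

test_that("per-channel slices carry packed pulses with only that channel active", {
  doc <- small_gre_doc(8, n_slices = 8, active = 1:8)
  rf_ids <- unique(doc$blocks$rf[doc$blocks$rf > 0])
  expect_length(rf_ids, 8L)
  for (s in 1:8) {
    rf <- unpack_ptx(seq_get_rf(doc, rf_ids[s]))
    expect_equal(rf$n_channels, 8L)
    nz <- which(vapply(rf$mag, function(m) any(m > 0), logical(1)))
    expect_equal(nz, s)
  }
})

test_that("a plain GRE fixture uses one-channel RF events", {
  doc <- small_gre_doc(8)
  rf <- seq_get_rf(doc, 1)
  expect_equal(rf$n_channels, 1L)
})

test_that("fixtures validate and round-trip deterministically", {
  d1 <- small_gre_doc(8, n_slices = 2, active = c(1, 2), n_channels = 2)
  d2 <- small_gre_doc(8, n_slices = 2, active = c(1, 2), n_channels = 2)
  expect_true(seq_equal(d1, d2))
  for (doc in list(d1, small_ktpoints(4, 4, seed = 3),
                   make_spiral_fixture())) {
    expect_true(validate_sequence(doc)$status %in% c("ok"))
    expect_true(seq_equal(doc, read_seq(write_seq(doc))))
  }
})

test_that("one CP-weighted subpulse is equivalent to a hard pulse on the CP-combined map", {
  g <- list(n = 24, fov = 0.256)
  maps <- synth_b1_maps(8, g, seed = 2)
  cp_w <- 120 * exp(2i * pi * (0:7) / 8)
  kp <- make_ktpoints_block(ktpoints_params(matrix(cp_w, 8, 1)))
  pg <- seq_to_pulse(kp)
  f_kt <- simulate_flip(pg$rf, pg$grads, maps, method = "full")

  cp_maps <- synth_b1_maps(1, g, uniform = TRUE)
  cp_maps$maps[, , 1] <- Reduce(`+`, lapply(1:8, function(c) exp(2i * pi * (c - 1) / 8) * maps$maps[, , c]))
  cp_maps$mask <- maps$mask
  hard <- multichannel_rf(list(rep(1, 100)), list(numeric(100)), amplitude = 120)
  f_hard <- simulate_flip(hard, NULL, cp_maps, method = "full")
  idx <- maps$mask & f_hard > 0.1
  expect_lt(max(abs(f_kt[idx] - f_hard[idx]) / f_hard[idx]), 0.002)
})

test_that("zero-blip subpulse trains merge into a single subpulse at k = 0", {
  g <- list(n = 24, fov = 0.256)
  maps <- synth_b1_maps(8, g, seed = 2)
  w <- matrix(complex(modulus = 25, argument = rep(-2 * pi * (0:7) / 8, 5)), 8, 5)
  kp5 <- make_ktpoints_block(ktpoints_params(w, blip_areas = matrix(0, 3, 4)))
  pg5 <- seq_to_pulse(kp5)
  f5 <- simulate_flip(pg5$rf, pg5$grads, maps, method = "small_tip")

  # merged equivalent: one subpulse 5x as long
  kp1 <- make_ktpoints_block(ktpoints_params(w[, 1, drop = FALSE], sub_dur = 5e-4))
  pg1 <- seq_to_pulse(kp1)
  f1 <- simulate_flip(pg1$rf, pg1$grads, maps, method = "small_tip")
  idx <- maps$mask & f1 > 0.05
  expect_lt(max(abs(f5[idx] - f1[idx]) / f1[idx]), 1e-6)
})

test_that("weights on channel 1 only excite in proportion to that channel's B1", {
  g <- list(n = 24, fov = 0.256)
  maps <- synth_b1_maps(8, g, seed = 2)
  w <- matrix(0i, 8, 1); w[1, 1] <- 150
  kp <- make_ktpoints_block(ktpoints_params(w))
  pg <- seq_to_pulse(kp)
  f <- simulate_flip(pg$rf, pg$grads, maps, method = "small_tip")
  idx <- maps$mask
  ref <- Mod(maps$maps[, , 1])
  expect_gt(stats::cor(f[idx], ref[idx]), 0.999999)
})

test_that("infeasible blips are rejected", {
  w <- matrix(complex(modulus = 10, argument = 0), 2, 2)
  expect_error(
    make_ktpoints_block(ktpoints_params(w, blip_areas = matrix(c(1e5, 0, 0), 3, 1),
                                        max_blip_dur = 2e-5)),
    "not realizable")
})

test_that("fixture generation rejects inconsistent parameters", {
  expect_error(gre_params(resolution = 3e-3), "integer matrix")
  expect_error(gre_params(te = 0.02, tr = 0.015), "smaller than tr")
  expect_error(gre_params(n_slices = 2, active_channel_per_slice = 1L), "one entry per slice")
})
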