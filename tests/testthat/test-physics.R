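test_that("synthetic B1 maps are deterministic and CP-combine center-bright", {
  g <- list(n = 32, fov = 0.256)
  a <- synth_b1_maps(8, g, seed = 4)
  b <- synth_b1_maps(8, g, seed = 4)
  expect_identical(a$maps, b$maps)
  expect_false(identical(a$maps, synth_b1_maps(8, g, seed = 5)$maps))

  # circularly polarized combination: maximum magnitude at the grid center
  cp <- Reduce(`+`, lapply(1:8, function(c) exp(2i * pi * (c - 1) / 8) * a$maps[, , c]))
  m <- Mod(cp)
  m[!a$mask] <- 0
  peak <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - (32 + 1) / 2) <= 1))

  u <- synth_b1_maps(1, g, uniform = TRUE)
  expect_true(all(u$maps == 1))
  expect_true(all(is.finite(Mod(a$maps[, , 1][a$mask]))))
})

test_that("zero RF produces zero flip everywhere", {
  maps <- synth_b1_maps(2, list(n = 16, fov = 0.2), seed = 1)
  rf <- multichannel_rf(list(numeric(10), numeric(10)),
                        list(numeric(10), numeric(10)), amplitude = 100)
  expect_true(all(simulate_flip(rf, NULL, maps) == 0))
})

test_that("a constant hard pulse matches the closed-form flip angle to 1e-9", {
  maps <- synth_b1_maps(1, list(n = 8, fov = 0.2), uniform = TRUE)
  for (amp in c(50, 250, 2500)) {
    rf <- multichannel_rf(list(rep(1, 100)), list(numeric(100)),
                          amplitude = amp, raster = 1e-6)
    fl <- simulate_flip(rf, NULL, maps, method = "full")
    expect_lt(max(abs(fl[maps$mask] - 360 * amp * 1e-4)), 1e-9)
  }
})

test_that("rotation integration conserves magnetization norm", {
  maps <- synth_b1_maps(4, list(n = 16, fov = 0.2), seed = 9)
  pg <- seq_to_pulse(small_ktpoints(4, 3, seed = 2, scale = 300))
  fl <- simulate_flip(pg$rf, pg$grads, maps, method = "full")
  mxy <- attr(fl, "mxy")
  # |Mxy| must equal sin(alpha) exactly when |M| = 1
  err <- abs(Mod(mxy[maps$mask]) - sin(fl[maps$mask] * pi / 180))
  expect_lt(max(err), 1e-9)
})

test_that("full Bloch and small-tip model agree within 2% below 10 degrees", {
  maps <- synth_b1_maps(8, list(n = 24, fov = 0.256), seed = 6)
  for (seed in c(13, 17)) {
    pg <- seq_to_pulse(small_ktpoints(8, 3, seed = seed))
    f_full <- simulate_flip(pg$rf, pg$grads, maps, method = "full")
    f_sta <- simulate_flip(pg$rf, pg$grads, maps, method = "small_tip")
    expect_lt(max(f_full), 10.5)
    idx <- maps$mask & f_full > 0.05 * max(f_full)
    expect_lt(max(abs(f_full[idx] - f_sta[idx]) / f_full[idx]), 0.02)
  }
})

test_that("small-tip linearity: CP-combined pulse equals single-channel pulse on CP map", {
  g <- list(n = 24, fov = 0.256)
  maps <- synth_b1_maps(8, g, seed = 3)
  n <- 100
  cp_w <- exp(2i * pi * (0:7) / 8)
  rf_cp <- multichannel_rf(mag = replicate(8, rep(1, n), simplify = FALSE),
                           phase = lapply(1:8, function(c) rep(Arg(cp_w[c]), n)),
                           amplitude = 100, raster = 1e-6)
  f_cp <- simulate_flip(rf_cp, NULL, maps, method = "full")

  cp_maps <- synth_b1_maps(1, g, uniform = TRUE)
  cp_maps$maps[, , 1] <- Reduce(`+`, lapply(1:8, function(c) cp_w[c] * maps$maps[, , c]))
  cp_maps$mask <- maps$mask
  rf1 <- multichannel_rf(list(rep(1, n)), list(numeric(n)), amplitude = 100)
  f_1 <- simulate_flip(rf1, NULL, cp_maps, method = "full")
  idx <- maps$mask & f_cp > 0.1
  expect_lt(max(abs(f_cp[idx] - f_1[idx]) / f_cp[idx]), 0.002)
})

test_that("k-space trajectories match closed forms", {
  gt0 <- grad_timeline(gx = numeric(50), dt = 1e-5)
  expect_true(all(as.matrix(compute_ktrajectory(gt0)[, 2:4]) == 0))

  gt <- grad_timeline(gx = rep(2e4, 120), dt = 1e-5)
  tr <- compute_ktrajectory(gt)
  expect_identical(tr$kx[1], 0)
  expect_equal(tr$kx[121], 2e4 * 120e-5, tolerance = 1e-12)
  expect_equal(tr$t[121], 1.2e-3)

  # balanced bipolar train returns to k = 0 exactly
  bal <- grad_timeline(gx = rep(c(rep(3e4, 10), rep(-3e4, 10)), 8), dt = 1e-5)
  trb <- compute_ktrajectory(bal)
  expect_equal(tail(trb$kx, 1), 0, tolerance = 1e-9)

  # trapezoid at cell centers integrates exactly (cell averages)
  rise <- 1e-4; flat <- 5e-4; fall <- 1e-4; amp <- 5e5
  tc <- (seq_len(70) - 0.5) * 1e-5
  w <- amp * pmin(pmax(tc / rise, 0), 1) * pmin(pmax((rise + flat + fall - tc) / fall, 0), 1)
  trt <- compute_ktrajectory(grad_timeline(gx = w, dt = 1e-5))
  expect_equal(tail(trt$kx, 1), amp * (rise / 2 + flat + fall / 2), tolerance = 1e-9)
})

test_that("the spiral fixture reaches the analytic endpoint within 1% and grows monotonically", {
  sg <- spiral_gradients(kmax = 200, turns = 6, dur = 8e-3, dt = 1e-5)
  tr <- compute_ktrajectory(sg)
  ke <- attr(sg, "k_end")
  err <- sqrt((tail(tr$kx, 1) - ke[1])^2 + (tail(tr$ky, 1) - ke[2])^2) / 200
  expect_lt(err, 0.01)
  rad <- sqrt(tr$kx^2 + tr$ky^2)
  expect_true(all(diff(rad) > -1e-9))
})

test_that("power reports match closed forms and tile into the energy", {
  cal <- 1e-3
  rf <- multichannel_rf(mag = list(rep(1, 500), numeric(500)),
                        phase = list(numeric(500), numeric(500)),
                        amplitude = 200, raster = 1e-6)
  pr <- power_report(rf, limits = list(peak = 30, avg = 50), window = 1e-4,
                     cal = cal)
  expect_equal(pr$table$energy[1], cal * 200^2 * 5e-4)
  expect_equal(pr$table$peak[1], cal * 200^2)
  expect_identical(pr$table$energy[2], 0)
  expect_true(pr$table$pass[2])   # zero-waveform channel passes
  expect_false(pr$table$pass[1])  # peak 40 exceeds the 30 W limit
  # energy equals the sum of window averages times window length
  expect_lt(abs(sum(pr$windows[, 1] * 1e-4) - pr$table$energy[1]),
            1e-9 * pr$table$energy[1])
})

test_that("per-channel activation shows up only in the active channel's power windows", {
  doc <- small_gre_doc(8, n_slices = 4, active = c(2, 4, 1, 3), n_channels = 4)
  slice_dur <- seq_duration(doc) / 4
  pr <- power_report(doc, window = slice_dur)
  expect_equal(nrow(pr$windows), 4L)
  active <- apply(pr$windows, 1, which.max)
  expect_equal(active, c(2L, 4L, 1L, 3L))
  for (w in 1:4) {
    expect_true(all(pr$windows[w, -active[w]] == 0))
    expect_gt(pr$windows[w, active[w]], 0)
  }
})
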