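test_that("channel reordering is a group action", {
  set.seed(4)
  rf <- random_ptx_pulse(8)
  expect_identical(reorder_channels(rf, 1:8), rf)
  perm <- sample(8)
  back <- reorder_channels(reorder_channels(rf, perm), order(perm))
  expect_identical(back, rf)
  expect_identical(reorder_channels(rf, perm)$mag[[3]], rf$mag[[perm[3]]])
  expect_error(reorder_channels(rf, 1:7), "permutation")
})

test_that("conversion specs validate their gradient transform", {
  expect_error(conversion_spec(gradient_transform = matrix(1, 3, 3)),
               "signed permutation")
  expect_error(conversion_spec(gradient_transform = diag(c(2, 1, 1))),
               "signed permutation")
  expect_error(conversion_spec(channel_permutation = c(1, 1, 2)), "permutation")
  spec <- conversion_spec(b0_flip = TRUE)
  expect_true(spec$rf_conjugate)
  expect_equal(spec$gradient_transform, diag(c(1, 1, -1)))
  inv <- invert_conversion_spec(spec)
  expect_equal(inv$gradient_transform, spec$gradient_transform)  # involutive
})

test_that("B0 conversion preserves magnitudes, energy and duration", {
  set.seed(10)
  rf <- random_ptx_pulse(8, len = 48)
  gt <- grad_timeline(gx = rnorm(30, sd = 1e4), gy = rnorm(30, sd = 1e4),
                      gz = rnorm(30, sd = 1e4), dt = 1e-5)
  conv <- convert_b0_direction(rf, gt, conversion_spec(b0_flip = TRUE))
  expect_identical(conv$rf$mag, rf$mag)
  expect_identical(ptx_duration(conv$rf), ptx_duration(rf))
  # gradient vector norm preserved at every time point
  expect_equal(colSums(conv$grads$g^2), colSums(gt$g^2))
  # energy: sum of |amp * mag|^2 over samples unchanged
  pr0 <- power_report(rf)
  pr1 <- power_report(conv$rf)
  expect_equal(pr1$table$energy, pr0$table$energy)
})

test_that("an all-zero-phase pulse is unchanged by conjugation and double conversion is bit-exact", {
  rf <- multichannel_rf(list(runif(20), runif(20)),
                        list(numeric(20), numeric(20)), amplitude = 100)
  gt <- grad_timeline(gx = rnorm(10, sd = 1e4), dt = 1e-5)
  spec <- conversion_spec(b0_flip = TRUE)
  once <- convert_b0_direction(rf, gt, spec)
  expect_identical(once$rf$phase, lapply(rf$phase, function(p) -p))
  expect_true(all(unlist(once$rf$phase) == 0))

  set.seed(2)
  rf2 <- random_ptx_pulse(4)
  twice <- convert_b0_direction(rf2, gt, spec)
  twice <- convert_b0_direction(twice$rf, twice$grads, spec)
  expect_identical(twice$rf, rf2)
  expect_identical(twice$grads$g, gt$g)
})

test_that("the converted pulse under reversed B0 reproduces the flip-angle map", {
  maps <- synth_b1_maps(8, grid = list(n = 24, fov = 0.256), seed = 3,
                        symmetric = TRUE)
  kp <- small_ktpoints(8, 3, seed = 13)
  pg <- seq_to_pulse(kp)
  f_orig <- simulate_flip(pg$rf, pg$grads, maps, method = "full")

  conv <- convert_b0_direction(pg$rf, pg$grads, conversion_spec(b0_flip = TRUE))
  maps_rev <- maps
  maps_rev$b0_sign <- -1L
  f_conv <- simulate_flip(conv$rf, conv$grads, maps_rev, method = "full")

  idx <- maps$mask & f_orig > 1e-3
  expect_lt(max(abs(f_conv[idx] - f_orig[idx]) / f_orig[idx]), 1e-6)
})

test_that("whole-sequence conversion round-trips through inverse specs", {
  doc <- small_gre_doc(8, n_slices = 2, active = c(1, 3), n_channels = 4)
  spec <- conversion_spec(channel_permutation = c(2, 1, 4, 3),
                          gradient_transform = diag(c(1, 1, -1)),
                          rf_conjugate = TRUE, b0_flip = TRUE)
  conv <- convert_seq(doc, spec)
  expect_false(seq_equal(doc, conv))
  back <- convert_seq(conv, invert_conversion_spec(spec))
  expect_true(seq_equal(doc, back, tol = 1e-7))
})

test_that("regridding preserves constants exactly and trapezoid areas to 1e-4", {
  # duration divisible by both rasters: a constant stays constant
  const <- rep(0.7, 32)  # 320 us = 50 cells of 6.4 us
  out <- regrid_waveform(const, 1e-5, 6.4e-6)
  expect_true(all(out == 0.7))
  expect_length(out, 50L)
  expect_equal(attr(out, "remainder"), 0)

  # with a sub-raster remainder, the straddling cell is averaged so the
  # area is still exact
  const2 <- rep(0.7, 50)  # 500 us -> 78.125 cells
  out2 <- regrid_waveform(const2, 1e-5, 6.4e-6)
  expect_equal(sum(out2) * 6.4e-6, sum(const2) * 1e-5, tolerance = 1e-12)
  expect_true(all(out2[-length(out2)] == 0.7))

  # 10 us-sampled trapezoid onto the 6.4 us grid: analytic area oracle
  rise <- 1.6e-4; flat <- 2.24e-3; fall <- 1.6e-4; amp <- 8e5
  nt <- round((rise + flat + fall) / 1e-5)
  tc <- (seq_len(nt) - 0.5) * 1e-5
  w10 <- amp * pmin(pmax(tc / rise, 0), 1) * pmin(pmax((rise + flat + fall - tc) / fall, 0), 1)
  w64 <- regrid_waveform(w10, 1e-5, 6.4e-6)
  area_true <- amp * (rise / 2 + flat + fall / 2)
  expect_lt(abs(sum(w64) * 6.4e-6 - area_true) / area_true, 1e-4)
  expect_identical(w64[1], w10[1])
  expect_identical(w64[length(w64)], w10[length(w10)])
  expect_equal(attr(w64, "remainder"), 0)

  expect_identical(regrid_waveform(w10, 1e-5, 1e-5), w10)
  expect_error(regrid_waveform(c(1, Inf), 1e-5, 6.4e-6), "finite")
})

test_that("validation rejects over-limit sequences with the specific violation", {
  hw <- hardware_profile()
  doc <- small_gre_doc(8)
  expect_equal(validate_sequence(doc, hw)$status, "ok")

  # push the readout gradient over the amplitude limit
  bad <- doc
  bad$gradients[["1"]]$amplitude <- 2 * hw$max_gradient
  val <- validate_sequence(bad, hw)
  expect_equal(val$status, "rejected")
  expect_true("gradient_amplitude" %in% val$violations$check)

  # instantaneous rise: slew violation
  bad2 <- doc
  bad2$gradients[["2"]]$rise <- 1e-6
  val2 <- validate_sequence(bad2, hw)
  expect_true("slew_rate" %in% val2$violations$check)

  # ADC beyond the bandwidth limit
  bad3 <- doc
  bad3$adc[["1"]]$dwell <- 1e-7
  val3 <- validate_sequence(bad3, hw)
  expect_true("adc_bandwidth" %in% val3$violations$check)

  empty <- new_seq()
  expect_equal(validate_sequence(empty, hw)$status, "ok")
})

test_that("validation equals a brute-force per-sample limit check", {
  hw <- hardware_profile(max_gradient = 9e5, max_slew = 5e9)
  for (doc in list(small_gre_doc(8), small_ktpoints(4, 3, seed = 5))) {
    gt <- seq_gradients(doc)
    brute_amp <- max(abs(gt$g))
    brute_slew <- max(abs(t(diff(t(cbind(0, gt$g)))))) / gt$dt
    brute_ok <- brute_amp <= hw$max_gradient && brute_slew <= hw$max_slew
    val <- validate_sequence(doc, hw)
    expect_equal(val$status == "ok", brute_ok)
  }
})

test_that("a 10 us arbitrary gradient flags regrid on 6.4 us hardware and passes after regridding", {
  hw64 <- hardware_profile(gradient_raster = 6.4e-6, name = "philips")
  doc <- make_spiral_fixture()
  val <- validate_sequence(doc, hw64)
  expect_equal(val$status, "needs_regrid")
  expect_true("raster_alignment" %in% val$violations$check)

  # regrid every arbitrary gradient onto the hardware grid and recheck
  doc64 <- new_seq(name = "spiral64", grad_raster = 6.4e-6)
  for (ax in c("gx", "gy")) {
    id <- doc$blocks[[ax]][2]
    ev <- doc$gradients[[as.character(id)]]
    w <- ev$amplitude * decompress_shape(doc$shapes[[as.character(ev$shape_id)]])
    w2 <- regrid_waveform(w, 1e-5, 6.4e-6)
    amp <- max(abs(w2))
    r <- ptxseq:::add_shape(doc64, as.numeric(w2) / amp); doc64 <- r$doc
    r2 <- ptxseq:::add_event(doc64, "gradients",
                             ptxseq:::grad_event(amplitude = amp, shape_id = r$id,
                                                 first = w2[1], last = w2[length(w2)]))
    doc64 <- r2$doc
    doc64 <- ptxseq:::add_block(doc64, length(w2) * 6.4e-6,
                                gx = if (ax == "gx") r2$id else 0L,
                                gy = if (ax == "gy") r2$id else 0L)
  }
  expect_equal(validate_sequence(doc64, hw64)$status, "ok")
})

test_that("receive windows coalesce across consecutive ADC blocks", {
  mk <- function(pattern) {
    doc <- small_gre_doc(8)  # provides event ids 1 (adc) and rf 1
    rows <- lapply(pattern, function(p) {
      switch(p,
             rf = data.frame(dur = 1e-3, rf = 1L, gx = 0L, gy = 0L, gz = 0L, adc = 0L, ext = 0L),
             adc = data.frame(dur = 3e-3, rf = 0L, gx = 0L, gy = 0L, gz = 0L, adc = 1L, ext = 0L),
             gap = data.frame(dur = 1e-3, rf = 0L, gx = 0L, gy = 0L, gz = 0L, adc = 0L, ext = 0L))
    })
    doc$blocks <- do.call(rbind, rows)
    doc
  }
  # EPI-like train: one excitation, 64 consecutive readout blocks
  epi <- mk(c("rf", rep("adc", 64)))
  sw <- count_hw_switches(epi)
  expect_equal(sw$rx_switches, 1L)
  expect_equal(sw$rx_raw, 64L)
  expect_equal(sw$coalesced_blocks, 63L)

  single <- mk(c("rf", "adc"))
  expect_equal(count_hw_switches(single)$rx_switches, 1L)

  # strictly alternating transmit/receive: no coalescing possible
  alt <- mk(rep(c("rf", "adc"), 16))
  expect_equal(count_hw_switches(alt)$rx_switches, 16L)
  expect_equal(count_hw_switches(alt)$tx_switches, 16L)

  # neutral gradient gaps inside a readout train do not break the window
  gappy <- mk(c("rf", "adc", "gap", "adc", "gap", "adc"))
  expect_equal(count_hw_switches(gappy)$rx_switches, 1L)
})

test_that("excitation blocks merge into a template without touching readouts", {
  tpl <- make_mprage_template(n_lines = 8)
  kp <- small_ktpoints(8, 3, seed = 7)
  merged <- merge_excitation(tpl, kp, at = list(use = "e"))
  expect_equal(sum(merged$blocks$adc > 0), sum(tpl$blocks$adc > 0))
  n_exc <- sum(vapply(seq_len(nrow(tpl$blocks)), function(i) {
    rid <- tpl$blocks$rf[i]
    rid > 0 && tpl$rf[[as.character(rid)]]$use == "e"
  }, logical(1)))
  expect_equal(nrow(merged$blocks),
               nrow(tpl$blocks) + n_exc * (nrow(kp$blocks) - 1L))
  expect_equal(validate_sequence(merged)$status, "ok")
  expect_true(seq_equal(merged, read_seq(write_seq(merged))))

  # replacing a block with itself is the identity
  frag <- tpl
  frag$blocks <- tpl$blocks[3, , drop = FALSE]
  expect_true(seq_equal(merge_excitation(tpl, frag, at = "block=3"), tpl))

  expect_error(merge_excitation(tpl, kp, at = list(use = "z")), "matched no blocks")
  hw_strict <- hardware_profile(max_gradient = 1)
  expect_error(merge_excitation(tpl, kp, at = list(use = "e"), hw = hw_strict),
               "violates")
})
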