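test_that("a single-active-channel pulse packs into one event with repeated time ranges", {
  # 8-channel head-coil case: channel 1 carries a sinc, channels 2-8 are
  # zero magnitude over the same time range
  n <- 128
  tt <- seq(-3, 3, length.out = n)
  sinc <- abs(sin(pi * tt) / (pi * tt))
  sinc[!is.finite(sinc)] <- 1
  mag <- c(list(sinc), replicate(7, numeric(n), simplify = FALSE))
  phase <- replicate(8, numeric(n), simplify = FALSE)
  rf <- multichannel_rf(mag, phase, amplitude = 500)

  packed <- pack_ptx(rf)
  expect_length(packed$mag, 8 * n)
  expect_identical(packed$mag[1:n], sinc)
  expect_true(all(packed$mag[-(1:n)] == 0))
  expect_identical(packed$time, rep(as.numeric(1:n), 8))
  expect_equal(infer_channel_count(packed$time), 8L)
  expect_equal(sum(diff(packed$time) <= 0) + 1L, 8L)

  back <- unpack_ptx(packed)
  expect_equal(back$n_channels, 8L)
  expect_identical(back$mag[[1]], sinc)
})

test_that("a packed one-channel pulse is byte-identical to the plain encoding", {
  set.seed(5)
  n <- 64
  mag <- runif(n)
  phase <- runif(n, 0, 2 * pi)

  rf <- multichannel_rf(list(mag), list(phase), amplitude = 300)
  doc_packed <- new_seq(name = "x")
  r <- seq_add_rf(doc_packed, pack_ptx(rf))
  doc_packed <- r$doc
  doc_packed <- ptxseq:::add_block(doc_packed, 1e-4, rf = r$id)

  # plain encoding built directly from the event tables
  doc_plain <- new_seq(name = "x")
  s1 <- ptxseq:::add_shape(doc_plain, mag); doc_plain <- s1$doc
  s2 <- ptxseq:::add_shape(doc_plain, (phase / (2 * pi)) %% 1); doc_plain <- s2$doc
  s3 <- ptxseq:::add_shape(doc_plain, as.numeric(1:n)); doc_plain <- s3$doc
  r2 <- ptxseq:::add_event(doc_plain, "rf",
                           ptxseq:::rf_event(amplitude = 300, mag_id = s1$id,
                                             phase_id = s2$id, time_id = s3$id,
                                             center = n * 1e-6 / 2, use = "e"))
  doc_plain <- r2$doc
  doc_plain <- ptxseq:::add_block(doc_plain, 1e-4, rf = r2$id)

  expect_identical(write_seq(doc_packed, sign = FALSE),
                   write_seq(doc_plain, sign = FALSE))
})

test_that("pack/unpack is the identity for randomized 1-16 channel pulses", {
  set.seed(21)
  for (C in sample(1:16, 8)) {
    rf <- random_ptx_pulse(C, len = sample(8:64, 1))
    back <- unpack_ptx(pack_ptx(rf))
    expect_identical(back$mag, rf$mag)
    expect_identical(back$phase, rf$phase)
    expect_identical(back$time, lapply(rf$time, as.numeric))
    expect_identical(back$amplitude, rf$amplitude)
    # and packing again reproduces the packed form
    expect_identical(pack_ptx(back)$mag, pack_ptx(rf)$mag)
  }
})

test_that("packing preserves the pulse duration", {
  set.seed(8)
  for (C in c(1, 3, 8)) {
    rf <- random_ptx_pulse(C, len = 40)
    expect_identical(ptx_duration(pack_ptx(rf)), ptx_duration(rf))
    expect_identical(ptx_duration(rf), 40 * rf$raster)
  }
})

test_that("channel count inference follows the non-increase rule", {
  expect_equal(infer_channel_count(c(0, 1, 2, 3)), 1L)
  expect_equal(infer_channel_count(c(0, 1, 2, 0, 1, 2)), 2L)
  expect_equal(infer_channel_count(5), 1L)
  # ranges starting at a nonzero offset
  expect_equal(infer_channel_count(c(10, 11, 12, 10, 11, 12, 10, 11, 12)), 3L)
  expect_error(infer_channel_count(numeric(0)), "empty")
})

test_that("a strictly increasing time shape decodes as one channel", {
  packed <- structure(list(n_channels = 1L, raster = 1e-6, amplitude = 100,
                           delay = 0, freq_offset = 0, phase_offset = 0,
                           mag = runif(10), phase = numeric(10),
                           time = as.numeric(1:10)),
                      class = "ptx_packed")
  rf <- unpack_ptx(packed)
  expect_equal(rf$n_channels, 1L)
  expect_identical(rf$mag[[1]], packed$mag)
})

test_that("pad_channels aligns final time points and is idempotent", {
  rf <- multichannel_rf(mag = list(runif(100), runif(80)),
                        phase = list(numeric(100), numeric(80)),
                        time = list(1:100, 1:80), amplitude = 100)
  expect_error(pack_ptx(rf), "pad_channels")

  padded <- pad_channels(rf)
  expect_equal(ptxseq:::rf_final_times(padded), c(100, 100))
  expect_length(padded$mag[[2]], 81)
  expect_identical(padded$mag[[2]][81], 0)
  expect_identical(padded$time[[2]][81], 100)
  expect_identical(pad_channels(padded), padded)

  # already aligned and single channel: unchanged
  aligned <- random_ptx_pulse(2, len = 16)
  expect_identical(pad_channels(aligned), aligned)
  single <- random_ptx_pulse(1, len = 16)
  expect_identical(pad_channels(single), single)

  # round-trip through pack/unpack preserves the padded structure
  back <- unpack_ptx(pack_ptx(padded))
  expect_identical(back$time, lapply(padded$time, as.numeric))
})

test_that("unpacking rejects segments ending at different time points", {
  packed <- structure(list(n_channels = 2L, raster = 1e-6, amplitude = 100,
                           delay = 0, freq_offset = 0, phase_offset = 0,
                           mag = runif(8), phase = numeric(8),
                           time = c(1, 2, 3, 4, 1, 2, 3, 5)),
                      class = "ptx_packed")
  expect_error(unpack_ptx(packed), "different time points")
})
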