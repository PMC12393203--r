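# Shared fixtures and independent oracles.

# Naive sample-by-sample decoder for the derivative run-length shape payload,
# kept deliberately simple and separate from the package implementation: walk
# the payload, emit literals, and treat the value after two equal literals as
# an extra repetition count; then accumulate the derivative.
naive_decode <- function(payload, num_samples) {
  if (length(payload) == num_samples) return(payload)
  deriv <- numeric(0)
  i <- 1L
  last_literal <- NA_real_
  expect_count <- FALSE
  while (i <= length(payload)) {
    v <- payload[i]
    if (expect_count) {
      deriv <- c(deriv, rep(last_literal, v))
      expect_count <- FALSE
      last_literal <- NA_real_
    } else {
      deriv <- c(deriv, v)
      if (!is.na(last_literal) && v == last_literal) {
        expect_count <- TRUE
      } else {
        last_literal <- v
      }
    }
    i <- i + 1L
  }
  out <- numeric(length(deriv))
  acc <- 0
  for (j in seq_along(deriv)) {
    acc <- acc + deriv[j]
    out[j] <- acc
  }
  out
}

random_shape_samples <- function(n, kind = c("mixed", "constant", "ramp", "noise")) {
  kind <- match.arg(kind)
  switch(kind,
         constant = rep(stats::runif(1), n),
         ramp = seq(0, stats::runif(1), length.out = n),
         noise = stats::runif(n),
         mixed = {
           base <- seq(0, stats::runif(1), length.out = n)
           flat <- rep(stats::runif(1), n)
           pick <- stats::runif(1)
           if (pick < 0.4) base
           else if (pick < 0.7) flat
           else pmin(1, pmax(0, base + 0.05 * stats::rnorm(n)))
         })
}

random_ptx_pulse <- function(n_channels, len = 32, raster = 1e-6) {
  mag <- lapply(seq_len(n_channels), function(c) stats::runif(len))
  phase <- lapply(seq_len(n_channels), function(c) stats::runif(len, 0, 2 * pi))
  multichannel_rf(mag, phase, amplitude = stats::runif(1, 100, 1000),
                  raster = raster)
}

small_gre_doc <- function(n = 16, n_slices = 1, active = NULL, n_channels = 8) {
  make_gre_fixture(gre_params(resolution = 0.256 / n, te = 3e-3, tr = 8e-3,
                              n_slices = n_slices,
                              active_channel_per_slice = active,
                              n_channels = n_channels))
}

small_ktpoints <- function(n_channels = 8, n_sub = 3, seed = 11, scale = 40) {
  set.seed(seed)
  w <- matrix(complex(modulus = stats::runif(n_channels * n_sub, 0.3, 1) * scale,
                      argument = stats::runif(n_channels * n_sub, -pi, pi)),
              n_channels, n_sub)
  areas <- matrix(stats::runif(3 * (n_sub - 1), -15, 15), 3, n_sub - 1)
  make_ktpoints_block(ktpoints_params(w, blip_areas = areas))
}
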