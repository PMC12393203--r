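## Multi-channel Bloch / small-tip physics on a 2D central-plane grid.
##
## Conventions: RF amplitudes are gamma*B1 in Hz, gradients gamma*G in Hz/m,
## so the gyromagnetic ratio is already folded into the sequence units; the
## proton value is exposed for converting T/m inputs. The rotating-frame
## field at voxel r is
##   omega_xy = 2*pi * sum_c S_c(r) b_c(t),   omega_z = s * 2*pi * G(t).r
## where S_c is the channel sensitivity and s the B0 sign. For a reversed
## main field (s = -1) the effective sensitivities are the conjugates of the
## stored B1+ maps, the Bloch-level statement of the transverse-plane mirror
## symmetry assumed of the coil (see the vignette for the derivation).

#' Proton gyromagnetic ratio (Hz/T)
#' @export
GAMMA_PROTON <- 42.577478518e6

#' Synthetic multi-channel B1+ transmit sensitivity maps
#'
#' Emulates a multi-channel head coil on a 2D grid through the magnet
#' isocenter: each channel has a smooth magnitude lobe centered on the coil
#' ring, rotated azimuthally by `2*pi/n_channels` per channel, a constant
#' channel phase of `-2*pi*(c-1)/n_channels` (so the circularly polarized
#' combination adds coherently at the center) and a mild linear phase ramp
#' along the channel direction. With `symmetric = TRUE` the set represents
#' the central plane of a coil whose 3D profile is mirror-symmetric across
#' the transverse plane (magnitude even, phase odd in z), the regime in which
#' the reversed-B0 sensitivities are exactly the conjugate maps;
#' `symmetric = FALSE` adds random smooth asymmetry and per-channel phase
#' offsets that break that symmetry. Deterministic given the seed.
#'
#' @param n_channels Number of transmit channels.
#' @param grid List with `n` (grid size) and `fov` (meters); default 64 over
#'   0.256 m.
#' @param seed Integer seed for the reproducible jitter.
#' @param symmetric Enforce the transverse mirror symmetry exactly.
#' @param uniform All-ones maps (single-channel birdcage idealization).
#' @return A `b1_maps` object: coordinate vectors `x`, `y` (m), complex array
#'   `maps[n, n, n_channels]`, logical `mask`, and `b0_sign` (+1).
#' @export
synth_b1_maps <- function(n_channels, grid = list(n = 64, fov = 0.256),
                          seed = 1, symmetric = TRUE, uniform = FALSE) {
  stopifnot(n_channels >= 1)
  n <- grid$n
  fov <- grid$fov
  x <- (seq_len(n) - (n + 1) / 2) * (fov / n)
  y <- x
  X <- matrix(x, n, n)
  Y <- matrix(y, n, n, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  mask <- R <= 0.43 * fov
  maps <- array(complex(real = 0), dim = c(n, n, n_channels))
  if (uniform) {
    maps[] <- 1
    mask[] <- TRUE  # idealized birdcage: valid everywhere
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    rcoil <- 0.42 * fov
    sigma <- 0.40 * fov
    amp_jit <- 1 + 0.05 * (stats::runif(n_channels) - 0.5)
    ramp_jit <- 1 + 0.1 * (stats::runif(n_channels) - 0.5)
    phase_jit <- if (symmetric) rep(0, n_channels) else stats::runif(n_channels, -0.5, 0.5)
    for (c in seq_len(n_channels)) {
      th <- 2 * pi * (c - 1) / n_channels
      cx <- rcoil * cos(th)
      cy <- rcoil * sin(th)
      magc <- amp_jit[c] * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2))
      ph <- -th + (pi / fov) * ramp_jit[c] * (X * cos(th) + Y * sin(th)) + phase_jit[c]
      if (!symmetric) {
        bump <- 0.15 * exp(-((X - cx / 3)^2 + (Y + cy / 4)^2) / (2 * (0.2 * fov)^2))
        ph <- ph + bump * sin(c)
      }
      maps[, , c] <- magc * exp(1i * ph)
    }
  }
  structure(list(n_channels = n_channels, n = n, fov = fov, x = x, y = y,
                 maps = maps, mask = mask, b0_sign = 1L,
                 symmetric = isTRUE(symmetric)),
            class = "b1_maps")
}

#' @export
print.b1_maps <- function(x, ...) {
  cat(sprintf("<b1_maps> %d channel(s) on %dx%d grid, FOV %.3g m, B0 sign %+d\n",
              x$n_channels, x$n, x$n, x$fov, x$b0_sign))
  invisible(x)
}

#' @export
plot.b1_maps <- function(x, channel = 1, what = c("mag", "phase"), ...) {
  what <- match.arg(what)
  z <- if (what == "mag") Mod(x$maps[, , channel]) else Arg(x$maps[, , channel])
  graphics::image(x$x, x$y, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("channel %d %s", channel, what), ...)
  invisible(x)
}

## ---- gradient timelines -----------------------------------------------

#' Gradient timeline: sampled three-axis waveform
#'
#' Center-sampled waveforms (sample `i` at `(i - 1/2) * dt`) for the three
#' gradient axes, in Hz/m. Shorter axes are zero-padded to the longest.
#'
#' @param gx,gy,gz Numeric sample vectors (Hz/m).
#' @param dt Raster time (s).
#' @export
grad_timeline <- function(gx = numeric(0), gy = numeric(0), gz = numeric(0),
                          dt = 1e-5) {
  n <- max(length(gx), length(gy), length(gz))
  pad <- function(v) c(v, numeric(n - length(v)))
  structure(list(dt = dt, g = rbind(gx = pad(gx), gy = pad(gy), gz = pad(gz))),
            class = "grad_timeline")
}

#' @export
print.grad_timeline <- function(x, ...) {
  cat(sprintf("<grad_timeline> %d samples at %.3g us (%.4g ms), max |G| %.4g Hz/m\n",
              ncol(x$g), x$dt * 1e6, ncol(x$g) * x$dt * 1e3,
              if (ncol(x$g) > 0) max(abs(x$g)) else 0))
  invisible(x)
}

# sample one gradient event onto raster-center cells of a block
grad_event_samples <- function(doc, ev, nsamp, raster) {
  wave <- numeric(nsamp)
  tc <- (seq_len(nsamp) - 0.5) * raster
  if (ev$kind == "trap") {
    t <- tc - ev$delay
    up <- if (ev$rise > 0) pmin(pmax(t / ev$rise, 0), 1) else as.numeric(t >= 0)
    dn <- if (ev$fall > 0) pmin(pmax((ev$rise + ev$flat + ev$fall - t) / ev$fall, 0), 1) else as.numeric(t <= ev$rise + ev$flat)
    wave <- ev$amplitude * pmin(up, dn)
    wave[t < 0 | t > ev$rise + ev$flat + ev$fall] <- 0
  } else {
    samples <- decompress_shape(doc$shapes[[as.character(ev$shape_id)]])
    if (ev$time_id > 0) {
      tk <- decompress_shape(doc$shapes[[as.character(ev$time_id)]]) * raster
      inside <- tc >= ev$delay + tk[1] & tc <= ev$delay + tk[length(tk)]
      wave[inside] <- stats::approx(ev$delay + tk, ev$amplitude * samples,
                                    xout = tc[inside])$y
    } else {
      i0 <- round(ev$delay / raster)
      idx <- seq_along(samples) + i0
      keep <- idx >= 1 & idx <= nsamp
      wave[idx[keep]] <- ev$amplitude * samples[keep]
    }
  }
  wave
}

#' Expand the gradient events of a sequence into a sampled timeline
#'
#' @param doc A `pulseq_seq`.
#' @param blocks Optional block indices (default: all blocks, concatenated).
#' @return A `grad_timeline` on the sequence's gradient raster.
#' @export
seq_gradients <- function(doc, blocks = NULL) {
  rasters <- seq_rasters(doc)
  if (is.null(blocks)) blocks <- seq_len(nrow(doc$blocks))
  per_axis <- list(gx = list(), gy = list(), gz = list())
  for (i in blocks) {
    b <- doc$blocks[i, ]
    nsamp <- round(b$dur / rasters$grad)
    for (col in c("gx", "gy", "gz")) {
      if (b[[col]] > 0) {
        ev <- doc$gradients[[as.character(b[[col]])]]
        per_axis[[col]][[length(per_axis[[col]]) + 1L]] <-
          grad_event_samples(doc, ev, nsamp, rasters$grad)
      } else {
        per_axis[[col]][[length(per_axis[[col]]) + 1L]] <- numeric(nsamp)
      }
    }
  }
  grad_timeline(gx = unlist(per_axis$gx), gy = unlist(per_axis$gy),
                gz = unlist(per_axis$gz), dt = rasters$grad)
}

#' k-space trajectory of a gradient timeline
#'
#' Running integral of the gradient waveform. Because the samples are cell
#' centers (cell averages for piecewise-linear waveforms), the cumulative
#' rectangle sum at the cell boundaries is exact for trapezoids. Gradients in
#' Hz/m integrate directly to 1/m; the gyromagnetic ratio is already folded
#' into the units.
#'
#' @param grads A `grad_timeline`.
#' @return A `k_trajectory` data frame with columns `t` (s) and `kx`, `ky`,
#'   `kz` (1/m), starting at `k(0) = 0`.
#' @export
compute_ktrajectory <- function(grads) {
  stopifnot(inherits(grads, "grad_timeline"))
  if (!all(is.finite(grads$g))) stop("non-finite gradient sample")
  nt <- ncol(grads$g)
  out <- data.frame(t = (0:nt) * grads$dt,
                    kx = c(0, cumsum(grads$g[1, ]) * grads$dt),
                    ky = c(0, cumsum(grads$g[2, ]) * grads$dt),
                    kz = c(0, cumsum(grads$g[3, ]) * grads$dt))
  class(out) <- c("k_trajectory", "data.frame")
  out
}

#' @export
plot.k_trajectory <- function(x, ...) {
  graphics::plot(x$kx, x$ky, type = "l", asp = 1, xlab = "kx (1/m)",
                 ylab = "ky (1/m)", ...)
  invisible(x)
}

## ---- RF expansion -------------------------------------------------------

# complex channel waveforms (Hz) on the RF raster grid; sample i covers
# cells (t[i-1], t[i]] with t[0] = 0
expand_rf <- function(rf) {
  if (inherits(rf, "ptx_packed")) rf <- unpack_ptx(rf)
  stopifnot(inherits(rf, "ptx_rf"))
  ncell <- max(rf_final_times(rf))
  B <- matrix(complex(real = 0), nrow = rf$n_channels, ncol = ncell)
  for (c in seq_len(rf$n_channels)) {
    t <- rf$time[[c]]
    env <- rf$amplitude * rf$mag[[c]] * exp(1i * (rf$phase[[c]] + rf$phase_offset))
    prev <- 0
    for (i in seq_along(t)) {
      cells <- (prev + 1):t[i]
      B[c, cells] <- env[i]
      prev <- t[i]
    }
  }
  if (rf$freq_offset != 0) {
    tc <- ((seq_len(ncell)) - 0.5) * rf$raster
    B <- sweep(B, 2, exp(1i * 2 * pi * rf$freq_offset * tc), `*`)
  }
  B
}

#' Flatten a sequence (fragment) into one pulse and gradient timeline
#'
#' Concatenates the RF events of the selected blocks, on the RF raster and
#' with block timing respected, into a single dense `ptx_rf`, together with
#' the matching `grad_timeline`. This is how a multi-block excitation module
#' (e.g. a kT-points fragment) is handed to [simulate_flip()].
#'
#' @param doc A `pulseq_seq`.
#' @param blocks Optional block indices (default all).
#' @return `list(rf, grads)`.
#' @export
seq_to_pulse <- function(doc, blocks = NULL) {
  rasters <- seq_rasters(doc)
  if (is.null(blocks)) blocks <- seq_len(nrow(doc$blocks))
  ncells <- round(doc$blocks$dur[blocks] / rasters$rf)
  tot <- sum(ncells)
  nC <- 1L
  for (i in blocks) {
    rid <- doc$blocks$rf[i]
    if (rid > 0) nC <- max(nC, seq_get_rf(doc, rid)$n_channels)
  }
  env <- matrix(0i, nC, tot)
  off <- 0L
  for (j in seq_along(blocks)) {
    rid <- doc$blocks$rf[blocks[j]]
    if (rid > 0) {
      rf <- unpack_ptx(seq_get_rf(doc, rid))
      B <- expand_rf(rf)
      i0 <- off + round(rf$delay / rasters$rf)
      env[seq_len(nrow(B)), i0 + seq_len(ncol(B))] <- B
    }
    off <- off + ncells[j]
  }
  amp <- max(Mod(env))
  if (amp == 0) amp <- 1
  rf <- multichannel_rf(mag = lapply(seq_len(nC), function(c) Mod(env[c, ]) / amp),
                        phase = lapply(seq_len(nC), function(c) Arg(env[c, ])),
                        amplitude = amp, raster = rasters$rf)
  list(rf = rf, grads = seq_gradients(doc, blocks))
}

#' Flip-angle map of a multi-channel pulse
#'
#' Simulates the excitation produced by a pTx pulse on a B1+ map set, either
#' by full rotation-matrix Bloch integration of the effective field
#' (`method = "full"`) or by the small-tip-angle model, the magnitude of the
#' Fourier-weighted integral of the drive along the excitation k-space
#' trajectory (`method = "small_tip"`). Relaxation is neglected (pulses are
#' short). The integration step is the minimum of the RF and gradient
#' rasters; the RF raster must be an integer multiple of it.
#'
#' @param rf A `ptx_rf` or `ptx_packed` with `n_channels` matching `maps`.
#' @param grads A `grad_timeline` aligned with the pulse (t = 0 at the start
#'   of the RF shape), or `NULL` for no gradients.
#' @param maps A `b1_maps` object; `maps$b0_sign = -1` simulates a reversed
#'   main field (conjugate effective sensitivities, negated gradient phase).
#' @param method `"full"` or `"small_tip"`.
#' @return A `flip_map` matrix (degrees, zero outside the mask) with the
#'   complex transverse magnetization in attribute `"mxy"`.
#' @export
simulate_flip <- function(rf, grads = NULL, maps, method = c("full", "small_tip")) {
  method <- match.arg(method)
  stopifnot(inherits(maps, "b1_maps"))
  if (inherits(rf, "ptx_packed")) rf <- unpack_ptx(rf)
  if (rf$n_channels != maps$n_channels)
    stop(sprintf("pulse has %d channels but maps have %d", rf$n_channels, maps$n_channels))
  dt <- if (is.null(grads)) rf$raster else min(rf$raster, grads$dt)
  rrf <- rf$raster / dt
  if (abs(rrf - round(rrf)) > 1e-9)
    stop("RF raster is not an integer multiple of the integration step; resample first")
  rrf <- round(rrf)

  B <- expand_rf(rf)                      # C x Trf on rf raster
  B <- B[, rep(seq_len(ncol(B)), each = rrf), drop = FALSE]
  nt <- ncol(B)
  G <- matrix(0, 3, nt)
  if (!is.null(grads)) {
    ng <- ncol(grads$g)
    nt <- max(nt, as.integer(ceiling(ng * grads$dt / dt - 1e-9)))
    if (nt > ncol(B)) B <- cbind(B, matrix(0, nrow(B), nt - ncol(B)))
    G <- matrix(0, 3, nt)
    tc <- (seq_len(nt) - 0.5) * dt
    gi <- pmin(floor(tc / grads$dt) + 1L, ng)
    G[] <- grads$g[, gi]
  }

  s <- maps$b0_sign
  vox <- which(maps$mask)
  X <- matrix(maps$x, maps$n, maps$n)[vox]
  Y <- matrix(rep(maps$y, each = maps$n), maps$n, maps$n)[vox]
  P <- matrix(0i, length(vox), maps$n_channels)
  for (c in seq_len(maps$n_channels)) {
    m <- maps$maps[, , c][vox]
    P[, c] <- if (s < 0) Conj(m) else m
  }
  if (!all(is.finite(Mod(P)))) stop("non-finite B1 map inside mask")

  Fdrive <- P %*% B                       # V x T complex, Hz

  if (method == "small_tip") {
    # excitation k-space: remaining gradient area after each sample (midpoint)
    garea <- G * dt
    kx <- -(rev(cumsum(rev(garea[1, ]))) - garea[1, ] / 2)
    ky <- -(rev(cumsum(rev(garea[2, ]))) - garea[2, ] / 2)
    phase <- outer(X, kx) + outer(Y, ky)  # V x T, in 1/m * m
    mxy <- (2i * pi * dt) * rowSums(Fdrive * exp(2i * pi * s * phase))
    alpha <- Mod(mxy)
  } else {
    Mx <- numeric(length(vox)); My <- numeric(length(vox)); Mz <- rep(1, length(vox))
    two_pi <- 2 * pi
    wz_xy <- s * two_pi * (outer(X, G[1, ]) + outer(Y, G[2, ]))  # V x T
    for (j in seq_len(nt)) {
      wx <- two_pi * Re(Fdrive[, j])
      wy <- two_pi * Im(Fdrive[, j])
      wz <- wz_xy[, j]
      wn <- sqrt(wx^2 + wy^2 + wz^2)
      act <- wn > 0
      if (!any(act)) next
      phi <- -wn[act] * dt                 # dM/dt = M x w -> rotate by -|w|dt
      nx <- wx[act] / wn[act]; ny <- wy[act] / wn[act]; nz <- wz[act] / wn[act]
      cphi <- cos(phi); sphi <- sin(phi); vphi <- 1 - cphi
      mx <- Mx[act]; my <- My[act]; mz <- Mz[act]
      ndm <- nx * mx + ny * my + nz * mz
      cx <- ny * mz - nz * my
      cy <- nz * mx - nx * mz
      cz <- nx * my - ny * mx
      Mx[act] <- mx * cphi + cx * sphi + nx * ndm * vphi
      My[act] <- my * cphi + cy * sphi + ny * ndm * vphi
      Mz[act] <- mz * cphi + cz * sphi + nz * ndm * vphi
    }
    mxy <- complex(real = Mx, imaginary = My)
    alpha <- atan2(sqrt(Mx^2 + My^2), Mz)
  }

  flip <- matrix(0, maps$n, maps$n)
  flip[vox] <- alpha * 180 / pi
  mxy_full <- matrix(0i, maps$n, maps$n)
  mxy_full[vox] <- mxy
  structure(flip, class = c("flip_map", "matrix"), mxy = mxy_full,
            x = maps$x, y = maps$y)
}

#' @export
plot.flip_map <- function(x, ...) {
  graphics::image(attr(x, "x"), attr(x, "y"), unclass(x), asp = 1,
                  xlab = "x (m)", ylab = "y (m)", main = "flip angle (deg)", ...)
  invisible(x)
}

## ---- power monitoring ---------------------------------------------------

#' Per-channel RF power report
#'
#' Instantaneous power is `cal * |amplitude * magnitude|^2` on an arbitrary
#' but fixed calibration scale (hardware watt levels are scanner-specific).
#' The report gives per-channel peak power, the maximum of contiguous
#' windowed time averages, and total energy, compared against limits.
#' Because the windows tile the waveform, the energy equals the sum of
#' window averages times window length.
#'
#' @param x A `ptx_rf`/`ptx_packed` pulse or a whole `pulseq_seq`.
#' @param limits List with `peak` and `avg` limits (calibrated W), or a
#'   `hardware_profile`.
#' @param window Averaging window in seconds.
#' @param cal Calibration constant (W per Hz^2).
#' @param ... Unused.
#' @return A `power_report`: per-channel table, the window-average matrix
#'   (windows x channels) and an overall pass flag.
#' @export
power_report <- function(x, limits = NULL, window = 1e-3, cal = 1e-3, ...) {
  UseMethod("power_report")
}

finish_power_report <- function(p, raster, limits, window, cal) {
  # p: T x C instantaneous power matrix on `raster`
  nwin_len <- max(1L, round(window / raster))
  nwin <- ceiling(nrow(p) / nwin_len)
  widx <- rep(seq_len(nwin), each = nwin_len)[seq_len(nrow(p))]
  wlen <- tabulate(widx, nwin) * raster
  avg <- apply(p, 2, function(col) tapply(col, widx, sum) * raster) / wlen
  avg <- matrix(avg, nrow = nwin)
  energy <- colSums(avg * wlen)
  peak <- apply(p, 2, max)
  if (inherits(limits, "hardware_profile"))
    limits <- list(peak = limits$peak_power, avg = limits$avg_power)
  peak_lim <- if (is.null(limits$peak)) Inf else limits$peak
  avg_lim <- if (is.null(limits$avg)) Inf else limits$avg
  avg_max <- apply(avg, 2, max)
  pass <- peak <= peak_lim & avg_max <= avg_lim
  tab <- data.frame(channel = seq_len(ncol(p)), peak = peak, avg_max = avg_max,
                    energy = energy, pass = pass)
  structure(list(table = tab, windows = avg, window = window, cal = cal,
                 pass = all(pass)), class = "power_report")
}

#' @export
power_report.ptx_packed <- function(x, limits = NULL, window = 1e-3,
                                    cal = 1e-3, ...) {
  power_report(unpack_ptx(x), limits, window, cal, ...)
}

#' @export
power_report.ptx_rf <- function(x, limits = NULL, window = 1e-3, cal = 1e-3, ...) {
  B <- expand_rf(x)
  p <- t(cal * Mod(B)^2)
  finish_power_report(p, x$raster, limits, window, cal)
}

#' @export
power_report.pulseq_seq <- function(x, limits = NULL, window = 1e-3,
                                    cal = 1e-3, ...) {
  rasters <- seq_rasters(x)
  nC <- 1L
  for (id in names(x$rf)) {
    t <- if (x$rf[[id]]$time_id > 0)
      decompress_shape(x$shapes[[as.character(x$rf[[id]]$time_id)]]) else NULL
    if (!is.null(t)) nC <- max(nC, infer_channel_count(t))
  }
  total <- seq_duration(x)
  ncell <- ceiling(total / rasters$rf - 1e-9)
  p <- matrix(0, ncell, nC)
  t0 <- 0
  for (i in seq_len(nrow(x$blocks))) {
    b <- x$blocks[i, ]
    if (b$rf > 0) {
      rf <- unpack_ptx(seq_get_rf(x, b$rf))
      B <- expand_rf(rf)
      off <- round((t0 + rf$delay) / rasters$rf)
      idx <- off + seq_len(ncol(B))
      for (c in seq_len(rf$n_channels)) {
        p[idx, c] <- p[idx, c] + cal * Mod(B[c, ])^2
      }
    }
    t0 <- t0 + b$dur
  }
  finish_power_report(p, rasters$rf, limits, window, cal)
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("<power_report> window %.3g ms, overall %s\n", x$window * 1e3,
              if (x$pass) "PASS" else "FAIL"))
  print(x$table, row.names = FALSE)
  invisible(x)
}
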