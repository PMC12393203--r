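#' Parameters for the 2D GRE fixture sequence
#'
#' Defaults reproduce the phantom protocol used for per-channel verification:
#' FOV 256 x 256 mm2 at 1 mm resolution, 3 mm slice,
#' TE/TR/flip/bandwidth = 6 ms / 15 ms / 6 deg / 900 Hz/px.
#'
#' @param fov Field of view (m).
#' @param resolution In-plane resolution (m); `fov/resolution` must be an
#'   integer (the matrix size).
#' @param slice_thickness Slice thickness (m), stored in the FOV definition.
#' @param te,tr Echo and repetition time (s); `te < tr` required.
#' @param flip Flip angle (degrees).
#' @param bandwidth_per_pixel Readout bandwidth (Hz/px).
#' @param n_slices Number of repeated slices.
#' @param active_channel_per_slice Optional integer vector (one entry per
#'   slice): each slice's excitation becomes a packed pTx pulse with only
#'   that channel active.
#' @param n_channels Number of transmit channels for pTx slices.
#' @return A `gre_params` list.
#' @export
gre_params <- function(fov = 0.256, resolution = 1e-3, slice_thickness = 3e-3,
                       te = 6e-3, tr = 15e-3, flip = 6,
                       bandwidth_per_pixel = 900, n_slices = 1,
                       active_channel_per_slice = NULL, n_channels = 8) {
  N <- fov / resolution
  if (abs(N - round(N)) > 1e-9)
    stop("fov/resolution must be an integer matrix size")
  if (te >= tr) stop("te must be smaller than tr")
  if (!is.null(active_channel_per_slice)) {
    if (length(active_channel_per_slice) != n_slices)
      stop("active_channel_per_slice must have one entry per slice")
    if (any(active_channel_per_slice < 1 | active_channel_per_slice > n_channels))
      stop("active channel outside 1..n_channels")
  }
  structure(list(fov = fov, resolution = resolution, N = as.integer(round(N)),
                 slice_thickness = slice_thickness, te = te, tr = tr,
                 flip = flip, bandwidth_per_pixel = bandwidth_per_pixel,
                 n_slices = n_slices,
                 active_channel_per_slice = active_channel_per_slice,
                 n_channels = as.integer(n_channels)),
            class = "gre_params")
}

# hard excitation pulse; with `active` set, a packed pTx pulse with only
# that channel nonzero (inactive channels hold a single terminal zero)
hard_pulse <- function(flip_deg, dur = 1e-4, raster = 1e-6, active = NULL,
                       n_channels = 1L) {
  nsub <- round(dur / raster)
  amp <- flip_deg / (360 * dur)
  if (is.null(active) || n_channels == 1L) {
    return(multichannel_rf(mag = list(rep(1, nsub)), phase = list(numeric(nsub)),
                           amplitude = amp, raster = raster))
  }
  mag <- phase <- time <- vector("list", n_channels)
  for (c in seq_len(n_channels)) {
    if (c == active) {
      mag[[c]] <- rep(1, nsub); phase[[c]] <- numeric(nsub); time[[c]] <- seq_len(nsub)
    } else {
      mag[[c]] <- 0; phase[[c]] <- 0; time[[c]] <- nsub
    }
  }
  multichannel_rf(mag, phase, time, amplitude = amp, raster = raster)
}

# symmetric trapezoid realizing a gradient area (1/m); durations on raster
trap_for_area <- function(area, rise = 2e-4, flat = 6e-4, delay = 0) {
  trap_event(amplitude = area / (rise + flat), rise = rise, flat = flat,
             fall = rise, delay = delay)
}

#' Generate a Cartesian 2D GRE fixture sequence
#'
#' Builds the phantom verification sequence: per slice, `N` repetitions of
#' excitation / prephase + phase encode / readout + ADC / spoiler + rewinder
#' blocks on the default rasters. Readout samples land exactly on the
#' k-space grid (`dk = 1/fov`), the echo is centered at TE and each
#' repetition lasts TR. With `active_channel_per_slice` set, each slice's
#' excitation is a packed pTx pulse activating a single transmit channel, as
#' in a per-channel B1 verification scan. The result passes
#' [validate_sequence()] under the default hardware profile.
#'
#' @param p A `gre_params` object.
#' @return A `pulseq_seq`.
#' @export
make_gre_fixture <- function(p = gre_params()) {
  stopifnot(inherits(p, "gre_params"))
  doc <- new_seq(name = if (is.null(p$active_channel_per_slice)) "gre" else "gre_ptx")
  rasters <- seq_rasters(doc)
  N <- p$N
  dk <- 1 / p$fov

  dwell <- round((1 / p$bandwidth_per_pixel / N) / rasters$adc) * rasters$adc
  if (dwell <= 0) stop("bandwidth too high for the ADC raster")
  g_read <- dk / dwell
  rise_ro <- 2e-4
  flat_ro <- ceiling(N * dwell / rasters$grad) * rasters$grad

  rf_dur <- 1e-4
  d1 <- ceiling(rf_dur / rasters$block) * rasters$block
  # echo (k = 0 sample) at TE after the RF center
  d2 <- p$te - (d1 - rf_dur / 2) - rise_ro - (N / 2 + 0.5) * dwell
  d2 <- round(d2 / rasters$block) * rasters$block
  trap_len <- 2e-4 + 6e-4 + 2e-4
  if (d2 < trap_len) stop("te too short for the encoding gradients")
  d3 <- ceiling((rise_ro + flat_ro + rise_ro) / rasters$block) * rasters$block
  d4 <- p$tr - d1 - d2 - d3
  d4 <- round(d4 / rasters$block) * rasters$block
  spoil_len <- 2e-4 + 1.2e-3 + 2e-4
  if (d4 < spoil_len) stop("tr too short for the spoiler")

  area_pre <- -(N / 2 + 0.5) * dk - g_read * rise_ro / 2

  # shared events
  r <- add_event(doc, "adc", adc_event(num_samples = N, dwell = dwell,
                                       delay = rise_ro))
  doc <- r$doc; adc_id <- r$id
  r <- add_event(doc, "gradients", trap_event(g_read, rise_ro, flat_ro, rise_ro))
  doc <- r$doc; ro_id <- r$id
  r <- add_event(doc, "gradients", trap_for_area(area_pre, delay = d2 - trap_len))
  doc <- r$doc; pre_id <- r$id
  r <- add_event(doc, "gradients",
                 trap_event(N * dk / 1.4e-3, 2e-4, 1.2e-3, 2e-4))
  doc <- r$doc; spoil_id <- r$id

  pe_ids <- integer(N)
  rew_ids <- integer(N)
  for (l in seq_len(N)) {
    ky <- (l - 1 - N / 2) * dk
    r <- add_event(doc, "gradients", trap_for_area(ky, delay = d2 - trap_len))
    doc <- r$doc; pe_ids[l] <- r$id
    r <- add_event(doc, "gradients", trap_for_area(-ky))
    doc <- r$doc; rew_ids[l] <- r$id
  }

  rf_ids <- integer(p$n_slices)
  for (s in seq_len(p$n_slices)) {
    act <- if (is.null(p$active_channel_per_slice)) NULL else p$active_channel_per_slice[s]
    rf <- hard_pulse(p$flip, rf_dur, rasters$rf, active = act,
                     n_channels = if (is.null(act)) 1L else p$n_channels)
    r <- seq_add_rf(doc, rf, use = "e")
    doc <- r$doc; rf_ids[s] <- r$id
  }

  rows <- vector("list", p$n_slices * N * 4L)
  k <- 0L
  for (s in seq_len(p$n_slices)) {
    for (l in seq_len(N)) {
      rows[[k + 1L]] <- c(d1, rf_ids[s], 0L, 0L, 0L, 0L, 0L)
      rows[[k + 2L]] <- c(d2, 0L, pre_id, pe_ids[l], 0L, 0L, 0L)
      rows[[k + 3L]] <- c(d3, 0L, ro_id, 0L, 0L, adc_id, 0L)
      rows[[k + 4L]] <- c(d4, 0L, spoil_id, rew_ids[l], 0L, 0L, 0L)
      k <- k + 4L
    }
  }
  m <- do.call(rbind, rows)
  doc$blocks <- data.frame(dur = m[, 1], rf = as.integer(m[, 2]),
                           gx = as.integer(m[, 3]), gy = as.integer(m[, 4]),
                           gz = as.integer(m[, 5]), adc = as.integer(m[, 6]),
                           ext = as.integer(m[, 7]))
  doc$definitions$FOV <- c(p$fov, p$fov, p$slice_thickness)
  doc$definitions$TotalDuration <- seq_duration(doc)
  doc
}

#' Parameters for a kT-points excitation block
#'
#' A kT-points pulse alternates short nonselective hard subpulses, each with
#' its own per-channel complex weight, with small gradient blips that move
#' the excitation k-space location between subpulses.
#'
#' @param weights Complex matrix, `n_channels x n_subpulses`: per-subpulse
#'   per-channel weights in Hz (gamma * B1).
#' @param sub_dur Duration of each hard subpulse (s).
#' @param blip_areas `3 x (n_subpulses - 1)` matrix of gradient blip areas
#'   (1/m) per axis, or `NULL` for no blips.
#' @param max_blip_dur Longest admissible blip (s); a blip area that cannot
#'   be realized within this duration at the hardware slew limit is an error.
#' @param hw `hardware_profile` used to shape the blips.
#' @return A `ktpoints_params` list.
#' @export
ktpoints_params <- function(weights, sub_dur = 1e-4, blip_areas = NULL,
                            max_blip_dur = 1e-3, hw = hardware_profile()) {
  weights <- as.matrix(weights)
  if (!all(is.finite(Mod(weights)))) stop("non-finite subpulse weight")
  S <- ncol(weights)
  if (S < 1) stop("need at least one subpulse")
  if (is.null(blip_areas)) blip_areas <- matrix(0, 3, max(S - 1, 0))
  blip_areas <- as.matrix(blip_areas)
  if (S > 1 && !all(dim(blip_areas) == c(3, S - 1)))
    stop("blip_areas must be 3 x (n_subpulses - 1)")
  structure(list(weights = weights, n_subpulses = S, sub_dur = sub_dur,
                 blip_areas = blip_areas, max_blip_dur = max_blip_dur,
                 hw = hw), class = "ktpoints_params")
}

blip_trap <- function(area, hw, graster, max_dur) {
  if (area == 0) return(NULL)
  slew <- 0.9 * hw$max_slew
  rise <- max(sqrt(abs(area) / slew), abs(area) / (0.9 * hw$max_gradient))
  rise <- max(ceiling(rise / graster), 1) * graster
  if (2 * rise > max_dur)
    stop(sprintf("blip area %.3g 1/m not realizable within %.3g ms at the slew limit",
                 area, max_dur * 1e3))
  trap_event(amplitude = area / rise, rise = rise, flat = 0, fall = rise)
}

#' Build a kT-points excitation block as a sequence fragment
#'
#' Returns a small `pulseq_seq` whose blocks alternate packed pTx hard
#' subpulses with gradient blips; insertable into a template with
#' [merge_excitation()]. The total duration is stored in the fragment's
#' `TotalDuration` definition.
#'
#' @param p A `ktpoints_params` object.
#' @return A `pulseq_seq` fragment.
#' @export
make_ktpoints_block <- function(p) {
  stopifnot(inherits(p, "ktpoints_params"))
  doc <- new_seq(name = "ktpoints")
  rasters <- seq_rasters(doc)
  C <- nrow(p$weights)
  S <- p$n_subpulses
  nsub <- round(p$sub_dur / rasters$rf)
  amp <- max(Mod(p$weights))
  if (amp == 0) amp <- 1

  for (s in seq_len(S)) {
    mag <- phase <- time <- vector("list", C)
    for (c in seq_len(C)) {
      mag[[c]] <- rep(Mod(p$weights[c, s]) / amp, nsub)
      phase[[c]] <- rep(Arg(p$weights[c, s]), nsub)
      time[[c]] <- seq_len(nsub)
    }
    rf <- multichannel_rf(mag, phase, time, amplitude = amp, raster = rasters$rf)
    r <- seq_add_rf(doc, rf, use = "e")
    doc <- r$doc
    doc <- add_block(doc, ceiling(p$sub_dur / rasters$block) * rasters$block,
                     rf = r$id)
    if (s < S) {
      ids <- c(gx = 0L, gy = 0L, gz = 0L)
      dur <- rasters$block
      for (ax in 1:3) {
        tr <- blip_trap(p$blip_areas[ax, s], p$hw, rasters$grad, p$max_blip_dur)
        if (!is.null(tr)) {
          r <- add_event(doc, "gradients", tr)
          doc <- r$doc
          ids[ax] <- r$id
          dur <- max(dur, tr$rise + tr$flat + tr$fall)
        }
      }
      doc <- add_block(doc, ceiling(dur / rasters$block) * rasters$block,
                       gx = ids[1], gy = ids[2], gz = ids[3])
    }
  }
  doc$definitions$TotalDuration <- seq_duration(doc)
  doc
}

#' Simplified MPRAGE-like template sequence
#'
#' An adiabatic-style inversion (hard 180 here), an inversion delay, and a
#' short train of low-flip gradient-echo readouts. This is a deliberately
#' simplified stand-in for a vendor MPRAGE loop, intended as a merge target:
#' its excitation blocks carry the RF use tag `"e"` and can be replaced with
#' a kT-points fragment via [merge_excitation()].
#'
#' @param n_lines Readout lines in the echo train.
#' @param ti Inversion delay (s).
#' @param p `gre_params` for the readout train geometry.
#' @return A `pulseq_seq`.
#' @export
make_mprage_template <- function(n_lines = 16, ti = 0.12,
                                 p = gre_params(resolution = 0.256 / n_lines,
                                                te = 3e-3, tr = 7e-3)) {
  doc <- make_gre_fixture(p)
  rasters <- seq_rasters(doc)
  inv <- hard_pulse(180, dur = 5e-4, raster = rasters$rf)
  r <- seq_add_rf(doc, inv, use = "i")
  doc <- r$doc
  inv_row <- data.frame(dur = ceiling(5e-4 / rasters$block) * rasters$block,
                        rf = r$id, gx = 0L, gy = 0L, gz = 0L, adc = 0L, ext = 0L)
  delay_row <- data.frame(dur = round(ti / rasters$block) * rasters$block,
                          rf = 0L, gx = 0L, gy = 0L, gz = 0L, adc = 0L, ext = 0L)
  doc$blocks <- rbind(inv_row, delay_row, doc$blocks)
  rownames(doc$blocks) <- NULL
  doc$definitions$Name <- "mprage_like"
  doc$definitions$TotalDuration <- seq_duration(doc)
  doc
}

#' Archimedean spiral gradient fixture
#'
#' Gradient waveforms realizing the spiral k-space trajectory
#' `k(t) = kmax * (t/T) * (cos(2 pi n t / T), sin(2 pi n t / T))`, sampled
#' analytically at the raster cell centers. The analytic trajectory endpoint
#' `(kmax, 0)` is stored in the `"k_end"` attribute.
#'
#' @param kmax Final k-space radius (1/m).
#' @param turns Number of spiral turns.
#' @param dur Duration (s).
#' @param dt Gradient raster (s).
#' @return A `grad_timeline`.
#' @export
spiral_gradients <- function(kmax = 200, turns = 6, dur = 8e-3, dt = 1e-5) {
  nt <- round(dur / dt)
  tc <- (seq_len(nt) - 0.5) * dt
  th <- 2 * pi * turns * tc / dur
  gx <- kmax / dur * (cos(th) - th * sin(th))
  gy <- kmax / dur * (sin(th) + th * cos(th))
  gt <- grad_timeline(gx = gx, gy = gy, dt = dt)
  attr(gt, "k_end") <- c(kmax * cos(2 * pi * turns), kmax * sin(2 * pi * turns), 0)
  gt
}

#' Spiral readout fixture sequence with arbitrary gradient events
#'
#' Wraps [spiral_gradients()] into a single-block sequence using arbitrary
#' (shape-sampled) gradient events, the event type that requires raster
#' regridding when moved to hardware with a different gradient time grid.
#'
#' @inheritParams spiral_gradients
#' @return A `pulseq_seq` with one excitation block and one spiral block.
#' @export
make_spiral_fixture <- function(kmax = 200, turns = 6, dur = 8e-3, dt = 1e-5) {
  doc <- new_seq(name = "spiral", grad_raster = dt)
  rasters <- seq_rasters(doc)
  gt <- spiral_gradients(kmax, turns, dur, dt)
  rf <- hard_pulse(10, dur = 1e-4, raster = rasters$rf)
  r <- seq_add_rf(doc, rf, use = "e")
  doc <- r$doc
  doc <- add_block(doc, 1e-4, rf = r$id)
  ids <- integer(2)
  for (ax in 1:2) {
    w <- gt$g[ax, ]
    amp <- max(abs(w))
    r <- add_shape(doc, w / amp)
    doc <- r$doc
    r2 <- add_event(doc, "gradients", grad_event(amplitude = amp, shape_id = r$id,
                                                 first = w[1], last = w[length(w)]))
    doc <- r2$doc
    ids[ax] <- r2$id
  }
  doc <- add_block(doc, dur, gx = ids[1], gy = ids[2])
  doc$definitions$TotalDuration <- seq_duration(doc)
  doc
}
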