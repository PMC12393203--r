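#' Digital phantoms
#'
#' `phantom_disc()` is a uniform disc (the 2D section of a spherical
#' phantom); `phantom_head()` is an ellipse with a few internal structures,
#' loosely emulating a head-shaped phantom. Values are proton densities in
#' `[0, 1]` on the same grid convention as [synth_b1_maps()].
#'
#' @param n Grid size.
#' @param fov Field of view (m).
#' @param radius Disc radius (m).
#' @return An `n x n` numeric matrix.
#' @export
phantom_disc <- function(n = 64, fov = 0.256, radius = 0.05) {
  x <- (seq_len(n) - (n + 1) / 2) * (fov / n)
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  (X^2 + Y^2 <= radius^2) * 1
}

#' @rdname phantom_disc
#' @export
phantom_head <- function(n = 64, fov = 0.256) {
  x <- (seq_len(n) - (n + 1) / 2) * (fov / n)
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  inside <- (X / 0.075)^2 + (Y / 0.09)^2 <= 1
  p <- inside * 1
  p[(X / 0.05)^2 + ((Y - 0.02) / 0.06)^2 <= 1] <- 0.85
  p[((X - 0.02) / 0.012)^2 + ((Y + 0.03) / 0.02)^2 <= 1] <- 0.6
  p[((X + 0.02) / 0.012)^2 + ((Y + 0.03) / 0.02)^2 <= 1] <- 0.6
  p
}

#' Simulate a Cartesian 2D GRE acquisition and reconstruct it
#'
#' Runs the acquisition described by a 2D gradient-echo sequence document on
#' a digital phantom: for each slice (group of readouts sharing an RF event)
#' the transverse magnetization is obtained from the full Bloch simulation of
#' that slice's (possibly pTx) excitation on the B1+ maps, the k-space
#' location of every ADC sample is integrated from the gradient events, and
#' each acquired line is the discrete Fourier transform of
#' (phantom x transmit magnetization x receive sensitivity) at those
#' locations. Reconstruction is the 2D inverse Fourier transform per receive
#' channel followed by root-sum-of-squares combination.
#'
#' @param doc A Cartesian 2D GRE `pulseq_seq` (see [make_gre_fixture()]).
#'   Non-Cartesian trajectories are rejected (trajectory analysis only).
#' @param maps A `b1_maps` object (transmit sensitivities).
#' @param phantom Proton-density matrix on the same grid.
#' @param recv Receive sensitivities, `n x n x n_recv` array; defaults to the
#'   magnitudes of the transmit maps (transmit/receive coil).
#' @return A `gre_sim` object: `images` (list of per-slice magnitude
#'   matrices), `slices` (data frame with the RF event per slice), `kspace`
#'   (per-slice list of per-channel k-space matrices), and grid info.
#' @export
simulate_gre <- function(doc, maps, phantom, recv = NULL) {
  stopifnot(inherits(doc, "pulseq_seq"), inherits(maps, "b1_maps"))
  n <- maps$n
  if (!all(dim(phantom) == c(n, n))) stop("phantom grid does not match maps")
  if (is.null(recv)) {
    recv <- array(0, dim = c(n, n, maps$n_channels))
    for (c in seq_len(maps$n_channels)) recv[, , c] <- Mod(maps$maps[, , c])
  }
  n_recv <- dim(recv)[3]
  dk <- 1 / maps$fov
  rasters <- seq_rasters(doc)

  # locate excitations and the readouts that belong to them
  lines <- list()
  cur_rf <- NA_integer_
  cur_rf_block <- NA_integer_
  for (i in seq_len(nrow(doc$blocks))) {
    b <- doc$blocks[i, ]
    if (b$rf > 0) { cur_rf <- b$rf; cur_rf_block <- i }
    if (b$adc > 0) {
      if (is.na(cur_rf)) stop("ADC before any excitation")
      lines[[length(lines) + 1L]] <- list(adc_block = i, rf = cur_rf,
                                          rf_block = cur_rf_block)
    }
  }
  if (length(lines) == 0) stop("sequence contains no ADC events")

  block_start <- cumsum(c(0, doc$blocks$dur))

  # k-space location of each ADC sample, integrating from the end of the
  # excitation block (transverse phase is reset by the excitation)
  line_k <- lapply(lines, function(ln) {
    blocks <- (ln$rf_block + 1):ln$adc_block
    gt <- seq_gradients(doc, blocks)
    traj <- compute_ktrajectory(gt)
    adc <- doc$adc[[as.character(doc$blocks$adc[ln$adc_block])]]
    t_adc <- (block_start[ln$adc_block] - block_start[ln$rf_block + 1L]) +
      adc$delay + (seq_len(adc$num_samples) - 0.5) * adc$dwell
    list(kx = stats::approx(traj$t, traj$kx, xout = t_adc, rule = 2)$y,
         ky = stats::approx(traj$t, traj$ky, xout = t_adc, rule = 2)$y)
  })

  # Cartesian check: constant ky per line, shared kx per line
  kx_ref <- line_k[[1]]$kx
  for (lk in line_k) {
    if (max(abs(lk$ky - lk$ky[1])) > 1e-3 * dk ||
        max(abs(lk$kx - kx_ref)) > 1e-3 * dk)
      stop("non-Cartesian trajectory: only Cartesian 2D GRE is supported")
  }
  kx_idx <- kx_ref / dk + nrow(phantom) / 2 + 1
  if (max(abs(kx_idx - round(kx_idx))) > 1e-3)
    stop("readout samples do not fall on the k-space grid")
  kx_idx <- round(kx_idx)

  X <- matrix(maps$x, n, n)[, 1]
  Y <- X
  Ex <- exp(-2i * pi * outer(kx_ref, X))       # J x n
  rf_ids <- vapply(lines, function(ln) ln$rf, numeric(1))
  slice_rf <- unique(rf_ids)

  images <- list()
  kspaces <- list()
  for (srf in slice_rf) {
    flip <- simulate_flip(seq_get_rf(doc, srf), grads = NULL, maps = maps,
                          method = "full")
    mxy <- attr(flip, "mxy")
    sel <- which(rf_ids == srf)
    ky_l <- vapply(sel, function(i) line_k[[i]]$ky[1], numeric(1))
    ky_idx <- ky_l / dk + n / 2 + 1
    if (max(abs(ky_idx - round(ky_idx))) > 1e-3)
      stop("phase-encode lines do not fall on the k-space grid")
    ky_idx <- round(ky_idx)
    Ey <- exp(-2i * pi * outer(ky_l, Y))       # L x n
    # full-grid encoding kernels; A^H A = n I, so the inverse transform is
    # exact for fully sampled Cartesian data with these exact conventions
    kx_full <- (seq_len(n) - n / 2 - 1) * dk
    ExF <- exp(-2i * pi * outer(kx_full, X))
    EyF <- exp(-2i * pi * outer(kx_full, Y))
    imgs_c <- array(0i, dim = c(n, n, n_recv))
    kspace_c <- vector("list", n_recv)
    for (c in seq_len(n_recv)) {
      W <- phantom * mxy * recv[, , c]
      S <- Ex %*% W %*% t(Ey)                  # J x L
      K <- matrix(0i, n, n)
      K[cbind(rep(kx_idx, times = length(sel)),
              rep(ky_idx, each = length(kx_idx)))] <- as.vector(S)
      kspace_c[[c]] <- K
      imgs_c[, , c] <- (Conj(t(ExF)) %*% K %*% Conj(EyF)) / (n * n)
    }
    images[[length(images) + 1L]] <- sqrt(apply(Mod(imgs_c)^2, c(1, 2), sum))
    kspaces[[length(kspaces) + 1L]] <- kspace_c
  }
  structure(list(images = images, kspace = kspaces,
                 slices = data.frame(slice = seq_along(slice_rf), rf = slice_rf),
                 n = n, fov = maps$fov, x = maps$x, y = maps$y),
            class = "gre_sim")
}

#' @export
print.gre_sim <- function(x, ...) {
  cat(sprintf("<gre_sim> %d slice(s) at %dx%d, FOV %.3g m\n",
              length(x$images), x$n, x$n, x$fov))
  invisible(x)
}

#' @export
plot.gre_sim <- function(x, slice = 1, ...) {
  graphics::image(x$x, x$y, x$images[[slice]], asp = 1, col = grDevices::gray.colors(128),
                  xlab = "x (m)", ylab = "y (m)", main = sprintf("slice %d", slice), ...)
  invisible(x)
}
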