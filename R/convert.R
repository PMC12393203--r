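#' Cross-platform pulse conversion specification
#'
#' Describes how a pTx pulse moves between scanner platforms: a permutation
#' of the transmit channels, a signed permutation of the gradient axes, and
#' an RF conjugation flag. A B0-direction reversal is realized by the
#' combination of RF phase negation and a z-gradient sign flip: reversing the
#' main field reverses the precession sense, which (for transmit sensitivity
#' sets mirror-symmetric across the transverse plane) is equivalent to
#' conjugating the per-voxel drive field and negating the through-plane
#' gradient phase evolution. See the package vignette for the derivation.
#'
#' @param channel_permutation Integer vector: output channel `c` takes input
#'   channel `channel_permutation[c]`. `NULL` means identity.
#' @param gradient_transform 3x3 signed permutation matrix (one entry of
#'   +/-1 per row and column) applied to the gradient axis vector.
#' @param rf_conjugate Negate all RF phases (and frequency/phase offsets).
#' @param b0_flip Semantic tag marking that `rf_conjugate` and
#'   `gradient_transform` together realize a B0-direction reversal. When
#'   `TRUE` and the other arguments are left at their defaults, they are set
#'   to the canonical composite (conjugation + `diag(1, 1, -1)`).
#' @return A `conversion_spec` object.
#' @export
conversion_spec <- function(channel_permutation = NULL,
                            gradient_transform = diag(3),
                            rf_conjugate = FALSE, b0_flip = FALSE) {
  if (b0_flip && missing(rf_conjugate) && missing(gradient_transform)) {
    rf_conjugate <- TRUE
    gradient_transform <- diag(c(1, 1, -1))
  }
  check_signed_permutation(gradient_transform)
  if (!is.null(channel_permutation)) {
    p <- as.integer(channel_permutation)
    if (!identical(sort(p), seq_along(p)))
      stop("channel_permutation must be a permutation of 1..n_channels")
    channel_permutation <- p
  }
  structure(list(channel_permutation = channel_permutation,
                 gradient_transform = gradient_transform,
                 rf_conjugate = isTRUE(rf_conjugate),
                 b0_flip = isTRUE(b0_flip)),
            class = "conversion_spec")
}

check_signed_permutation <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)))
    stop("gradient_transform must be a 3x3 matrix")
  if (!all(m %in% c(-1, 0, 1)) ||
      !all(rowSums(abs(m)) == 1) || !all(colSums(abs(m)) == 1))
    stop("gradient_transform must be a signed permutation matrix (one +/-1 per row and column)")
  invisible(TRUE)
}

#' @export
print.conversion_spec <- function(x, ...) {
  cat("<conversion_spec>\n")
  cat("  channel_permutation:",
      if (is.null(x$channel_permutation)) "identity" else paste(x$channel_permutation, collapse = " "), "\n")
  cat("  gradient_transform:\n")
  for (i in 1:3) cat("   ", sprintf("% d % d % d", x$gradient_transform[i, 1],
                                    x$gradient_transform[i, 2], x$gradient_transform[i, 3]), "\n")
  cat("  rf_conjugate:", x$rf_conjugate, " b0_flip:", x$b0_flip, "\n")
  invisible(x)
}

#' Invert a conversion specification
#'
#' The inverse permutation and the transposed (= inverse) signed permutation
#' matrix; conjugation is its own inverse.
#' @param spec A `conversion_spec`.
#' @export
invert_conversion_spec <- function(spec) {
  conversion_spec(channel_permutation = if (is.null(spec$channel_permutation)) NULL else order(spec$channel_permutation),
                  gradient_transform = t(spec$gradient_transform),
                  rf_conjugate = spec$rf_conjugate, b0_flip = spec$b0_flip)
}

#' Reorder the transmit channels of a pTx pulse
#'
#' Output channel `c` carries input channel `perm[c]`; nothing else changes.
#' Platforms map RF channels to hardware in different orders, so pulses moved
#' between platforms may need relabelling.
#'
#' @param rf A `ptx_rf`.
#' @param perm Integer permutation of `1:n_channels`.
#' @export
reorder_channels <- function(rf, perm) {
  stopifnot(inherits(rf, "ptx_rf"))
  perm <- as.integer(perm)
  if (length(perm) != rf$n_channels || !identical(sort(perm), seq_len(rf$n_channels)))
    stop("perm must be a permutation of 1..", rf$n_channels)
  rf$mag <- rf$mag[perm]
  rf$phase <- rf$phase[perm]
  rf$time <- rf$time[perm]
  rf
}

#' Convert a pulse for a reversed B0 direction
#'
#' Applies the conjugation and gradient-axis components of a conversion spec
#' to an unpacked pulse and its gradient timeline: RF phases (and the scalar
#' frequency/phase offsets) are negated when `rf_conjugate`, and the gradient
#' axis waveforms are permuted/negated by `gradient_transform`. Magnitude
#' waveforms and pulse duration are untouched; applying the conjugation twice
#' restores the original phases bit-exactly.
#'
#' @param rf A `ptx_rf`.
#' @param grads A `grad_timeline` (see [grad_timeline()]) or `NULL`.
#' @param spec A `conversion_spec`.
#' @return `list(rf, grads)` with the converted pulse and gradients.
#' @export
convert_b0_direction <- function(rf, grads, spec) {
  stopifnot(inherits(rf, "ptx_rf"), inherits(spec, "conversion_spec"))
  check_signed_permutation(spec$gradient_transform)
  if (spec$b0_flip && !spec$rf_conjugate)
    stop("a B0-direction reversal requires rf_conjugate = TRUE")
  if (spec$rf_conjugate) {
    rf$phase <- lapply(rf$phase, function(p) -p)
    rf$phase_offset <- -rf$phase_offset
    rf$freq_offset <- -rf$freq_offset
  }
  if (!is.null(grads)) {
    stopifnot(inherits(grads, "grad_timeline"))
    nm <- rownames(grads$g)
    grads$g <- spec$gradient_transform %*% grads$g
    rownames(grads$g) <- nm
  }
  list(rf = rf, grads = grads)
}

#' @rdname convert_b0_direction
#' @details `convert_pulse()` is the full composite: channel reordering
#'   followed by the B0/axis conversion.
#' @export
convert_pulse <- function(rf, grads, spec) {
  if (!is.null(spec$channel_permutation))
    rf <- reorder_channels(rf, spec$channel_permutation)
  convert_b0_direction(rf, grads, spec)
}

#' Convert a whole sequence document between platforms
#'
#' Applies a conversion spec to every RF and gradient event of a sequence:
#' RF events are unpacked, channel-permuted and conjugated, gradient events
#' are remapped across the gx/gy/gz block columns with sign flips applied to
#' their amplitudes. ADC events, block structure and definitions are
#' untouched.
#'
#' @param doc A `pulseq_seq`.
#' @param spec A `conversion_spec`.
#' @return The converted `pulseq_seq`.
#' @export
convert_seq <- function(doc, spec) {
  stopifnot(inherits(doc, "pulseq_seq"), inherits(spec, "conversion_spec"))
  out <- doc
  out$keys <- NULL
  # the shape table is rebuilt in normalized order (RF events first, then
  # gradient shapes, in event-id order), so converting twice with inverse
  # specs reproduces the original layout
  out$shapes <- list()

  for (id in names(doc$rf)) {
    packed <- seq_get_rf(doc, id)
    rf <- unpack_ptx(packed)
    if (!is.null(spec$channel_permutation)) {
      if (length(spec$channel_permutation) == rf$n_channels)
        rf <- reorder_channels(rf, spec$channel_permutation)
      else if (rf$n_channels > 1)
        stop(sprintf("RF event %s has %d channels but the permutation covers %d",
                     id, rf$n_channels, length(spec$channel_permutation)))
    }
    if (spec$rf_conjugate) {
      rf$phase <- lapply(rf$phase, function(p) -p)
      rf$phase_offset <- -rf$phase_offset
      rf$freq_offset <- -rf$freq_offset
    }
    packed2 <- pack_ptx(rf)
    ev <- out$rf[[id]]
    s1 <- add_shape(out, packed2$mag); out <- s1$doc
    s2 <- add_shape(out, (packed2$phase / (2 * pi)) %% 1); out <- s2$doc
    s3 <- add_shape(out, packed2$time); out <- s3$doc
    ev$mag_id <- s1$id; ev$phase_id <- s2$id; ev$time_id <- s3$id
    ev$phase_offset <- packed2$phase_offset
    ev$freq_offset <- packed2$freq_offset
    out$rf[[id]] <- ev
  }

  for (id in names(doc$gradients)) {
    ev <- out$gradients[[id]]
    if (ev$kind == "grad") {
      r <- add_shape(out, doc$shapes[[as.character(ev$shape_id)]]); out <- r$doc
      ev$shape_id <- r$id
      if (ev$time_id > 0) {
        r <- add_shape(out, doc$shapes[[as.character(ev$time_id)]]); out <- r$doc
        ev$time_id <- r$id
      }
      out$gradients[[id]] <- ev
    }
  }

  tm <- spec$gradient_transform
  if (!all(tm == diag(3))) {
    axes <- c("gx", "gy", "gz")
    oldblocks <- out$blocks
    for (i in 1:3) {
      j <- which(tm[i, ] != 0)
      sgn <- tm[i, j]
      ids <- oldblocks[[axes[j]]]
      if (sgn < 0) {
        newids <- ids
        for (id in unique(ids[ids > 0])) {
          ev <- out$gradients[[as.character(id)]]
          ev$amplitude <- -ev$amplitude
          if (ev$kind == "grad") { ev$first <- -ev$first; ev$last <- -ev$last }
          r <- add_event(out, "gradients", ev)
          out <- r$doc
          newids[ids == id] <- r$id
        }
        ids <- newids
      }
      out$blocks[[axes[i]]] <- ids
    }
    out <- drop_unused_gradients(out)
  }
  out$signature <- NULL
  out$raw_body <- NULL
  out$keys <- NULL
  out
}

# drop gradient events no longer referenced by any block and renumber densely
drop_unused_gradients <- function(doc) {
  used <- sort(unique(c(doc$blocks$gx, doc$blocks$gy, doc$blocks$gz)))
  used <- used[used > 0]
  remap <- stats::setNames(seq_along(used), as.character(used))
  doc$gradients <- doc$gradients[as.character(used)]
  names(doc$gradients) <- as.character(seq_along(used))
  fix <- function(v) ifelse(v > 0, unname(remap[as.character(v)]), 0L)
  doc$blocks$gx <- fix(doc$blocks$gx)
  doc$blocks$gy <- fix(doc$blocks$gy)
  doc$blocks$gz <- fix(doc$blocks$gz)
  doc$keys <- NULL
  doc
}

#' Resample a waveform onto a different raster
#'
#' Linear interpolation of a center-sampled waveform (sample `i` at
#' `(i - 1/2) * raster`) onto the new raster over the same total duration.
#' Endpoint values are preserved exactly (constant extrapolation over the
#' half-cell edges); the zeroth moment of band-limited waveforms is preserved
#' to about 1e-4 relative. Used to move arbitrary gradients between platform
#' time grids (e.g. the 10 us grid common to existing Pulseq sequences and a
#' 6.4 us hardware grid).
#'
#' @param samples Numeric waveform samples.
#' @param from_raster,to_raster Source and target raster times in seconds.
#' @return Resampled samples. If the duration is not an integer multiple of
#'   `to_raster`, the grid is extended by one (zero-valued) sample and the
#'   sub-raster remainder is reported in the `"remainder"` attribute (s).
#' @export
regrid_waveform <- function(samples, from_raster, to_raster) {
  if (from_raster <= 0 || to_raster <= 0) stop("raster times must be positive")
  if (!all(is.finite(samples))) stop("non-finite waveform sample")
  if (from_raster == to_raster) return(samples)
  n <- length(samples)
  dur <- n * from_raster
  m <- dur / to_raster
  m_int <- round(m)
  remainder <- 0
  if (abs(m - m_int) > 1e-9) {
    m_int <- ceiling(m - 1e-9)
    remainder <- m_int * to_raster - dur
  }
  tc_from <- (seq_len(n) - 0.5) * from_raster
  tc_to <- (seq_len(m_int) - 0.5) * to_raster
  out <- stats::approx(tc_from, samples, xout = pmin(tc_to, dur), rule = 2)$y
  # cells beyond the waveform end are zero; the single cell straddling the
  # end carries the cell-averaged value so the zeroth moment is preserved
  lo <- (seq_len(m_int) - 1) * to_raster
  hi <- lo + to_raster
  out[lo >= dur] <- 0
  strad <- which(lo < dur & hi > dur)
  if (length(strad) > 0) {
    mid <- (lo[strad] + dur) / 2
    out[strad] <- stats::approx(tc_from, samples, xout = mid, rule = 2)$y *
      (dur - lo[strad]) / to_raster
  }
  attr(out, "remainder") <- remainder
  out
}
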