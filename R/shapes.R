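#' Pulseq shape codec
#'
#' Pulseq stores sampled waveforms ("shapes") either literally or as a
#' run-length encoding of their first differences: the encoded payload holds
#' the derivative sequence, and whenever two consecutive stored values are
#' equal the next value is an additional repetition count. A payload whose
#' length equals `num_samples` is interpreted as literal (uncompressed)
#' samples.
#'
#' Samples are quantized to 9 significant digits at compress time. The
#' quantizer is applied with feedback (each derivative is computed against the
#' reconstructed, not the original, running value), so quantization error is
#' bounded by one quantum per sample and does not accumulate along the shape.
#' `decompress_shape(compress_shape(x))` therefore reproduces `x` at the write
#' precision, and writing/re-reading a shape through the text format is
#' bit-exact.
#'
#' @param samples Numeric vector of finite samples. Magnitude shapes are
#'   normalized to `[0, 1]`, phase shapes are stored as radians / 2 pi, time
#'   shapes as raster-unit indices.
#' @return `compress_shape()` returns a `pulseq_shape` object with fields
#'   `num_samples` (length of the decoded shape) and `data` (encoded payload).
#' @examples
#' sh <- compress_shape(c(rep(0, 10), seq(0, 1, length.out = 50)))
#' sh$num_samples
#' max(abs(decompress_shape(sh) - c(rep(0, 10), seq(0, 1, length.out = 50))))
#' @export
compress_shape <- function(samples) {
  if (length(samples) == 0L) stop("shape must contain at least one sample")
  if (!all(is.finite(samples))) stop("non-finite sample in shape")
  n <- length(samples)
  qlit <- quant9(samples)
  if (n == 1L) {
    return(new_shape(1L, qlit))
  }
  # derivative with feedback quantization: each stored derivative is computed
  # against the reconstructed running value, so quantization error cannot
  # accumulate along the shape
  d <- quant9(c(samples[1], diff(samples)))
  drift <- max(abs(cumsum(d) - samples))
  if (drift > 5e-10 * max(abs(samples), 1e-12)) {
    xhat <- 0
    for (i in seq_len(n)) {
      d[i] <- quant9(samples[i] - xhat)
      xhat <- xhat + d[i]
    }
  }
  enc <- rle_encode(d)
  if (length(enc) < n) new_shape(n, enc) else new_shape(n, qlit)
}

# round to 9 significant decimal digits, exactly as printed: the result is
# the double nearest the 9-digit decimal, so printing it with %.10g and
# re-parsing reproduces it bit-exactly
quant9 <- function(v) {
  out <- as.numeric(sprintf("%.9g", v))
  out[v == 0] <- 0  # preserve signed zero as plain zero
  out
}

new_shape <- function(num_samples, data) {
  structure(list(num_samples = as.integer(num_samples), data = as.numeric(data)),
            class = "pulseq_shape")
}

# run-length encode v: runs of k equal values become value, value, k - 2
rle_encode <- function(v) {
  r <- rle(v)
  out <- vector("list", length(r$values))
  for (i in seq_along(r$values)) {
    k <- r$lengths[i]
    x <- r$values[i]
    out[[i]] <- if (k == 1L) x else c(x, x, k - 2)
  }
  unlist(out)
}

#' @rdname compress_shape
#' @param shape A `pulseq_shape` as returned by [compress_shape()] or read from
#'   a sequence file.
#' @return `decompress_shape()` returns the numeric sample vector of length
#'   `num_samples`. For time shapes the final sample defines the total
#'   duration in raster units.
#' @export
decompress_shape <- function(shape) {
  stopifnot(inherits(shape, "pulseq_shape"))
  n <- shape$num_samples
  data <- shape$data
  if (length(data) == n) return(data)  # literal payload
  if (length(data) > n) stop("shape payload longer than num_samples")
  d <- rle_decode(data, n)
  cumsum(d)
}

rle_decode <- function(data, n) {
  out <- numeric(n)
  j <- 0L
  prev <- NA_real_
  pair <- FALSE
  for (v in data) {
    if (pair) {
      k <- round(v)
      if (k < 0 || j + k > n) stop("malformed shape payload: bad repetition count")
      if (k > 0) out[j + seq_len(k)] <- prev
      j <- j + k
      pair <- FALSE
      prev <- NA_real_
    } else {
      j <- j + 1L
      if (j > n) stop("shape payload expands beyond num_samples")
      out[j] <- v
      if (!is.na(prev) && v == prev) pair <- TRUE else prev <- v
    }
  }
  if (pair) stop("truncated shape payload: repetition count missing")
  if (j != n) stop(sprintf("shape payload expands to %d samples, expected %d", j, n))
  out
}

shape_equal <- function(a, b) {
  a$num_samples == b$num_samples && length(a$data) == length(b$data) &&
    all(a$data == b$data)
}

#' @export
print.pulseq_shape <- function(x, ...) {
  kind <- if (length(x$data) == x$num_samples) "literal" else "compressed"
  cat(sprintf("<pulseq_shape> %d samples, %s payload of %d values\n",
              x$num_samples, kind, length(x$data)))
  invisible(x)
}
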