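#' Hardware profile for sequence validation
#'
#' Gradient, RF and receiver limits of a target system, in the same units the
#' sequence uses (gradient amplitudes in Hz/m, i.e. gamma * G; slew in
#' Hz/m/s). Power limits are expressed on the arbitrary but fixed calibration
#' scale used by [power_report()].
#'
#' @param max_gradient Maximum gradient amplitude per axis (Hz/m).
#' @param max_slew Maximum slew rate per axis (Hz/m/s).
#' @param gradient_raster,rf_raster Hardware time grids (s).
#' @param max_adc_bandwidth Maximum ADC sample rate (Hz).
#' @param peak_power,avg_power Per-channel RF power limits (calibrated W).
#' @param name Optional profile name.
#' @return A `hardware_profile` object.
#' @export
hardware_profile <- function(max_gradient = 1.5e6, max_slew = 8e9,
                             gradient_raster = 1e-5, rf_raster = 1e-6,
                             max_adc_bandwidth = 2e6,
                             peak_power = 3000, avg_power = 20,
                             name = "default") {
  vals <- c(max_gradient, max_slew, gradient_raster, rf_raster,
            max_adc_bandwidth, peak_power, avg_power)
  if (any(vals <= 0)) stop("hardware limits must all be positive")
  structure(list(max_gradient = max_gradient, max_slew = max_slew,
                 gradient_raster = gradient_raster, rf_raster = rf_raster,
                 max_adc_bandwidth = max_adc_bandwidth,
                 peak_power = peak_power, avg_power = avg_power, name = name),
            class = "hardware_profile")
}

#' @export
print.hardware_profile <- function(x, ...) {
  cat(sprintf("<hardware_profile> %s: Gmax %.3g Hz/m, slew %.3g Hz/m/s, grad raster %.3g us, ADC bw %.3g Hz\n",
              x$name, x$max_gradient, x$max_slew, x$gradient_raster * 1e6,
              x$max_adc_bandwidth))
  invisible(x)
}

violation_row <- function(block, event, check, value, limit, severity, message) {
  data.frame(block = block, event = event, check = check, value = value,
             limit = limit, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a sequence against hardware limits
#'
#' Per-block checks mirroring a scanner's pre-scan safety validation:
#' gradient amplitude and slew rate (forward difference over the raster; the
#' first sample slews from zero), ADC bandwidth, arbitrary-gradient raster
#' alignment, and block timing. Violations are report content, not errors; a
#' sequence with any hard violation is flagged `"rejected"`, mirroring the
#' scanner's safe abort. A mismatch between the sequence's gradient raster
#' and the hardware grid yields a `"needs_regrid"` flag (fixable with
#' [regrid_waveform()]).
#'
#' @param doc A `pulseq_seq`.
#' @param hw A `hardware_profile`.
#' @return A `seq_validation` object: `status` ("ok", "needs_regrid" or
#'   "rejected") plus a data frame of violations.
#' @export
validate_sequence <- function(doc, hw = hardware_profile()) {
  stopifnot(inherits(doc, "pulseq_seq"), inherits(hw, "hardware_profile"))
  rasters <- seq_rasters(doc)
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- violation_row(...)

  raster_mismatch <- abs(rasters$grad - hw$gradient_raster) > 1e-12
  for (i in seq_len(nrow(doc$blocks))) {
    b <- doc$blocks[i, ]
    for (col in c("gx", "gy", "gz")) {
      if (b[[col]] == 0) next
      id <- b[[col]]
      ev <- doc$gradients[[as.character(id)]]
      if (is.null(ev)) {
        add(i, paste0(col, ":", id), "reference", NA, NA, "violation",
            "dangling gradient event reference")
        next
      }
      if (ev$kind == "trap") {
        if (abs(ev$amplitude) > hw$max_gradient)
          add(i, paste0(col, ":", id), "gradient_amplitude", abs(ev$amplitude),
              hw$max_gradient, "violation", "trapezoid amplitude exceeds maximum gradient")
        for (leg in c("rise", "fall")) {
          tl <- ev[[leg]]
          if (abs(ev$amplitude) > 0 && tl == 0) {
            add(i, paste0(col, ":", id), "slew_rate", Inf, hw$max_slew,
                "violation", sprintf("instantaneous %s of trapezoid", leg))
          } else if (tl > 0 && abs(ev$amplitude) / tl > hw$max_slew) {
            add(i, paste0(col, ":", id), "slew_rate", abs(ev$amplitude) / tl,
                hw$max_slew, "violation", sprintf("trapezoid %s slew exceeds maximum", leg))
          }
        }
      } else {
        samples <- decompress_shape(doc$shapes[[as.character(ev$shape_id)]])
        wave <- ev$amplitude * samples
        if (max(abs(samples)) > 1 + 1e-9)
          add(i, paste0(col, ":", id), "shape_range", max(abs(samples)), 1,
              "violation", "arbitrary gradient shape outside [-1, 1]")
        if (max(abs(wave)) > hw$max_gradient)
          add(i, paste0(col, ":", id), "gradient_amplitude", max(abs(wave)),
              hw$max_gradient, "violation", "arbitrary gradient exceeds maximum amplitude")
        slew <- max(abs(diff(c(0, wave)))) / rasters$grad
        if (slew > hw$max_slew)
          add(i, paste0(col, ":", id), "slew_rate", slew, hw$max_slew,
              "violation", "arbitrary gradient slew exceeds maximum")
        if (ev$time_id == 0 && raster_mismatch)
          add(i, paste0(col, ":", id), "raster_alignment", rasters$grad,
              hw$gradient_raster, "regrid",
              "arbitrary gradient raster differs from hardware grid; regrid required")
      }
    }
    if (b$adc > 0) {
      ev <- doc$adc[[as.character(b$adc)]]
      if (!is.null(ev) && 1 / ev$dwell > hw$max_adc_bandwidth)
        add(i, paste0("adc:", b$adc), "adc_bandwidth", 1 / ev$dwell,
            hw$max_adc_bandwidth, "violation", "ADC sample rate exceeds maximum bandwidth")
    }
    end <- tryCatch(block_event_end(doc, i), error = function(e) NA_real_)
    if (!is.na(end) && end > b$dur + 1e-9)
      add(i, "block", "block_duration", end, b$dur, "violation",
          "events end after the block duration")
  }

  tab <- if (length(v) > 0) do.call(rbind, v) else
    violation_row(integer(0), character(0), character(0), numeric(0),
                  numeric(0), character(0), character(0))
  status <- if (any(tab$severity == "violation")) "rejected"
            else if (any(tab$severity == "regrid")) "needs_regrid"
            else "ok"
  structure(list(status = status, violations = tab, hw = hw$name),
            class = "seq_validation")
}

#' @export
print.seq_validation <- function(x, ...) {
  cat(sprintf("<seq_validation> status: %s (%d finding(s), hardware profile '%s')\n",
              x$status, nrow(x$violations), x$hw))
  if (nrow(x$violations) > 0) print(x$violations, row.names = FALSE)
  invisible(x)
}

#' Count transmit/receive hardware switch windows
#'
#' Scans the block list in order and coalesces consecutive receive (ADC)
#' activity into single receive windows: a window continues across blocks
#' that contain an ADC or are neutral (neither RF nor ADC), and is broken by
#' a transmit block. This models an interpreter that merges Pulseq blocks and
#' removes per-block dead/ringdown time, so a long readout train needs one
#' receive switch pair instead of one per block. Transmit windows are counted
#' symmetrically.
#'
#' @param doc A `pulseq_seq`.
#' @return A list: `tx_switches` and `rx_switches` (window counts after
#'   coalescing), `rx_raw` (ADC block count = windows without coalescing),
#'   and `coalesced_blocks` (ADC blocks absorbed into an existing window).
#' @export
count_hw_switches <- function(doc) {
  rf_on <- doc$blocks$rf > 0
  adc_on <- doc$blocks$adc > 0
  count_windows <- function(active, breaker) {
    win <- 0L
    open <- FALSE
    for (i in seq_along(active)) {
      if (breaker[i]) open <- FALSE
      if (active[i]) {
        if (!open) win <- win + 1L
        open <- TRUE
      }
    }
    win
  }
  rx <- count_windows(adc_on, rf_on)
  tx <- count_windows(rf_on, adc_on)
  list(tx_switches = tx, rx_switches = rx, rx_raw = sum(adc_on),
       coalesced_blocks = sum(adc_on) - rx)
}
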