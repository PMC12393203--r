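#' Create an empty Pulseq sequence document
#'
#' A `pulseq_seq` is the in-memory model of a Pulseq v1.5.0 file: a block
#' list referencing event tables (RF, gradients, ADC), a shape table, a
#' definitions map, and an optional signature. All internal quantities are SI
#' (seconds, Hz, Hz/m, radians); raster times live in `[DEFINITIONS]`.
#'
#' @param name Optional sequence name stored in the definitions.
#' @param rf_raster,grad_raster,block_raster,adc_raster Raster times in
#'   seconds. Defaults follow common Pulseq usage: RF 1 us, gradient 10 us,
#'   block 10 us, ADC 0.1 us.
#' @return A `pulseq_seq` object.
#' @export
new_seq <- function(name = NULL, rf_raster = 1e-6, grad_raster = 1e-5,
                    block_raster = 1e-5, adc_raster = 1e-7) {
  defs <- list(
    AdcRasterTime = adc_raster,
    BlockDurationRaster = block_raster,
    GradientRasterTime = grad_raster,
    RadiofrequencyRasterTime = rf_raster
  )
  if (!is.null(name)) defs$Name <- name
  structure(list(
    version = c(1L, 5L, 0L),
    definitions = defs,
    blocks = data.frame(dur = numeric(0), rf = integer(0), gx = integer(0),
                        gy = integer(0), gz = integer(0), adc = integer(0),
                        ext = integer(0)),
    rf = list(),
    gradients = list(),
    adc = list(),
    shapes = list(),
    other_sections = list(),
    signature = NULL,
    raw_body = NULL
  ), class = "pulseq_seq")
}

CORE_DEFINITION_KEYS <- c("AdcRasterTime", "BlockDurationRaster",
                          "GradientRasterTime", "RadiofrequencyRasterTime",
                          "FOV", "Name", "TotalDuration")

seq_rasters <- function(doc) {
  d <- doc$definitions
  num1 <- function(key, default) {
    v <- d[[key]]
    if (is.null(v) || !is.numeric(v)) default else v[1]
  }
  list(rf = num1("RadiofrequencyRasterTime", 1e-6),
       grad = num1("GradientRasterTime", 1e-5),
       block = num1("BlockDurationRaster", 1e-5),
       adc = num1("AdcRasterTime", 1e-7))
}

## ---- event constructors -----------------------------------------------

rf_event <- function(amplitude, mag_id, phase_id, time_id = 0L, center = 0,
                     delay = 0, freq_ppm = 0, phase_ppm = 0, freq_offset = 0,
                     phase_offset = 0, use = "u") {
  list(amplitude = amplitude, mag_id = as.integer(mag_id),
       phase_id = as.integer(phase_id), time_id = as.integer(time_id),
       center = center, delay = delay, freq_ppm = freq_ppm,
       phase_ppm = phase_ppm, freq_offset = freq_offset,
       phase_offset = phase_offset, use = use)
}

trap_event <- function(amplitude, rise, flat, fall, delay = 0) {
  if (any(c(rise, flat, fall) < 0)) stop("trapezoid durations must be non-negative")
  list(kind = "trap", amplitude = amplitude, rise = rise, flat = flat,
       fall = fall, delay = delay)
}

grad_event <- function(amplitude, shape_id, time_id = 0L, first = 0, last = 0,
                       delay = 0) {
  list(kind = "grad", amplitude = amplitude, first = first, last = last,
       shape_id = as.integer(shape_id), time_id = as.integer(time_id),
       delay = delay)
}

adc_event <- function(num_samples, dwell, delay = 0, freq_ppm = 0,
                      phase_ppm = 0, freq_offset = 0, phase_offset = 0,
                      phase_id = 0L) {
  if (num_samples * dwell <= 0) stop("ADC must have positive duration")
  list(num_samples = as.integer(num_samples), dwell = dwell, delay = delay,
       freq_ppm = freq_ppm, phase_ppm = phase_ppm, freq_offset = freq_offset,
       phase_offset = phase_offset, phase_id = as.integer(phase_id))
}

## ---- registration helpers (return list(doc, id)) ----------------------
## identical shapes/events are deduplicated via a key map rebuilt lazily,
## so re-adding existing content returns the existing id

shape_key <- function(sh) paste(c(sh$num_samples, sh$data), collapse = " ")

event_key <- function(ev) paste(unlist(ev), collapse = " ")

get_keymap <- function(doc, table, keyfun) {
  km <- doc$keys[[table]]
  if (is.null(km) || length(km) != length(doc[[table]])) {
    km <- vapply(doc[[table]], keyfun, character(1))
    if (length(km) > 0) km <- stats::setNames(names(doc[[table]]), unname(km))
    else km <- character(0)
  }
  km
}

add_shape <- function(doc, samples) {
  sh <- if (inherits(samples, "pulseq_shape")) samples else compress_shape(samples)
  km <- get_keymap(doc, "shapes", shape_key)
  key <- shape_key(sh)
  hit <- unname(km[key])
  if (!is.na(hit)) {
    doc$keys$shapes <- km
    return(list(doc = doc, id = as.integer(hit)))
  }
  id <- length(doc$shapes) + 1L
  doc$shapes[[as.character(id)]] <- sh
  km[[key]] <- as.character(id)
  doc$keys$shapes <- km
  list(doc = doc, id = id)
}

add_event <- function(doc, table, ev) {
  km <- get_keymap(doc, table, event_key)
  key <- event_key(ev)
  hit <- unname(km[key])
  if (!is.na(hit)) {
    doc$keys[[table]] <- km
    return(list(doc = doc, id = as.integer(hit)))
  }
  id <- length(doc[[table]]) + 1L
  doc[[table]][[as.character(id)]] <- ev
  km[[key]] <- as.character(id)
  doc$keys[[table]] <- km
  list(doc = doc, id = id)
}

add_block <- function(doc, dur, rf = 0L, gx = 0L, gy = 0L, gz = 0L,
                      adc = 0L, ext = 0L) {
  rasters <- seq_rasters(doc)
  dur <- round(dur / rasters$block) * rasters$block
  doc$blocks <- rbind(doc$blocks,
                      data.frame(dur = dur, rf = as.integer(rf),
                                 gx = as.integer(gx), gy = as.integer(gy),
                                 gz = as.integer(gz), adc = as.integer(adc),
                                 ext = as.integer(ext)))
  doc
}

## ---- durations and consistency ----------------------------------------

rf_duration <- function(doc, ev) {
  rasters <- seq_rasters(doc)
  if (ev$time_id > 0) {
    t <- decompress_shape(doc$shapes[[as.character(ev$time_id)]])
    t[length(t)] * rasters$rf
  } else {
    doc$shapes[[as.character(ev$mag_id)]]$num_samples * rasters$rf
  }
}

grad_duration <- function(doc, ev) {
  rasters <- seq_rasters(doc)
  if (ev$kind == "trap") return(ev$delay + ev$rise + ev$flat + ev$fall)
  if (ev$time_id > 0) {
    t <- decompress_shape(doc$shapes[[as.character(ev$time_id)]])
    ev$delay + t[length(t)] * rasters$grad
  } else {
    n <- doc$shapes[[as.character(ev$shape_id)]]$num_samples
    ev$delay + n * rasters$grad
  }
}

adc_duration <- function(ev) ev$delay + ev$num_samples * ev$dwell

block_event_end <- function(doc, i) {
  b <- doc$blocks[i, ]
  ends <- 0
  if (b$rf > 0) {
    ev <- doc$rf[[as.character(b$rf)]]
    ends <- max(ends, ev$delay + rf_duration(doc, ev))
  }
  for (col in c("gx", "gy", "gz")) {
    if (b[[col]] > 0) ends <- max(ends, grad_duration(doc, doc$gradients[[as.character(b[[col]])]]))
  }
  if (b$adc > 0) ends <- max(ends, adc_duration(doc$adc[[as.character(b$adc)]]))
  ends
}

# referential integrity and block timing; called before write
check_seq <- function(doc) {
  for (i in seq_len(nrow(doc$blocks))) {
    b <- doc$blocks[i, ]
    if (b$rf > 0 && is.null(doc$rf[[as.character(b$rf)]]))
      stop(sprintf("block %d references missing RF event %d", i, b$rf))
    for (col in c("gx", "gy", "gz")) {
      if (b[[col]] > 0 && is.null(doc$gradients[[as.character(b[[col]])]]))
        stop(sprintf("block %d references missing gradient event %d", i, b[[col]]))
    }
    if (b$adc > 0 && is.null(doc$adc[[as.character(b$adc)]]))
      stop(sprintf("block %d references missing ADC event %d", i, b$adc))
  }
  for (id in names(doc$rf)) {
    ev <- doc$rf[[id]]
    for (f in c("mag_id", "phase_id", "time_id")) {
      sid <- ev[[f]]
      if (sid > 0 && is.null(doc$shapes[[as.character(sid)]]))
        stop(sprintf("RF event %s references missing shape %d", id, sid))
    }
    ns <- function(sid) doc$shapes[[as.character(sid)]]$num_samples
    if (ns(ev$mag_id) != ns(ev$phase_id))
      stop(sprintf("RF event %s: magnitude and phase shapes differ in length", id))
    if (ev$time_id > 0 && ns(ev$time_id) != ns(ev$mag_id))
      stop(sprintf("RF event %s: time shape length differs from magnitude shape", id))
  }
  for (id in names(doc$gradients)) {
    ev <- doc$gradients[[id]]
    if (ev$kind == "grad") {
      for (f in c("shape_id", "time_id")) {
        sid <- ev[[f]]
        if (sid > 0 && is.null(doc$shapes[[as.character(sid)]]))
          stop(sprintf("gradient event %s references missing shape %d", id, sid))
      }
    }
  }
  for (i in seq_len(nrow(doc$blocks))) {
    end <- block_event_end(doc, i)
    if (end > doc$blocks$dur[i] + 1e-9)
      stop(sprintf("block %d duration %.6g s shorter than event end %.6g s",
                   i, doc$blocks$dur[i], end))
  }
  invisible(TRUE)
}

#' Total duration of a sequence in seconds
#' @param doc A `pulseq_seq`.
#' @export
seq_duration <- function(doc) sum(doc$blocks$dur)

#' @export
print.pulseq_seq <- function(x, ...) {
  cat(sprintf("<pulseq_seq> v%s, %d blocks, %d RF / %d gradient / %d ADC events, %d shapes\n",
              paste(x$version, collapse = "."), nrow(x$blocks),
              length(x$rf), length(x$gradients), length(x$adc), length(x$shapes)))
  cat(sprintf("  duration %.4g s; signed: %s\n", seq_duration(x),
              if (is.null(x$signature)) "no" else x$signature$type))
  invisible(x)
}

## ---- semantic equality -------------------------------------------------

num_close <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol * pmax(1, abs(a), abs(b)))
}

defs_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(names(a), names(b))) return(FALSE)
  for (k in names(a)) {
    va <- a[[k]]; vb <- b[[k]]
    if (is.numeric(va) != is.numeric(vb)) return(FALSE)
    ok <- if (is.numeric(va)) num_close(va, vb, tol) else identical(va, vb)
    if (!ok) return(FALSE)
  }
  TRUE
}

events_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(names(a), names(b))) return(FALSE)
  for (id in names(a)) {
    ea <- a[[id]]; eb <- b[[id]]
    if (!setequal(names(ea), names(eb))) return(FALSE)
    for (f in names(ea)) {
      va <- ea[[f]]; vb <- eb[[f]]
      ok <- if (is.numeric(va) && is.numeric(vb)) num_close(va, vb, tol) else identical(va, vb)
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

#' Semantic equality of two sequence documents
#'
#' Compares definitions, blocks, event tables and decoded shapes with a small
#' numeric tolerance (file storage rounds times to integer microseconds and
#' shape samples to the write precision). Signatures and raw text are ignored.
#'
#' @param a,b `pulseq_seq` objects.
#' @param tol Relative numeric tolerance.
#' @export
seq_equal <- function(a, b, tol = 1e-9) {
  if (!defs_equal(a$definitions, b$definitions, tol)) return(FALSE)
  if (nrow(a$blocks) != nrow(b$blocks)) return(FALSE)
  for (col in c("rf", "gx", "gy", "gz", "adc", "ext")) {
    if (!all(a$blocks[[col]] == b$blocks[[col]])) return(FALSE)
  }
  if (!num_close(a$blocks$dur, b$blocks$dur, tol)) return(FALSE)
  if (!events_equal(a$rf, b$rf, tol)) return(FALSE)
  if (!events_equal(a$gradients, b$gradients, tol)) return(FALSE)
  if (!events_equal(a$adc, b$adc, tol)) return(FALSE)
  if (!setequal(names(a$shapes), names(b$shapes))) return(FALSE)
  for (id in names(a$shapes)) {
    sa <- a$shapes[[id]]; sb <- b$shapes[[id]]
    if (sa$num_samples != sb$num_samples) return(FALSE)
    if (!num_close(decompress_shape(sa), decompress_shape(sb), tol)) return(FALSE)
  }
  na <- names(a$other_sections) %||% character(0)
  nb <- names(b$other_sections) %||% character(0)
  identical(a$other_sections[order(na)], b$other_sections[order(nb)])
}

## ---- safety definitions ------------------------------------------------

SAFETY_PREFIX <- "safety_"

#' Store and retrieve safety-prediction results in the definitions header
#'
#' Offline safety predictions (power, SAR proxies, the scanner-specific
#' parameters used in the calculation) are carried inside the sequence file
#' itself, namespaced with a fixed `safety_` prefix so they can never collide
#' with core Pulseq definitions such as the raster times or the FOV.
#'
#' @param doc A `pulseq_seq`.
#' @param report Named list of scalar strings/numbers or numeric vectors.
#' @return `set_safety_definitions()` returns the updated document;
#'   `get_safety_definitions()` returns the stored map with the prefix
#'   stripped, or `NULL` when no safety entries are present (absence is a
#'   result, not an error).
#' @export
set_safety_definitions <- function(doc, report) {
  if (length(report) == 0) return(doc)
  keys <- names(report)
  if (is.null(keys) || any(keys == "")) stop("safety report entries must be named")
  clash <- intersect(keys, CORE_DEFINITION_KEYS)
  if (length(clash) > 0)
    stop("safety keys collide with core Pulseq definitions: ",
         paste(clash, collapse = ", "))
  for (k in keys) doc$definitions[[paste0(SAFETY_PREFIX, k)]] <- report[[k]]
  doc
}

#' @rdname set_safety_definitions
#' @export
get_safety_definitions <- function(doc) {
  keys <- grep(paste0("^", SAFETY_PREFIX), names(doc$definitions), value = TRUE)
  if (length(keys) == 0) return(NULL)
  out <- doc$definitions[keys]
  names(out) <- sub(paste0("^", SAFETY_PREFIX), "", keys)
  out
}
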