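## Pulseq v1.5.0 text reader/writer.
##
## File layout (sections in canonical order on write):
##   [VERSION] [DEFINITIONS] [BLOCKS] [RF] [GRADIENTS] [TRAP] [ADC]
##   <unknown sections, preserved opaquely> [SHAPES] [SIGNATURE]
## Times are stored in integer microseconds (ADC dwell in nanoseconds),
## amplitudes in Hz (RF) / Hz/m (gradients), following the format convention.

fmt_num <- function(x) sprintf("%.10g", x)

us <- function(x) sprintf("%.0f", round(x * 1e6))

write_definitions <- function(defs) {
  lines <- character(0)
  for (k in names(defs)) {
    v <- defs[[k]]
    vstr <- if (is.numeric(v)) paste(fmt_num(v), collapse = " ") else paste(v, collapse = " ")
    lines <- c(lines, paste(k, vstr))
  }
  lines
}

write_body <- function(doc) {
  check_seq(doc)
  rasters <- seq_rasters(doc)
  L <- c("# Pulseq sequence file",
         "# Created by the ptxseq toolbox",
         "",
         "[VERSION]",
         "major 1", "minor 5", "revision 0",
         "")
  L <- c(L, "[DEFINITIONS]", write_definitions(doc$definitions), "")

  if (nrow(doc$blocks) > 0) {
    L <- c(L, "[BLOCKS]", "# NUM DUR RF GX GY GZ ADC EXT")
    b <- doc$blocks
    L <- c(L, sprintf("%d %.0f %d %d %d %d %d %d", seq_len(nrow(b)),
                      round(b$dur / rasters$block), b$rf, b$gx, b$gy, b$gz,
                      b$adc, b$ext), "")
  }

  if (length(doc$rf) > 0) {
    L <- c(L, "[RF]", "# id amp mag_id phase_id time_id center delay freq_ppm phase_ppm freq phase use")
    for (id in names(doc$rf)) {
      e <- doc$rf[[id]]
      L <- c(L, paste(id, fmt_num(e$amplitude), e$mag_id, e$phase_id, e$time_id,
                      fmt_num(e$center * 1e6), us(e$delay), fmt_num(e$freq_ppm),
                      fmt_num(e$phase_ppm), fmt_num(e$freq_offset),
                      fmt_num(e$phase_offset), e$use))
    }
    L <- c(L, "")
  }

  arb <- Filter(function(e) e$kind == "grad", doc$gradients)
  trp <- Filter(function(e) e$kind == "trap", doc$gradients)
  if (length(arb) > 0) {
    L <- c(L, "[GRADIENTS]", "# id amp first last shape_id time_id delay")
    for (id in names(doc$gradients)) {
      e <- doc$gradients[[id]]
      if (e$kind != "grad") next
      L <- c(L, paste(id, fmt_num(e$amplitude), fmt_num(e$first), fmt_num(e$last),
                      e$shape_id, e$time_id, us(e$delay)))
    }
    L <- c(L, "")
  }
  if (length(trp) > 0) {
    L <- c(L, "[TRAP]", "# id amp rise flat fall delay")
    for (id in names(doc$gradients)) {
      e <- doc$gradients[[id]]
      if (e$kind != "trap") next
      L <- c(L, paste(id, fmt_num(e$amplitude), us(e$rise), us(e$flat),
                      us(e$fall), us(e$delay)))
    }
    L <- c(L, "")
  }

  if (length(doc$adc) > 0) {
    L <- c(L, "[ADC]", "# id num dwell delay freq_ppm phase_ppm freq phase phase_id")
    for (id in names(doc$adc)) {
      e <- doc$adc[[id]]
      L <- c(L, paste(id, e$num_samples, sprintf("%.0f", round(e$dwell * 1e9)),
                      us(e$delay), fmt_num(e$freq_ppm), fmt_num(e$phase_ppm),
                      fmt_num(e$freq_offset), fmt_num(e$phase_offset), e$phase_id))
    }
    L <- c(L, "")
  }

  for (sec in names(doc$other_sections)) {
    L <- c(L, paste0("[", sec, "]"), doc$other_sections[[sec]], "")
  }

  if (length(doc$shapes) > 0) {
    L <- c(L, "[SHAPES]", "")
    for (id in names(doc$shapes)) {
      sh <- doc$shapes[[id]]
      L <- c(L, paste("shape_id", id), paste("num_samples", sh$num_samples),
             fmt_num(sh$data), "")
    }
  }
  paste0(paste(L, collapse = "\n"), "\n")
}

md5_of_string <- function(s) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeChar(s, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

#' Write a sequence document as Pulseq v1.5.0 text
#'
#' @param doc A `pulseq_seq` satisfying its invariants (checked).
#' @param file Optional path; when given the text is also written to disk.
#' @param sign Append a `[SIGNATURE]` section with the MD5 hash of the body
#'   (everything preceding the `[SIGNATURE]` line), matching the v1.4+
#'   signature convention. Default `TRUE`.
#' @return The file text, invisibly.
#' @export
write_seq <- function(doc, file = NULL, sign = TRUE) {
  body <- write_body(doc)
  text <- body
  if (sign) {
    hash <- md5_of_string(body)
    text <- paste0(body,
                   "[SIGNATURE]\n",
                   "# This is the hash of the Pulseq file, calculated right before the [SIGNATURE] section was added\n",
                   "# It can be reproduced/verified with md5sum if the file trimmed to the position right above [SIGNATURE]\n",
                   "Type md5\n",
                   "Hash ", hash, "\n")
  }
  if (!is.null(file)) cat(text, file = file)
  invisible(text)
}

#' Compute or verify the signature of a sequence document
#'
#' The hash is computed over the canonical serialized body, excluding the
#' `[SIGNATURE]` section itself. For documents read from disk the raw file
#' text is hashed, so any single-byte tampering with the stored body is
#' detected.
#'
#' @param doc A `pulseq_seq`.
#' @return `compute_signature()` returns `list(type = "md5", hash = ...)`.
#'   `verify_signature()` returns `TRUE` (hash matches), `FALSE` (mismatch),
#'   or `NA` when the document carries no signature ("unsigned" is a status,
#'   not a failure).
#' @export
compute_signature <- function(doc) {
  list(type = "md5", hash = md5_of_string(write_body(doc)))
}

#' @rdname compute_signature
#' @export
verify_signature <- function(doc) {
  if (is.null(doc$signature)) return(NA)
  if (!identical(tolower(doc$signature$type), "md5"))
    stop("unsupported signature type: ", doc$signature$type)
  body <- if (!is.null(doc$raw_body)) doc$raw_body else write_body(doc)
  identical(tolower(md5_of_string(body)), tolower(doc$signature$hash))
}

## ---- reader ------------------------------------------------------------

strip_line <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))

split_sections <- function(lines) {
  lines <- sub("\r$", "", lines)
  hdr <- grep("^\\[[A-Za-z]+\\]\\s*$", lines)
  if (length(hdr) == 0) stop("no Pulseq section headers found")
  out <- list()
  for (i in seq_along(hdr)) {
    name <- sub("^\\[([A-Za-z]+)\\].*$", "\\1", lines[hdr[i]])
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- if (from <= to) lines[from:to] else character(0)
    out[[name]] <- body
  }
  out
}

section_rows <- function(body) {
  body <- strip_line(body)
  body <- body[body != "" & !startsWith(body, "#")]
  lapply(body, function(l) strsplit(l, "\\s+")[[1]])
}

parse_num <- function(tok, what, line) {
  v <- suppressWarnings(as.numeric(tok))
  if (any(is.na(v))) stop(sprintf("cannot parse %s in line: %s", what, line))
  v
}

#' Read a Pulseq sequence file
#'
#' Accepts Pulseq v1.5.x files and tolerates v1.4.x, which is normalized to
#' the v1.5.0 in-memory model (writing always emits v1.5.0). Sections the
#' model does not interpret (e.g. `[EXTENSIONS]`) are preserved opaquely and
#' re-emitted on write.
#'
#' @param x A file path, or the file content as a single string / character
#'   vector of lines.
#' @return A `pulseq_seq` document.
#' @export
read_seq <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  sec <- split_sections(lines)

  if (is.null(sec$VERSION)) stop("missing [VERSION] section")
  vr <- section_rows(sec$VERSION)
  vmap <- list()
  for (r in vr) vmap[[r[1]]] <- as.integer(r[2])
  version <- c(vmap$major, vmap$minor, vmap$revision %||% 0L)
  if (is.null(vmap$major) || is.null(vmap$minor))
    stop("malformed [VERSION] section")
  if (!(version[1] == 1L && version[2] %in% c(4L, 5L)))
    stop(sprintf("unsupported Pulseq version %s", paste(version, collapse = ".")))
  v14 <- version[2] == 4L

  doc <- new_seq()
  doc$definitions <- list()

  if (!is.null(sec$DEFINITIONS)) {
    for (r in section_rows(sec$DEFINITIONS)) {
      key <- r[1]
      vals <- suppressWarnings(as.numeric(r[-1]))
      doc$definitions[[key]] <- if (length(vals) > 0 && !any(is.na(vals))) {
        vals
      } else paste(r[-1], collapse = " ")
    }
  }
  rasters <- seq_rasters(doc)

  if (!is.null(sec$SHAPES)) {
    rows <- section_rows(sec$SHAPES)
    i <- 1L
    while (i <= length(rows)) {
      r <- rows[[i]]
      if (!identical(r[1], "shape_id")) stop("malformed [SHAPES] section")
      id <- as.integer(r[2])
      rn <- rows[[i + 1L]]
      if (!identical(rn[1], "num_samples")) stop("malformed [SHAPES] section")
      nsamp <- as.integer(rn[2])
      i <- i + 2L
      vals <- numeric(0)
      while (i <= length(rows) && !identical(rows[[i]][1], "shape_id")) {
        vals <- c(vals, parse_num(rows[[i]], "shape sample", paste(rows[[i]], collapse = " ")))
        i <- i + 1L
      }
      doc$shapes[[as.character(id)]] <- new_shape(nsamp, vals)
    }
  }

  if (!is.null(sec$RF)) {
    for (r in section_rows(sec$RF)) {
      if (v14) {
        v <- parse_num(r, "RF event", paste(r, collapse = " "))
        doc$rf[[as.character(as.integer(v[1]))]] <- rf_event(
          amplitude = v[2], mag_id = v[3], phase_id = v[4], time_id = v[5],
          center = 0, delay = v[6] * 1e-6, freq_offset = v[7], phase_offset = v[8])
      } else {
        v <- parse_num(r[-length(r)], "RF event", paste(r, collapse = " "))
        doc$rf[[as.character(as.integer(v[1]))]] <- rf_event(
          amplitude = v[2], mag_id = v[3], phase_id = v[4], time_id = v[5],
          center = v[6] * 1e-6, delay = v[7] * 1e-6, freq_ppm = v[8],
          phase_ppm = v[9], freq_offset = v[10], phase_offset = v[11],
          use = r[length(r)])
      }
    }
  }

  if (!is.null(sec$GRADIENTS)) {
    for (r in section_rows(sec$GRADIENTS)) {
      v <- parse_num(r, "gradient event", paste(r, collapse = " "))
      doc$gradients[[as.character(as.integer(v[1]))]] <- if (v14) {
        grad_event(amplitude = v[2], shape_id = v[3], time_id = v[4],
                   delay = v[5] * 1e-6)
      } else {
        grad_event(amplitude = v[2], first = v[3], last = v[4], shape_id = v[5],
                   time_id = v[6], delay = v[7] * 1e-6)
      }
    }
  }

  if (!is.null(sec$TRAP)) {
    for (r in section_rows(sec$TRAP)) {
      v <- parse_num(r, "trapezoid event", paste(r, collapse = " "))
      doc$gradients[[as.character(as.integer(v[1]))]] <- trap_event(
        amplitude = v[2], rise = v[3] * 1e-6, flat = v[4] * 1e-6,
        fall = v[5] * 1e-6, delay = v[6] * 1e-6)
    }
  }

  if (!is.null(sec$ADC)) {
    for (r in section_rows(sec$ADC)) {
      v <- parse_num(r, "ADC event", paste(r, collapse = " "))
      doc$adc[[as.character(as.integer(v[1]))]] <- if (v14) {
        adc_event(num_samples = v[2], dwell = v[3] * 1e-9, delay = v[4] * 1e-6,
                  freq_offset = v[5], phase_offset = v[6])
      } else {
        adc_event(num_samples = v[2], dwell = v[3] * 1e-9, delay = v[4] * 1e-6,
                  freq_ppm = v[5], phase_ppm = v[6], freq_offset = v[7],
                  phase_offset = v[8], phase_id = if (length(v) >= 9) v[9] else 0L)
      }
    }
  }

  if (!is.null(sec$BLOCKS)) {
    for (r in section_rows(sec$BLOCKS)) {
      v <- parse_num(r, "block", paste(r, collapse = " "))
      if (length(v) != 8) stop("malformed block line: ", paste(r, collapse = " "))
      doc <- add_block(doc, dur = v[2] * rasters$block, rf = v[3], gx = v[4],
                       gy = v[5], gz = v[6], adc = v[7], ext = v[8])
    }
  }

  known <- c("VERSION", "DEFINITIONS", "BLOCKS", "RF", "GRADIENTS", "TRAP",
             "ADC", "SHAPES", "SIGNATURE")
  for (name in setdiff(names(sec), known)) {
    body <- sec[[name]]
    while (length(body) > 0 && strip_line(body[length(body)]) == "")
      body <- body[-length(body)]
    doc$other_sections[[name]] <- body
  }

  if (!is.null(sec$SIGNATURE)) {
    sig <- list(type = NULL, hash = NULL)
    for (r in section_rows(sec$SIGNATURE)) {
      if (identical(r[1], "Type")) sig$type <- r[2]
      if (identical(r[1], "Hash")) sig$hash <- r[2]
    }
    if (!is.null(sig$type) && !is.null(sig$hash)) {
      doc$signature <- sig
      idx <- grep("^\\[SIGNATURE\\]\\s*$", sub("\r$", "", lines))[1]
      if (!is.na(idx) && idx > 1) {
        doc$raw_body <- paste0(paste(lines[seq_len(idx - 1L)], collapse = "\n"), "\n")
      }
    }
  }

  doc$version <- c(1L, 5L, 0L)
  check_seq(doc)
  doc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
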