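#' Merge Pulseq excitation blocks into a template sequence
#'
#' Hybrid-sequence support: selected block(s) of a template (typically its
#' excitation) are replaced by the blocks of a Pulseq fragment, leaving every
#' other block, their order and the readout/ADC structure untouched. The
#' fragment's shapes and events are imported into the template's tables
#' (identical content is deduplicated), so replacing a block with itself
#' yields an identical document.
#'
#' @param template A `pulseq_seq` providing the overall sequence structure.
#' @param fragment A `pulseq_seq` whose blocks replace the selected blocks
#'   (e.g. from [make_ktpoints_block()]).
#' @param at Target selector: `list(block = indices)` for explicit block
#'   indices, `list(use = "e")` to select every block whose RF event carries
#'   that use tag, or the string forms `"block=5"` / `"use=e"`.
#' @param hw Optional `hardware_profile`; when given, a fragment that fails
#'   [validate_sequence()] is rejected.
#' @return The merged `pulseq_seq`.
#' @export
merge_excitation <- function(template, fragment, at, hw = NULL) {
  stopifnot(inherits(template, "pulseq_seq"), inherits(fragment, "pulseq_seq"))
  at <- parse_selector(at)
  targets <- if (!is.null(at$block)) {
    idx <- as.integer(at$block)
    if (any(idx < 1 | idx > nrow(template$blocks)))
      stop("block selector outside 1..", nrow(template$blocks))
    idx
  } else {
    found <- integer(0)
    for (i in seq_len(nrow(template$blocks))) {
      rid <- template$blocks$rf[i]
      if (rid > 0 && identical(template$rf[[as.character(rid)]]$use, at$use))
        found <- c(found, i)
    }
    found
  }
  if (length(targets) == 0) stop("selector matched no blocks in the template")

  if (!is.null(hw)) {
    val <- validate_sequence(fragment, hw)
    if (val$status == "rejected")
      stop("fragment violates the hardware profile; merge refused")
  }

  imp <- import_blocks(template, fragment)
  doc <- imp$doc
  rows <- imp$rows

  pieces <- list()
  last <- 0L
  for (tgt in sort(targets)) {
    if (tgt > last + 1L) pieces[[length(pieces) + 1L]] <- doc$blocks[(last + 1L):(tgt - 1L), , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- rows
    last <- tgt
  }
  if (last < nrow(doc$blocks))
    pieces[[length(pieces) + 1L]] <- doc$blocks[(last + 1L):nrow(doc$blocks), , drop = FALSE]
  doc$blocks <- do.call(rbind, pieces)
  rownames(doc$blocks) <- NULL
  doc$signature <- NULL
  doc$raw_body <- NULL
  doc
}

parse_selector <- function(at) {
  if (is.character(at) && length(at) == 1L) {
    kv <- strsplit(at, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("selector string must be 'block=IDX' or 'use=TAG'")
    at <- if (kv[1] == "block") list(block = as.integer(strsplit(kv[2], ",")[[1]]))
          else if (kv[1] == "use") list(use = kv[2])
          else stop("unknown selector key: ", kv[1])
  }
  if (!is.list(at) || is.null(at$block) && is.null(at$use))
    stop("selector must provide $block indices or an RF $use tag")
  at
}

# import every block of `fragment` into `doc`, re-registering shapes and
# events; returns the updated doc and the imported block rows
import_blocks <- function(doc, fragment) {
  shape_map <- integer(0)
  map_shape <- function(sid) {
    if (sid == 0) return(0L)
    key <- as.character(sid)
    if (!is.null(shape_map[key]) && !is.na(shape_map[key])) return(shape_map[[key]])
    r <- add_shape(doc, fragment$shapes[[key]])
    doc <<- r$doc
    shape_map[key] <<- r$id
    r$id
  }
  map_event <- function(table, id) {
    if (id == 0) return(0L)
    ev <- fragment[[table]][[as.character(id)]]
    if (is.null(ev)) stop("fragment block references missing event")
    if (table == "rf") {
      ev$mag_id <- map_shape(ev$mag_id)
      ev$phase_id <- map_shape(ev$phase_id)
      ev$time_id <- map_shape(ev$time_id)
    } else if (table == "gradients" && ev$kind == "grad") {
      ev$shape_id <- map_shape(ev$shape_id)
      ev$time_id <- map_shape(ev$time_id)
    }
    r <- add_event(doc, table, ev)
    doc <<- r$doc
    r$id
  }
  rows <- fragment$blocks
  for (i in seq_len(nrow(rows))) {
    rows$rf[i] <- map_event("rf", rows$rf[i])
    rows$gx[i] <- map_event("gradients", rows$gx[i])
    rows$gy[i] <- map_event("gradients", rows$gy[i])
    rows$gz[i] <- map_event("gradients", rows$gz[i])
    rows$adc[i] <- map_event("adc", rows$adc[i])
  }
  list(doc = doc, rows = rows)
}
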