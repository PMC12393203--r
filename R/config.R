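## Plain-text key/value config files: one `key value...` pair per line,
## `#` comments; numeric values where they parse as numbers.

#' Read and write plain-text configuration files
#'
#' @param file Path to a config file.
#' @return `read_config()` returns a named list; values are numeric vectors
#'   where parseable, strings otherwise.
#' @export
read_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- strip_line(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  out <- list()
  for (l in lines) {
    tok <- strsplit(l, "[= \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[-1]))
    out[[tok[1]]] <- if (length(vals) > 0 && !any(is.na(vals))) vals
                     else paste(tok[-1], collapse = " ")
  }
  out
}

#' @rdname read_config
#' @param cfg Named list of scalar/vector values.
#' @export
write_config <- function(cfg, file) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste(k, paste(if (is.numeric(v)) fmt_num(v) else v, collapse = " "))
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read or write a conversion spec as a config file
#'
#' Keys: `channel_permutation` (optional integer list),
#' `gradient_transform` (9 numbers, row-major), `rf_conjugate`, `b0_flip`
#' (0/1 flags).
#'
#' @param file Path to the config file.
#' @export
read_conversion_spec <- function(file) {
  cfg <- read_config(file)
  gt <- if (is.null(cfg$gradient_transform)) diag(3) else
    matrix(cfg$gradient_transform, 3, 3, byrow = TRUE)
  conversion_spec(channel_permutation = cfg$channel_permutation,
                  gradient_transform = gt,
                  rf_conjugate = isTRUE(cfg$rf_conjugate == 1),
                  b0_flip = isTRUE(cfg$b0_flip == 1))
}

#' @rdname read_conversion_spec
#' @param spec A `conversion_spec`.
#' @export
write_conversion_spec <- function(spec, file) {
  cfg <- list(gradient_transform = as.vector(t(spec$gradient_transform)),
              rf_conjugate = as.integer(spec$rf_conjugate),
              b0_flip = as.integer(spec$b0_flip))
  if (!is.null(spec$channel_permutation))
    cfg$channel_permutation <- spec$channel_permutation
  write_config(cfg, file)
}

#' Read or write a hardware profile as a config file
#' @param file Path to the config file.
#' @export
read_hardware_profile <- function(file) {
  cfg <- read_config(file)
  args <- cfg[intersect(names(cfg), names(formals(hardware_profile)))]
  do.call(hardware_profile, args)
}

#' @rdname read_hardware_profile
#' @param hw A `hardware_profile`.
#' @export
write_hardware_profile <- function(hw, file) {
  write_config(unclass(hw), file)
}
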