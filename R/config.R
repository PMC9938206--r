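#' Read a flat key-value simulation configuration
#'
#' The configuration format is a plain-text file with one section per module
#' and \code{key = value} lines. Values may carry a trailing unit string,
#' which is kept for documentation but not parsed; all physics values are in
#' the display units of \code{\link{pf_params}}. Lines starting with
#' \code{#} are comments.
#'
#' \preformatted{
#' [physics]
#' kappa_B  = 432      J/m^3
#' epsilon  = 0.17     um
#' eta      = 8.0e-12  J/m
#' [grid]
#' n  = 90 90 90
#' dx = 0.17           um
#' [protocol]
#' offset_d      = 0      um
#' speed_v       = 0.57   um/s
#' reversal_time = 1.18   s
#' total_time    = 2.5    s
#' [output]
#' directory = out
#' }
#'
#' @param path path to the configuration file.
#' @param overrides optional character vector of \code{"section.key=value"}
#'   strings applied after reading (the CLI \code{--param} mechanism).
#' @return Nested named list, one element per section; numeric values parsed
#'   where possible (multi-number values become numeric vectors).
#' @export
read_config <- function(path, overrides = character()) {
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    cfg[[section]][[key]] <- parse_config_value(trimws(paste(kv[-1], collapse = "=")))
  }
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([^.=]+)\\.([^=]+)=(.*)$", ov))[[1]]
    if (length(m) != 4) stop("override must look like section.key=value: ", ov)
    cfg[[m[2]]][[trimws(m[3])]] <- parse_config_value(m[4])
  }
  cfg
}

# Numeric tokens at the start of a value are parsed; a trailing unit string
# (or any non-numeric value) is tolerated.
parse_config_value <- function(s) {
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  nums <- suppressWarnings(as.numeric(toks))
  if (length(nums) && !is.na(nums[1])) {
    keep <- cumprod(!is.na(nums)) == 1
    return(nums[keep])
  }
  s
}

#' Build model objects from a configuration list
#'
#' @param cfg list as returned by \code{\link{read_config}}.
#' @return List with \code{params} (\code{\link{pf_params}}), \code{grid}
#'   (\code{\link{grid_spec}}), and \code{protocol}
#'   (\code{\link{collision_protocol}}); sections absent from the file fall
#'   back to package defaults.
#' @export
config_objects <- function(cfg) {
  phys <- cfg$physics %||% list()
  params <- do.call(pf_params, phys)
  g <- cfg$grid %||% list()
  grid <- grid_spec(n = if (!is.null(g$n)) as.integer(g$n) else c(90L, 90L, 90L),
                    dx = g$dx %||% params$internal$epsilon)
  pr <- cfg$protocol %||% list()
  protocol <- collision_protocol(
    offset_d = pr$offset_d %||% 0,
    speed_v = pr$speed_v %||% params$internal$v,
    reversal_time = pr$reversal_time %||% 1.18,
    total_time = pr$total_time %||% 2.5,
    eta = if (!is.null(pr$eta)) pr$eta else params$display$eta)
  list(params = params, grid = grid, protocol = protocol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
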