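## Plain-text I/O: extension traces as CSV with a commented metadata header,
## dwell tables as CSV, and rate-parameter sets as flat key-value JSON/YAML
## (keys are the canonical rate names, see rateVector()).

#' Read and write extension traces
#'
#' Traces are stored as two-column CSV (`time_s`, `extension_nm`) preceded by
#' `#`-prefixed `key: value` header lines carrying the metadata (`mg_mM`,
#' `force_pN`, `amplitude_nm`, `noise_sd_nm`, `rate_hz`, `seed`).
#'
#' @param trace an [ExtensionTrace-class].
#' @param path file path.
#' @return `writeTrace()` returns `path` invisibly; `readTrace()` returns an
#'   [ExtensionTrace-class].
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "ExtensionTrace"))
  md <- trace@metadata
  hdr <- sprintf("# %s: %s", names(md), vapply(md, format, character(1L)))
  writeLines(c(hdr, "time_s,extension_nm",
               sprintf("%.6f,%.6f", trace@time, trace@extension)), path)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  md <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1L]]
    if (length(kv) == 2L)
      md[[kv[1L]]] <- if (grepl("^-?[0-9.eE+-]+$", kv[2L]))
        as.numeric(kv[2L]) else kv[2L]
  }
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!is.null(md$seed)) md$seed <- as.integer(md$seed)
  new("ExtensionTrace", time = dat$time_s, extension = dat$extension_nm,
      metadata = md)
}

#' Read and write dwell tables
#'
#' Dwell tables are CSV with columns `state`, `duration_s`, `mg_mM`,
#' `trace_id`, `boundary`.
#'
#' @param dwells a dwell table data.frame.
#' @param path file path.
#' @return `writeDwells()` returns `path` invisibly; `readDwells()` a
#'   data.frame.
#' @export
writeDwells <- function(dwells, path) {
  stopifnot(all(c("state", "duration_s", "mg_mM", "trace_id", "boundary")
                %in% names(dwells)))
  utils::write.csv(dwells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDwells
#' @export
readDwells <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  dat$boundary <- as.logical(dat$boundary)
  dat
}

#' Read and write rate-parameter sets
#'
#' Parameters are serialized as a flat key-value mapping with keys exactly
#' the canonical rate names (`k_on`, `k_off`, `k_cat`, `k_break0`,
#' `k_form_CC`, `k_form_OC`, `k_gate_open`, `k_gate_close`,
#' `k_gate_close0`), in JSON (`.json`) or YAML (`.yml`/`.yaml`) by file
#' extension.
#'
#' @param params a [RateParameters-class].
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @return `writeRateParameters()` returns `path` invisibly;
#'   `readRateParameters()` a [RateParameters-class].
#' @export
writeRateParameters <- function(params, path) {
  v <- as.list(rateVector(params))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(v, path, precision = 15L)
  } else stop("unsupported parameter-file extension: ", path)
  invisible(path)
}

#' @rdname writeRateParameters
#' @export
readRateParameters <- function(path) {
  v <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else stop("unsupported parameter-file extension: ", path)
  need <- names(rateVector(rateParameters()))
  missing <- setdiff(need, names(v))
  if (length(missing))
    stop("parameter file missing keys: ", paste(missing, collapse = ", "))
  do.call(rateParameters, as.list(unlist(v[need])))
}
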