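#' Read a flat key/value configuration file
#'
#' YAML-style `key: value` lines; `#` starts a comment; values are parsed
#' as numeric when possible, comma-separated values become vectors, and
#' dotted keys (`rkhs.n_kernels: 4`) populate nested lists.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num else parts
    keys <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(keys) == 1) {
      out[[keys]] <- parsed
    } else {
      if (is.null(out[[keys[1]]])) out[[keys[1]]] <- list()
      out[[keys[1]]][[paste(keys[-1], collapse = ".")]] <- parsed
    }
  }
  out
}

#' Write the resolved run configuration next to its outputs
#'
#' Serializes a [run_config] (including the master seed, so any run can
#' be reproduced bit-for-bit) as JSON.
#'
#' @param config a [run_config] or plain list.
#' @param path output path (e.g. `file.path(out_dir, "run_config.json")`).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Build a run_config from a flat option list
#'
#' @param opts named list, e.g. from [read_config] or CLI flags; unknown
#'   keys matching model names become model-specific blocks.
#' @return a [run_config].
#' @export
as_run_config <- function(opts) {
  base <- names(formals(run_config))
  args <- opts[intersect(names(opts), base)]
  do.call(run_config, args)
}
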