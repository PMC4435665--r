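#' Read and write the plain-text sweep interchange format
#'
#' Ladders are exchanged as UTF-8 text. Header lines are `#key=value`
#' (required keys `mode`, `dt_ms`, `units_command`, `units_response`,
#' `n_sweeps`; any other keys round-trip as metadata, with per-protocol keys
#' prefixed `protocol.`). Each sweep follows as a block of
#' `command<TAB>response` rows, blocks separated by one blank line. Values are
#' written with 15 significant digits so doubles round-trip losslessly for
#' analysis purposes.
#'
#' @param ladder A `ladder` (see [make_step_protocol()]).
#' @param path File path.
#' @return `read_sweeps()` returns a `ladder`; `write_sweeps()` returns
#'   `path` invisibly.
#' @export
write_sweeps <- function(ladder, path) {
  p <- ladder$protocol
  units <- sweep_units(p$mode)
  hdr <- c(mode = p$mode, dt_ms = format(p$dt, digits = 15),
           units_command = units$units_command,
           units_response = units$units_response,
           n_sweeps = length(ladder$sweeps),
           protocol.holding = format(p$holding, digits = 15),
           protocol.pre_ms = p$pre_ms, protocol.step_ms = p$step_ms,
           protocol.post_ms = p$post_ms,
           protocol.amplitudes = paste(format(p$amplitudes, digits = 15,
                                              trim = TRUE), collapse = ","))
  if (!is.null(p$prepulse_mV)) {
    hdr <- c(hdr, protocol.prepulse_mV = p$prepulse_mV,
             protocol.prepulse_ms = p$prepulse_ms)
  }
  if (!is.null(p$tail_mV)) {
    hdr <- c(hdr, protocol.tail_mV = p$tail_mV, protocol.tail_ms = p$tail_ms)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", names(hdr), "=", hdr), con)
  for (i in seq_along(ladder$sweeps)) {
    sw <- ladder$sweeps[[i]]
    writeLines(paste(format(sw$command, digits = 15, trim = TRUE),
                     format(sw$response, digits = 15, trim = TRUE),
                     sep = "\t"), con)
    if (i < length(ladder$sweeps)) writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  kv <- regmatches(hdr_lines, regexec("^#([^=]+)=(.*)$", hdr_lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    abort(sprintf("malformed header at line %d.", which(is_hdr)[bad[1]]))
  hdr <- setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  req <- c("mode", "dt_ms", "units_command", "units_response", "n_sweeps")
  miss <- setdiff(req, names(hdr))
  if (length(miss))
    abort(sprintf("missing required header key(s): %s.",
                  paste(miss, collapse = ", ")))
  mode <- hdr[["mode"]]
  if (!mode %in% c("current_clamp", "voltage_clamp"))
    abort(sprintf("unknown mode '%s'.", mode))
  units <- sweep_units(mode)
  if (!identical(hdr[["units_command"]], units$units_command) ||
      !identical(hdr[["units_response"]], units$units_response))
    abort(sprintf(
      "unit mismatch: mode '%s' expects command in %s and response in %s, file declares %s/%s.",
      mode, units$units_command, units$units_response,
      hdr[["units_command"]], hdr[["units_response"]]))
  dt <- as.numeric(hdr[["dt_ms"]])
  n_sweeps <- as.integer(hdr[["n_sweeps"]])

  body <- lines[!is_hdr]
  body_lineno <- which(!is_hdr)
  blank <- body == ""
  block_id <- cumsum(c(TRUE, blank[-length(blank)])) # blanks end a block
  blocks <- split(seq_along(body)[!blank], block_id[!blank])
  if (length(blocks) != n_sweeps)
    abort(sprintf("header declares %d sweeps but file contains %d blocks.",
                  n_sweeps, length(blocks)))

  sweeps <- lapply(blocks, function(idx) {
    parts <- strsplit(body[idx], "\t", fixed = TRUE)
    ragged <- which(lengths(parts) != 2L)
    if (length(ragged))
      abort(sprintf("ragged row (expected 2 tab-separated columns) at line %d.",
                    body_lineno[idx[ragged[1]]]))
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2, byrow = TRUE)
    nonnum <- which(rowSums(is.na(m)) > 0 &
                      !grepl("\tNA$|^NA\t", body[idx]))
    if (length(nonnum))
      abort(sprintf("non-numeric value at line %d.", body_lineno[idx[nonnum[1]]]))
    new_sweep(dt, command = m[, 1], response = m[, 2], mode = mode)
  })

  hget <- function(key) {
    i <- match(key, names(hdr))
    if (is.na(i)) NULL else unname(hdr[i])
  }
  pk <- function(key, default = NULL) {
    v <- hget(paste0("protocol.", key))
    if (is.null(v)) default else as.numeric(v)
  }
  amp_hdr <- hget("protocol.amplitudes")
  amplitudes <- if (!is.null(amp_hdr)) as.numeric(strsplit(amp_hdr, ",")[[1]])
  else vapply(sweeps, function(s) parse_step_command(s)$amplitude, 0)
  protocol <- structure(
    list(holding = pk("holding", sweeps[[1]]$command[1]),
         pre_ms = pk("pre_ms", 0), step_ms = pk("step_ms", 1),
         post_ms = pk("post_ms", 0), amplitudes = amplitudes,
         dt = dt, mode = mode,
         prepulse_mV = pk("prepulse_mV"), prepulse_ms = pk("prepulse_ms", 0),
         tail_mV = pk("tail_mV"), tail_ms = pk("tail_ms", 0)),
    class = "step_protocol")
  new_ladder(protocol, unname(sweeps))
}

#' Read or write a flat key/value configuration file
#'
#' Run configurations (preset names, protocol parameters, seeds, output
#' paths) are stored as plain `key = value` lines; `#` starts a comment.
#' Values that parse as numbers are returned numeric.
#'
#' @param path File path.
#' @param config Named list to write.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L)) abort("malformed config line (expected key = value).")
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, function(m) trimws(m[2]), ""))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(lapply(config, format)), sep = " = "),
             path)
  invisible(path)
}
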