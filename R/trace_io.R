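#' Write and read stopped-flow trace sets as delimited text
#'
#' One file holds a whole trace set. Each trace is a block: `# key=value`
#' metadata lines (wavelength first), a `time_s,absorbance_AU` column
#' header, then CSV rows at full double precision. Blocks are separated by
#' a `# trace` marker line. The round trip preserves values to 1e-12 and
#' all metadata.
#'
#' @param set a `lox_trace_set`
#' @param path output file path
#' @return `read_traces()` returns a `lox_trace_set`.
#' @export
write_traces <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# lox_traces v1", con)
  for (tr in set) {
    writeLines("# trace", con)
    writeLines(sprintf("# wavelength_nm=%s", format(tr$wavelength)), con)
    for (nm in names(tr$meta)) {
      val <- tr$meta[[nm]]
      writeLines(sprintf("# %s=%s", nm,
                         if (is.numeric(val)) formatC(val, format = "g",
                                                      digits = 17) else
                           as.character(val)), con)
    }
    writeLines("time_s,absorbance_AU", con)
    writeLines(paste(formatC(tr$time, format = "g", digits = 17),
                     formatC(tr$absorbance, format = "g", digits = 17),
                     sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# lox_traces v1")
    lox_stop("line 1: not a lox trace file (missing '# lox_traces v1')",
             "lox_parse_error")
  starts <- which(lines == "# trace")
  traces <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    offset <- bounds[i]                      # 1-based line number of '# trace'
    meta_lines <- grep("^# ", block)
    hdr <- which(block == "time_s,absorbance_AU")
    if (length(hdr) != 1)
      lox_stop(sprintf("line %d: trace block lacks 'time_s,absorbance_AU' header",
                       offset), "lox_parse_error")
    meta <- list()
    for (j in meta_lines) {
      kv <- sub("^# ", "", block[j])
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0)
        lox_stop(sprintf("line %d: malformed metadata line '%s'",
                         offset + j, block[j]), "lox_parse_error")
      key <- substr(kv, 1, eq - 1)
      meta[[key]] <- substring(kv, eq + 1)
    }
    data_lines <- if (hdr < length(block))
      block[(hdr + 1L):length(block)] else character(0)
    data_lines <- data_lines[nzchar(data_lines)]
    parts <- strsplit(data_lines, ",", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad) > 0)
      lox_stop(sprintf("line %d: expected two comma-separated values",
                       offset + hdr + bad[1]), "lox_parse_error")
    tt <- as.numeric(vapply(parts, `[`, "", 1L))
    aa <- as.numeric(vapply(parts, `[`, "", 2L))
    if (any(is.na(tt)) || any(is.na(aa)))
      lox_stop(sprintf("line %d: non-numeric value in data row",
                       offset + hdr + which(is.na(tt) | is.na(aa))[1]),
               "lox_parse_error")
    if (length(tt) > 1 && any(diff(tt) <= 0))
      lox_stop(sprintf("line %d: time column is not strictly increasing",
                       offset + hdr + which(diff(tt) <= 0)[1] + 1L),
               "lox_parse_error")
    wl <- as.numeric(meta[["wavelength_nm"]])
    meta[["wavelength_nm"]] <- NULL
    num_keys <- grepl("(_M|_s|^seed)$", names(meta))
    meta[num_keys] <- lapply(meta[num_keys], as.numeric)
    traces[[i]] <- lox_trace(tt, aa, wl, meta)
  }
  lox_trace_set(traces)
}
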