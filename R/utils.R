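# Shared helpers.

# Degenerate-data errors get their own condition class so the CLI can map
# them to exit code 3 (validation errors are exit 2).
stop_degenerate <- function(...) {
  stop(structure(class = c("sumoscreen_degenerate", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Minimal key-value config reader: "key = value" or "key value" lines,
# '#' comments. Values are left as strings; callers coerce.
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[= ]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    out[[m[[2L]]]] <- trimws(m[[3L]])
  }
  out
}
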