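# Shared internal helpers: classed conditions, atomic file writes, path splitting.

#' @keywords internal
stop_exdirr <- function(subclass, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(subclass, "exdirr_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Write text to `path` atomically: temp file in the same directory, then rename.
# Rename within one directory is the portable atomic primitive, so readers never
# observe a half-written metadata file.
write_text_atomic <- function(path, text) {
  dir <- dirname(path)
  tmp <- tempfile(pattern = ".exdirr-tmp-", tmpdir = dir)
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeBin(charToRaw(enc2utf8(text)), con)
    ok <- TRUE
  }, finally = close(con))
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    stop_exdirr("exdirr_io_error", sprintf("failed to write '%s'", path))
  }
  invisible(path)
}

read_text_utf8 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  txt
}

# Split a "/"-separated relative path into components, rejecting empty
# components, "." and "..".  A leading "/" is tolerated (name-style input).
split_path <- function(path) {
  if (!is_string(path)) {
    stop_exdirr("exdirr_invalid_name", "object path must be a single string")
  }
  path <- sub("^/", "", path)
  if (path == "") return(character(0))
  comps <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (any(comps == "" | comps == "." | comps == "..")) {
    stop_exdirr("exdirr_invalid_name",
                sprintf("invalid path '%s': empty, '.' or '..' components are not allowed", path))
  }
  comps
}

# Lexicographic-by-code-point sort, independent of the session locale.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
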