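# NPY binary array storage: v1.0 writer, v1.0/v2.0 reader, sliced access.
#
# Dataset payloads are stored C-contiguous and little-endian in `data.npy`.
# The reader parses only the header on open; slice reads seek to the byte
# ranges a selection covers instead of loading the whole payload.
#
# R-side element types: float32/64 -> double; int8/16/32, uint8/16 -> integer;
# int64, uint32, uint64 -> double (exact for magnitudes below 2^53);
# bool -> logical; |S / <U fixed-width strings -> character.

NPY_MAGIC <- as.raw(c(0x93, 0x4E, 0x55, 0x4D, 0x50, 0x59))

parse_descr <- function(descr) {
  if (!is_string(descr)) stop_exdirr("exdirr_unsupported_dtype", "dtype descriptor must be a string")
  if (grepl("^\\[", descr) || grepl("^\\(", descr)) {
    stop_exdirr("exdirr_unsupported_dtype",
                sprintf("structured/record dtypes are not supported: %s", descr))
  }
  m <- regmatches(descr, regexec("^([<>|=]?)([a-zA-Z])([0-9]+)$", descr))[[1]]
  if (length(m) == 0L) {
    stop_exdirr("exdirr_unsupported_dtype", sprintf("unsupported dtype descriptor '%s'", descr))
  }
  order <- m[2]; kind <- m[3]; size <- as.integer(m[4])
  endian <- switch(order, ">" = "big", "little")
  itemsize <- size
  valid <- switch(kind,
    f = size %in% c(4L, 8L),
    i = size %in% c(1L, 2L, 4L, 8L),
    u = size %in% c(1L, 2L, 4L, 8L),
    b = size == 1L,
    S = size >= 1L,
    U = size >= 1L,
    FALSE)
  if (!isTRUE(valid)) {
    stop_exdirr("exdirr_unsupported_dtype", sprintf("unsupported dtype descriptor '%s'", descr))
  }
  if (kind == "U") itemsize <- 4L * size
  norm_order <- if (kind %in% c("b") || (kind %in% c("i", "u", "S") && size == 1L)) "|" else "<"
  list(descr = paste0(norm_order, kind, size), kind = kind, size = size,
       itemsize = itemsize, endian = endian)
}

# numpy-style name ("float64") for display
dtype_name <- function(dt) {
  switch(dt$kind,
    f = paste0("float", dt$size * 8L),
    i = paste0("int", dt$size * 8L),
    u = paste0("uint", dt$size * 8L),
    b = "bool",
    S = sprintf("bytes%d", dt$size),
    U = sprintf("str%d", dt$size))
}

infer_descr <- function(values) {
  if (is.double(values)) return("<f8")
  if (is.integer(values)) return("<i4")
  if (is.logical(values)) return("|b1")
  if (is.character(values)) {
    width <- max(1L, if (length(values)) max(nchar(values, type = "bytes")) else 1L)
    return(sprintf("|S%d", width))
  }
  stop_exdirr("exdirr_unsupported_dtype",
              sprintf("cannot store values of type '%s'", typeof(values)))
}

zero_value <- function(dt) {
  switch(dt$kind, f = 0, i = if (dt$size == 8L) 0 else 0L,
         u = if (dt$size >= 4L) 0 else 0L, b = FALSE, S = "", U = "")
}

# ---- 64-bit integer <-> raw (R doubles; exact within 2^53) ------------------

decode64 <- function(raw, signed, endian) {
  n <- length(raw) %/% 8L
  m <- matrix(as.numeric(raw), nrow = 8L)
  if (endian == "big") m <- m[8:1, , drop = FALSE]
  lo <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536 + m[4, ] * 16777216
  hi <- m[5, ] + m[6, ] * 256 + m[7, ] * 65536 + m[8, ] * 16777216
  if (signed) hi <- ifelse(hi >= 2^31, hi - 2^32, hi)
  hi * 2^32 + lo
}

encode64 <- function(v) {
  v <- as.double(v)
  hi_s <- floor(v / 2^32)
  lo <- v - hi_s * 2^32
  hi <- hi_s %% 2^32
  m <- rbind(lo %% 256, (lo %/% 256) %% 256, (lo %/% 65536) %% 256, (lo %/% 16777216) %% 256,
             hi %% 256, (hi %/% 256) %% 256, (hi %/% 65536) %% 256, (hi %/% 16777216) %% 256)
  as.raw(as.integer(m))
}

# ---- typed stream I/O -------------------------------------------------------

read_typed <- function(con, n, dt) {
  e <- dt$endian
  k <- dt$kind; sz <- dt$size
  if (n == 0L) {
    return(switch(k, f = double(0), b = logical(0), S = character(0), U = character(0),
                  i = if (sz == 8L) double(0) else integer(0),
                  u = if (sz >= 4L) double(0) else integer(0)))
  }
  if (k == "f") return(readBin(con, "double", n, size = sz, endian = e))
  if (k == "i" && sz <= 4L) return(readBin(con, "integer", n, size = sz, signed = TRUE, endian = e))
  if (k == "u" && sz <= 2L) return(readBin(con, "integer", n, size = sz, signed = FALSE, endian = e))
  if (k == "u" && sz == 4L) {
    # byte math: readBin("integer") maps 0x80000000 to NA (R has no INT_MIN)
    m <- matrix(as.numeric(readBin(con, "raw", n * 4L)), nrow = 4L)
    if (e == "big") m <- m[4:1, , drop = FALSE]
    return(m[1, ] + m[2, ] * 256 + m[3, ] * 65536 + m[4, ] * 16777216)
  }
  if (k %in% c("i", "u") && sz == 8L) {
    return(decode64(readBin(con, "raw", n * 8L), signed = (k == "i"), endian = e))
  }
  if (k == "b") return(as.integer(readBin(con, "raw", n)) != 0L)
  if (k == "S") {
    raw <- readBin(con, "raw", n * sz)
    return(vapply(seq_len(n), function(i) {
      chunk <- raw[((i - 1L) * sz + 1L):(i * sz)]
      nul <- which(chunk == as.raw(0))
      if (length(nul)) chunk <- chunk[seq_len(nul[1] - 1L)]
      if (!length(chunk)) "" else { s <- rawToChar(chunk); Encoding(s) <- "UTF-8"; s }
    }, ""))
  }
  if (k == "U") {
    cp <- readBin(con, "integer", n * sz, size = 4L, endian = e)
    return(vapply(seq_len(n), function(i) {
      chunk <- cp[((i - 1L) * sz + 1L):(i * sz)]
      chunk <- chunk[chunk != 0L]
      if (!length(chunk)) "" else intToUtf8(chunk)
    }, ""))
  }
  stop_exdirr("exdirr_unsupported_dtype", dt$descr)
}

write_typed <- function(con, vals, dt) {
  k <- dt$kind; sz <- dt$size
  if (length(vals) == 0L) return(invisible())
  if (k == "f") return(writeBin(as.double(vals), con, size = sz, endian = "little"))
  if (k == "i" && sz <= 4L) return(writeBin(as.integer(vals), con, size = sz, endian = "little"))
  if (k == "u" && sz == 1L) return(writeBin(as.raw(as.integer(vals)), con))
  if (k == "u" && sz == 2L) {
    v <- as.double(vals); v[v >= 2^15] <- v[v >= 2^15] - 2^16
    return(writeBin(as.integer(v), con, size = 2L, endian = "little"))
  }
  if (k == "u" && sz == 4L) {
    v <- as.double(vals)
    m <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               (v %/% 16777216) %% 256)
    return(writeBin(as.raw(as.integer(m)), con))
  }
  if (k %in% c("i", "u") && sz == 8L) return(writeBin(encode64(vals), con))
  if (k == "b") return(writeBin(as.raw(as.logical(vals)), con))
  if (k == "S") {
    raw <- raw(length(vals) * sz)
    for (i in seq_along(vals)) {
      b <- charToRaw(enc2utf8(vals[i]))
      if (length(b) > sz) stop_exdirr("exdirr_unsupported_value",
                                      sprintf("string wider than |S%d field", sz))
      if (length(b)) raw[((i - 1L) * sz + 1L):((i - 1L) * sz + length(b))] <- b
    }
    return(writeBin(raw, con))
  }
  if (k == "U") {
    cp <- integer(length(vals) * sz)
    for (i in seq_along(vals)) {
      u <- utf8ToInt(enc2utf8(vals[i]))
      if (length(u) > sz) stop_exdirr("exdirr_unsupported_value",
                                      sprintf("string wider than <U%d field", sz))
      if (length(u)) cp[((i - 1L) * sz + 1L):((i - 1L) * sz + length(u))] <- u
    }
    return(writeBin(cp, con, size = 4L, endian = "little"))
  }
  stop_exdirr("exdirr_unsupported_dtype", dt$descr)
}

# ---- header -----------------------------------------------------------------

npy_header_build <- function(descr, shape) {
  shape_str <- if (length(shape) == 0L) "()"
  else if (length(shape) == 1L) sprintf("(%d,)", shape)
  else sprintf("(%s)", paste(shape, collapse = ", "))
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                  descr, shape_str)
  total <- 10L + nchar(dict) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")
  c(NPY_MAGIC, as.raw(c(1L, 0L)),
    writeBin(nchar(header), raw(), size = 2L, endian = "little")[1:2],
    charToRaw(header))
}

npy_header_parse <- function(con, path = "<connection>") {
  head <- readBin(con, "raw", 8L)
  if (length(head) < 8L || !identical(head[1:6], NPY_MAGIC)) {
    stop_exdirr("exdirr_not_npy", sprintf("'%s' is not an NPY file (bad magic)", path))
  }
  major <- as.integer(head[7])
  if (major == 1L) {
    hl <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
    offset <- 10L + hl
  } else if (major == 2L) {
    hl <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    offset <- 12L + hl
  } else {
    stop_exdirr("exdirr_not_npy", sprintf("unsupported NPY version %d in '%s'", major, path))
  }
  header <- rawToChar(readBin(con, "raw", hl))
  get1 <- function(pat) {
    m <- regmatches(header, regexec(pat, header))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  descr <- get1("'descr'\\s*:\\s*['\"]([^'\"]+)['\"]")
  fortran <- get1("'fortran_order'\\s*:\\s*(True|False)")
  shape_s <- get1("'shape'\\s*:\\s*\\(([^)]*)\\)")
  if (is.na(descr) || is.na(fortran) || is.na(shape_s)) {
    if (grepl("'descr'\\s*:\\s*\\[", header)) {
      stop_exdirr("exdirr_unsupported_dtype",
                  sprintf("structured dtype in '%s' is not supported", path))
    }
    stop_exdirr("exdirr_not_npy", sprintf("malformed NPY header in '%s'", path))
  }
  parts <- strsplit(shape_s, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  shape <- as.integer(parts)
  if (anyNA(shape)) stop_exdirr("exdirr_not_npy", sprintf("bad shape in '%s'", path))
  list(dt = parse_descr(descr), fortran = identical(fortran, "True"),
       shape = shape, data_offset = as.double(offset))
}

# ---- public-ish layer (used by the Dataset object and the linter) -----------

#' Write an array as an NPY v1.0 file
#'
#' The file is written atomically (temp file + rename), C-contiguous and
#' little-endian, with the header padded so the payload starts on a 64-byte
#' boundary.
#'
#' @param path Destination file path.
#' @param values Numeric, logical or character vector/array.
#' @param dtype Optional dtype descriptor (e.g. `"<f8"`, `"<i2"`, `"|b1"`);
#'   inferred from `values` when omitted.
#' @param shape Optional extent vector overriding `dim(values)`/`length(values)`;
#'   `integer(0)` stores a 0-d scalar.
#' @return The path, invisibly.
#' @export
npy_write <- function(path, values, dtype = NULL, shape = NULL) {
  dt <- parse_descr(dtype %||% infer_descr(values))
  shape <- as.integer(shape %||% (dim(values) %||% length(values)))
  if (any(shape < 0L)) stop_exdirr("exdirr_invalid_shape", "negative extents")
  n <- if (length(shape) == 0L) 1L else prod(shape)
  if (length(values) != n) {
    stop_exdirr("exdirr_inconsistent",
                sprintf("data length %d does not match shape (%s)",
                        length(values), paste(shape, collapse = ", ")))
  }
  if (is.array(values) && length(dim(values)) > 1L) {
    values <- as.vector(aperm(values, rev(seq_along(dim(values)))))  # C order
  } else {
    values <- as.vector(values)
  }
  dir <- dirname(path)
  tmp <- tempfile(pattern = ".exdirr-npy-", tmpdir = dir)
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeBin(npy_header_build(dt$descr, shape), con)
    write_typed(con, values, dt)
    ok <- TRUE
  }, finally = close(con))
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    stop_exdirr("exdirr_io_error", sprintf("failed to write '%s'", path))
  }
  invisible(path)
}

#' Open an NPY file without reading its payload
#'
#' Parses the header only; the returned handle records shape, dtype and the
#' payload offset.  A payload shorter than `prod(shape) * itemsize` raises a
#' corrupt-dataset error at open time, so corruption is detected and contained
#' to the one file.
#'
#' @param path An NPY file (versions 1.0 and 2.0 accepted).
#' @param mode `"read_only"` or `"read_write"`.
#' @return An object of class `npy_handle` with fields `shape`, `descr`, etc.
#' @export
npy_open <- function(path, mode = c("read_only", "read_write")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_exdirr("exdirr_not_found", sprintf("no such file '%s'", path))
  con <- file(path, open = "rb")
  hdr <- tryCatch(npy_header_parse(con, path), finally = close(con))
  n <- if (length(hdr$shape) == 0L) 1 else prod(as.double(hdr$shape))
  have <- file.info(path)$size - hdr$data_offset
  if (have < n * hdr$dt$itemsize) {
    stop_exdirr("exdirr_corrupt",
                sprintf("'%s': payload holds %.0f bytes but header promises %.0f",
                        path, have, n * hdr$dt$itemsize))
  }
  structure(list(path = path, mode = mode, dt = hdr$dt, shape = hdr$shape,
                 n = n, fortran = hdr$fortran, data_offset = hdr$data_offset),
            class = "npy_handle")
}

#' @export
print.npy_handle <- function(x, ...) {
  cat(sprintf("<npy %s shape (%s) %s %s>\n", x$dt$descr,
              paste(x$shape, collapse = ", "), x$mode, x$path))
  invisible(x)
}

# Full payload read -> R vector/array in natural (column-major) R layout.
#' @rdname npy_open
#' @param handle An `npy_handle` or a path.
#' @export
npy_read <- function(handle) {
  if (is.character(handle)) handle <- npy_open(handle)
  con <- file(handle$path, open = "rb")
  vals <- tryCatch({
    seek(con, handle$data_offset)
    read_typed(con, handle$n, handle$dt)
  }, finally = close(con))
  shape_values(vals, handle$shape, handle$fortran)
}

shape_values <- function(vals, shape, fortran = FALSE) {
  if (length(shape) <= 1L) return(vals)
  if (fortran) return(array(vals, dim = shape))
  aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
}

# element strides (in elements) of the on-disk layout, per R axis
elem_strides <- function(shape, fortran) {
  nd <- length(shape)
  if (nd == 0L) return(integer(0))
  if (fortran) cumprod(c(1, shape))[seq_len(nd)]
  else rev(cumprod(c(1, rev(shape))))[-1]
}

# 0-based flat offsets of a selection, in result (column-major) order
selection_offsets <- function(handle, indices) {
  shape <- handle$shape
  nd <- length(shape)
  if (length(indices) != nd) {
    stop_exdirr("exdirr_index_error",
                sprintf("selection has %d axes; dataset has %d", length(indices), nd))
  }
  if (nd == 0L) return(list(off = 0, lens = integer(0)))
  strides <- elem_strides(shape, handle$fortran)
  contrib <- vector("list", nd)
  for (k in seq_len(nd)) {
    idx <- indices[[k]]
    if (anyNA(idx) || (length(idx) && (min(idx) < 1L || max(idx) > shape[k]))) {
      stop_exdirr("exdirr_index_error",
                  sprintf("index out of bounds on axis %d (extent %d)", k, shape[k]))
    }
    contrib[[k]] <- (as.double(idx) - 1) * strides[k]
  }
  off <- contrib[[1]]
  if (nd > 1L) for (k in 2:nd) off <- outer(off, contrib[[k]], `+`)
  list(off = as.vector(off), lens = vapply(indices, length, 1L))
}

# Group sorted offsets into maximal contiguous runs; fall back to one spanning
# read/write when the selection is too fragmented for per-run seeks to pay off.
MAX_IO_RUNS <- 4096L

#' Read a rectangular/fancy selection from an NPY file
#'
#' `indices` is a list with one integer vector per axis (1-based, in-range,
#' arbitrary order and repetition — "fancy" selections included); `NULL` for an
#' axis selects it fully.  Only the byte ranges covered by the selection are
#' read.
#'
#' @param handle An `npy_handle`.
#' @param indices List of per-axis integer vectors (or `NULL`s).
#' @return An array of extents `lengths(indices)` (no dimension dropping).
#' @export
npy_read_slice <- function(handle, indices) {
  indices <- complete_indices(handle, indices)
  sel <- selection_offsets(handle, indices)
  off <- sel$off
  if (length(off) == 0L) {
    vals <- read_typed(NULL, 0L, handle$dt)
    return(array(vals, dim = sel$lens))
  }
  ord <- order(off)
  soff <- off[ord]
  runs <- run_starts(soff)
  con <- file(handle$path, open = "rb")
  sorted_vals <- tryCatch({
    if (length(runs$start) > MAX_IO_RUNS) {
      lo <- soff[1]; hi <- soff[length(soff)]
      seek(con, handle$data_offset + lo * handle$dt$itemsize)
      block <- read_typed(con, as.integer(hi - lo + 1), handle$dt)
      block[soff - lo + 1]
    } else {
      parts <- vector("list", length(runs$start))
      for (i in seq_along(runs$start)) {
        seek(con, handle$data_offset + soff[runs$start[i]] * handle$dt$itemsize)
        parts[[i]] <- read_typed(con, runs$len[i], handle$dt)
      }
      unlist(parts, use.names = FALSE)
    }
  }, finally = close(con))
  vals <- sorted_vals
  vals[ord] <- sorted_vals
  if (length(sel$lens) == 0L) vals else array(vals, dim = sel$lens)
}

run_starts <- function(sorted_off) {
  d <- diff(sorted_off)
  brk <- which(d != 1)
  start <- c(1L, brk + 1L)
  end <- c(brk, length(sorted_off))
  list(start = start, len = end - start + 1L)
}

#' Write values into a selection of an NPY file
#'
#' Values are recycled to the selection size when their length divides it
#' evenly (R-style recycling); otherwise a broadcast error is raised.  A
#' subsequent [npy_open()] + read observes the new bytes.
#'
#' @inheritParams npy_read_slice
#' @param values Replacement values.
#' @export
npy_write_slice <- function(handle, indices, values) {
  if (handle$mode != "read_write") {
    stop_exdirr("exdirr_read_only", sprintf("'%s' opened read-only", handle$path))
  }
  indices <- complete_indices(handle, indices)
  sel <- selection_offsets(handle, indices)
  off <- sel$off
  nsel <- length(off)
  values <- if (is.array(values) && length(dim(values)) > 1L) {
    # caller passes values in result layout; flatten column-major to match off
    as.vector(values)
  } else as.vector(values)
  if (nsel == 0L) return(invisible(handle))
  if (length(values) == 0L || nsel %% length(values) != 0L) {
    stop_exdirr("exdirr_broadcast_error",
                sprintf("cannot broadcast %d values into a selection of %d elements",
                        length(values), nsel))
  }
  values <- rep_len(values, nsel)
  ord <- order(off)
  soff <- off[ord]
  if (anyDuplicated(soff)) {              # duplicate fancy indices: last write wins
    keep <- !duplicated(soff, fromLast = TRUE)
    soff <- soff[keep]
    svals <- (values[ord])[keep]
  } else {
    svals <- values[ord]
  }
  runs <- run_starts(soff)
  con <- file(handle$path, open = "r+b")
  tryCatch({
    for (i in seq_along(runs$start)) {
      s <- runs$start[i]
      seek(con, handle$data_offset + soff[s] * handle$dt$itemsize, rw = "write")
      write_typed(con, svals[s:(s + runs$len[i] - 1L)], handle$dt)
    }
  }, finally = close(con))
  invisible(handle)
}

complete_indices <- function(handle, indices) {
  nd <- length(handle$shape)
  if (is.null(indices)) indices <- vector("list", nd)
  if (length(indices) != nd) {
    stop_exdirr("exdirr_index_error",
                sprintf("selection has %d axes; dataset has %d", length(indices), nd))
  }
  for (k in seq_len(nd)) {
    if (is.null(indices[[k]])) indices[[k]] <- seq_len(handle$shape[k])
  }
  indices
}
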