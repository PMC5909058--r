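# Dataset objects: creation and sliced read/write access.

data_path <- function(obj) file.path(obj_dir(obj), "data.npy")

dataset_handle <- function(dset, mode = NULL) {
  assert_live(dset)
  mode <- mode %||% if (dset$config$mode == "read_write") "read_write" else "read_only"
  npy_open(data_path(dset), mode)
}

#' Create a Dataset
#'
#' A dataset directory holds an `exdir.yaml` with the `dataset` tag and the
#' array payload in `data.npy`.  The array is determined either by `data`, or
#' by `shape` (zero-filled, dtype `"<f8"` unless given).  When `data` is
#' supplied, dataset-targeted plugin `prepare_write` hooks run first; any
#' attributes they produce are written to `attributes.yaml`, and plugin markers
#' to the metadata file.
#'
#' @param parent A File or Group handle.
#' @param name Object name (validated by the File's policy).
#' @param shape Optional extent vector (`integer(0)` for a 0-d scalar).
#' @param dtype Optional NPY dtype descriptor such as `"<f8"`, `"<i4"`, `"|b1"`.
#' @param data Optional array/vector, or a value a plugin can convert (for
#'   example an [exdir_quantity()] under the quantity plugin).
#' @return The new Dataset handle.
#' @export
#' @examples
#' f <- exdir_open(file.path(tempdir(), "ex2.exdir"), "w")
#' d <- create_dataset(f, "mydata", data = c(1, 2, 3))
#' d[2:3]
create_dataset <- function(parent, name, shape = NULL, dtype = NULL, data = NULL) {
  assert_live(parent)
  assert_writable(parent)
  if (is.null(shape) && is.null(data)) {
    stop_exdirr("exdirr_missing_spec", "one of `shape` or `data` must be given")
  }
  attrs <- NULL
  plugins_meta <- NULL
  if (!is.null(data)) {
    dd <- apply_write_chain(parent$config$plugins, data)
    data <- dd$data
    if (!is.atomic(data) || is.null(data)) {
      stop_exdirr("exdirr_unsupported_value",
                  "data is not storable after plugin processing")
    }
    if (length(dd$attrs)) attrs <- dd$attrs
    if (length(dd$meta)) plugins_meta <- dd$meta
    dshape <- dim(data) %||% length(data)
    if (!is.null(shape)) {
      if (prod(as.integer(shape)) != prod(as.integer(dshape))) {
        stop_exdirr("exdirr_inconsistent",
                    sprintf("shape (%s) inconsistent with data extents (%s)",
                            paste(shape, collapse = ", "), paste(dshape, collapse = ", ")))
      }
    } else {
      shape <- dshape
    }
  } else {
    dtype <- dtype %||% "<f8"
    dt <- parse_descr(dtype)
    n <- if (length(shape) == 0L) 1L else prod(as.integer(shape))
    data <- rep(zero_value(dt), n)
  }
  dset <- create_child(parent, name, "dataset")
  dir <- obj_dir(dset)
  ok <- FALSE
  tryCatch({
    npy_write(file.path(dir, "data.npy"), data, dtype = dtype, shape = shape)
    if (!is.null(plugins_meta)) write_object_meta(dir, "dataset", plugins_meta)
    if (!is.null(attrs)) write_text_atomic(file.path(dir, "attributes.yaml"),
                                           emit_restricted(attrs))
    ok <- TRUE
  }, finally = if (!ok) unlink(dir, recursive = TRUE))
  dset
}

#' Shape and dtype of a Dataset
#'
#' Both are read from the NPY header of `data.npy`; the payload is not loaded.
#'
#' @param dset A Dataset handle.
#' @return `exdir_shape()`: integer vector of extents (length 0 for a 0-d
#'   scalar); `exdir_dtype()`: the dtype descriptor string.
#' @export
exdir_shape <- function(dset) dataset_handle(dset, "read_only")$shape

#' @rdname exdir_shape
#' @export
exdir_dtype <- function(dset) dataset_handle(dset, "read_only")$dt$descr

#' Full dataset value, after plugin post-processing
#'
#' Reads the whole payload plus the object's attributes and runs the
#' `prepare_read` hooks of whichever plugins stamped the object at write time
#' (objects without plugin markers are returned as plain arrays).
#'
#' @param dset A Dataset handle.
#' @return The reconstructed value (plain array when no plugin applies).
#' @export
exdir_data <- function(dset) {
  h <- dataset_handle(dset, "read_only")
  vals <- npy_read(h)
  markers <- read_object_meta(obj_dir(dset))$plugins
  apply_read_chain(dset$config$plugins, vals, exdir_attrs(dset), markers)
}

# Translate `[`-style arguments into per-axis index vectors (NULL = full
# axis).  R index semantics apply per axis: negative drops, logical recycles.
normalize_axis_index <- function(arg, extent, axis) {
  if (is.null(arg)) return(NULL)
  idx <- tryCatch(seq_len(extent)[arg], error = function(e) {
    stop_exdirr("exdirr_index_error", sprintf("bad index on axis %d", axis))
  })
  if (anyNA(idx)) {
    stop_exdirr("exdirr_index_error",
                sprintf("index out of bounds on axis %d (extent %d)", axis, extent))
  }
  as.integer(idx)
}

gather_index_args <- function(call_args, env) {
  lapply(call_args, function(a) {
    if (identical(a, quote(expr = ))) NULL else eval(a, env)
  })
}

#' @export
`[.exdir_dataset` <- function(x, ..., drop = TRUE) {
  h <- dataset_handle(x, "read_only")
  call_args <- as.list(sys.call())[-(1:2)]
  call_args$drop <- NULL
  args <- gather_index_args(call_args, parent.frame())
  nd <- length(h$shape)
  if (length(args) == 0L) return(npy_read(h))
  if (length(args) == 1L && nd != 1L) {
    if (is.null(args[[1]])) return(npy_read(h))        # x[] -> full read
    return(flat_read(h, args[[1]]))
  }
  if (length(args) != nd) {
    stop_exdirr("exdirr_index_error",
                sprintf("selection has %d axes; dataset has %d", length(args), nd))
  }
  idx <- mapply(normalize_axis_index, args, h$shape, seq_len(nd), SIMPLIFY = FALSE)
  res <- npy_read_slice(h, idx)
  if (nd <= 1L) res <- as.vector(res)       # vectors never carry a dim in R
  else if (drop) res <- drop(res)
  res
}

# Flat (vector-style) indexing of an n-d dataset, column-major like R.
flat_read <- function(h, arg) {
  n_total <- h$n
  flat <- tryCatch(seq_len(n_total)[arg], error = function(e) {
    stop_exdirr("exdirr_index_error", "bad flat index")
  })
  if (anyNA(flat)) stop_exdirr("exdirr_index_error", "flat index out of bounds")
  coords <- arrayInd(flat, .dim = h$shape)
  strides <- elem_strides(h$shape, h$fortran)
  off <- as.vector((coords - 1) %*% strides)
  read_offsets(h, off)
}

read_offsets <- function(h, off) {
  if (length(off) == 0L) return(read_typed(NULL, 0L, h$dt))
  ord <- order(off)
  soff <- off[ord]
  runs <- run_starts(soff)
  con <- file(h$path, open = "rb")
  sorted_vals <- tryCatch({
    if (length(runs$start) > MAX_IO_RUNS) {
      lo <- soff[1]; hi <- soff[length(soff)]
      seek(con, h$data_offset + lo * h$dt$itemsize)
      block <- read_typed(con, as.integer(hi - lo + 1), h$dt)
      block[soff - lo + 1]
    } else {
      parts <- vector("list", length(runs$start))
      for (i in seq_along(runs$start)) {
        seek(con, h$data_offset + soff[runs$start[i]] * h$dt$itemsize)
        parts[[i]] <- read_typed(con, runs$len[i], h$dt)
      }
      unlist(parts, use.names = FALSE)
    }
  }, finally = close(con))
  vals <- sorted_vals
  vals[ord] <- sorted_vals
  vals
}

#' @export
`[<-.exdir_dataset` <- function(x, ..., value) {
  assert_writable(x)
  h <- dataset_handle(x, "read_write")
  call_args <- as.list(sys.call())[-(1:2)]
  call_args$value <- NULL
  args <- gather_index_args(call_args, parent.frame())
  nd <- length(h$shape)
  if (length(args) == 0L ||
      (length(args) == 1L && nd != 1L && is.null(args[[1]]))) {
    args <- vector("list", nd)
  } else if (length(args) == 1L && nd != 1L) {
    flat <- seq_len(h$n)[args[[1]]]
    if (anyNA(flat)) stop_exdirr("exdirr_index_error", "flat index out of bounds")
    coords <- arrayInd(flat, .dim = h$shape)
    strides <- elem_strides(h$shape, h$fortran)
    off <- as.vector((coords - 1) %*% strides)
    write_offsets(h, off, value)
    return(x)
  } else if (length(args) != nd) {
    stop_exdirr("exdirr_index_error",
                sprintf("selection has %d axes; dataset has %d", length(args), nd))
  }
  idx <- mapply(normalize_axis_index, args, h$shape, seq_len(nd), SIMPLIFY = FALSE)
  npy_write_slice(h, idx, value)
  x
}

write_offsets <- function(h, off, values) {
  nsel <- length(off)
  values <- as.vector(values)
  if (nsel == 0L) return(invisible())
  if (length(values) == 0L || nsel %% length(values) != 0L) {
    stop_exdirr("exdirr_broadcast_error",
                sprintf("cannot broadcast %d values into a selection of %d elements",
                        length(values), nsel))
  }
  values <- rep_len(values, nsel)
  ord <- order(off)
  soff <- off[ord]
  svals <- values[ord]
  if (anyDuplicated(soff)) {
    keep <- !duplicated(soff, fromLast = TRUE)
    soff <- soff[keep]; svals <- svals[keep]
  }
  runs <- run_starts(soff)
  con <- file(h$path, open = "r+b")
  tryCatch({
    for (i in seq_along(runs$start)) {
      s <- runs$start[i]
      seek(con, h$data_offset + soff[s] * h$dt$itemsize, rw = "write")
      write_typed(con, svals[s:(s + runs$len[i] - 1L)], h$dt)
    }
  }, finally = close(con))
  invisible()
}

#' @export
dim.exdir_dataset <- function(x) {
  s <- exdir_shape(x)
  if (length(s) <= 1L) NULL else s
}

#' @export
length.exdir_dataset <- function(x) {
  as.integer(dataset_handle(x, "read_only")$n)
}
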