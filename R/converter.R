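# Bidirectional HDF5 <-> Exdir structural conversion.
#
# HDF5 I/O goes through a small Python bridge (inst/python/hdf5_bridge.py,
# driven by h5py + numpy); the structural mapping — tree walking, attribute
# flattening, validation relaxations, reports — is implemented here.

find_python <- function() {
  for (cand in c(Sys.getenv("EXDIRR_PYTHON", ""), "python", "python3")) {
    if (!nzchar(cand)) next
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop_exdirr("exdirr_no_python",
              "no 'python' executable found; HDF5 conversion needs python with h5py")
}

bridge_script <- function() {
  p <- system.file("python", "hdf5_bridge.py", package = "exdirr")
  if (!nzchar(p)) {
    # during in-source development (pkgload) system.file still resolves; this
    # fallback covers direct source()ing in a checkout
    p <- file.path("inst", "python", "hdf5_bridge.py")
  }
  if (!file.exists(p)) stop_exdirr("exdirr_io_error", "hdf5_bridge.py not found")
  p
}

run_bridge <- function(verb, from, to) {
  out <- suppressWarnings(
    system2(find_python(), c(bridge_script(), verb, shQuote(from), shQuote(to)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop_exdirr("exdirr_converter_error",
                sprintf("hdf5 bridge '%s' failed:\n%s", verb,
                        paste(out, collapse = "\n")))
  }
  invisible()
}

new_conversion_report <- function(converted, skipped, lossy) {
  empty <- data.frame(path = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  structure(list(
    converted = converted,
    skipped = if (length(skipped)) do.call(rbind, skipped) else empty,
    lossy = if (length(lossy)) {
      df <- do.call(rbind, lossy); names(df) <- c("path", "description"); df
    } else stats::setNames(empty, c("path", "description"))
  ), class = "exdir_conversion_report")
}

#' @export
print.exdir_conversion_report <- function(x, ...) {
  cat(sprintf("converted: %s\n",
              paste(sprintf("%d %s", x$converted, names(x$converted)), collapse = ", ")))
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    for (i in seq_len(nrow(x$skipped)))
      cat(sprintf("  %s: %s\n", x$skipped$path[i], x$skipped$reason[i]))
  }
  if (nrow(x$lossy)) {
    cat("lossy:\n")
    for (i in seq_len(nrow(x$lossy)))
      cat(sprintf("  %s: %s\n", x$lossy$path[i], x$lossy$description[i]))
  }
  invisible(x)
}

# ---- typed attribute encoding shared with the bridge ------------------------

# floats cross the JSON hop as shortest-round-trip strings so no precision is
# lost to the serializer's default significant-digit cap
enc_float_json <- function(v) {
  if (is.nan(v)) "nan" else if (v == Inf) "inf" else if (v == -Inf) "-inf"
  else fmt_double(v)
}

dec_float_json <- function(v) {
  if (is.character(v)) {
    switch(v, nan = NaN, inf = Inf, `-inf` = -Inf, as.double(v))
  } else as.double(v)
}

encode_attr_entry <- function(key, value) {
  if (is_attr_scalar(value)) {
    if (is.integer(value)) return(list(key = key, t = "i", v = value))
    if (is.double(value)) return(list(key = key, t = "f", v = enc_float_json(value)))
    if (is.logical(value)) return(list(key = key, t = "b", v = value))
    if (is.character(value)) return(list(key = key, t = "s", v = value))
  }
  if (is_attr_seq(value) && length(value) &&
      all(vapply(value, is_attr_scalar, TRUE))) {
    types <- unique(vapply(value, typeof, ""))
    if (length(types) == 1L) {
      t <- switch(types, integer = "ia", double = "fa", logical = "ba",
                  character = "sa", NULL)
      if (!is.null(t)) {
        v <- if (t == "fa") lapply(value, enc_float_json) else value
        return(list(key = key, t = t, v = v))
      }
    }
  }
  NULL
}

decode_attr_entry <- function(entry) {
  t <- entry$t; v <- entry$v
  switch(t,
    i = as.integer(v),
    f = dec_float_json(v),
    b = as.logical(v),
    s = as.character(v),
    ia = lapply(v, as.integer),
    fa = lapply(v, dec_float_json),
    ba = lapply(v, as.logical),
    sa = lapply(v, as.character),
    stop_exdirr("exdirr_converter_error", sprintf("unknown attr tag '%s'", t)))
}

# Nested maps are legal in Exdir but not in HDF5 attributes: flatten to dotted
# keys, escaping literal dots in key names as "\.".
flatten_attrs <- function(doc, prefix = "") {
  out <- list()
  for (key in names(doc)) {
    ekey <- gsub(".", "\\.", key, fixed = TRUE)
    full <- if (nzchar(prefix)) paste0(prefix, ".", ekey) else ekey
    v <- doc[[key]]
    if (is_attr_map(v)) {
      out <- c(out, flatten_attrs(v, full))
    } else {
      out <- c(out, list(list(key = full, value = v)))
    }
  }
  out
}

# ---- HDF5 -> Exdir ----------------------------------------------------------

#' Convert an HDF5 file to an Exdir directory
#'
#' Groups, datasets and attributes map one-for-one; dataset payloads keep
#' shape and dtype bitwise.  HDF5 features with no Exdir counterpart (links,
#' references, compound types) are skipped per object, never fatally.  Source
#' names that fail thorough validation are still converted (under minimal
#' validation) and noted in the report.
#'
#' @param source_hdf5 Path to a readable HDF5 file.
#' @param target_directory Destination Exdir File root (absent, or existing
#'   Exdir File when `overwrite = TRUE`).
#' @param overwrite Truncate an existing target.
#' @return An `exdir_conversion_report`: counts by type, skipped objects with
#'   reasons, lossy transformations.
#' @export
hdf5_to_exdir <- function(source_hdf5, target_directory, overwrite = FALSE) {
  if (!file.exists(source_hdf5)) {
    stop_exdirr("exdirr_not_found", sprintf("no such file '%s'", source_hdf5))
  }
  exch <- tempfile("exdirr-h5dump-")
  on.exit(unlink(exch, recursive = TRUE), add = TRUE)
  run_bridge("dump", source_hdf5, exch)
  manifest <- jsonlite::fromJSON(file.path(exch, "manifest.json"),
                                 simplifyVector = FALSE)
  skipped <- lapply(manifest$skipped, function(s)
    data.frame(path = s$path, reason = s$reason, stringsAsFactors = FALSE))
  lossy <- lapply(manifest$lossy, function(l)
    data.frame(path = l$path, description = l$description, stringsAsFactors = FALSE))
  counts <- c(groups = 0L, datasets = 0L, attributes = 0L)

  f <- exdir_open(target_directory, mode = if (overwrite) "w" else "w-",
                  name_validation = "minimal")
  set_attrs <- function(obj, entries) {
    if (!length(entries)) return()
    doc <- attr_map()
    for (e in entries) doc[[e$key]] <- decode_attr_entry(e)
    # HDF5 keys (dotted, spaced, ...) legitimately break the key convention;
    # they are emitted quoted, which is exactly what we want here
    withCallingHandlers(
      exdir_attrs(obj) <- doc,
      exdirr_key_convention_warning = function(w) invokeRestart("muffleWarning"))
    counts["attributes"] <<- counts["attributes"] + length(entries)
  }
  set_attrs(f, manifest$root_attrs)
  for (obj in manifest$objects) {
    comps <- split_path(obj$path)
    name <- comps[length(comps)]
    parent <- if (length(comps) > 1L) {
      exdir_item(f, paste(comps[-length(comps)], collapse = "/"))
    } else f
    verdict <- check_name(list_entries(obj_dir(parent)), name, "thorough")
    if (!isTRUE(verdict$ok)) {
      lossy <- c(lossy, list(data.frame(
        path = obj$path,
        description = sprintf("name accepted under minimal validation only (%s)",
                              verdict$reason),
        stringsAsFactors = FALSE)))
    }
    if (obj$kind == "group") {
      node <- create_group(parent, name)
      counts["groups"] <- counts["groups"] + 1L
    } else {
      src <- npy_open(file.path(exch, obj$npy))
      node <- create_dataset(parent, name, data = npy_read(src),
                             dtype = src$dt$descr,
                             shape = unlist(obj$shape) %||% integer(0))
      counts["datasets"] <- counts["datasets"] + 1L
    }
    set_attrs(node, obj$attrs)
  }
  new_conversion_report(counts, skipped, lossy)
}

# ---- Exdir -> HDF5 ----------------------------------------------------------

#' Convert an Exdir directory to an HDF5 file
#'
#' Inverse structural mapping.  Map-valued (nested) attributes are flattened
#' to dotted keys with a report entry (HDF5 attributes cannot nest); Raw
#' directories are skipped, or stored as opaque uint8 datasets (one per
#' contained file) with `raw_mode = "opaque"`.
#'
#' @param source_directory A valid Exdir File root.
#' @param target_hdf5 Destination HDF5 file path.
#' @param raw_mode `"skip"` (default) or `"opaque"`.
#' @param overwrite Replace an existing target file.
#' @return An `exdir_conversion_report`.
#' @export
exdir_to_hdf5 <- function(source_directory, target_hdf5,
                          raw_mode = c("skip", "opaque"), overwrite = FALSE) {
  raw_mode <- match.arg(raw_mode)
  if (file.exists(target_hdf5) && !overwrite) {
    stop_exdirr("exdirr_exists", sprintf("'%s' already exists", target_hdf5))
  }
  f <- exdir_open(source_directory, mode = "r")
  exch <- tempfile("exdirr-h5build-")
  dir.create(exch)
  on.exit(unlink(exch, recursive = TRUE), add = TRUE)
  objects <- list()
  skipped <- list()
  lossy <- list()
  counts <- c(groups = 0L, datasets = 0L, attributes = 0L)

  attrs_for <- function(obj) {
    doc <- exdir_attrs(obj)
    if (!length(doc)) return(list())
    had_nested <- any(vapply(doc, is_attr_map, TRUE))
    flat <- flatten_attrs(doc)
    if (had_nested) {
      lossy[[length(lossy) + 1L]] <<- data.frame(
        path = exdir_name(obj),
        description = "nested attributes flattened to dotted keys",
        stringsAsFactors = FALSE)
    }
    out <- list()
    for (e in flat) {
      enc <- encode_attr_entry(e$key, e$value)
      if (is.null(enc)) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          path = exdir_name(obj),
          reason = sprintf("attribute '%s' has no HDF5 counterpart", e$key),
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- enc
        counts["attributes"] <<- counts["attributes"] + 1L
      }
    }
    out
  }

  walk <- function(group, rel) {
    for (key in exdir_keys(group)) {
      child <- exdir_item(group, key)
      path <- if (nzchar(rel)) paste0(rel, "/", key) else key
      if (inherits(child, "exdir_dataset")) {
        h <- dataset_handle(child, "read_only")
        objects[[length(objects) + 1L]] <<- list(
          path = path, kind = "dataset", npy = normalizePath(h$path),
          attrs = attrs_for(child))
        counts["datasets"] <<- counts["datasets"] + 1L
      } else if (inherits(child, "exdir_raw")) {
        if (raw_mode == "skip") {
          skipped[[length(skipped) + 1L]] <<- data.frame(
            path = path, reason = "raw directory skipped", stringsAsFactors = FALSE)
        } else {
          objects[[length(objects) + 1L]] <<- list(
            path = path, kind = "group", attrs = attrs_for(child))
          counts["groups"] <<- counts["groups"] + 1L
          for (fn in sort_c(list.files(obj_dir(child)))) {
            if (fn %in% c("exdir.yaml", "attributes.yaml")) next
            fp <- file.path(obj_dir(child), fn)
            if (dir.exists(fp)) next
            bytes <- readBin(fp, "raw", file.info(fp)$size)
            npy <- file.path(exch, sprintf("raw%05d.npy", length(objects)))
            npy_write(npy, as.integer(bytes), dtype = "|u1")
            objects[[length(objects) + 1L]] <<- list(
              path = paste0(path, "/", fn), kind = "dataset", npy = npy,
              attrs = list())
            counts["datasets"] <<- counts["datasets"] + 1L
            lossy[[length(lossy) + 1L]] <<- data.frame(
              path = paste0(path, "/", fn),
              description = "raw file stored as opaque uint8 dataset",
              stringsAsFactors = FALSE)
          }
        }
      } else {                                           # group
        objects[[length(objects) + 1L]] <<- list(
          path = path, kind = "group", attrs = attrs_for(child))
        counts["groups"] <<- counts["groups"] + 1L
        walk(child, path)
      }
    }
  }
  root_attrs <- attrs_for(f)
  walk(f, "")
  manifest <- list(root_attrs = root_attrs, objects = objects,
                   skipped = list(), lossy = list())
  jsonlite::write_json(manifest, file.path(exch, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (file.exists(target_hdf5)) unlink(target_hdf5)
  run_bridge("build", exch, target_hdf5)
  new_conversion_report(counts, skipped, lossy)
}

# ---- walk-comparison helper -------------------------------------------------

#' Flatten an Exdir tree into a comparable manifest
#'
#' For every object below the File root: its path, type, and for datasets the
#' shape, dtype descriptor and full payload, plus the attribute document.
#' Two trees are structurally equal iff their walks are equal; used by the
#' converter round-trip and fixture tests.
#'
#' @param file An open File (or Group) handle.
#' @return Named list keyed by relative path.
#' @export
exdir_walk <- function(file) {
  out <- list()
  rec <- function(group, rel) {
    for (key in exdir_keys(group)) {
      child <- exdir_item(group, key)
      path <- if (nzchar(rel)) paste0(rel, "/", key) else key
      entry <- list(type = child$type, attrs = exdir_attrs(child))
      if (inherits(child, "exdir_dataset")) {
        h <- dataset_handle(child, "read_only")
        entry$shape <- h$shape
        entry$descr <- h$dt$descr
        entry$data <- npy_read(h)
      }
      out[[path]] <<- entry
      if (inherits(child, "exdir_group")) rec(child, path)
    }
  }
  rec(file, "")
  out[sort_c(names(out) %||% character(0))]
}

#' Compare two tree walks for structural equality
#'
#' @param a,b Walks from [exdir_walk()].
#' @return `TRUE`, or a character description of the first difference.
#' @export
walk_equal <- function(a, b) {
  if (!identical(names(a), names(b))) {
    return(sprintf("path sets differ: {%s} vs {%s}",
                   paste(names(a), collapse = ","), paste(names(b), collapse = ",")))
  }
  for (p in names(a)) {
    ea <- a[[p]]; eb <- b[[p]]
    if (!identical(ea$type, eb$type)) return(sprintf("%s: type %s vs %s", p, ea$type, eb$type))
    if (!attr_doc_equal(ea$attrs, eb$attrs)) return(sprintf("%s: attrs differ", p))
    if (identical(ea$type, "dataset")) {
      if (!identical(ea$shape, eb$shape)) return(sprintf("%s: shape differs", p))
      if (!identical(ea$descr, eb$descr)) return(sprintf("%s: dtype %s vs %s", p, ea$descr, eb$descr))
      if (!isTRUE(all.equal(ea$data, eb$data, tolerance = 0))) {
        return(sprintf("%s: payload differs", p))
      }
    }
  }
  TRUE
}
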