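# Core object handles and the attribute interface.
#
# An Exdir object is one directory.  Its identity on disk is the pair
# (root directory of the File, relative path), and its kind is declared by the
# `exdir.yaml` file inside it: one of file, group, dataset, raw.  A directory
# with no `exdir.yaml` found inside an Exdir tree is read as Raw (the metadata
# file is optional for Raw objects).

EXDIR_VERSION <- 1L
OBJECT_TYPES <- c("file", "group", "dataset", "raw")

new_exdir_object <- function(root, relpath, type, config) {
  cls <- switch(type,
    file = c("exdir_file", "exdir_group", "exdir_object"),
    group = c("exdir_group", "exdir_object"),
    dataset = c("exdir_dataset", "exdir_object"),
    raw = c("exdir_raw", "exdir_object"))
  structure(list(root = root, relpath = relpath, type = type, config = config),
            class = cls)
}

obj_dir <- function(obj) {
  if (length(obj$relpath) == 0L) obj$root
  else file.path(obj$root, paste(obj$relpath, collapse = "/"))
}

assert_live <- function(obj) {
  if (!dir.exists(obj_dir(obj))) {
    stop_exdirr("exdirr_stale",
                sprintf("object '%s' no longer exists on disk", exdir_name(obj)))
  }
  invisible(obj)
}

assert_writable <- function(obj) {
  if (obj$config$mode != "read_write") {
    stop_exdirr("exdirr_read_only", "the File was opened read-only")
  }
  invisible(obj)
}

#' Is this an Exdir object handle?
#' @param x Any value.
#' @export
is_exdir_object <- function(x) inherits(x, "exdir_object")

#' Absolute name of an object within its File
#'
#' `"/"` for the File root, otherwise `"/"`-joined path components with the
#' case exactly as created.
#'
#' @param obj An Exdir object handle.
#' @return A single string.
#' @export
exdir_name <- function(obj) {
  paste0("/", paste(obj$relpath, collapse = "/"))
}

#' Object type tag
#' @param obj An Exdir object handle.
#' @return `"file"`, `"group"`, `"dataset"` or `"raw"`.
#' @export
exdir_type <- function(obj) obj$type

#' @export
print.exdir_object <- function(x, ...) {
  extra <- if (inherits(x, "exdir_dataset")) {
    h <- dataset_handle(x, "read_only")
    sprintf(" shape (%s) %s", paste(h$shape, collapse = ", "), dtype_name(h$dt))
  } else ""
  cat(sprintf("<exdir %s \"%s\"%s (%s)>\n", x$type, exdir_name(x), extra, x$root))
  invisible(x)
}

# ---- exdir.yaml -------------------------------------------------------------

meta_path <- function(dir) file.path(dir, "exdir.yaml")

write_object_meta <- function(dir, type, plugins_meta = NULL) {
  doc <- list(exdir = list(type = type, version = EXDIR_VERSION))
  if (!is.null(plugins_meta) && length(plugins_meta)) doc$plugins <- plugins_meta
  write_text_atomic(meta_path(dir), emit_restricted(doc))
}

# Parsed exdir.yaml (full document, so plugin markers are available), or NULL
# when the file is absent.
read_object_meta <- function(dir) {
  p <- meta_path(dir)
  if (!file.exists(p)) return(NULL)
  parse_lenient(read_text_utf8(p))$document
}

meta_type <- function(meta) {
  t <- meta$exdir$type
  if (is_string(t) && t %in% OBJECT_TYPES) t else NA_character_
}

# Classify a directory found inside an Exdir tree.  No exdir.yaml -> raw.
# A nested "file" tag violates the file-in-file prohibition; the reader
# tolerates it as a group (the linter reports it as an error).
classify_dir <- function(dir, is_root = FALSE) {
  meta <- read_object_meta(dir)
  if (is.null(meta)) return("raw")
  t <- meta_type(meta)
  if (is.na(t)) {
    stop_exdirr("exdirr_not_exdir",
                sprintf("'%s' has an exdir.yaml with an unknown or missing type tag", dir))
  }
  if (t == "file" && !is_root) return("group")
  t
}

# ---- attributes -------------------------------------------------------------

attrs_path <- function(obj) file.path(obj_dir(obj), "attributes.yaml")

#' Read an object's attributes
#'
#' Attributes live in `attributes.yaml` next to the object's metadata; an
#' absent file reads as an empty document.  Parsing is lenient: restriction
#' breaches are tolerated (use [exdir_lint()] to surface them).
#'
#' @param obj An Exdir object handle.
#' @return A named list (canonical attribute document).
#' @export
exdir_attrs <- function(obj) {
  assert_live(obj)
  p <- attrs_path(obj)
  if (!file.exists(p)) return(attr_map())
  parse_lenient(read_text_utf8(p))$document
}

#' Replace an object's attributes in one write
#'
#' The whole document is serialized and the file replaced atomically, so many
#' attributes assigned in bulk cost one file write (assigning keys one at a
#' time rewrites the file each call).  Attribute-targeted plugin handlers are
#' applied to the document before serialization.
#'
#' @param obj An Exdir object handle.
#' @param value A named list of supported attribute values.
#' @return `obj`, invisibly (the write is the side effect).
#' @export
`exdir_attrs<-` <- function(obj, value) {
  assert_live(obj)
  assert_writable(obj)
  doc <- as_attr_document(value)
  if (is.null(doc)) doc <- attr_map()
  if (!is_attr_map(doc)) {
    stop_exdirr("exdirr_unsupported_attribute", "attributes must form a map")
  }
  doc <- apply_attr_write_chain(obj$config$plugins, doc)
  write_text_atomic(attrs_path(obj), emit_restricted(doc))
  invisible(obj)
}

#' Set one attribute key
#'
#' Reads the current document, merges the key, and rewrites the whole
#' `attributes.yaml` (every single-key write is a complete rewrite of the
#' file; prefer a bulk `exdir_attrs<-` assignment when setting many keys).
#'
#' @param obj An Exdir object handle.
#' @param key Attribute name (string).
#' @param value Supported attribute value.
#' @return `obj`, invisibly.
#' @export
exdir_set_attr <- function(obj, key, value) {
  if (!is_string(key)) stop_exdirr("exdirr_invalid_key", "attribute key must be a string")
  doc <- exdir_attrs(obj)
  doc[key] <- list(as_attr_document(value))
  exdir_attrs(obj) <- doc
  invisible(obj)
}
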