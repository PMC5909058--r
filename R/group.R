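# Group operations: creation, lookup, iteration, deletion.

# Resolve a multi-component name against existing ancestors; returns the
# parent handle of the final component plus the final name.  Intermediate
# components must already exist (no implicit "mkdir -p") and must be groups.
resolve_parent <- function(parent, name) {
  comps <- split_path(name)
  if (length(comps) == 0L) {
    stop_exdirr("exdirr_invalid_name", "empty object name")
  }
  node <- parent
  for (comp in comps[-length(comps)]) {
    node <- get_child(node, comp)
  }
  if (!inherits(node, "exdir_group")) {
    stop_exdirr("exdirr_not_a_group",
                sprintf("'%s' is a %s, not a group", exdir_name(node), node$type))
  }
  list(parent = node, name = comps[length(comps)])
}

get_child <- function(parent, comp) {
  if (!inherits(parent, "exdir_group")) {
    stop_exdirr("exdirr_not_a_group",
                sprintf("cannot descend through '%s': it is a %s",
                        exdir_name(parent), parent$type))
  }
  dir <- file.path(obj_dir(parent), comp)
  # case-exact lookup: the directory must exist under exactly this name
  if (!dir.exists(dir) || !(comp %in% list_entries(obj_dir(parent)))) {
    stop_exdirr("exdirr_not_found",
                sprintf("no object '%s' in '%s'", comp, exdir_name(parent)))
  }
  type <- classify_dir(dir)
  new_exdir_object(parent$root, c(parent$relpath, comp), type, parent$config)
}

create_child <- function(parent, name, type) {
  assert_live(parent)
  assert_writable(parent)
  r <- resolve_parent(parent, name)
  pdir <- obj_dir(r$parent)
  verdict <- parent$config$policy(pdir, r$name)
  if (!isTRUE(verdict$ok)) {
    existing <- r$name %in% list_entries(pdir) ||
      grepl("already exists|collides", verdict$reason %||% "")
    stop_exdirr(if (existing) "exdirr_exists" else "exdirr_invalid_name",
                sprintf("cannot create '%s' in '%s': %s",
                        r$name, exdir_name(r$parent), verdict$reason %||% "rejected"))
  }
  dir <- file.path(pdir, r$name)
  if (!dir.create(dir)) {
    stop_exdirr("exdirr_io_error", sprintf("could not create directory '%s'", dir))
  }
  write_object_meta(dir, type)
  new_exdir_object(parent$root, c(r$parent$relpath, r$name), type, parent$config)
}

#' Create a Group
#'
#' Creates a subdirectory holding an `exdir.yaml` with the `group` type tag.
#' Multi-component names (`"a/b"`) require every ancestor to exist already.
#' The File's name-validation policy decides whether the name is acceptable
#' (under the default thorough policy, names colliding case-insensitively with
#' an existing sibling are rejected).
#'
#' @param parent A File or Group handle.
#' @param name Object name, or `"/"`-separated path whose ancestors exist.
#' @return The new Group handle.
#' @export
#' @examples
#' f <- exdir_open(file.path(tempdir(), "ex1.exdir"), "w")
#' g <- create_group(f, "session1")
create_group <- function(parent, name) {
  create_child(parent, name, "group")
}

#' Return a Group, creating it if absent
#'
#' Case-exact: an existing group of exactly this name is returned untouched;
#' otherwise the group is created.  An existing child of a different type is a
#' type-mismatch error.
#'
#' @inheritParams create_group
#' @return A Group handle.
#' @export
require_group <- function(parent, name) {
  assert_live(parent)
  r <- resolve_parent(parent, name)
  if (r$name %in% list_entries(obj_dir(r$parent))) {
    child <- get_child(r$parent, r$name)
    if (!identical(child$type, "group")) {
      stop_exdirr("exdirr_type_mismatch",
                  sprintf("'%s' exists but is a %s, not a group",
                          exdir_name(child), child$type))
    }
    return(child)
  }
  create_group(r$parent, r$name)
}

#' Create a Raw directory
#'
#' Raw objects hold arbitrary files in foreign formats.  This library writes
#' an `exdir.yaml` with the `raw` tag (the file is optional for Raw: on read,
#' any directory without `exdir.yaml` is treated as Raw).
#'
#' @inheritParams create_group
#' @return The new Raw handle.
#' @export
create_raw <- function(parent, name) {
  create_child(parent, name, "raw")
}

#' Retrieve an object by path
#'
#' Resolves `"/"`-separated paths component by component, classifying each
#' directory by its `exdir.yaml`.  Lookup is case-exact regardless of the
#' validation policy.
#'
#' @param parent A File or Group handle.
#' @param path Relative path (a leading `"/"` is tolerated).
#' @return An Exdir object handle (group, dataset or raw).
#' @export
exdir_item <- function(parent, path) {
  assert_live(parent)
  comps <- split_path(path)
  if (length(comps) == 0L) return(parent)
  node <- parent
  for (comp in comps) node <- get_child(node, comp)
  node
}

#' @export
`[[.exdir_group` <- function(x, i) exdir_item(x, i)

#' Containership test
#'
#' `TRUE` iff [exdir_item()] on the same path would succeed; lookup failures
#' are absorbed.
#'
#' @inheritParams exdir_item
#' @export
exdir_contains <- function(parent, path) {
  !is.null(exdir_get(parent, path))
}

#' Lookup with a default instead of an error
#' @inheritParams exdir_item
#' @param default Returned when the path does not resolve.
#' @export
exdir_get <- function(parent, path, default = NULL) {
  tryCatch(exdir_item(parent, path), exdirr_error = function(e) default)
}

#' Child names of a Group
#'
#' Children are the subdirectories of the group's directory, in lexicographic
#' code-point order (deterministic across file systems and locales); the
#' special files `exdir.yaml`/`attributes.yaml`/`data.npy` are never children.
#'
#' @param group A File or Group handle.
#' @return Character vector of names, byte-identical to those used at creation.
#' @export
exdir_keys <- function(group) {
  assert_live(group)
  if (!inherits(group, "exdir_group")) {
    stop_exdirr("exdirr_not_a_group", sprintf("'%s' is not a group", exdir_name(group)))
  }
  d <- obj_dir(group)
  entries <- list_entries(d)
  sort_c(entries[dir.exists(file.path(d, entries))])
}

#' @export
names.exdir_group <- function(x) exdir_keys(x)

#' @rdname exdir_keys
#' @return `exdir_values()`: list of child handles; `exdir_items()`: named
#'   list of child handles.
#' @export
exdir_values <- function(group) {
  lapply(exdir_keys(group), function(k) get_child(group, k))
}

#' @rdname exdir_keys
#' @export
exdir_items <- function(group) {
  ks <- exdir_keys(group)
  stats::setNames(lapply(ks, function(k) get_child(group, k)), ks)
}

#' @export
length.exdir_group <- function(x) length(exdir_keys(x))

#' Delete a child object and its whole subtree
#'
#' Physical removal: the directory and everything below it are unlinked, so
#' the disk space is freed immediately.  Handles pointing into the deleted
#' subtree raise a stale-handle error on next use.
#'
#' @param parent A File or Group handle.
#' @param name Child name or `"/"`-separated path (case-exact).
#' @export
exdir_delete <- function(parent, name) {
  assert_live(parent)
  assert_writable(parent)
  child <- exdir_item(parent, name)     # errors exdirr_not_found if missing
  if (length(child$relpath) == 0L) {
    stop_exdirr("exdirr_invalid_name", "cannot delete the File root through itself")
  }
  unlink(obj_dir(child), recursive = TRUE)
  invisible(parent)
}
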