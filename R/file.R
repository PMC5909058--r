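# Opening and creating File objects (the hierarchy roots).

#' Open or create an Exdir File
#'
#' A File is the root object of an Exdir hierarchy: a directory containing an
#' `exdir.yaml` with the `file` type tag.  Files behave as Groups in every
#' group operation.  Open modes follow the h5py convention:
#'
#' * `"r"`  — read-only; the File must exist.
#' * `"r+"` — read-write; the File must exist.
#' * `"w"`  — create, truncating an existing File at the location.
#' * `"w-"` / `"x"` — create; fail if the location exists.
#' * `"a"`  — read-write; create if absent (default).
#'
#' The name-validation policy and the plugin list are fixed here and inherited
#' by every object handle below this File.
#'
#' @param location Directory path of the File root (a `.exdir` suffix on the
#'   name is conventional, not enforced).  The parent directory must exist.
#' @param mode Open-mode token, see above.
#' @param name_validation `"thorough"` (default), `"minimal"`, or a function
#'   `(parent_directory, name) -> list(ok=, reason=)`.
#' @param plugins List of [exdir_plugin()] handlers.
#' @return A File handle (also a Group).
#' @export
#' @examples
#' f <- exdir_open(file.path(tempdir(), "experiment.exdir"), mode = "w")
#' exdir_type(f)
exdir_open <- function(location, mode = c("a", "r", "r+", "w", "w-", "x"),
                       name_validation = "thorough", plugins = list()) {
  mode <- match.arg(mode)
  if (!is_string(location)) {
    stop_exdirr("exdirr_invalid_argument", "location must be a single path")
  }
  location <- sub("/+$", "", location)
  parent_dir <- dirname(location)
  if (!dir.exists(parent_dir)) {
    stop_exdirr("exdirr_not_found",
                sprintf("parent directory '%s' does not exist", parent_dir))
  }
  if (file.exists(location) && !dir.exists(location)) {
    stop_exdirr("exdirr_not_exdir", sprintf("'%s' exists and is not a directory", location))
  }
  exists <- dir.exists(location)
  if (mode %in% c("r", "r+") && !exists) {
    stop_exdirr("exdirr_not_found", sprintf("no Exdir File at '%s'", location))
  }
  if (mode %in% c("w-", "x") && exists) {
    stop_exdirr("exdirr_exists", sprintf("'%s' already exists", location))
  }
  if (exists && mode != "w") {
    meta <- read_object_meta(location)
    if (is.null(meta)) {
      stop_exdirr("exdirr_not_exdir",
                  sprintf("'%s' exists but holds no exdir.yaml", location))
    }
    t <- meta_type(meta)
    if (!identical(t, "file")) {
      stop_exdirr("exdirr_type_mismatch",
                  sprintf("'%s' is an Exdir %s, not a File", location, t))
    }
  }
  if (mode == "w" && exists) {
    meta <- read_object_meta(location)
    if (is.null(meta) || !identical(meta_type(meta), "file")) {
      # refuse to truncate a directory that is not an Exdir File
      stop_exdirr("exdirr_not_exdir",
                  sprintf("'%s' exists and is not an Exdir File; not truncating", location))
    }
    unlink(location, recursive = TRUE)
    exists <- FALSE
  }
  if (!exists) {
    if (!dir.create(location)) {
      stop_exdirr("exdirr_io_error", sprintf("could not create '%s'", location))
    }
    write_object_meta(location, "file")
  }
  root <- normalizePath(location, winslash = "/", mustWork = TRUE)
  config <- new.env(parent = emptyenv())
  config$mode <- if (mode == "r") "read_only" else "read_write"
  config$policy <- resolve_policy(name_validation)
  config$plugins <- validate_plugins(plugins)
  new_exdir_object(root, character(0), "file", config)
}
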