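# Object-name acceptance policies.
#
# Exdir objects become file-system directories, so sibling names that differ
# only by case collide when a tree written on a case-sensitive file system is
# copied to a case-insensitive one (Windows, default macOS).  The default
# "thorough" policy rejects such names up front; "minimal" only rejects exact
# collisions and is much cheaper when creating many objects.

RESERVED_NAMES <- c("exdir.yaml", "attributes.yaml", "data.npy")

#' Name-acceptance core (pure, directory state passed in)
#'
#' @param existing Character vector of entry names already present in the
#'   parent directory.
#' @param name Proposed object name.
#' @param policy `"thorough"` or `"minimal"`.
#' @return A list with `ok` (logical) and, when rejected, `reason`.
#' @export
check_name <- function(existing, name, policy = c("thorough", "minimal")) {
  policy <- match.arg(policy)
  rej <- function(reason) list(ok = FALSE, reason = reason)
  if (!is_string(name) || !nzchar(name)) return(rej("name must be a non-empty string"))
  # (R strings cannot embed NUL, so only "/" needs rejecting here)
  if (grepl("/", name, fixed = TRUE)) {
    return(rej("name must not contain '/'"))
  }
  if (name %in% RESERVED_NAMES) {
    return(rej(sprintf("'%s' is a reserved file name", name)))
  }
  if (policy == "minimal") {
    if (name %in% existing) return(rej(sprintf("an object named '%s' already exists", name)))
    return(list(ok = TRUE))
  }
  # thorough: ASCII charset (letters, digits, _-. and space; no leading or
  # trailing space/dot, not all dots) + ASCII-case-insensitive uniqueness
  if (!grepl("^[A-Za-z0-9_. -]+$", name)) {
    return(rej(sprintf("'%s' contains characters outside [A-Za-z0-9_. -]", name)))
  }
  if (grepl("^[ .]|[ .]$", name) || grepl("^\\.+$", name)) {
    return(rej(sprintf("'%s' has a leading/trailing space or dot", name)))
  }
  if (tolower(name) %in% tolower(existing)) {
    clash <- existing[tolower(existing) == tolower(name)][1]
    reason <- if (identical(clash, name)) {
      sprintf("an object named '%s' already exists", name)
    } else {
      sprintf("'%s' collides case-insensitively with existing '%s'", name, clash)
    }
    return(rej(reason))
  }
  list(ok = TRUE)
}

#' Name validation against a directory on disk
#'
#' `validate_thorough()` enforces case-insensitive (ASCII-folded) uniqueness
#' and a portable character set; `validate_minimal()` only rejects exact-name
#' collisions and reserved names.  Every name accepted under thorough is
#' accepted under minimal on the same directory state.
#'
#' @param parent_directory Existing directory whose entries are the siblings.
#' @param name Proposed object name.
#' @return list(ok=, reason=) as in [check_name()]; rejection is a value, not
#'   an error.
#' @export
validate_thorough <- function(parent_directory, name) {
  check_name(list_entries(parent_directory), name, "thorough")
}

#' @rdname validate_thorough
#' @export
validate_minimal <- function(parent_directory, name) {
  check_name(list_entries(parent_directory), name, "minimal")
}

list_entries <- function(dir) {
  list.files(dir, all.files = TRUE, no.. = TRUE, include.dirs = TRUE)
}

# Resolve the File-open `name_validation` argument to a predicate function
# (parent_directory, name) -> list(ok, reason).
resolve_policy <- function(name_validation) {
  if (is.function(name_validation)) return(name_validation)
  if (is_string(name_validation)) {
    return(switch(name_validation,
      thorough = validate_thorough,
      minimal = validate_minimal,
      stop_exdirr("exdirr_invalid_argument",
                  sprintf("unknown name_validation '%s'", name_validation))))
  }
  stop_exdirr("exdirr_invalid_argument",
              "name_validation must be \"thorough\", \"minimal\" or a function")
}
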