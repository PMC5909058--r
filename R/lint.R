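# Conformance linter: walks an Exdir tree and reports schema errors and
# restricted-YAML warnings.
#
# Errors (tree is not conformant): missing/unparsable exdir.yaml where
# required, unknown type tags, a nested `file` tag, a dataset without
# data.npy or with a corrupt/truncated payload, special files in places they
# do not belong, case-colliding sibling names.
# Warnings (tree readable, but off-spec style): YAML restriction breaches in
# exdir.yaml/attributes.yaml, foreign files inside group directories.

lint_record <- function(path, rule, severity, message) {
  data.frame(path = path, rule = rule, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Lint an Exdir directory tree
#'
#' @param location Root directory of an Exdir File.
#' @return An object of class `exdir_lint_report`: a data frame with columns
#'   `path`, `rule`, `severity` (`"error"`/`"warning"`) and `message`.
#'   `exdir_lint_ok()` is `TRUE` iff the report contains no errors (warnings
#'   allowed — reading is lenient by design).
#' @export
exdir_lint <- function(location) {
  recs <- list()
  add <- function(r) recs[[length(recs) + 1L]] <<- r
  if (!dir.exists(location)) {
    add(lint_record("/", "missing_root", "error",
                    sprintf("'%s' is not a directory", location)))
    return(new_lint_report(recs))
  }
  root_meta <- lint_yaml_file(file.path(location, "exdir.yaml"), "/", add,
                              required = TRUE)
  if (!is.null(root_meta)) {
    t <- meta_type(root_meta)
    if (is.na(t)) {
      add(lint_record("/", "bad_type_tag", "error",
                      "root exdir.yaml has a missing or unknown type tag"))
    } else if (t != "file") {
      add(lint_record("/", "root_not_file", "error",
                      sprintf("root object is tagged '%s', expected 'file'", t)))
    }
  }
  lint_walk(location, "/", "file", add)
  new_lint_report(recs)
}

# Parse one YAML file, recording parse errors and restriction warnings.
# Returns the document, or NULL if absent/unparsable.
lint_yaml_file <- function(path, obj_path, add, required = FALSE) {
  if (!file.exists(path)) {
    if (required) {
      add(lint_record(obj_path, "missing_meta", "error",
                      sprintf("required file '%s' is missing", basename(path))))
    }
    return(NULL)
  }
  res <- tryCatch(parse_lenient(read_text_utf8(path)),
                  exdirr_error = function(e) e)
  if (inherits(res, "error")) {
    add(lint_record(obj_path, "yaml_parse_error", "error",
                    sprintf("%s: %s", basename(path), conditionMessage(res))))
    return(NULL)
  }
  for (v in res$violations) {
    add(lint_record(obj_path, paste0("yaml_", v$rule), "warning",
                    sprintf("%s: %s", basename(path), format(v))))
  }
  res$document
}

lint_walk <- function(dir, obj_path, type, add) {
  entries <- list_entries(dir)
  subdirs <- entries[dir.exists(file.path(dir, entries))]
  files <- setdiff(entries, subdirs)

  lint_yaml_file(file.path(dir, "attributes.yaml"), obj_path, add)

  if (type %in% c("file", "group")) {
    stray <- setdiff(files, c("exdir.yaml", "attributes.yaml"))
    if ("data.npy" %in% files) {
      add(lint_record(obj_path, "stray_special_file", "error",
                      "data.npy found in a group directory"))
      stray <- setdiff(stray, "data.npy")
    }
    for (s in stray) {
      add(lint_record(obj_path, "foreign_file", "warning",
                      sprintf("non-Exdir file '%s' inside a group directory", s)))
    }
    folded <- tolower(subdirs)
    if (anyDuplicated(folded)) {
      for (nm in unique(folded[duplicated(folded)])) {
        clash <- subdirs[folded == nm]
        add(lint_record(obj_path, "case_collision", "error",
                        sprintf("sibling names collide case-insensitively: %s",
                                paste(sort_c(clash), collapse = ", "))))
      }
    }
    for (child in sort_c(subdirs)) {
      cdir <- file.path(dir, child)
      cpath <- paste0(sub("/$", "", obj_path), "/", child)
      meta <- lint_yaml_file(file.path(cdir, "exdir.yaml"), cpath, add)
      if (is.null(meta)) {                       # absent or unparsable -> raw
        lint_walk(cdir, cpath, "raw", add)
        next
      }
      ct <- meta_type(meta)
      if (is.na(ct)) {
        add(lint_record(cpath, "bad_type_tag", "error",
                        "exdir.yaml has a missing or unknown type tag"))
        next
      }
      if (ct == "file") {
        add(lint_record(cpath, "nested_file", "error",
                        "a File cannot contain another File object"))
        ct <- "group"
      }
      lint_walk(cdir, cpath, ct, add)
    }
  } else if (type == "dataset") {
    npy <- file.path(dir, "data.npy")
    if (!file.exists(npy)) {
      add(lint_record(obj_path, "missing_data", "error",
                      "dataset directory has no data.npy"))
    } else {
      err <- tryCatch({ npy_open(npy); NULL }, exdirr_error = function(e) e)
      if (!is.null(err)) {
        add(lint_record(obj_path, "corrupt_dataset", "error",
                        sprintf("data.npy: %s", conditionMessage(err))))
      }
    }
    stray <- setdiff(files, c("exdir.yaml", "attributes.yaml", "data.npy"))
    for (s in stray) {
      add(lint_record(obj_path, "foreign_file", "warning",
                      sprintf("unexpected file '%s' inside a dataset directory", s)))
    }
    if (length(subdirs)) {
      add(lint_record(obj_path, "dataset_with_children", "error",
                      sprintf("dataset directory contains subdirectories: %s",
                              paste(sort_c(subdirs), collapse = ", "))))
    }
  }
  # raw directories: anything goes
  invisible()
}

new_lint_report <- function(recs) {
  df <- if (length(recs)) do.call(rbind, recs)
  else data.frame(path = character(0), rule = character(0),
                  severity = character(0), message = character(0),
                  stringsAsFactors = FALSE)
  structure(df, class = c("exdir_lint_report", "data.frame"))
}

#' @rdname exdir_lint
#' @param report A lint report.
#' @export
exdir_lint_ok <- function(report) {
  !any(report$severity == "error")
}

#' @export
print.exdir_lint_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("OK: no findings\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-7s %s [%s] %s\n", toupper(x$severity[i]), x$path[i],
                x$rule[i], x$message[i]))
  }
  cat(sprintf("%d error(s), %d warning(s)\n",
              sum(x$severity == "error"), sum(x$severity == "warning")))
  invisible(x)
}
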