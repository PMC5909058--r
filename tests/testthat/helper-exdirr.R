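# Shared test machinery: fresh roots, a python oracle runner, random attribute
# documents, and the operation-program generator with its in-memory oracle.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_root <- function(name = "ex") {
  file.path(withr::local_tempdir(.local_envir = parent.frame()),
            paste0(name, ".exdir"))
}

# Run a snippet of python (numpy/h5py/yaml available in the test image) and
# return its stdout lines.  Used only as an independent oracle.
run_py <- function(code) {
  script <- withr::local_tempfile(fileext = ".py", .local_envir = parent.frame())
  writeLines(code, script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("python oracle failed:\n", paste(out, collapse = "\n"))
  }
  out
}

# One random per-axis selection: full axis (NULL), scalar, contiguous range,
# strided range, or fancy (arbitrary order with repetition).
rand_axis_sel <- function(extent) {
  switch(sample.int(5L, 1L),
    NULL,
    sample.int(extent, 1L),
    {
      a <- sample.int(extent, 1L); b <- sample.int(extent, 1L)
      min(a, b):max(a, b)
    },
    seq(sample.int(extent, 1L), extent, by = sample.int(3L, 1L)),
    sample.int(extent, sample.int(extent, 1L), replace = TRUE))
}

# ---- random attribute documents --------------------------------------------

rand_scalar <- function() {
  switch(sample.int(6L, 1L),
         sample.int(10000L, 1L),
         signif(stats::rnorm(1), sample(3:15, 1)),
         sample(c(TRUE, FALSE), 1L),
         paste(sample(c(letters, " ", "-", ":", "#"), sample.int(12L, 1L),
                      replace = TRUE), collapse = ""),
         NULL,
         -sample.int(500L, 1L))
}

rand_doc <- function(depth = 3L, width = 3L) {
  n <- sample.int(width, 1L)
  doc <- attr_map()
  for (i in seq_len(n)) {
    key <- paste0(sample(c("alpha", "beta", "rate", "id", "note"), 1L), "_", i)
    doc[key] <- list(rand_node(depth - 1L, width))
  }
  doc
}

rand_node <- function(depth, width) {
  if (depth <= 0L || stats::runif(1) < 0.55) return(rand_scalar())
  if (stats::runif(1) < 0.5) rand_doc(depth, width)
  else lapply(seq_len(sample.int(width, 1L)), function(i) {
    if (depth > 1L && stats::runif(1) < 0.25) rand_doc(depth - 1L, width)
    else rand_scalar()
  })
}

# Canonicalize jsonlite::parse_json output (lists of lists/scalars) into an
# attribute document for comparison with what we emitted.
json_to_doc <- function(x) as_attr_document(x)

# ---- operation programs + in-memory oracle ---------------------------------
#
# A program is a random sequence of create_group / require_group /
# create_dataset / set-attribute / bulk-attribute / delete operations, applied
# simultaneously to a live Exdir File and to a plain nested record of what the
# tree should contain.  The record is the oracle the reopened tree is compared
# against.

run_random_program <- function(root, n_ops = 30L, max_depth = 4L) {
  f <- exdir_open(root, mode = "w-")
  model <- new.env(parent = emptyenv())
  model$objs <- list()                    # path -> list(type, attrs, ...)
  model$root_attrs <- attr_map()
  groups_of <- function() {
    c("", names(model$objs)[vapply(model$objs, function(o) o$type == "group", TRUE)])
  }
  node_of <- function(path) if (path == "") f else exdir_item(f, path)
  depth_of <- function(path) if (path == "") 0L else length(strsplit(path, "/")[[1]])
  fresh_name <- function(parent) {
    sibs <- names(model$objs) %||% character(0)
    sibs <- basename(sibs[dirname(sibs) == (if (parent == "") "." else parent)])
    repeat {
      nm <- paste0(sample(letters, 1L), paste(sample(c(letters, 0:9), 5L, TRUE), collapse = ""))
      if (isTRUE(check_name(sibs, nm, "thorough")$ok)) return(nm)
    }
  }
  for (i in seq_len(n_ops)) {
    op <- sample(c("group", "require", "dataset", "attr", "bulk", "delete"), 1L,
                 prob = c(0.28, 0.10, 0.25, 0.17, 0.08, 0.12))
    parents <- groups_of()
    parent <- sample(parents, 1L)
    if (op %in% c("group", "require", "dataset") && depth_of(parent) >= max_depth) {
      op <- "attr"
    }
    if (op == "group" || op == "require") {
      nm <- fresh_name(parent)
      path <- if (parent == "") nm else paste0(parent, "/", nm)
      if (op == "group") create_group(node_of(parent), nm)
      else require_group(node_of(parent), nm)
      model$objs[[path]] <- list(type = "group", attrs = attr_map())
    } else if (op == "dataset") {
      nm <- fresh_name(parent)
      path <- if (parent == "") nm else paste0(parent, "/", nm)
      if (stats::runif(1) < 0.5) {
        vals <- stats::rnorm(sample.int(6L, 1L))
        create_dataset(node_of(parent), nm, data = vals)
        model$objs[[path]] <- list(type = "dataset", attrs = attr_map(),
                                   shape = length(vals), descr = "<f8", data = vals)
      } else {
        vals <- sample.int(100L, sample.int(6L, 1L), replace = TRUE)
        create_dataset(node_of(parent), nm, data = vals, dtype = "<i4")
        model$objs[[path]] <- list(type = "dataset", attrs = attr_map(),
                                   shape = length(vals), descr = "<i4", data = vals)
      }
    } else if (op == "attr") {
      targets <- c("", names(model$objs))
      t <- sample(targets, 1L)
      key <- paste0("k", sample.int(20L, 1L))
      val <- rand_scalar()
      exdir_set_attr(node_of(t), key, val)
      if (t == "") model$root_attrs[key] <- list(val)
      else model$objs[[t]]$attrs[key] <- list(val)
    } else if (op == "bulk") {
      targets <- c("", names(model$objs))
      t <- sample(targets, 1L)
      doc <- rand_doc(2L)
      obj <- node_of(t)
      exdir_attrs(obj) <- doc
      if (t == "") model$root_attrs <- doc else model$objs[[t]]$attrs <- doc
    } else if (op == "delete") {
      if (length(model$objs) == 0L) next
      t <- sample(names(model$objs), 1L)
      exdir_delete(f, t)
      pref <- paste0(t, "/")
      gone <- names(model$objs)[names(model$objs) == t |
                                  startsWith(names(model$objs), pref)]
      model$objs[gone] <- NULL
    }
  }
  list(file_root = root, objs = model$objs[sort(names(model$objs), method = "radix")],
       root_attrs = model$root_attrs)
}

# Compare a reopened tree against the oracle record; TRUE or a message.
check_against_model <- function(oracle) {
  f <- exdir_open(oracle$file_root, mode = "r")
  if (!attr_doc_equal(exdir_attrs(f), oracle$root_attrs)) return("root attrs differ")
  walk <- exdir_walk(f)
  if (!identical(names(walk) %||% character(0),
                 names(oracle$objs) %||% character(0))) {
    return(sprintf("paths differ: {%s} vs {%s}",
                   paste(names(walk), collapse = ","),
                   paste(names(oracle$objs), collapse = ",")))
  }
  for (p in names(walk)) {
    got <- walk[[p]]; want <- oracle$objs[[p]]
    if (!identical(got$type, want$type)) return(sprintf("%s: type", p))
    if (!attr_doc_equal(got$attrs, want$attrs)) return(sprintf("%s: attrs", p))
    if (identical(want$type, "dataset")) {
      if (!identical(got$shape, as.integer(want$shape))) return(sprintf("%s: shape", p))
      if (!identical(got$descr, want$descr)) return(sprintf("%s: dtype", p))
      if (!identical(got$data, if (want$descr == "<i4") as.integer(want$data) else
                     as.double(want$data))) {
        return(sprintf("%s: data", p))
      }
    }
  }
  TRUE
}
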