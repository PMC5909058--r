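# Seeded generator of Exdir trees (valid or deliberately broken) and HDF5
# twins.  Every test input in the package is produced by this module — no
# downloaded data.  Trees are written through the public API, so generating a
# fixture doubles as an integration exercise of the library; fault injections
# bypass the API on purpose and edit raw files.

#' Specification for a generated tree
#'
#' @param seed Integer seed; identical (seed, spec) pairs produce identical
#'   manifests and byte-identical trees (modulo timestamps).
#' @param max_depth Maximum nesting depth of groups below the root.
#' @param children Length-2 integer range: children drawn per group.
#' @param dataset_shapes List of extent vectors datasets are drawn from.
#' @param dtypes NPY dtype descriptors datasets are drawn from.
#' @param p_dataset,p_raw Per-child probabilities of dataset/raw (otherwise a
#'   group, until `max_depth`).
#' @param attr_depth Maximum nesting of generated attribute documents (0 = no
#'   attributes).
#' @param faults Character vector drawn from `"truncate_npy"`,
#'   `"bad_type_tag"`, `"case_collision"`, `"flow_style_yaml"`,
#'   `"missing_meta"`; each is injected once, after generation.
#' @return A `tree_spec` object.
#' @export
tree_spec <- function(seed = 1L, max_depth = 3L, children = c(1L, 3L),
                      dataset_shapes = list(5L, c(2L, 3L)),
                      dtypes = c("<f8", "<i4"),
                      p_dataset = 0.4, p_raw = 0.1,
                      attr_depth = 2L, faults = character()) {
  bad <- setdiff(faults, c("truncate_npy", "bad_type_tag", "case_collision",
                           "flow_style_yaml", "missing_meta"))
  if (length(bad)) {
    stop_exdirr("exdirr_invalid_argument",
                sprintf("unknown fault injection(s): %s", paste(bad, collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), max_depth = as.integer(max_depth),
                 children = as.integer(children), dataset_shapes = dataset_shapes,
                 dtypes = dtypes, p_dataset = p_dataset, p_raw = p_raw,
                 attr_depth = as.integer(attr_depth), faults = faults),
            class = "tree_spec")
}

gen_name <- function(taken) {
  stems <- c("session", "trial", "unit", "lfp", "stim", "probe", "sweep", "epoch")
  repeat {
    nm <- sprintf("%s_%02d", sample(stems, 1L), sample.int(99L, 1L))
    if (!tolower(nm) %in% tolower(taken)) return(nm)
  }
}

gen_scalar <- function() {
  switch(sample.int(4L, 1L),
         sample.int(1000L, 1L),
         stats::runif(1L),
         sample(c(TRUE, FALSE), 1L),
         paste0("v ", sample.int(99L, 1L)))   # space forces quoting
}

gen_attr_doc <- function(depth) {
  n <- sample.int(3L, 1L)
  keys <- paste0("k", sample.int(50L, n))
  doc <- attr_map()
  for (k in keys) {
    doc[[k]] <- if (depth > 0L && stats::runif(1L) < 0.3) {
      if (stats::runif(1L) < 0.5) gen_attr_doc(depth - 1L)
      else lapply(seq_len(sample.int(3L, 1L)), function(i) gen_scalar())
    } else gen_scalar()
  }
  doc
}

gen_values <- function(dt, n) {
  switch(dt$kind,
         f = round(stats::rnorm(n), 6),
         i = sample.int(1000L, n, replace = TRUE),
         u = sample.int(1000L, n, replace = TRUE),
         b = sample(c(TRUE, FALSE), n, replace = TRUE),
         S = ,
         U = replicate(n, paste0("s", sample.int(999L, 1L))))
}

#' Generate an Exdir tree from a spec
#'
#' The tree is written through the public API (so every fixture is also an
#' API integration run); the returned manifest is the ground-truth oracle that
#' tests compare walks against.  Fault injections are applied afterwards by
#' editing files directly (they produce trees the API itself refuses to
#' create) and are recorded in the manifest's `faults` attribute.
#'
#' @param spec A [tree_spec()].
#' @param target Path for the new File root (must not exist).
#' @return Named list keyed by relative path: `type`, and for datasets
#'   `shape`/`descr`/`data`, plus `attrs`; ordering is deterministic.
#' @export
generate_tree <- function(spec, target) {
  stopifnot(inherits(spec, "tree_spec"))
  set.seed(spec$seed)
  f <- exdir_open(target, mode = "w-")
  manifest <- list()
  gen_children <- function(group, rel, depth) {
    n <- sample(seq(spec$children[1], spec$children[2]), 1L)
    for (i in seq_len(n)) {
      nm <- gen_name(exdir_keys(group))
      path <- if (nzchar(rel)) paste0(rel, "/", nm) else nm
      u <- stats::runif(1L)
      if (u < spec$p_dataset || depth >= spec$max_depth) {
        shape <- spec$dataset_shapes[[sample.int(length(spec$dataset_shapes), 1L)]]
        descr <- sample(spec$dtypes, 1L)
        dt <- parse_descr(descr)
        nvals <- if (length(shape) == 0L) 1L else prod(shape)
        vals <- gen_values(dt, nvals)
        if (length(shape) > 1L) vals <- array(vals, dim = shape)
        d <- create_dataset(group, nm, data = vals, dtype = descr,
                            shape = shape)
        entry <- list(type = "dataset", shape = as.integer(shape),
                      descr = dataset_handle(d)$dt$descr,
                      data = npy_read(dataset_handle(d)))
      } else if (u < spec$p_dataset + spec$p_raw) {
        r <- create_raw(group, nm)
        writeLines(sprintf("payload %d", sample.int(1e6L, 1L)),
                   file.path(obj_dir(r), "blob.txt"))
        entry <- list(type = "raw")
        d <- r
      } else {
        g <- create_group(group, nm)
        entry <- list(type = "group")
        d <- g
      }
      attrs <- if (spec$attr_depth > 0L && stats::runif(1L) < 0.6) {
        gen_attr_doc(spec$attr_depth - 1L)
      } else attr_map()
      if (length(attrs)) {
        obj <- exdir_item(f, path)
        exdir_attrs(obj) <- attrs
      }
      entry$attrs <- attrs
      manifest[[path]] <<- entry
      if (identical(entry$type, "group")) {
        kid <- exdir_item(f, path)
        gen_children(kid, path, depth + 1L)
      }
    }
    invisible()
  }
  gen_children(f, "", 1L)
  manifest <- manifest[sort_c(names(manifest))]
  faults <- lapply(spec$faults, function(fl) inject_fault(f, manifest, fl))
  names(faults) <- spec$faults
  attr(manifest, "faults") <- faults
  manifest
}

# Injections write files directly (the API would refuse these states).
inject_fault <- function(f, manifest, fault) {
  root <- obj_dir(f)
  paths <- names(manifest)
  types <- vapply(manifest, function(e) e$type, "")
  pick <- function(type) {
    cands <- paths[types == type]
    if (!length(cands)) return(NULL)
    cands[[sample.int(length(cands), 1L)]]
  }
  switch(fault,
    truncate_npy = {
      p <- pick("dataset")
      if (is.null(p)) return(NULL)
      npy <- file.path(root, p, "data.npy")
      sz <- file.info(npy)$size
      raw <- readBin(npy, "raw", sz)
      writeBin(raw[seq_len(max(1, sz - 16))], npy)   # chop payload bytes
      list(path = p, detail = "data.npy truncated by 16 bytes")
    },
    bad_type_tag = {
      p <- pick("group") %||% pick("dataset")
      if (is.null(p)) return(NULL)
      write_text_atomic(file.path(root, p, "exdir.yaml"),
                        "exdir:\n  type: \"banana\"\n  version: 1\n")
      list(path = p, detail = "unknown type tag")
    },
    case_collision = {
      p <- pick("group")
      if (is.null(p)) return(NULL)
      twin <- file.path(dirname(file.path(root, p)), toupper(basename(p)))
      if (dir.exists(twin)) return(NULL)
      dir.create(twin)
      write_text_atomic(file.path(twin, "exdir.yaml"),
                        "exdir:\n  type: \"group\"\n  version: 1\n")
      list(path = p, detail = "case-colliding sibling added")
    },
    flow_style_yaml = {
      p <- pick("group") %||% pick("dataset")
      if (is.null(p)) return(NULL)
      write_text_atomic(file.path(root, p, "attributes.yaml"),
                        "flowy: [1, 2, 3]\n")
      list(path = p, detail = "flow-style attributes.yaml")
    },
    missing_meta = {
      p <- pick("group")
      if (is.null(p)) return(NULL)
      unlink(file.path(root, p, "exdir.yaml"))
      list(path = p, detail = "exdir.yaml removed (reads as raw)")
    })
}

#' Write an HDF5 twin of a generated tree
#'
#' Converts the common subset (groups, datasets, scalar/sequence attributes;
#' raw directories skipped, nested attributes flattened) of an Exdir tree to
#' an HDF5 file, feeding the converter round-trip tests.
#'
#' @param tree_root Path of an Exdir File root.
#' @param target Destination HDF5 file.
#' @return The conversion report, invisibly.
#' @export
generate_hdf5_twin <- function(tree_root, target) {
  invisible(exdir_to_hdf5(tree_root, target, raw_mode = "skip", overwrite = TRUE))
}
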