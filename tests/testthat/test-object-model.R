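# The four-object hierarchy: open modes, creation, lookup, iteration,
# deletion, attributes, naming.

test_that("open modes follow the h5py convention", {
  root <- new_root("modes")
  expect_error(exdir_open(root, "r"), class = "exdirr_not_found")
  expect_error(exdir_open(root, "r+"), class = "exdirr_not_found")
  f <- exdir_open(root, "w")
  expect_identical(exdir_type(f), "file")
  expect_identical(exdir_name(f), "/")
  expect_true(file.exists(file.path(root, "exdir.yaml")))
  expect_error(exdir_open(root, "w-"), class = "exdirr_exists")
  expect_error(exdir_open(root, "x"), class = "exdirr_exists")
  create_group(f, "g")
  f2 <- exdir_open(root, "a")                    # opens, does not truncate
  expect_true(exdir_contains(f2, "g"))
  f3 <- exdir_open(root, "w")                    # truncates
  expect_false(exdir_contains(f3, "g"))
  # parent must exist
  expect_error(exdir_open(file.path(root, "no", "such", "parent.exdir"), "w"),
               class = "exdirr_not_found")
})

test_that("opening rejects non-File and non-Exdir directories", {
  dir <- withr::local_tempdir()
  plain <- file.path(dir, "plain")
  dir.create(plain)
  expect_error(exdir_open(plain, "r"), class = "exdirr_not_exdir")
  expect_error(exdir_open(plain, "w"), class = "exdirr_not_exdir")  # refuses truncate
  # a dataset's metadata at the root is a type mismatch
  dsdir <- file.path(dir, "ds")
  dir.create(dsdir)
  writeLines("exdir:\n  type: \"dataset\"\n  version: 1", file.path(dsdir, "exdir.yaml"))
  expect_error(exdir_open(dsdir, "r"), class = "exdirr_type_mismatch")
})

test_that("create_group creates one level at a time; ancestors must exist", {
  root <- new_root("grp")
  f <- exdir_open(root, "w")
  g <- create_group(f, "session1")
  expect_identical(exdir_type(g), "group")
  expect_true(file.exists(file.path(root, "session1", "exdir.yaml")))
  expect_error(create_group(f, "a/b"), class = "exdirr_not_found")
  create_group(f, "a")
  ab <- create_group(f, "a/b")
  expect_identical(exdir_name(ab), "/a/b")
  expect_error(create_group(f, "session1"), class = "exdirr_exists")
  expect_error(create_group(f, ""), class = "exdirr_invalid_name")
  expect_error(create_group(f, "x/../y"), class = "exdirr_invalid_name")
})

test_that("require_group is idempotent and type-checked", {
  root <- new_root("req")
  f <- exdir_open(root, "w")
  g1 <- require_group(f, "g")
  g2 <- require_group(f, "g")
  expect_identical(obj_dir <- exdir_name(g1), exdir_name(g2))
  expect_length(exdir_keys(f), 1L)
  create_dataset(f, "d", data = 1:3)
  expect_error(require_group(f, "d"), class = "exdirr_type_mismatch")
  # interleaved create/require over random names equals the set-union oracle
  set.seed(11)
  want <- character(0)
  for (i in 1:20) {
    nm <- paste0("n", sample.int(8L, 1L))
    if (nm %in% want) require_group(f, nm) else { create_group(f, nm); want <- c(want, nm) }
  }
  expect_identical(exdir_keys(f), sort(c("d", "g", want), method = "radix"))
})

test_that("dataset creation from shape zero-fills; from data round-trips", {
  root <- new_root("ds")
  f <- exdir_open(root, "w")
  z <- create_dataset(f, "mydata", shape = 3L, dtype = "<i4")
  expect_identical(z[], c(0L, 0L, 0L))
  vals <- stats::rnorm(1000)
  d <- create_dataset(f, "a", data = vals)
  expect_identical(d[], vals)
  expect_identical(exdir_shape(d), 1000L)
  expect_identical(exdir_dtype(d), "<f8")
  expect_error(create_dataset(f, "x"), class = "exdirr_missing_spec")
  expect_error(create_dataset(f, "x", shape = 4L, data = 1:3),
               class = "exdirr_inconsistent")
  # default dtype for shape-only creation is float64
  expect_identical(exdir_dtype(create_dataset(f, "zz", shape = c(2L, 2L))), "<f8")
})

test_that("raw objects hold foreign files; meta-less directories read as raw", {
  root <- new_root("raw")
  f <- exdir_open(root, "w")
  r <- create_raw(f, "acquisition")
  writeLines("scope trace", file.path(root, "acquisition", "trace.csv"))
  f2 <- exdir_open(root, "a")
  r2 <- f2[["acquisition"]]
  expect_identical(exdir_type(r2), "raw")
  expect_true("trace.csv" %in% list.files(file.path(root, "acquisition")))
  # raw objects can carry attributes
  exdir_set_attr(r2, "scope", "model-7")
  expect_true(file.exists(file.path(root, "acquisition", "attributes.yaml")))
  # an externally created bare directory classifies as raw
  dir.create(file.path(root, "external"))
  expect_identical(exdir_type(f2[["external"]]), "raw")
  expect_identical(exdir_keys(f2), c("acquisition", "external"))
})

test_that("item lookup is case-exact and refuses descent through non-groups", {
  root <- new_root("lookup")
  f <- exdir_open(root, "w")
  g <- create_group(f, "g")
  create_dataset(g, "d", data = 1:3)
  expect_identical(exdir_type(exdir_item(f, "g/d")), "dataset")
  expect_identical(exdir_name(f[["g/d"]]), "/g/d")
  expect_error(exdir_item(f, "G/d"), class = "exdirr_not_found")
  expect_error(exdir_item(f, "g/D"), class = "exdirr_not_found")
  expect_error(exdir_item(f, "g/d/x"), class = "exdirr_not_a_group")
  expect_true(exdir_contains(f, "g/d"))
  expect_false(exdir_contains(f, "g/x"))
  expect_null(exdir_get(f, "nope"))
  expect_identical(exdir_get(f, "nope", default = "fallback"), "fallback")
})

test_that("iteration lists children in code-point order, case preserved", {
  root <- new_root("iter")
  f <- exdir_open(root, "w", name_validation = "minimal")
  for (nm in c("b", "A", "c", "Zz", "a")) create_group(f, nm)
  expect_identical(exdir_keys(f), c("A", "Zz", "a", "b", "c"))
  expect_identical(names(f), exdir_keys(f))
  vals <- exdir_values(f)
  expect_true(all(vapply(vals, exdir_type, "") == "group"))
  items <- exdir_items(f)
  expect_identical(names(items), exdir_keys(f))
  empty <- create_group(f, "empty")
  expect_identical(exdir_keys(empty), character(0))
})

test_that("deletion removes the whole subtree and frees the space", {
  root <- new_root("del")
  f <- exdir_open(root, "w")
  g <- create_group(f, "g")
  sub <- create_group(g, "sub")
  create_dataset(sub, "big", data = stats::rnorm(1e6))
  create_dataset(g, "keep", data = 1:3)
  size_before <- sum(file.info(list.files(root, recursive = TRUE,
                                          full.names = TRUE))$size)
  exdir_delete(g, "sub")
  remaining <- list.files(root, recursive = TRUE, full.names = TRUE)
  expect_false(any(grepl("sub", remaining, fixed = TRUE)))
  size_after <- sum(file.info(remaining)$size)
  expect_gte(size_before - size_after, 8e6)
  expect_false(exdir_contains(f, "g/sub"))
  expect_true(exdir_contains(f, "g/keep"))
  expect_error(exdir_delete(g, "sub"), class = "exdirr_not_found")
  # stale handles fail loudly
  expect_error(exdir_keys(sub), class = "exdirr_stale")
})

test_that("attribute writes merge per key; bulk assignment replaces; bytes match", {
  root <- new_root("attrs")
  f <- exdir_open(root, "w")
  g <- create_group(f, "g")
  exdir_set_attr(g, "temperature", 32L)
  expect_identical(exdir_attrs(g)$temperature, 32L)
  exdir_set_attr(g, "ratio", 0.5)
  expect_identical(exdir_attrs(g)$temperature, 32L)      # merge kept the key
  nested <- list(rig = list(room = "2B", probes = list(1L, 2L)))
  exdir_attrs(g) <- nested
  expect_true(attr_doc_equal(exdir_attrs(g), nested))     # replace dropped old keys
  # one-by-one vs one bulk write: byte-identical attributes.yaml
  set.seed(5)
  keys <- sprintf("k%03d", 1:200)
  vals <- lapply(1:200, function(i) rand_scalar())
  a <- create_group(f, "one_by_one")
  for (i in 1:200) exdir_set_attr(a, keys[i], vals[[i]])
  b <- create_group(f, "bulk")
  doc <- attr_map()
  for (i in 1:200) doc[keys[i]] <- vals[i]
  exdir_attrs(b) <- doc
  expect_identical(readBin(file.path(root, "one_by_one", "attributes.yaml"), "raw", 1e6),
                   readBin(file.path(root, "bulk", "attributes.yaml"), "raw", 1e6))
})

test_that("object names render with slashes and invert through lookup", {
  root <- new_root("names")
  f <- exdir_open(root, "w")
  g <- create_group(f, "g")
  s <- create_group(g, "Sub")
  d <- create_dataset(s, "d", data = 1:2)
  expect_identical(exdir_name(f), "/")
  expect_identical(exdir_name(d), "/g/Sub/d")
  # inverse property over a generated tree
  tree <- new_root("invtree")
  manifest <- generate_tree(tree_spec(seed = 19, max_depth = 3, children = c(2L, 3L)),
                            tree)
  fr <- exdir_open(tree, "r")
  for (p in names(manifest)) {
    obj <- exdir_item(fr, p)
    expect_identical(exdir_name(obj), paste0("/", p))
    expect_identical(exdir_type(obj), manifest[[p]]$type)
  }
})

test_that("no operation can nest a File, and every object dir carries its schema", {
  root <- new_root("schema")
  f <- exdir_open(root, "w")
  g <- create_group(f, "g")
  create_dataset(g, "d", data = 1:3)
  create_raw(g, "r")
  for (p in c("", "g", "g/d", "g/r")) {
    dir <- if (nzchar(p)) file.path(root, p) else root
    meta <- parse_lenient(paste(readLines(file.path(dir, "exdir.yaml")),
                                collapse = "\n"))$document
    expect_false(identical(meta$exdir$type, "file") && nzchar(p))
    expect_identical(meta$exdir$version, 1L)
  }
  expect_true(file.exists(file.path(root, "g", "d", "data.npy")))
  # a hand-corrupted nested "file" tag is tolerated on read as a group
  writeLines("exdir:\n  type: \"file\"\n  version: 1",
             file.path(root, "g", "exdir.yaml"))
  f2 <- exdir_open(root, "a")
  expect_identical(exdir_type(f2[["g"]]), "group")
  expect_false(exdir_lint_ok(exdir_lint(root)))
})

test_that("read-only files refuse every mutating operation", {
  root <- new_root("ro")
  f <- exdir_open(root, "w")
  create_group(f, "g")
  r <- exdir_open(root, "r")
  expect_error(create_group(r, "x"), class = "exdirr_read_only")
  expect_error(create_dataset(r, "x", data = 1:3), class = "exdirr_read_only")
  expect_error(create_raw(r, "x"), class = "exdirr_read_only")
  expect_error(exdir_delete(r, "g"), class = "exdirr_read_only")
  expect_error(exdir_set_attr(r, "a", 1L), class = "exdirr_read_only")
  expect_error({ exdir_attrs(r) <- list(a = 1L) }, class = "exdirr_read_only")
})

test_that("random operation programs survive close/reopen (oracle replay)", {
  set.seed(777)
  for (i in 1:10) {
    root <- file.path(withr::local_tempdir(), sprintf("prog%02d.exdir", i))
    oracle <- run_random_program(root, n_ops = 40L)
    expect_true(isTRUE(check_against_model(oracle)), info = sprintf("program #%d", i))
  }
})
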