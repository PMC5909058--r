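# HDF5 <-> Exdir structural conversion (h5py through `python` is the HDF5
# side; everything structural is checked via tree walks).

test_that("a small HDF5 file maps group-for-group, dataset-for-dataset", {
  dir <- withr::local_tempdir()
  h5 <- file.path(dir, "small.h5")
  run_py(sprintf("
import h5py, numpy as np
with h5py.File('%s', 'w') as f:
    g = f.create_group('session')
    d = g.create_dataset('lfp', data=np.arange(6, dtype='<f8').reshape(3, 2))
    d.attrs['channels'] = np.int64(2)
    g.attrs['note'] = 'first day'
    f.attrs['temperature'] = 21.5
", h5))
  target <- file.path(dir, "out.exdir")
  report <- hdf5_to_exdir(h5, target)
  expect_identical(unname(report$converted), c(1L, 1L, 3L))
  f <- exdir_open(target, "r")
  expect_identical(exdir_attrs(f)$temperature, 21.5)
  expect_identical(exdir_attrs(f[["session"]])$note, "first day")
  d <- f[["session/lfp"]]
  expect_identical(exdir_shape(d), c(3L, 2L))
  expect_identical(exdir_dtype(d), "<f8")
  expect_identical(d[], matrix(as.double(0:5), nrow = 3, byrow = TRUE))
  expect_identical(exdir_attrs(d)$channels, 2L)
  expect_true(exdir_lint_ok(exdir_lint(target)))
})

test_that("soft links and compound dtypes are skipped with reasons, never fatal", {
  dir <- withr::local_tempdir()
  h5 <- file.path(dir, "links.h5")
  run_py(sprintf("
import h5py, numpy as np
with h5py.File('%s', 'w') as f:
    f.create_dataset('real', data=np.ones(3))
    f['alias'] = h5py.SoftLink('/real')
    f.create_dataset('table', data=np.zeros(2, dtype=[('a', '<f8')]))
", h5))
  target <- file.path(dir, "out.exdir")
  report <- hdf5_to_exdir(h5, target)
  expect_identical(unname(report$converted["datasets"]), 1L)
  expect_identical(sort(report$skipped$path), c("alias", "table"))
  expect_true(any(grepl("link", report$skipped$reason)))
  f <- exdir_open(target, "r")
  expect_true(exdir_contains(f, "real"))
  expect_false(exdir_contains(f, "alias"))
})

test_that("nested attributes flatten to dotted keys with a lossy report entry", {
  dir <- withr::local_tempdir()
  root <- file.path(dir, "src.exdir")
  f <- exdir_open(root, "w")
  g <- create_group(f, "g")
  suppressWarnings(                       # 'dot.ted' key draws the (intended)
    exdir_attrs(g) <- list(a = list(b = 1L), plain = "x", `dot.ted` = 2L)
  )                                       # convention warning at write time
  h5 <- file.path(dir, "flat.h5")
  report <- exdir_to_hdf5(root, h5)
  expect_true(any(grepl("flatten", report$lossy$description)))
  back <- file.path(dir, "back.exdir")
  hdf5_to_exdir(h5, back)
  attrs <- exdir_attrs(exdir_open(back, "r")[["g"]])
  expect_identical(attrs[["a.b"]], 1L)
  expect_identical(attrs[["plain"]], "x")
  expect_identical(attrs[["dot\\.ted"]], 2L)     # literal dot escaped
})

test_that("raw directories are skipped by default or stored as opaque bytes", {
  dir <- withr::local_tempdir()
  root <- file.path(dir, "src.exdir")
  f <- exdir_open(root, "w")
  r <- create_raw(f, "acq")
  payload <- as.raw(c(1, 2, 250, 0, 9))
  writeBin(payload, file.path(root, "acq", "blob.bin"))
  h5a <- file.path(dir, "skip.h5")
  rep_skip <- exdir_to_hdf5(root, h5a, raw_mode = "skip")
  expect_identical(rep_skip$skipped$path, "acq")
  out_a <- file.path(dir, "back_skip.exdir")
  hdf5_to_exdir(h5a, out_a)
  expect_false(exdir_contains(exdir_open(out_a, "r"), "acq"))
  h5b <- file.path(dir, "opaque.h5")
  rep_op <- exdir_to_hdf5(root, h5b, raw_mode = "opaque")
  expect_true(any(grepl("opaque", rep_op$lossy$description)))
  out_b <- file.path(dir, "back_opaque.exdir")
  hdf5_to_exdir(h5b, out_b)
  d <- exdir_open(out_b, "r")[["acq/blob.bin"]]
  expect_identical(d[], as.integer(payload))
})

test_that("seeded fixtures round trip exdir -> hdf5 -> exdir walk-equal", {
  for (seed in c(5L, 17L, 41L)) {
    dir <- withr::local_tempdir()
    tree <- file.path(dir, "t.exdir")
    generate_tree(tree_spec(seed = seed, max_depth = 3L, children = c(2L, 3L),
                            p_raw = 0, attr_depth = 1L), tree)
    h5 <- file.path(dir, "t.h5")
    generate_hdf5_twin(tree, h5)
    back <- file.path(dir, "b.exdir")
    hdf5_to_exdir(h5, back)
    expect_true(isTRUE(walk_equal(exdir_walk(exdir_open(tree, "r")),
                                  exdir_walk(exdir_open(back, "r")))),
                info = sprintf("seed %d", seed))
    expect_true(exdir_lint_ok(exdir_lint(back)), info = sprintf("seed %d", seed))
    # second hop is exactly idempotent
    h52 <- file.path(dir, "t2.h5")
    exdir_to_hdf5(back, h52)
    back2 <- file.path(dir, "b2.exdir")
    hdf5_to_exdir(h52, back2)
    expect_true(isTRUE(walk_equal(exdir_walk(exdir_open(back, "r")),
                                  exdir_walk(exdir_open(back2, "r")))),
                info = sprintf("seed %d (idempotence)", seed))
  }
})

test_that("names invalid under thorough validation convert with a report entry", {
  dir <- withr::local_tempdir()
  h5 <- file.path(dir, "odd.h5")
  run_py(sprintf("
import h5py, numpy as np
with h5py.File('%s', 'w') as f:
    f.create_dataset('name', data=np.ones(2))
    f.create_dataset('Name', data=np.zeros(2))   # case-colliding pair
", h5))
  target <- file.path(dir, "out.exdir")
  report <- hdf5_to_exdir(h5, target)
  expect_identical(unname(report$converted["datasets"]), 2L)
  expect_true(any(grepl("minimal validation", report$lossy$description)))
  f <- exdir_open(target, "r")
  expect_true(exdir_contains(f, "name") && exdir_contains(f, "Name"))
})
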