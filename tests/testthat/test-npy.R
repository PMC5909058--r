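# NPY storage: conformance across dtypes and shapes, header handling,
# corruption detection.  numpy (through `python`) is the independent
# reference implementation.

npy_dtypes <- c("<i1", "<i2", "<i4", "<i8", "|u1", "<u2", "<u4", "<u8",
                "<f4", "<f8", "|b1")

sample_values <- function(descr, n) {
  switch(substr(descr, 2, 2),
    # dyadic fractions stay exact in float32 as well as float64
    f = if (descr == "<f4") sample.int(2048L, n, replace = TRUE) / 64
        else stats::rnorm(n),
    b = sample(c(TRUE, FALSE), n, replace = TRUE),
    i = switch(descr,
      "<i1" = sample(-128:127, n, replace = TRUE),
      "<i2" = sample(c(-32768L, -1L, 0L, 1L, 32767L), n, replace = TRUE),
      "<i4" = sample(c(-.Machine$integer.max, -5L, 0L, 7L, .Machine$integer.max),
                     n, replace = TRUE),
      "<i8" = c(-2^52, -5, 0, 3, 2^52)[sample.int(5L, n, replace = TRUE)]),
    u = switch(descr,
      "|u1" = sample(0:255, n, replace = TRUE),
      "<u2" = sample(c(0L, 1L, 32768L, 65535L), n, replace = TRUE),
      "<u4" = c(0, 1, 2^31, 2^32 - 1)[sample.int(4L, n, replace = TRUE)],
      "<u8" = c(0, 1, 2^52, 2^53 - 1)[sample.int(4L, n, replace = TRUE)]))
}

test_that("written files round-trip through our own reader across dtypes and shapes", {
  set.seed(101)
  dir <- withr::local_tempdir()
  shapes <- list(integer(0), 0L, 5L, c(0L, 3L), c(2L, 3L), c(2L, 3L, 4L))
  for (descr in npy_dtypes) {
    for (si in seq_along(shapes)) {
      shape <- shapes[[si]]
      n <- if (length(shape) == 0L) 1L else prod(shape)
      vals <- sample_values(descr, n)
      if (length(shape) > 1L) vals <- array(vals, dim = shape)
      p <- file.path(dir, sprintf("%s_%d.npy", gsub("[<|]", "", descr), si))
      npy_write(p, vals, dtype = descr, shape = shape)
      h <- npy_open(p)
      expect_identical(h$shape, as.integer(shape), info = paste(descr, si))
      expect_identical(npy_read(h), vals, info = paste(descr, si))
    }
  }
})

test_that("numpy reads our files and we read numpy's, payloads identical", {
  set.seed(102)
  dir <- withr::local_tempdir()
  specs <- list()
  for (descr in npy_dtypes) {
    vals <- sample_values(descr, 24L)
    a <- array(vals, dim = c(2L, 3L, 4L))
    p <- file.path(dir, paste0("r_", gsub("[<|]", "", descr), ".npy"))
    npy_write(p, a, dtype = descr)
    specs[[descr]] <- list(path = p, values = a)
  }
  # scalars and empties too
  npy_write(file.path(dir, "r_scalar.npy"), 1.5, shape = integer(0))
  npy_write(file.path(dir, "r_empty.npy"), array(double(0), c(0L, 3L)))
  run_py(sprintf("
import glob, os
import numpy as np
d = '%s'
for fn in sorted(glob.glob(os.path.join(d, 'r_*.npy'))):
    a = np.load(fn)                       # independent reader must accept it
    out = os.path.join(d, 'py_' + os.path.basename(fn)[2:])
    np.save(out, a)                       # and re-emit for us to read back
", dir))
  for (descr in names(specs)) {
    back <- npy_read(file.path(dir, paste0("py_", gsub("[<|]", "", descr), ".npy")))
    expect_identical(back, specs[[descr]]$values, info = descr)
  }
  s <- npy_open(file.path(dir, "py_scalar.npy"))
  expect_identical(s$shape, integer(0))
  expect_identical(npy_read(s), 1.5)
  e <- npy_open(file.path(dir, "py_empty.npy"))
  expect_identical(e$shape, c(0L, 3L))
})

test_that("float payloads survive bit-exactly, including signed zero and NaN", {
  dir <- withr::local_tempdir()
  vals <- c(0, -0, NaN, Inf, -Inf, .Machine$double.xmin, 5e-324)
  p <- file.path(dir, "bits.npy")
  npy_write(p, vals)
  back <- npy_read(p)
  expect_true(identical(back, vals, num.eq = FALSE, single.NA = FALSE))
})

test_that("open parses only the header and flags truncated payloads", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.npy")
  npy_write(p, as.double(1:100))
  h <- npy_open(p)
  expect_identical(h$shape, 100L)
  expect_identical(h$dt$descr, "<f8")
  # chop payload: header intact, data short
  raw <- readBin(p, "raw", file.info(p)$size)
  writeBin(raw[1:(length(raw) - 40L)], p)
  expect_error(npy_open(p), class = "exdirr_corrupt")
  # not an NPY file at all
  writeBin(charToRaw("PK\x03\x04 not numpy at all"), p)
  expect_error(npy_open(p), class = "exdirr_not_npy")
})

test_that("version 2.0 headers and fortran-ordered payloads are read", {
  dir <- withr::local_tempdir()
  run_py(sprintf("
import numpy as np
from numpy.lib import format as nf
d = '%s'
a = np.arange(12, dtype='<i4').reshape(3, 4)
with open(d + '/v2.npy', 'wb') as fh:
    nf.write_array(fh, a, version=(2, 0))
np.save(d + '/fort.npy', np.asfortranarray(np.arange(6, dtype='<f8').reshape(2, 3)))
np.save(d + '/big.npy', np.arange(6, dtype='>f8').reshape(2, 3))
", dir))
  v2 <- npy_read(file.path(dir, "v2.npy"))
  expect_identical(v2, matrix(0:11, nrow = 3, byrow = TRUE))
  fort <- npy_read(file.path(dir, "fort.npy"))
  expect_identical(fort, matrix(as.double(0:5), nrow = 2, byrow = TRUE))
  big <- npy_read(file.path(dir, "big.npy"))
  expect_identical(big, matrix(as.double(0:5), nrow = 2, byrow = TRUE))
})

test_that("read_only handles refuse writes; structured dtypes are rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ro.npy")
  npy_write(p, as.double(1:10))
  h <- npy_open(p, "read_only")
  expect_error(npy_write_slice(h, list(1:2), 0), class = "exdirr_read_only")
  run_py(sprintf("
import numpy as np
a = np.zeros(3, dtype=[('x', '<f8'), ('y', '<i4')])
np.save('%s/rec.npy', a)
", dir))
  expect_error(npy_open(file.path(dir, "rec.npy")),
               class = "exdirr_unsupported_dtype")
})

test_that("fixed-width string payloads round trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "s.npy")
  npy_write(p, c("ab", "xyz", ""), dtype = "|S5")
  expect_identical(npy_read(p), c("ab", "xyz", ""))
  run_py(sprintf("
import numpy as np
assert list(np.load('%s')) == [b'ab', b'xyz', b'']
np.save('%s', np.array(['alpha', 'b']))
", p, file.path(dir, "u.npy")))
  expect_identical(npy_read(file.path(dir, "u.npy")), c("alpha", "b"))
})
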