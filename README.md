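# exdirr

Hierarchical scientific data storage on plain file-system directories: an R
implementation of the **Experimental Directory Structure (Exdir)**
specification.

## The problem it addresses

Experimental pipelines — electrophysiology, imaging, behavior — accumulate
n-dimensional arrays, nested metadata, and raw acquisition files that belong
together in one annotated hierarchy. HDF5 offers exactly that abstract data
model (File / Group / Dataset / attributes), but packs everything into one
complex binary container: metadata is unreadable without HDF5 tooling, a
corrupted block can take the whole file with it, deleting a dataset does not
return its disk space, version-control systems see one giant changed blob, and
raw files from acquisition systems cannot live inside the container in their
native formats.

Exdir keeps the HDF5 abstract data model but maps it onto the file system
itself:

| Object  | On disk | Required | Optional |
|---------|---------|----------|----------|
| File    | root directory | `exdir.yaml` | `attributes.yaml` |
| Group   | directory | `exdir.yaml` | `attributes.yaml` |
| Dataset | directory | `exdir.yaml`, `data.npy` | `attributes.yaml` |
| Raw     | directory (arbitrary files) | — | `exdir.yaml`, `attributes.yaml` |

* **Metadata and attributes** are a restricted, human-readable YAML 1.2 subset
  (Core-schema types only; block style; string values quoted; no directives,
  tags, anchors, complex keys, or block scalars). Files are *written* strictly
  in the subset but *read* with full YAML — nonconforming files produce
  warnings, never errors.
* **Dataset payloads** are NPY binary arrays (`data.npy`), readable by NumPy
  and NPY libraries in many languages; this package writes NPY v1.0,
  C-contiguous, little-endian, and reads v1.0/v2.0 including Fortran-ordered
  and big-endian payloads. Slice reads seek only the bytes a selection covers.
* **Raw directories** hold acquisition files in their native formats, inside
  the same annotated hierarchy.

Because every object is its own directory, deletion frees space immediately,
corruption stays contained to a single `data.npy`, diffs are meaningful, and
any file browser can inspect an experiment.

The package is for researchers and data engineers who want an HDF5-style
programmatic interface (`create_group()`, `create_dataset()`, `[[`-lookup,
array slicing, an attribute dictionary) over such trees in R, plus a
conformance linter, an HDF5 converter, and a small CLI.

## Worked example

```r
library(exdirr)
set.seed(1)

root <- file.path(tempdir(), "experiment.exdir")
f <- exdir_open(root, mode = "w")               # create/truncate a File
session <- create_group(f, "session1")
lfp <- create_dataset(session, "lfp", data = matrix(rnorm(6), nrow = 2))
exdir_set_attr(session, "animal_id", "rat42")
exdir_attrs(lfp) <- list(sampling = list(rate = 30000L, unit = "Hz"))

lfp
#> <exdir dataset "/session1/lfp" shape (2, 3) float64 (/tmp/.../experiment.exdir)>
lfp[1, 2:3]                                     # reads only those 16 bytes
#> [1] -0.8356286  0.3295078
exdir_keys(f)
#> [1] "session1"
```

On disk, `session1/lfp/attributes.yaml` is ordinary YAML you could edit by
hand (note the quoted string value and unquoted conforming keys):

```yaml
sampling:
  rate: 30000
  unit: "Hz"
```

The same tree from the shell, via the bundled CLI (`inst/cli/exdir`):

```
$ exdir ls experiment.exdir::session1
lfp                      dataset (2, 3) float64
$ exdir lint experiment.exdir
0 error(s), 0 warning(s)
```

Other entry points: `exdir_open(..., name_validation = "minimal")` trades the
default case-collision checking for speed; `plugin_quantity()` stores
magnitude-plus-unit values; `hdf5_to_exdir()` / `exdir_to_hdf5()` convert
to and from HDF5 with per-object skip/lossy reports; `generate_tree()`
produces seeded synthetic trees (including deliberately broken ones) for
testing; `exdir_lint()` checks conformance of any tree.

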