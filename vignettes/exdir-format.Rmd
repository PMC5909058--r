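---
title: "The directory-backed data model in exdirr: design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The directory-backed data model in exdirr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exdirr)
```

## The model

exdirr implements the Experimental Directory Structure (Exdir): the HDF5
abstract data model — a rooted hierarchy of groups holding datasets, every
object carrying key–value attributes — realized as file-system directories
rather than a single binary container. Four object kinds exist. A **File** is
the root directory; it behaves as a group in every group operation and may not
contain another File. **Groups** nest arbitrarily. A **Dataset** holds one
n-dimensional array in `data.npy`. A **Raw** directory holds arbitrary foreign
files. Each object's directory carries an `exdir.yaml` declaring its type and
a format version (optional for Raw: on read, any directory without `exdir.yaml`
is classified as Raw — the only interpretation consistent with the metadata
file being optional there), and an optional `attributes.yaml` with
user-defined, arbitrarily nested attributes.

The model's central assumption is that the operating system's directory tree
is the hierarchy. That buys containment (a flipped byte in one `data.npy`
cannot affect a sibling), real deletion (removing a dataset's directory frees
its space immediately), human-readable metadata, and version-control-friendly
diffs. It costs per-object file-system overhead — creating thousands of tiny
objects is slower than appending records inside one container — and it offers
no chunked or compressed storage. Concurrent writers to the *same* object are
not coordinated; parallel access to *different* objects is delegated to the
operating system.

## Restricted YAML: strict writer, lenient reader

Metadata files use YAML 1.2 restricted to the Core-schema types (map,
sequence, string, null, boolean, integer, float) in block style, with string
*values* always double-quoted and conforming *keys* (`[A-Za-z0-9_-]+`) always
plain. Directives, tags, anchors/aliases, complex keys, flow collections, and
block scalars are excluded. The writer (`emit_restricted()`) only ever
produces this subset; the reader (`parse_lenient()`) accepts full YAML and
reports subset breaches as warnings with rule identifiers (`yaml_rules`),
never as errors. This asymmetry is deliberate: files written by other tools
remain readable, while everything this package writes is parseable by the
simplest conceivable YAML consumer.

Numerical choices in the emitter:

* Doubles print as the shortest decimal that round-trips (digits grown 1–17
  until re-parsing reproduces the value), always with a decimal point or
  exponent so the integer/float kind survives re-reading; integers print bare.
  Exponent forms are canonicalized to `1.5e+3` (dot present, exponent signed)
  because YAML 1.1 resolvers — including the libyaml binding used for reading
  — do not recognize the dotless or unsigned-exponent spellings the 1.2 Core
  schema allows. The reader applies the inverse rewrite to unquoted scalar
  values before parsing, so `1.5e3` resolves as a float, as Core requires.
* `NaN`, `Inf`, `-Inf` render as `.nan`, `.inf`, `-.inf`. `NA` has no
  representation and is rejected.
* Indentation is fixed at two spaces; key order is insertion order. Both are
  determinism choices: a document written twice is byte-identical, which is
  what makes the bulk-versus-single-key attribute test meaningful and keeps
  diffs minimal.
* Multi-line strings are emitted with escaped newlines inside double quotes
  (block scalars are excluded from the subset).
* Empty maps and sequences cannot be expressed in block style (only flow
  `{}`/`[]` could) and are rejected by the emitter rather than silently
  written in a forbidden style.

Reader behavior worth knowing: Core-schema resolution is restored on top of
the 1.1 parser (so `yes`/`no`/`on`/`off` are strings, not booleans, both as
values and as keys); duplicate mapping keys resolve to the *last* occurrence
with a `duplicate_key` warning (the underlying parser treats them as fatal, so
the earlier occurrence is excised textually and the document re-parsed); and
subnormal doubles (below about `2.2e-308`) cannot be read back — the binding
reports them out of range — so attribute values should stay in the normal
range. Structural equality of documents (`attr_doc_equal()`) compares maps
order-insensitively; byte-level determinism is a property of the emitter, not
of equality.

The violation scanner is line-oriented and quote-aware. It is exact on
everything the strict emitter can produce and on the common breaches (flow
style, plain strings, block scalars, directives, tags); pathological
multi-line constructs may be classified approximately. That is acceptable for
its role: a linter whose findings are warnings by design.

## NPY storage and sliced access

Dataset payloads are NPY files: magic, a header dict (`descr`,
`fortran_order`, `shape`), then the raw array bytes. The writer emits version
1.0 only, C-contiguous, little-endian, header padded so the payload starts on
a 64-byte boundary — the most widely readable combination for third-party
consumers. The reader accepts versions 1.0 and 2.0, Fortran order, and
big-endian payloads. Structured (record) dtypes are rejected with a classed
error on both paths; the format's tabular ambitions are explicitly deferred
and supporting half of them quietly seemed worse than refusing clearly.

R has no 64-bit integer, so `<i8`, `<u4` and `<u8` surface as doubles (exact
for magnitudes below 2^53, which covers counters and timestamps; beyond that,
precision loss is the caller's responsibility). `int8/16/32` and `uint8/16`
surface as R integers; note R cannot represent `INT32_MIN`, which would read
as `NA`. Booleans map to logicals and fixed-width `|S`/`<U` strings to
character vectors (`|S` on write, sized to the widest element).

`npy_open()` parses only the header — opening a dataset never loads its
payload. A payload shorter than `prod(shape) * itemsize` raises a
corrupt-dataset error at open, which is how corruption stays both detected and
contained. Slice reads translate per-axis index vectors into flat offsets of
the on-disk order, group them into maximal contiguous runs, and seek-read each
run; when a selection fragments into more than 4096 runs, one spanning read
of the bounding range is cheaper than thousands of seeks and is used instead.
Writes follow the same plan; when fancy indices repeat a position, the last
value wins (matching what sequential assignment would do). Dataset handles
expose R's own `[`/`[<-` semantics — negative and logical indices, recycling
whose length must divide the selection, `drop = TRUE` by default — so a
selection on a dataset equals the same selection on an in-memory R array,
which is precisely the oracle the tests use.

## Name validation

Because objects are directories, sibling names that differ only in case
collide when a tree moves from a case-sensitive to a case-insensitive file
system. The default **thorough** policy rejects, at creation time: names
colliding case-insensitively with an existing sibling (ASCII folding — the
accepted charset is ASCII anyway, and locale-dependent Unicode folding would
make acceptance environment-dependent); characters outside
`[A-Za-z0-9_. -]`; leading/trailing spaces or dots and all-dot names (Windows
legality); and the reserved names `exdir.yaml`, `attributes.yaml`, `data.npy`,
which every policy reserves since they would collide with the special files.
Space and dot are allowed mid-name to accommodate common session labels. The
**minimal** policy checks only exact-name existence plus reserved names — the
right trade when creating thousands of objects, where case scanning dominates
creation cost. The policy is fixed when the File is opened and inherited by
all descendants; a custom predicate `(parent_dir, name) -> list(ok, reason)`
can replace either. Monotonicity (anything thorough accepts, minimal accepts)
and fold-soundness (thorough-accepted siblings never collide after
lower-casing) are tested as properties.

Lookup is the deliberate counterpart: case-*exact* always, under every policy.
Validation prevents ambiguous trees; it does not make retrieval fuzzy.

## Object model decisions

* Open modes follow the h5py convention (`r`, `r+`, `w`, `w-`/`x`, `a`).
  `w` refuses to truncate a directory that is not an Exdir File — truncation
  should never destroy data the library did not write.
* Multi-component names in `create_*` require every ancestor to exist; there
  is no implicit `mkdir -p`, so no object ever materializes that the caller
  did not request.
* `create_dataset(shape = ...)` zero-fills (dtype `<f8` unless given):
  deterministic content, h5py-compatible.
* Iteration order is lexicographic by code point (radix sort, locale-proof).
  File systems do not agree on an order; tests and diffs need one.
* Attribute writes serialize to a temporary file and rename over
  `attributes.yaml` — the portable atomic primitive, so a crash mid-write
  cannot leave a half-document. Every single-key write rewrites the whole
  file; bulk assignment via `exdir_attrs<-` costs one write for any number of
  keys and produces byte-identical output to the equivalent single-key
  sequence.
* Deletion is physical directory removal. Handles into a deleted subtree
  raise a stale-handle error on next use; nothing is cached, so there is
  nothing subtler to invalidate.
* A nested `file` type tag (only producible by hand-editing) is read
  tolerantly as a group; the linter reports it as an error.

## Plugins

Plugins are pure value transformations: `prepare_write` folds a caller value
into storable data plus attributes before any I/O, `prepare_read`
reconstructs it after. Handlers run in increasing `order` on write and
decreasing on read, never touch the file system, and record which of them
transformed an object under a reserved `plugins` key in that object's
`exdir.yaml` — not in `attributes.yaml`, so user attributes stay clean, and
the on-disk layout remains plain Exdir (plugin-written trees pass the linter
unchanged). On read, a handler fires only if its marker is present, so
plugins are retroactively inert on objects written without them; a marker
whose plugin is not enabled warns and returns the raw payload (an
`exdirr.missing_plugin = "error"` option upgrades this). The built-in
quantity plugin stores a magnitude array plus a unit string symbol — no
dimensional analysis, deliberately: unit algebra belongs to dedicated
packages, storage only needs the symbol to survive the round trip.

## HDF5 conversion

Conversion is schema-agnostic structural mapping. The Exdir side — tree
walking, validation, reports — is R; HDF5 reading/writing is delegated to the
h5py/NumPy stack through a small bridge script invoked as a subprocess, with
an exchange directory of NPY payloads plus a JSON manifest. Attribute values
cross the JSON hop with explicit type tags (integer/float/boolean/string,
scalar or homogeneous array), floats as shortest-round-trip strings so no
serializer rounds them, and non-finite floats as `"nan"`/`"inf"`/`"-inf"`.

Mapping asymmetries are reported, never fatal: HDF5 links, references and
compound types are skipped per object with a reason; nested (map-valued)
attributes — legal in Exdir, impossible in HDF5 — flatten to dotted keys with
literal dots escaped as `\.`, recorded as lossy; Raw directories are skipped
by default or stored as one `uint8` dataset per contained file under
`raw_mode = "opaque"`; source names failing thorough validation convert under
minimal validation with a report entry. Attribute insertion order does not
survive HDF5 (it iterates attributes alphabetically), which is why structural
comparison treats maps as unordered. On the common subset — groups, datasets,
scalar and homogeneous-array attributes — the round trip is walk-exact and
idempotent, and the tests assert exactly that.

## The fixture generator

`generate_tree()` produces seeded random trees through the package's own
public API, so every fixture run is also an integration exercise, and returns
the ground-truth manifest tests compare walks against. It emulates the
*structure* of experimental hierarchies — nested session/trial/probe groups,
datasets of mixed small shapes and dtypes, nested attributes, the occasional
raw directory — and deliberately not their content: no spike trains, no
imaging stacks, no realistic sizes. Passing fixtures therefore demonstrates
format correctness (layout, round trips, policy behavior), not performance or
domain plausibility on real recordings. Fault injections (`truncate_npy`,
`bad_type_tag`, `case_collision`, `flow_style_yaml`, `missing_meta`) bypass
the API and edit files directly, because they construct exactly the states
the API refuses to create; each maps to one expected linter finding. A single
seeded RNG stream drives each tree, making the manifest a pure function of
(seed, spec).

## Problem sizes and limitations

The test suite exercises 500 random operation programs of up to 50 objects,
the full dtype-by-shape NPY matrix against NumPy (including a
100 × 300 × 100 array), 200 random selections per shape with interleaved
writes, 500 random YAML documents plus an independent-parser cross-check,
10,000 name-validation sequences, 50 HDF5 round trips, and the
deletion/batching/corruption scenarios at the sizes named in their tests;
`scripts/acceptance.R` re-runs scaled versions (100 programs, 10 conversions,
2,000 name sequences) chosen to finish in about a minute while keeping every
property at a size where failures of the underlying logic would surface.

Known limitations, all stated above in context: no chunking/compression, no
object links, no locking for concurrent writers to one object; 64-bit
integers as doubles beyond 2^53; `INT32_MIN` unreadable as R integer;
subnormal attribute doubles unreadable; structured NPY dtypes rejected;
heterogeneous attribute sequences have no HDF5 image and are skipped on
conversion.
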