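Package: exdirr
Title: Experimental Directory Structure (Exdir) Hierarchical Data Storage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An implementation of the Experimental Directory Structure (Exdir),
    a specification that maps the HDF5 abstract data model (File, Group,
    Dataset, attributes) onto plain file-system directories: metadata and
    attributes live in a restricted, human-readable YAML subset, dataset
    payloads in NumPy '.npy' binary files, and arbitrary foreign files in Raw
    directories.  Provides an h5py-style hierarchical API with sliced dataset
    access, pluggable name-validation policies, a plugin system for value
    conversion (including a physical-quantity plugin), a conformance linter,
    a bidirectional HDF5 converter, a seeded fixture generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    yaml,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
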