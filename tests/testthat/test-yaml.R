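# Restricted YAML subset: strict emission, lenient parsing, violation scanner.

test_that("emitter renders the supported scalar kinds in restricted style", {
  expect_identical(emit_restricted(list(temperature = 32L)), "temperature: 32\n")
  expect_identical(emit_restricted(list(temperature = 32.0)), "temperature: 32.0\n")
  expect_identical(emit_restricted(list(note = "raw data")), "note: \"raw data\"\n")
  expect_identical(emit_restricted(list(ok = TRUE, off = FALSE)),
                   "ok: true\noff: false\n")
  expect_identical(emit_restricted(list(nothing = NULL)), "nothing: null\n")
  expect_identical(emit_restricted(attr_map()), "")
  # special floats use Core-schema spellings
  expect_identical(emit_restricted(list(a = NaN, b = Inf, c = -Inf)),
                   "a: .nan\nb: .inf\nc: -.inf\n")
  # multi-line strings are escaped, never block scalars
  expect_identical(emit_restricted(list(s = "two\nlines")), "s: \"two\\nlines\"\n")
})

test_that("nonconforming keys are emitted quoted, with a warning", {
  expect_warning(txt <- emit_restricted(list(`my key` = 1L)),
                 class = "exdirr_key_convention_warning")
  expect_identical(txt, "\"my key\": 1\n")
  expect_silent(emit_restricted(list(`sample_rate-2` = 1L)))
})

test_that("key convention accepts exactly [A-Za-z0-9_-]+", {
  expect_true(check_key_convention("sample_rate-2"))
  expect_true(check_key_convention("ABC09"))
  expect_false(check_key_convention("my key"))
  expect_false(check_key_convention(""))
  expect_false(check_key_convention("a.b"))
  expect_false(check_key_convention("café"))
})

test_that("lenient parser resolves Core-schema scalars without violations", {
  p <- parse_lenient("n: 32\nx: 1.5e3\ny: 4.9e-300\nt: true\nz: null\nq: \"hi\"\n")
  expect_length(p$violations, 0L)
  expect_identical(p$document$n, 32L)
  expect_identical(p$document$x, 1500)
  expect_identical(p$document$y, 4.9e-300)
  expect_identical(p$document$t, TRUE)
  expect_true("z" %in% names(p$document) && is.null(p$document$z))
  expect_identical(p$document$q, "hi")
  # YAML 1.2 Core does not treat yes/no/on/off as booleans: they are plain
  # strings (and, being plain strings, draw the quoting violation)
  p2 <- parse_lenient("v: yes\n")
  expect_identical(p2$document$v, "yes")
  expect_identical(vapply(p2$violations, `[[`, "", "rule"), "plain_string_value")
})

test_that("each restriction breach yields its rule id but still parses", {
  cases <- list(
    list(text = "a: [1, 2]", rule = "flow_style",
         check = function(d) identical(d$a, list(1L, 2L))),
    list(text = "a: {b: 1}", rule = "flow_style",
         check = function(d) identical(d$a$b, 1L)),
    list(text = "s: hello", rule = "plain_string_value",
         check = function(d) identical(d$s, "hello")),
    list(text = "b: |\n  text\n  more\n", rule = "block_scalar",
         check = function(d) identical(d$b, "text\nmore\n")),
    list(text = "%YAML 1.2\n---\na: 1", rule = "directive",
         check = function(d) identical(d$a, 1L)),
    list(text = "a: !!str 44", rule = "non_core_tag",
         check = function(d) identical(d$a, "44")),
    list(text = "anch: &x 1\nref: *x", rule = "node_properties",
         check = function(d) identical(d$ref, 1L)),
    list(text = "? complex\n: 1", rule = "complex_key",
         check = function(d) TRUE),
    list(text = "d: 1\nd: 2", rule = "duplicate_key",
         check = function(d) identical(d$d, 2L))
  )
  for (case in cases) {
    p <- parse_lenient(case$text)
    expect_true(case$rule %in% vapply(p$violations, `[[`, "", "rule"),
                info = case$text)
    expect_true(all(vapply(p$violations, `[[`, "", "severity") == "warning"),
                info = case$text)
    expect_true(case$check(p$document), info = case$text)
  }
})

test_that("key-convention recommendations are flagged as warnings", {
  p <- parse_lenient("my key: 1\n\"fine\": 2\n")
  rules <- vapply(p$violations, `[[`, "", "rule")
  expect_true("key_charset" %in% rules)
  expect_true("key_quoted" %in% rules)
})

test_that("malformed or non-map documents raise classed errors", {
  expect_error(parse_lenient("a: [1, 2"), class = "exdirr_parse_error")
  expect_error(parse_lenient("- 1\n- 2"), class = "exdirr_invalid_document")
  expect_error(parse_lenient("just a scalar"), class = "exdirr_invalid_document")
  expect_identical(parse_lenient("")$document, attr_map())
  expect_identical(parse_lenient("# only a comment\n")$document, attr_map())
})

test_that("emit/parse closure holds on random documents, with zero violations", {
  set.seed(42)
  for (i in 1:80) {
    doc <- rand_doc(depth = 4L)
    txt <- emit_restricted(doc)
    p <- parse_lenient(txt)
    expect_length(p$violations, 0L)
    expect_true(attr_doc_equal(doc, p$document), info = paste0("doc #", i, "\n", txt))
  }
})

test_that("integer vs float kind survives the round trip", {
  # tiny sits at the smallest *normal* double: the reader cannot represent
  # denormals (a documented limitation of the underlying YAML binding)
  doc <- list(i = 7L, f = 7.0, big = 1.25e300, tiny = 2.2250738585072014e-308)
  p <- parse_lenient(emit_restricted(doc))
  expect_identical(p$document$i, 7L)
  expect_identical(p$document$f, 7.0)
  expect_true(is.double(p$document$f))
  expect_identical(p$document$big, 1.25e300)
  expect_identical(p$document$tiny, 2.2250738585072014e-308)
})

test_that("an independent YAML 1.2 parser accepts emitter output unchanged", {
  set.seed(7)
  docs <- lapply(1:25, function(i) rand_doc(depth = 3L))
  dir <- withr::local_tempdir()
  for (i in seq_along(docs)) {
    writeLines(emit_restricted(docs[[i]]), file.path(dir, sprintf("d%03d.yaml", i)),
               sep = "")
  }
  out <- run_py(sprintf("
import glob, json, yaml
docs = []
for fn in sorted(glob.glob('%s/*.yaml')):
    with open(fn) as fh:
        docs.append(yaml.safe_load(fh))
print(json.dumps(docs))
", dir))
  parsed <- jsonlite::parse_json(paste(out, collapse = ""))
  for (i in seq_along(docs)) {
    expect_true(attr_doc_equal(json_to_doc(docs[[i]]), json_to_doc(parsed[[i]])),
                info = sprintf("python yaml disagrees on doc #%d", i))
  }
})
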