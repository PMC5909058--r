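# Restricted YAML subset: strict emitter + lenient parser + violation scanner.
#
# Exdir metadata (`exdir.yaml`) and attributes (`attributes.yaml`) use YAML 1.2
# limited to the Failsafe/JSON/Core schema types (map, sequence, string, null,
# boolean, integer, float), block style only, quoted string values, and no
# directives, node properties, complex keys or block scalars.  Files are
# WRITTEN strictly in this subset but READ with full YAML; restriction breaches
# on read are reported as warnings, never errors.

#' Rule identifiers reported by the restricted-YAML scanner
#'
#' Eight restriction rules plus two key-naming recommendations and a
#' duplicate-key rule.  All are reported with severity `"warning"`: reading is
#' lenient by design.
#'
#' @format A character vector of rule ids.
#' @export
yaml_rules <- c(
  "non_core_tag",       # types outside the Failsafe/JSON/Core schemas
  "directive",          # "%"-directives
  "node_properties",    # tags, anchors, aliases
  "complex_key",        # "?" complex mapping keys
  "plain_string_value", # unquoted string values
  "flow_style",         # {...} / [...] collections
  "empty_key",          # mapping entry with no key
  "block_scalar",       # "|" / ">" scalars
  "key_charset",        # key outside [A-Za-z0-9_-] left unquoted
  "key_quoted",         # conforming key needlessly quoted
  "duplicate_key"       # repeated key in one mapping (last occurrence wins)
)

new_yaml_violation <- function(rule, line, message) {
  stopifnot(rule %in% yaml_rules)
  structure(list(rule = rule, line = as.integer(line), message = message,
                 severity = "warning"),
            class = "exdirr_yaml_violation")
}

#' @export
format.exdirr_yaml_violation <- function(x, ...) {
  sprintf("line %s: [%s] %s", ifelse(is.na(x$line), "?", x$line), x$rule, x$message)
}

#' @export
print.exdirr_yaml_violation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Check the Exdir key naming convention
#'
#' Keys in attribute and metadata files should contain only ASCII letters,
#' digits, underscores and hyphens.  Keys that break the convention must be
#' quoted when emitted.
#'
#' @param key A single string.
#' @return `TRUE` iff the key is non-empty and matches `[A-Za-z0-9_-]+`.
#' @export
#' @examples
#' check_key_convention("sample_rate-2") # TRUE
#' check_key_convention("my key")        # FALSE
check_key_convention <- function(key) {
  if (!is_string(key)) return(FALSE)
  grepl("^[A-Za-z0-9_-]+$", key)
}

# ---------------------------------------------------------------------------
# Canonical attribute documents
#
# map      -> named list (unique, non-empty names; possibly empty with names
#             attribute present)
# sequence -> unnamed list
# scalar   -> length-1 atomic vector (character / logical / integer / double)
# null     -> NULL

#' Construct an (empty) attribute map
#'
#' A map is represented as a named list; an empty map keeps a zero-length
#' `names` attribute so it stays distinguishable from an empty sequence.
#'
#' @param ... Named entries.
#' @return A named list.
#' @export
attr_map <- function(...) {
  x <- list(...)
  if (length(x) == 0L) return(structure(list(), names = character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop_exdirr("exdirr_invalid_key", "all attr_map() entries must be named")
  }
  x
}

is_attr_map <- function(x) is.list(x) && !is.null(names(x)) &&
  !inherits(x, c("exdir_quantity", "exdir_dataset_data"))
is_attr_seq <- function(x) is.list(x) && is.null(names(x))
is_attr_scalar <- function(x) is.atomic(x) && length(x) == 1L && is.null(names(x))

#' Normalize a value into canonical attribute-document form
#'
#' Atomic vectors of length > 1 become sequences of scalars; named atomic
#' vectors become maps; factors become strings.  `NA` has no representation in
#' the restricted subset and is rejected (`NaN` is fine).
#'
#' @param x Any R value built from the seven supported kinds.
#' @return The canonical form (see Details in the package vignette).
#' @export
as_attr_document <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.factor(x)) x <- as.character(x)
  if (is.atomic(x)) {
    nm <- names(x)
    if (length(x) == 1L && is.null(nm)) {
      v <- as.vector(x)
      if (is.character(v) || is.logical(v) || is.integer(v) || is.double(v)) {
        if (!is.character(v) && is.na(v) && !(is.double(v) && is.nan(v))) {
          stop_exdirr("exdirr_unsupported_value", "NA has no restricted-YAML representation")
        }
        if (is.character(v) && is.na(v)) {
          stop_exdirr("exdirr_unsupported_value", "NA has no restricted-YAML representation")
        }
        return(v)
      }
      stop_exdirr("exdirr_unsupported_value",
                  sprintf("unsupported scalar type '%s'", typeof(v)))
    }
    if (!is.null(nm)) {
      x <- as.list(x)               # named vector -> map of scalars
    } else {
      return(lapply(as.vector(x), as_attr_document))  # sequence of scalars
    }
  }
  if (!is.list(x)) {
    stop_exdirr("exdirr_unsupported_value",
                sprintf("unsupported value of class '%s'", class(x)[1]))
  }
  nm <- names(x)
  if (is.null(nm) || (length(x) > 0L && all(nm == ""))) {
    return(lapply(x, as_attr_document))               # sequence
  }
  if (any(nm == "")) {
    stop_exdirr("exdirr_invalid_key", "map with a mixture of named and unnamed entries")
  }
  if (anyDuplicated(nm)) {
    stop_exdirr("exdirr_invalid_key",
                sprintf("duplicate map key '%s'", nm[duplicated(nm)][1]))
  }
  out <- lapply(x, as_attr_document)
  names(out) <- nm
  out
}

#' Structural equality of two attribute documents
#'
#' Compares after normalization; integer and double scalars are distinct kinds
#' (`1L != 1.0`), matching what the emitter/parser pair preserves.
#'
#' @param a,b Documents (any form accepted by [as_attr_document()]).
#' @return `TRUE` or `FALSE`.
#' @export
attr_doc_equal <- function(a, b) {
  doc_eq(as_attr_document(a), as_attr_document(b))
}

doc_eq <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (is_attr_scalar(a) || is_attr_scalar(b)) {
    if (!(is_attr_scalar(a) && is_attr_scalar(b))) return(FALSE)
    if (typeof(a) != typeof(b)) return(FALSE)
    if (is.double(a) && is.nan(a)) return(is.nan(b))
    return(isTRUE(a == b) || (is.character(a) && identical(a, b)))
  }
  am <- is_attr_map(a); bm <- is_attr_map(b)
  if (am != bm) return(FALSE)
  if (length(a) != length(b)) return(FALSE)
  if (am) {
    # maps compare order-insensitively (key order matters for emitted bytes,
    # not for structural equality)
    if (!setequal(names(a), names(b)) || anyDuplicated(names(a))) return(FALSE)
    for (k in names(a)) if (!doc_eq(a[[k]], b[[k]])) return(FALSE)
    return(TRUE)
  }
  for (i in seq_along(a)) if (!doc_eq(a[[i]], b[[i]])) return(FALSE)
  TRUE
}

# ---------------------------------------------------------------------------
# Emitter

fmt_double <- function(v) {
  if (is.nan(v)) return(".nan")
  if (v == Inf) return(".inf")
  if (v == -Inf) return("-.inf")
  s <- NULL
  for (d in 1:17) {                      # shortest decimal that round-trips
    s <- formatC(v, digits = d, format = "g", width = -1)
    if (as.numeric(s) == v) break
  }
  if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
  # canonical exponent form ("5e-324" -> "5.0e-324", "1e5" -> "1.0e+5") so the
  # value is a float to YAML 1.1 resolvers as well as the 1.2 Core schema
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]", perl = TRUE)[[1]]
    if (!grepl(".", parts[1], fixed = TRUE)) parts[1] <- paste0(parts[1], ".0")
    if (!grepl("^[-+]", parts[2])) parts[2] <- paste0("+", parts[2])
    s <- paste0(parts[1], "e", parts[2])
  }
  s
}

quote_yaml_string <- function(s) {
  s <- enc2utf8(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  # remaining C0 controls -> \xNN escapes
  if (grepl("[\x01-\x1f]", s, useBytes = TRUE)) {
    bytes <- charToRaw(s)
    ctl <- bytes <= as.raw(0x1f) & bytes != as.raw(0)
    pieces <- vapply(seq_along(bytes), function(i) {
      if (ctl[i]) sprintf("\\x%02X", as.integer(bytes[i])) else rawToChar(bytes[i])
    }, "")
    s <- paste(pieces, collapse = "")
  }
  paste0("\"", s, "\"")
}

fmt_scalar <- function(v) {
  if (is.null(v)) return("null")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.integer(v)) return(sprintf("%d", v))
  if (is.double(v)) return(fmt_double(v))
  if (is.character(v)) return(quote_yaml_string(v))
  stop_exdirr("exdirr_unsupported_value", sprintf("unsupported scalar '%s'", typeof(v)))
}

fmt_key <- function(key) {
  if (check_key_convention(key)) return(key)
  warning(structure(
    class = c("exdirr_key_convention_warning", "warning", "condition"),
    list(message = sprintf(
      "key '%s' breaks the key naming convention [A-Za-z0-9_-]; emitted quoted", key),
      call = NULL)))
  quote_yaml_string(key)
}

indent2 <- function(lines) {
  if (length(lines) == 0L) return(character(0))   # paste0 would recycle to "  "
  paste0("  ", lines)
}

emit_map_lines <- function(m) {
  nm <- names(m)
  out <- character(0)
  for (i in seq_along(m)) {
    k <- fmt_key(nm[i])
    v <- m[[i]]
    if (is.null(v) || is_attr_scalar(v)) {
      out <- c(out, paste0(k, ": ", fmt_scalar(v)))
    } else if (length(v) == 0L) {
      stop_exdirr("exdirr_unsupported_value",
                  "empty maps/sequences cannot be represented in block style")
    } else if (is_attr_map(v)) {
      out <- c(out, paste0(k, ":"), indent2(emit_map_lines(v)))
    } else {
      out <- c(out, paste0(k, ":"), indent2(emit_seq_lines(v)))
    }
  }
  out
}

emit_seq_lines <- function(s) {
  out <- character(0)
  for (v in s) {
    if (is.null(v) || is_attr_scalar(v)) {
      out <- c(out, paste0("- ", fmt_scalar(v)))
    } else if (length(v) == 0L) {
      stop_exdirr("exdirr_unsupported_value",
                  "empty maps/sequences cannot be represented in block style")
    } else if (is_attr_map(v)) {
      lines <- emit_map_lines(v)
      out <- c(out, paste0("- ", lines[1]), indent2(lines[-1]))
    } else {
      out <- c(out, "-", indent2(emit_seq_lines(v)))
    }
  }
  out
}

#' Serialize an attribute document in the restricted YAML subset
#'
#' Output is block-style YAML 1.2 with every string value double-quoted,
#' conforming keys plain, nonconforming keys quoted (with a warning), integers
#' printed without and doubles always with a decimal point or exponent (so the
#' integer/float kind survives a round trip), and two-space indentation.  The
#' output never triggers any restriction violation and is accepted unchanged by
#' any general YAML 1.2 parser.
#'
#' @param document A map (named list) of supported values, or `NULL`/empty map.
#' @return A single string of YAML text ("" for an empty document).
#' @export
#' @examples
#' cat(emit_restricted(list(temperature = 32L, note = "raw data")))
emit_restricted <- function(document) {
  doc <- as_attr_document(document)
  if (is.null(doc) || length(doc) == 0L) {
    if (!is.null(doc) && !is_attr_map(doc)) {
      stop_exdirr("exdirr_invalid_document", "top-level value must be a map")
    }
    return("")
  }
  if (!is_attr_map(doc)) {
    stop_exdirr("exdirr_invalid_document", "top-level value must be a map")
  }
  paste0(paste(emit_map_lines(doc), collapse = "\n"), "\n")
}

# ---------------------------------------------------------------------------
# Lenient parser

# Replace the contents of quoted spans with "_" (length-preserving) and drop
# comments, so indicator scans cannot misfire inside strings.
mask_quoted <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  n <- length(chars)
  state <- "plain"
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (state == "plain") {
      if (ch == "\"") state <- "dq"
      else if (ch == "'") state <- "sq"
      else if (ch == "#" && (i == 1L || chars[i - 1L] %in% c(" ", "\t"))) {
        return(substr(paste(chars, collapse = ""), 1L, i - 1L))
      }
    } else if (state == "dq") {
      if (ch == "\\") { if (i < n) chars[i + 1L] <- "_"; chars[i] <- "_"; i <- i + 1L }
      else if (ch == "\"") state <- "plain"
      else chars[i] <- "_"
    } else {                             # single-quoted; '' escapes itself
      if (ch == "'") {
        if (i < n && chars[i + 1L] == "'") { chars[i + 1L] <- "_"; i <- i + 1L }
        else state <- "plain"
      } else chars[i] <- "_"
    }
    i <- i + 1L
  }
  paste(chars, collapse = "")
}

is_core_scalar <- function(s) {
  grepl("^(null|Null|NULL|~)$", s) ||
    grepl("^(true|True|TRUE|false|False|FALSE)$", s) ||
    grepl("^[-+]?[0-9]+$", s) ||
    grepl("^0o[0-7]+$", s) ||
    grepl("^0x[0-9A-Fa-f]+$", s) ||
    grepl("^[-+]?(\\.[0-9]+|[0-9]+(\\.[0-9]*)?)([eE][-+]?[0-9]+)?$", s) ||
    grepl("^[-+]?\\.(inf|Inf|INF)$", s) ||
    grepl("^\\.(nan|NaN|NAN)$", s)
}

# Line-oriented scanner for the restriction rules.  It is a linter, not a
# parser: heuristic on exotic multi-line constructs, exact on everything the
# strict emitter can produce and on the common breaches (flow style, plain
# strings, block scalars, tags, directives).
scan_restricted_yaml <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- list()
  add <- function(rule, ln, msg) out[[length(out) + 1L]] <<- new_yaml_violation(rule, ln, msg)
  skip_indent <- -1L                     # inside a (forbidden) block scalar
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (grepl("^\\s*$", raw)) next
    indent <- nchar(sub("^(\\s*).*$", "\\1", raw))
    if (skip_indent >= 0L) {
      if (indent > skip_indent) next
      skip_indent <- -1L
    }
    masked <- mask_quoted(raw)
    if (grepl("^\\s*$", masked)) next    # comment-only line
    if (grepl("^%", masked)) { add("directive", ln, "YAML directive"); next }
    if (grepl("^---\\s*$|^\\.\\.\\.\\s*$", masked)) next
    if (grepl("!!", masked, fixed = TRUE)) {
      add("non_core_tag", ln, "explicit tag outside the Core schema")
    } else if (grepl("(^|[[:space:]])![^[:space:]]", masked)) {
      add("node_properties", ln, "explicit tag")
    }
    if (grepl("(^|[[:space:]])[&*][A-Za-z0-9_]", masked)) {
      add("node_properties", ln, "anchor or alias")
    }
    if (grepl("[][{}]", masked)) {
      add("flow_style", ln, "flow-style map/sequence")
    }
    if (grepl("^\\s*\\?($|\\s)", masked)) {
      add("complex_key", ln, "complex mapping key")
      next
    }
    # peel leading whitespace and "- " sequence-entry prefixes (masking is
    # length-preserving, so masked/raw positions stay aligned)
    in_seq_entry <- grepl("^\\s*-\\s", masked)
    body_m <- masked
    repeat {
      pre <- regmatches(body_m, regexpr("^\\s*(-\\s+)?", body_m))
      if (nchar(pre) == 0L) break
      body_m <- substring(body_m, nchar(pre) + 1L)
    }
    body_r <- substring(raw, nchar(raw) - nchar(body_m) + 1L)
    if (grepl("^:($|\\s)", body_m)) { add("empty_key", ln, "mapping entry with empty key"); next }
    cm <- regexpr(":(\\s|$)", body_m)
    if (cm > 0L) {
      key_m <- trimws(substr(body_m, 1L, cm - 1L))
      key_r <- trimws(substr(body_r, 1L, cm - 1L))
      if (nzchar(key_m)) {
        if (grepl("^[\"']", key_m)) {
          inner <- substr(key_r, 2L, nchar(key_r) - 1L)
          if (check_key_convention(inner)) {
            add("key_quoted", ln, sprintf("key %s needlessly quoted", key_r))
          }
        } else if (!check_key_convention(key_r)) {
          add("key_charset", ln,
              sprintf("key '%s' outside [A-Za-z0-9_-] should be quoted", key_r))
        }
      }
      val_m <- trimws(substring(body_m, cm + 1L))
      val_r <- trimws(substring(body_r, cm + 1L))
    } else if (in_seq_entry) {
      val_m <- trimws(body_m)
      val_r <- trimws(body_r)
    } else {
      val_m <- ""                        # bare token: likely a multi-line
      val_r <- ""                        # continuation; do not classify
    }
    if (nzchar(val_m)) {
      c1 <- substr(val_m, 1L, 1L)
      if (c1 %in% c("|", ">")) {
        add("block_scalar", ln, "block scalar style")
        skip_indent <- indent
      } else if (!c1 %in% c("\"", "'", "&", "*", "!", "{", "[", "}", "]")) {
        if (!is_core_scalar(val_r)) {
          add("plain_string_value", ln,
              sprintf("plain-style string value '%s' must be quoted", val_r))
        }
      }
    }
  }
  out
}

# The YAML 1.2 Core schema resolves exponent floats without a decimal point or
# exponent sign ("1.5e3", "5e-324"); the underlying 1.1 resolver does not.
# Rewrite such unquoted scalar values to the canonical dotted/signed spelling
# before parsing (the violation scanner always sees the original text).
preprocess_core_floats <- function(text) {
  had_nl <- grepl("\n$", text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  fix1 <- function(tok) {
    if (!grepl("^[-+]?(\\.[0-9]+|[0-9]+(\\.[0-9]*)?)[eE][-+]?[0-9]+$", tok)) return(tok)
    parts <- strsplit(tok, "[eE]", perl = TRUE)[[1]]
    if (!grepl(".", parts[1], fixed = TRUE)) parts[1] <- paste0(parts[1], ".0")
    if (!grepl("^[-+]", parts[2])) parts[2] <- paste0("+", parts[2])
    paste0(parts[1], "e", parts[2])
  }
  for (i in seq_along(lines)) {
    masked <- mask_quoted(lines[i])
    # the trailing unquoted token after ": " or "- ", if any
    for (pat in c("(: )([^\\s:#]+)(\\s*)$", "(^\\s*- )([^\\s:#]+)(\\s*)$")) {
      mm <- regexec(pat, masked, perl = TRUE)[[1]]
      if (mm[1] > 0L) {
        tok_start <- mm[3]
        tok_len <- attr(mm, "match.length")[3]
        tok <- substr(lines[i], tok_start, tok_start + tok_len - 1L)
        fixed <- fix1(tok)
        if (!identical(fixed, tok)) {
          lines[i] <- paste0(substr(lines[i], 1L, tok_start - 1L), fixed,
                             substring(lines[i], tok_start + tok_len))
        }
        break
      }
    }
  }
  paste0(paste(lines, collapse = "\n"), if (had_nl) "\n")
}

# Remove earlier occurrences of duplicated keys within one mapping block so the
# lenient parser can deliver last-occurrence-wins semantics (the underlying
# libyaml parser treats duplicates as fatal).
dedupe_yaml_lines <- function(lines) {
  n <- length(lines)
  indent_of <- function(s) nchar(sub("^(\\s*).*$", "\\1", s))
  drop <- rep(FALSE, n)
  dup_lines <- integer(0)
  frames <- list()                       # stack of list(indent, keys=env of key -> line)
  for (i in seq_len(n)) {
    s <- lines[i]
    if (grepl("^\\s*(#|$)", s)) next
    ind <- indent_of(s)
    m <- regexpr("^\\s*([^-\\s:#][^:]*):(\\s|$)", s)
    if (m < 0L) next
    key <- trimws(sub("^\\s*([^:]*):.*$", "\\1", s))
    while (length(frames) && frames[[length(frames)]]$indent > ind) {
      frames[[length(frames)]] <- NULL
    }
    if (!length(frames) || frames[[length(frames)]]$indent < ind) {
      frames[[length(frames) + 1L]] <- list(indent = ind, keys = new.env(parent = emptyenv()))
    }
    keys <- frames[[length(frames)]]$keys
    if (!is.null(keys[[key]])) {
      j <- keys[[key]]
      end <- j
      for (k in (j + 1L):n) {
        if (k > n) break
        if (grepl("^\\s*$", lines[k])) { end <- k; next }
        if (indent_of(lines[k]) <= ind && k > j) break
        end <- k
      }
      drop[j:end] <- TRUE
      dup_lines <- c(dup_lines, i)
    }
    keys[[key]] <- i
  }
  list(lines = lines[!drop], dup_lines = dup_lines)
}

#' Parse YAML leniently, collecting restriction violations
#'
#' Accepts the full YAML 1.2 language (Core-schema scalar resolution: unquoted
#' `32` is an integer, `true` a boolean, `null`/empty a null, `1.5e3` a float).
#' Breaches of the restricted subset are reported as warnings alongside the
#' parsed document; they never abort the read.  Duplicate keys resolve to the
#' last occurrence, with a warning.
#'
#' @param text YAML source text.
#' @return A list with elements `document` (canonical attribute document; an
#'   empty map for empty input) and `violations` (list of violation records).
#' @export
#' @examples
#' parse_lenient("a: [1, 2]")$violations  # one flow_style warning
parse_lenient <- function(text) {
  if (!is_string(text)) text <- paste(text, collapse = "\n")
  violations <- scan_restricted_yaml(text)
  if (trimws(text) == "") {
    return(list(document = attr_map(), violations = violations))
  }
  # seq handler keeps sequences as lists (even singletons); the bool handlers
  # restore YAML 1.2 Core-schema resolution (libyaml's 1.1 rules would turn
  # yes/no/on/off/y/n into booleans, both as values and as map keys)
  core_handlers <- list(
    seq = function(x) x,
    "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
    "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x
  )
  load1 <- function(txt) yaml::yaml.load(preprocess_core_floats(txt),
                                         handlers = core_handlers)
  parsed <- tryCatch(load1(text), error = function(e) e)
  if (inherits(parsed, "error")) {
    if (grepl("Duplicate map key", conditionMessage(parsed))) {
      dd <- dedupe_yaml_lines(strsplit(text, "\n", fixed = TRUE)[[1]])
      for (ln in dd$dup_lines) {
        violations[[length(violations) + 1L]] <-
          new_yaml_violation("duplicate_key", ln, "duplicate key; last occurrence wins")
      }
      parsed <- tryCatch(load1(paste(dd$lines, collapse = "\n")),
                         error = function(e) e)
    }
    if (inherits(parsed, "error")) {
      stop_exdirr("exdirr_parse_error",
                  sprintf("malformed YAML: %s", conditionMessage(parsed)))
    }
  }
  if (is.null(parsed)) {
    return(list(document = attr_map(), violations = violations))
  }
  if (!is.list(parsed) || is.null(names(parsed))) {
    stop_exdirr("exdirr_invalid_document", "top-level YAML value must be a map")
  }
  list(document = as_attr_document(parsed), violations = violations)
}
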