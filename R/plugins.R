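# Plugin pipeline: pure value transformations on the way to/from disk.
#
# Handlers never touch the file system; the core does all I/O.  A dataset
# handler's prepare_write receives a dataset-data container (data + attrs +
# meta) and must leave `data` NPY-storable; prepare_read reverses the
# transformation using the stored attributes.  Which plugins stamped an object
# is recorded under a reserved `plugins` key in the object's exdir.yaml (not in
# attributes.yaml, keeping user attributes clean), so reads can match writers.

#' Construct a plugin handler
#'
#' @param name Unique plugin name (stored as the on-disk marker).
#' @param target `"dataset"` or `"attribute"`.
#' @param prepare_write For datasets: `function(dataset_data) -> dataset_data`;
#'   for attributes: `function(document) -> document`.
#' @param prepare_read For datasets: `function(dataset_data) -> dataset_data`
#'   (its `data` field is the reconstructed value).
#' @param order Handlers run in increasing `order` on write and decreasing on
#'   read.
#' @param version Integer stored beside the marker.
#' @return An object of class `exdir_plugin`.
#' @export
exdir_plugin <- function(name, target = c("dataset", "attribute"),
                         prepare_write = NULL, prepare_read = NULL,
                         order = 1L, version = 1L) {
  target <- match.arg(target)
  stopifnot(is_string(name))
  structure(list(name = name, target = target,
                 prepare_write = prepare_write, prepare_read = prepare_read,
                 order = as.integer(order), version = as.integer(version)),
            class = "exdir_plugin")
}

validate_plugins <- function(plugins) {
  if (inherits(plugins, "exdir_plugin")) plugins <- list(plugins)
  if (!is.list(plugins) || !all(vapply(plugins, inherits, TRUE, "exdir_plugin"))) {
    stop_exdirr("exdirr_invalid_argument", "plugins must be a list of exdir_plugin objects")
  }
  plugins[order(vapply(plugins, function(p) p$order, 1L))]
}

#' Dataset-data container passed through plugin hooks
#'
#' @param data Array or scalar payload (must be NPY-storable after the last
#'   `prepare_write`).
#' @param attrs Attribute-document fragment merged into `attributes.yaml`.
#' @param meta Plugin bookkeeping entries.
#' @return An object of class `exdir_dataset_data`.
#' @export
dataset_data <- function(data, attrs = attr_map(), meta = list()) {
  structure(list(data = data, attrs = attrs, meta = meta),
            class = "exdir_dataset_data")
}

# Fold a caller value through the dataset-targeted prepare_write hooks.
# Returns dataset_data whose meta lists the plugins that transformed it.
apply_write_chain <- function(plugins, value) {
  dd <- if (inherits(value, "exdir_dataset_data")) value else dataset_data(value)
  for (p in plugins) {
    if (p$target != "dataset" || is.null(p$prepare_write)) next
    dd <- p$prepare_write(dd)
    if (!inherits(dd, "exdir_dataset_data")) {
      stop_exdirr("exdirr_unsupported_value",
                  sprintf("plugin '%s' prepare_write did not return dataset_data", p$name))
    }
  }
  if (!is.atomic(dd$data) && !is.null(dd$data)) {
    stop_exdirr("exdirr_unsupported_value",
                "value is not NPY-storable after the plugin write chain")
  }
  dd
}

marker_present <- function(meta, name) {
  any(vapply(meta, function(m) identical(m$name, name), TRUE))
}

# Inverse fold: handlers run in reverse order; a handler only fires when its
# on-disk marker is present (objects written without it are returned as-is).
apply_read_chain <- function(plugins, values, attrs, markers,
                             missing_plugin = getOption("exdirr.missing_plugin", "warn")) {
  if (is.null(markers) || length(markers) == 0L) return(values)
  dd <- dataset_data(values, attrs, markers)
  known <- vapply(plugins, function(p) p$name, "")
  for (m in markers) {
    if (!identical(m$name %in% known, TRUE)) {
      msg <- sprintf("dataset was written with plugin '%s', which is not enabled", m$name)
      if (identical(missing_plugin, "error")) stop_exdirr("exdirr_missing_plugin", msg)
      warning(msg)
    }
  }
  for (p in rev(plugins)) {
    if (p$target != "dataset" || is.null(p$prepare_read)) next
    if (!marker_present(markers, p$name)) next
    dd <- p$prepare_read(dd)
    if (!inherits(dd, "exdir_dataset_data")) return(dd)
  }
  dd$data
}

# Attribute-targeted handlers transform the whole document per write (matching
# the whole-file rewrite semantics of attributes.yaml).
apply_attr_write_chain <- function(plugins, document) {
  for (p in plugins) {
    if (p$target != "attribute" || is.null(p$prepare_write)) next
    document <- as_attr_document(p$prepare_write(document))
    if (!is.null(document) && !is_attr_map(document)) {
      stop_exdirr("exdirr_unsupported_attribute",
                  sprintf("plugin '%s' did not return an attribute map", p$name))
    }
  }
  document
}

# ---------------------------------------------------------------------------
# Built-in quantity plugin: magnitude + unit symbol

#' A physical quantity: magnitude with a unit symbol
#'
#' A minimal quantity value — a numeric magnitude (scalar or array) and a unit
#' stored as a plain string symbol; no dimensional analysis is performed.
#' Under [plugin_quantity()], such values round-trip through datasets: the
#' magnitude goes to `data.npy` and the unit to an `unit` attribute.
#'
#' @param magnitude Numeric scalar or array.
#' @param unit Unit symbol, e.g. `"s"` or `"mV"`.
#' @export
#' @examples
#' q <- exdir_quantity(1.5, "s")
exdir_quantity <- function(magnitude, unit) {
  stopifnot(is.numeric(magnitude), is_string(unit))
  structure(list(magnitude = magnitude, unit = unit), class = "exdir_quantity")
}

#' @export
print.exdir_quantity <- function(x, ...) {
  cat(format(x$magnitude), x$unit, "\n")
  invisible(x)
}

#' @export
format.exdir_quantity <- function(x, ...) paste(format(x$magnitude), x$unit)

#' The built-in quantity plugin
#'
#' Enables writing [exdir_quantity()] values as datasets.  `prepare_write`
#' stores the magnitude as the array payload and the unit under the `unit`
#' attribute key, stamping the object; `prepare_read` reconstructs the
#' quantity.  Values that are not quantities pass through untouched, and
#' datasets written without the plugin read back as plain arrays.
#'
#' @return An [exdir_plugin()] handler targeting datasets.
#' @export
#' @examples
#' f <- exdir_open(file.path(tempdir(), "q.exdir"), "w", plugins = list(plugin_quantity()))
#' d <- create_dataset(f, "dur", data = exdir_quantity(1.5, "s"))
#' exdir_data(d)
plugin_quantity <- function() {
  exdir_plugin(
    name = "quantity",
    target = "dataset",
    prepare_write = function(dd) {
      v <- dd$data
      if (!inherits(v, "exdir_quantity")) return(dd)
      dd$data <- v$magnitude
      dd$attrs[["unit"]] <- v$unit
      dd$meta[[length(dd$meta) + 1L]] <- list(name = "quantity", version = 1L)
      dd
    },
    prepare_read = function(dd) {
      unit <- dd$attrs[["unit"]]
      if (is.null(unit)) return(dd)
      dd$data <- exdir_quantity(dd$data, unit)
      dd
    }
  )
}
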