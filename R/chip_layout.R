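# Chip layout: logical and geometric structure of the chamber-array chip.

#' Chamber geometry
#'
#' Describes a single culture chamber and the exchange window through which
#' a feed channel replaces its liquid. All lengths are in micrometres. The
#' exchange window is a sub-region of the chamber wall, so its length must
#' not exceed the chamber length.
#'
#' @param chamber_width Chamber width in um (default 250).
#' @param chamber_length Chamber length in um (default 2000).
#' @param exchange_window_width Exchange-window width in um (default 250).
#' @param exchange_window_length Exchange-window length in um (default 790).
#' @param channel_height_class Cross-section profile of the flow channel,
#'   `"rounded"` (valve-compatible, made with reflowed photoresist) or
#'   `"rectangular"`.
#'
#' @return An object of class `chamber_geometry`.
#' @export
#' @examples
#' geom <- chamber_geometry()
#' geom$chamber_length
chamber_geometry <- function(chamber_width = 250,
                             chamber_length = 2000,
                             exchange_window_width = 250,
                             exchange_window_length = 790,
                             channel_height_class = c("rounded", "rectangular")) {
  channel_height_class <- match.arg(channel_height_class)
  lens <- c(chamber_width = chamber_width,
            chamber_length = chamber_length,
            exchange_window_width = exchange_window_width,
            exchange_window_length = exchange_window_length)
  for (nm in names(lens)) {
    v <- lens[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single strictly positive length (um)",
           call. = FALSE)
    }
  }
  if (exchange_window_length > chamber_length) {
    stop("`exchange_window_length` must not exceed `chamber_length` ",
         "(the exchange window is a sub-region of the chamber wall)",
         call. = FALSE)
  }
  structure(
    list(chamber_width = as.numeric(chamber_width),
         chamber_length = as.numeric(chamber_length),
         exchange_window_width = as.numeric(exchange_window_width),
         exchange_window_length = as.numeric(exchange_window_length),
         channel_height_class = channel_height_class),
    class = "chamber_geometry"
  )
}

#' Build a chip layout
#'
#' A chip consists of `n_arrays` chamber arrays (columns); each array holds
#' `chambers_per_array` serially connected culture chambers fed by
#' `channels_per_array` independently addressable channels. Chambers within
#' an array are numbered 1..m from the top; Path-1 (top-down flow) enters at
#' chamber 1. The default configuration is 8 arrays x 5 chambers x 3
#' channels: 40 chambers addressed through 24 inlets.
#'
#' @param n_arrays Number of chamber arrays (>= 1).
#' @param chambers_per_array Chambers per array (>= 1).
#' @param channels_per_array Feed channels per array (>= 1).
#' @param geometry A [chamber_geometry()] object.
#' @param metadata Optional named list of inert device metadata (e.g. chip
#'   footprint, valve closing-pressure range). Stored, never simulated.
#'
#' @return An object of class `chip_layout`.
#' @seealso [layout_summary()]
#' @export
#' @examples
#' lay <- build_layout()
#' layout_summary(lay)
build_layout <- function(n_arrays = 8,
                         chambers_per_array = 5,
                         channels_per_array = 3,
                         geometry = chamber_geometry(),
                         metadata = default_chip_metadata()) {
  counts <- c(n_arrays = n_arrays,
              chambers_per_array = chambers_per_array,
              channels_per_array = channels_per_array)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 1 || v != round(v)) {
      stop("`", nm, "` must be a single integer count >= 1", call. = FALSE)
    }
  }
  if (!inherits(geometry, "chamber_geometry")) {
    stop("`geometry` must be a `chamber_geometry` object", call. = FALSE)
  }
  if (!is.list(metadata)) stop("`metadata` must be a list", call. = FALSE)
  structure(
    list(n_arrays = as.integer(n_arrays),
         chambers_per_array = as.integer(chambers_per_array),
         channels_per_array = as.integer(channels_per_array),
         geometry = geometry,
         metadata = metadata),
    class = "chip_layout"
  )
}

#' Default device metadata
#'
#' Footprint and valve operating pressure of the reference chip, stored as
#' inert annotation on the layout.
#'
#' @return A named list.
#' @export
default_chip_metadata <- function() {
  list(footprint_cm = c(length = 6, width = 5, height = 0.5),
       valve_closing_pressure_psi = c(min = 25, max = 30))
}

#' Capacity summary of a chip layout
#'
#' @param layout A [build_layout()] object.
#' @return A named list with `chambers` (`n_arrays * chambers_per_array`),
#'   `inlets` (`n_arrays * channels_per_array`) and `arrays`.
#' @export
#' @examples
#' layout_summary(build_layout(2, 5, 3))
layout_summary <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  list(chambers = layout$n_arrays * layout$chambers_per_array,
       inlets = layout$n_arrays * layout$channels_per_array,
       arrays = layout$n_arrays)
}

#' @export
print.chip_layout <- function(x, ...) {
  s <- layout_summary(x)
  cat("<chip_layout> ", x$n_arrays, " arrays x ", x$chambers_per_array,
      " chambers x ", x$channels_per_array, " channels\n", sep = "")
  cat("  capacity: ", s$chambers, " chambers, ", s$inlets, " inlets\n",
      sep = "")
  g <- x$geometry
  cat("  chamber ", g$chamber_width, " x ", g$chamber_length,
      " um; exchange window ", g$exchange_window_width, " x ",
      g$exchange_window_length, " um (", g$channel_height_class,
      " channels)\n", sep = "")
  invisible(x)
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("<chamber_geometry> chamber ", x$chamber_width, " x ",
      x$chamber_length, " um; window ", x$exchange_window_width, " x ",
      x$exchange_window_length, " um; ", x$channel_height_class,
      " channels\n", sep = "")
  invisible(x)
}

#' Write / read a chip layout as JSON
#'
#' The on-disk document mirrors the layout fields one-to-one, so a
#' write/read round trip preserves the layout exactly.
#'
#' @param layout A `chip_layout`.
#' @param path File path.
#' @return `read_layout()` returns a `chip_layout`; `write_layout()` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  doc <- list(
    n_arrays = layout$n_arrays,
    chambers_per_array = layout$chambers_per_array,
    channels_per_array = layout$channels_per_array,
    geometry = unclass(layout$geometry),
    metadata = layout$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- do.call(chamber_geometry, as.list(doc$geometry))
  md <- if (is.null(doc$metadata)) list() else as.list(doc$metadata)
  build_layout(doc$n_arrays, doc$chambers_per_array, doc$channels_per_array,
               geometry = geom, metadata = md)
}
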