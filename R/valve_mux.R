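# Combinatorial (k-control-1) valve multiplexer for the chip's inlet
# channels. Each flow channel is assigned a unique k-subset of control
# valves; pressurizing a valve closes every channel whose address contains
# it, so a channel flows only when none of its k address valves is
# pressurized. n valves address up to choose(n, k) channels; the reference
# chip drives 24 channels with 7 valves in a three-control-one arrangement.

#' Minimum number of control valves for a k-control-1 multiplexer
#'
#' Smallest `n >= k` such that `choose(n, k) >= n_channels`. For the
#' reference chip, `min_valves(24, 3) == 7`.
#'
#' @param n_channels Number of flow channels to address (>= 1).
#' @param k Valves per channel address (>= 1).
#' @return Integer valve count.
#' @export
#' @examples
#' min_valves(24, 3)
min_valves <- function(n_channels, k) {
  check_count(n_channels, "n_channels")
  check_count(k, "k")
  n <- as.integer(k)
  while (choose(n, k) < n_channels) n <- n + 1L
  n
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 1 || x != round(x)) {
    stop("`", name, "` must be a single integer >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign multiplexer addresses to channels
#'
#' Builds a `mux_design` using the minimal valve count and the
#' lexicographically first `n_channels` k-subsets of `{1..n_valves}` as
#' channel addresses. Lexicographic assignment is a deterministic
#' convention; only the counts are physically constrained.
#'
#' @inheritParams min_valves
#' @return A `mux_design` with fields `n_valves`, `k` and `addresses`
#'   (a list of integer vectors, one per channel).
#' @export
#' @examples
#' d <- assign_addresses(24, 3)
#' d$n_valves
#' d$addresses[[1]]
assign_addresses <- function(n_channels, k) {
  n_valves <- min_valves(n_channels, k)
  subsets <- utils::combn(n_valves, k, simplify = FALSE)  # lexicographic
  addresses <- lapply(subsets[seq_len(n_channels)], as.integer)
  structure(
    list(n_valves = n_valves, k = as.integer(k), addresses = addresses),
    class = "mux_design"
  )
}

#' @export
print.mux_design <- function(x, ...) {
  cat("<mux_design> ", length(x$addresses), " channels, ", x$n_valves,
      " valves, k = ", x$k, " (", x$k, "-control-1)\n", sep = "")
  invisible(x)
}

mux_channel_address <- function(design, channel) {
  stopifnot(inherits(design, "mux_design"))
  if (!is.numeric(channel) || length(channel) != 1L ||
      channel != round(channel) || channel < 1 ||
      channel > length(design$addresses)) {
    stop("unknown channel index: ", channel, call. = FALSE)
  }
  design$addresses[[channel]]
}

#' Actuation pattern that isolates one channel
#'
#' Returns the set of valves to pressurize so that only `channel` flows:
#' the complement of the channel's address. Pressurized = closed
#' (push-down membrane valve polarity).
#'
#' @param design A [assign_addresses()] design.
#' @param channel Channel index.
#' @return An `actuation_pattern`: list with integer vector `pressurized`.
#' @export
actuation_pattern <- function(design, channel) {
  addr <- mux_channel_address(design, channel)
  structure(list(pressurized = setdiff(seq_len(design$n_valves), addr)),
            class = "actuation_pattern")
}

#' Is a channel open under an actuation pattern?
#'
#' A channel flows iff none of its address valves is pressurized.
#'
#' @param design A `mux_design`.
#' @param channel Channel index.
#' @param pattern An [actuation_pattern()], or an integer vector of
#'   pressurized valve indices.
#' @return Logical.
#' @export
is_open <- function(design, channel, pattern) {
  addr <- mux_channel_address(design, channel)
  pressurized <- if (inherits(pattern, "actuation_pattern")) {
    pattern$pressurized
  } else {
    as.integer(pattern)
  }
  if (length(pressurized) && (any(pressurized < 1) ||
                              any(pressurized > design$n_valves))) {
    stop("pattern refers to valves outside 1..n_valves", call. = FALSE)
  }
  length(intersect(addr, pressurized)) == 0L
}

#' Verify that every channel can be individually isolated
#'
#' Exhaustively checks that, for each channel, its [actuation_pattern()]
#' leaves exactly that channel open. Designs produced by
#' [assign_addresses()] always pass: any two distinct k-subsets differ in
#' at least one element, so every other channel has a pressurized address
#' valve.
#'
#' @param design A `mux_design`.
#' @return Logical. When `FALSE`, carries a `violations` attribute: a data
#'   frame of (selected_channel, leaking_channel) pairs.
#' @export
verify_isolation <- function(design) {
  stopifnot(inherits(design, "mux_design"))
  n <- length(design$addresses)
  bad_sel <- integer(0)
  bad_leak <- integer(0)
  for (c1 in seq_len(n)) {
    pat <- actuation_pattern(design, c1)
    for (c2 in seq_len(n)) {
      open <- is_open(design, c2, pat)
      if (open != (c1 == c2)) {
        bad_sel <- c(bad_sel, c1)
        bad_leak <- c(bad_leak, c2)
      }
    }
  }
  ok <- length(bad_sel) == 0L
  if (!ok) {
    attr(ok, "violations") <- data.frame(selected_channel = bad_sel,
                                         leaking_channel = bad_leak)
  }
  ok
}

#' Tabulate a multiplexer design
#'
#' One row per channel: its address valves and the valves pressurized to
#' isolate it, both as `+`-separated strings.
#'
#' @param design A `mux_design`.
#' @return A data frame with columns `channel`, `address_valves`,
#'   `pressurized_valves`.
#' @export
mux_table <- function(design) {
  stopifnot(inherits(design, "mux_design"))
  n <- length(design$addresses)
  data.frame(
    channel = seq_len(n),
    address_valves = vapply(design$addresses, paste, "", collapse = "+"),
    pressurized_valves = vapply(seq_len(n), function(ch) {
      paste(actuation_pattern(design, ch)$pressurized, collapse = "+")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Write / read a multiplexer design as JSON
#'
#' @param design A `mux_design`.
#' @param path File path.
#' @return `read_mux()` returns a `mux_design`.
#' @export
write_mux <- function(design, path) {
  stopifnot(inherits(design, "mux_design"))
  doc <- list(n_valves = design$n_valves, k = design$k,
              addresses = design$addresses)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mux
#' @export
read_mux <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  design <- structure(
    list(n_valves = as.integer(doc$n_valves), k = as.integer(doc$k),
         addresses = lapply(doc$addresses, function(a)
           as.integer(unlist(a)))),
    class = "mux_design"
  )
  validate_mux(design)
  design
}

validate_mux <- function(design) {
  addrs <- design$addresses
  ok_size <- vapply(addrs, function(a)
    length(a) == design$k && !anyDuplicated(a) &&
      all(a >= 1 & a <= design$n_valves), logical(1))
  if (!all(ok_size)) {
    stop("every address must be a set of k distinct valves in 1..n_valves",
         call. = FALSE)
  }
  keys <- vapply(addrs, function(a) paste(sort(a), collapse = ","), "")
  if (anyDuplicated(keys)) {
    stop("addresses must be pairwise distinct", call. = FALSE)
  }
  if (length(addrs) > choose(design$n_valves, design$k)) {
    stop("more channels than choose(n_valves, k) addresses", call. = FALSE)
  }
  invisible(TRUE)
}
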