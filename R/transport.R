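# Per-pulse liquid replacement in the chamber cascade. One pulse of a
# given flow speed and duration replaces a fraction f_i of chamber i's
# liquid with the inlet stream; downstream chambers exchange less because
# the stream is progressively diluted. The calibrated profile for a 4 s
# pulse at 5 mm/s replaces 22.48% of the topmost chamber, decreasing to
# 20.03%, 17.16%, 13.87% and 11.28% down the cascade.

#' Replacement-fraction profile
#'
#' Per-chamber replacement fractions for one pulse at a given flow speed
#' and duration. Index 1 is the chamber nearest the pulse entry. Fractions
#' must lie strictly in (0, 1) and be non-increasing along the cascade.
#'
#' @param fractions Numeric vector of replacement fractions.
#' @param flow_speed Inlet flow speed in mm/s.
#' @param duration Pulse duration in s.
#' @param allow_boundary Internal: permit fractions of exactly 0 or 1, as
#'   arise in the solver's short- and long-duration limits.
#' @return A `replacement_profile`.
#' @seealso [default_profile()], [fv_replacement_fractions()]
#' @export
replacement_profile <- function(fractions, flow_speed, duration,
                                allow_boundary = FALSE) {
  if (!is.numeric(fractions) || length(fractions) < 1L ||
      any(!is.finite(fractions))) {
    stop("`fractions` must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  lo <- if (allow_boundary) fractions >= 0 else fractions > 0
  hi <- if (allow_boundary) fractions <= 1 else fractions < 1
  if (!all(lo & hi)) {
    stop("replacement fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.unsorted(rev(fractions), strictly = FALSE)) {
    stop("replacement fractions must be non-increasing along the cascade ",
         "(downstream chambers exchange less)", call. = FALSE)
  }
  stopifnot(is.numeric(flow_speed), flow_speed > 0,
            is.numeric(duration), duration >= 0)
  structure(
    list(fractions = as.numeric(fractions),
         flow_speed = as.numeric(flow_speed),
         duration = as.numeric(duration)),
    class = "replacement_profile"
  )
}

#' Calibrated default replacement profile
#'
#' The measured per-chamber replacement fractions of the reference chip for
#' a 4 s pulse at 5 mm/s: 0.2248, 0.2003, 0.1716, 0.1387, 0.1128 from the
#' entry chamber down the five-chamber cascade.
#'
#' @return A [replacement_profile()] with five fractions.
#' @export
#' @examples
#' default_profile()$fractions
default_profile <- function() {
  replacement_profile(c(0.2248, 0.2003, 0.1716, 0.1387, 0.1128),
                      flow_speed = 5, duration = 4)
}

#' @export
print.replacement_profile <- function(x, ...) {
  cat("<replacement_profile> ", length(x$fractions), " chambers at ",
      x$flow_speed, " mm/s for ", x$duration, " s\n  fractions: ",
      paste(signif(x$fractions, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Orient a replacement profile along a flow path
#'
#' Path-1 drives the pulse top-down, so chamber 1 (topmost) exchanges the
#' most; Path-2 drives it bottom-up through the mirror-symmetric cascade,
#' so the stored fraction list applies in reverse chamber order.
#'
#' @param profile A [replacement_profile()].
#' @param path `"PATH1"` (top-down) or `"PATH2"` (bottom-up).
#' @return Numeric vector of fractions in chamber order 1..m (top to
#'   bottom).
#' @export
#' @examples
#' oriented_fractions(default_profile(), "PATH2")
oriented_fractions <- function(profile, path = c("PATH1", "PATH2")) {
  stopifnot(inherits(profile, "replacement_profile"))
  path <- match.arg(path)
  if (path == "PATH1") profile$fractions else rev(profile$fractions)
}

#' Per-chamber, per-species concentration state
#'
#' @param n_chambers Number of chambers in the array.
#' @param species Character vector of registered drug names.
#' @param concentrations Optional chamber x species matrix in ng/mL
#'   (defaults to drug-free, all zero).
#' @param time Elapsed time in s.
#' @return A `concentration_state` wrapping the concentration matrix.
#' @export
concentration_state <- function(n_chambers, species,
                                concentrations = NULL, time = 0) {
  check_count(n_chambers, "n_chambers")
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species))
  if (is.null(concentrations)) {
    concentrations <- matrix(0, nrow = n_chambers, ncol = length(species),
                             dimnames = list(NULL, species))
  }
  concentrations <- as.matrix(concentrations)
  if (nrow(concentrations) != n_chambers ||
      ncol(concentrations) != length(species)) {
    stop("`concentrations` must be an n_chambers x species matrix",
         call. = FALSE)
  }
  colnames(concentrations) <- species
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(list(concentrations = concentrations, time = as.numeric(time)),
            class = "concentration_state")
}

#' @export
print.concentration_state <- function(x, ...) {
  cat("<concentration_state> t = ", x$time, " s (ng/mL)\n", sep = "")
  print(round(x$concentrations, 3))
  invisible(x)
}

#' A single drug pulse through a chamber array
#'
#' @param species Drug name (must be registered in the state it is applied
#'   to).
#' @param inlet_concentration Inlet concentration in ng/mL (>= 0).
#' @param path Flow direction, `"PATH1"` (top-down) or `"PATH2"`
#'   (bottom-up).
#' @param profile The [replacement_profile()] governing the pulse; defaults
#'   to the calibrated [default_profile()].
#' @param channel Feed-channel index within the array (bookkeeping only;
#'   channels are idealized as fully independent).
#' @return A `pulse_event`.
#' @export
pulse_event <- function(species, inlet_concentration,
                        path = c("PATH1", "PATH2"),
                        profile = default_profile(), channel = 1L) {
  path <- match.arg(path)
  stopifnot(is.character(species), length(species) == 1L,
            is.numeric(inlet_concentration),
            length(inlet_concentration) == 1L,
            inlet_concentration >= 0,
            inherits(profile, "replacement_profile"))
  check_count(channel, "channel")
  structure(
    list(species = species,
         inlet_concentration = as.numeric(inlet_concentration),
         path = path, profile = profile, channel = as.integer(channel)),
    class = "pulse_event"
  )
}

#' Apply one pulse to a concentration state
#'
#' For each chamber i the pulsed species is updated by the convex mixing
#' rule c' = (1 - f_i) c + f_i c_inlet, with f_i the oriented replacement
#' fraction. Other species are untouched (channels are idealized as fully
#' independent) and time advances by the pulse duration.
#'
#' @param state A [concentration_state()].
#' @param pulse A [pulse_event()].
#' @return The updated `concentration_state`.
#' @export
#' @examples
#' st <- concentration_state(5, "EGF")
#' apply_pulse(st, pulse_event("EGF", 500))$concentrations
apply_pulse <- function(state, pulse) {
  stopifnot(inherits(state, "concentration_state"),
            inherits(pulse, "pulse_event"))
  if (!pulse$species %in% colnames(state$concentrations)) {
    stop("species `", pulse$species, "` is not registered in the state",
         call. = FALSE)
  }
  f <- oriented_fractions(pulse$profile, pulse$path)
  if (length(f) != nrow(state$concentrations)) {
    stop("profile length (", length(f), ") does not match chamber count (",
         nrow(state$concentrations), ")", call. = FALSE)
  }
  conc <- state$concentrations
  conc[, pulse$species] <- (1 - f) * conc[, pulse$species] +
    f * pulse$inlet_concentration
  concentration_state(nrow(conc), colnames(conc), conc,
                      time = state$time + pulse$profile$duration)
}

#' Run a pulse schedule
#'
#' Left-fold of [apply_pulse()] over an ordered list of pulses.
#'
#' @param state Initial [concentration_state()].
#' @param pulses List of [pulse_event()]s (may be empty).
#' @return A list of `concentration_state`s of length `length(pulses) + 1`:
#'   the initial state followed by the state after each pulse.
#' @export
run_schedule <- function(state, pulses) {
  stopifnot(inherits(state, "concentration_state"), is.list(pulses))
  trajectory <- vector("list", length(pulses) + 1L)
  trajectory[[1L]] <- state
  for (i in seq_along(pulses)) {
    state <- apply_pulse(state, pulses[[i]])
    trajectory[[i + 1L]] <- state
  }
  trajectory
}

#' Closed form of repeated identical pulses
#'
#' n identical pulses from a drug-free state drive chamber i to
#' c_inlet * (1 - (1 - f_i)^n), the unrolled mixing recurrence. Used both
#' as a fast steady-state estimate and as the analytic cross-check for
#' [apply_pulse()].
#'
#' @param pulse A [pulse_event()].
#' @param n_pulses Number of repeats (>= 0).
#' @return A `concentration_state` for the pulsed species alone.
#' @export
steady_state_limit <- function(pulse, n_pulses) {
  stopifnot(inherits(pulse, "pulse_event"),
            is.numeric(n_pulses), length(n_pulses) == 1L,
            n_pulses >= 0, n_pulses == round(n_pulses))
  f <- oriented_fractions(pulse$profile, pulse$path)
  conc <- matrix(pulse$inlet_concentration * (1 - (1 - f)^n_pulses),
                 ncol = 1, dimnames = list(NULL, pulse$species))
  concentration_state(length(f), pulse$species, conc,
                      time = n_pulses * pulse$profile$duration)
}

#' Flatten a trajectory to a long table
#'
#' @param trajectory A list of `concentration_state`s from
#'   [run_schedule()].
#' @return A data frame with columns `time_s`, `chamber`, `species`,
#'   `concentration_ng_per_mL`.
#' @export
trajectory_table <- function(trajectory) {
  stopifnot(is.list(trajectory), length(trajectory) >= 1L)
  do.call(rbind, lapply(trajectory, function(st) {
    conc <- st$concentrations
    data.frame(
      time_s = st$time,
      chamber = rep(seq_len(nrow(conc)), times = ncol(conc)),
      species = rep(colnames(conc), each = nrow(conc)),
      concentration_ng_per_mL = as.vector(conc),
      stringsAsFactors = FALSE
    )
  }))
}
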