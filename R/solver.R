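# De-novo depth-averaged finite-volume advection-diffusion solver for one
# chamber cascade. The domain is the flow path of a single feed channel:
# straight channel segments alternating with culture chambers. Inside a
# chamber the channel crosses the exchange window; the rest of the chamber
# volume is a stagnant side cavity coupled to the moving stream by
# transverse diffusion. Velocity is plug flow at the inlet speed confined
# to the channel strip (divergence-free by construction); concentration is
# advected upwind along the strip and diffused centrally everywhere, with
# no-flux walls. The solver runs at unit inlet concentration, so the
# per-chamber mean concentration after one pulse is directly the
# dimensionless replacement fraction.

#' Finite-volume solver configuration
#'
#' @param diffusivity Tracer diffusivity in m^2/s. Default 1.0e-10, a
#'   typical value for growth-factor-scale proteins in water.
#' @param grid_cells_per_chamber Cells along the flow direction per
#'   exchange window (>= 4); also sets the target cell size everywhere.
#' @param channel_segment_length Length of the channel segment between
#'   consecutive chambers (and before/after the cascade), in um.
#' @param inlet_speed Plug-flow speed in the channel, mm/s.
#' @param duration Pulse duration, s.
#' @param channel_width Width of the flow channel, um. Not printed on the
#'   device drawings; 100 um is typical for valve-compatible rounded
#'   channels and is the package default.
#' @param cfl Safety factor in (0, 1] applied to the stability limit.
#' @param dt Optional explicit time step, s. Must respect the CFL limit;
#'   the solver refuses a violating step with a stability diagnostic.
#'   `NULL` (default) chooses the step automatically.
#' @return A `solver_config`.
#' @export
solver_config <- function(diffusivity = 1e-10,
                          grid_cells_per_chamber = 24,
                          channel_segment_length = 500,
                          inlet_speed = 5,
                          duration = 4,
                          channel_width = 100,
                          cfl = 0.5,
                          dt = NULL) {
  stopifnot(is.numeric(diffusivity), diffusivity > 0,
            is.numeric(channel_segment_length), channel_segment_length > 0,
            is.numeric(inlet_speed), inlet_speed > 0,
            is.numeric(duration), duration >= 0,
            is.numeric(channel_width), channel_width > 0,
            is.numeric(cfl), cfl > 0, cfl <= 1)
  if (!is.numeric(grid_cells_per_chamber) ||
      grid_cells_per_chamber != round(grid_cells_per_chamber) ||
      grid_cells_per_chamber < 4) {
    stop("`grid_cells_per_chamber` must be an integer >= 4 ",
         "(coarser grids do not resolve the exchange window)",
         call. = FALSE)
  }
  if (!is.null(dt)) stopifnot(is.numeric(dt), dt > 0)
  structure(
    list(diffusivity = diffusivity,
         grid_cells_per_chamber = as.integer(grid_cells_per_chamber),
         channel_segment_length = channel_segment_length,
         inlet_speed = inlet_speed,
         duration = duration,
         channel_width = channel_width,
         cfl = cfl,
         dt = dt),
    class = "solver_config"
  )
}

# Build the grid: uniform dx along the flow path; the transverse direction
# has a channel strip (active along the whole path) and cavity rows active
# only over the exchange windows. Lengths in um, speeds in um/s.
fv_grid <- function(geometry, config, n_chambers) {
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(config, "solver_config"))
  check_count(n_chambers, "n_chambers")
  L_w <- geometry$exchange_window_length
  dx <- L_w / config$grid_cells_per_chamber
  n_wx <- config$grid_cells_per_chamber
  n_sx <- max(2L, as.integer(round(config$channel_segment_length / dx)))
  nx <- (n_chambers + 1L) * n_sx + n_chambers * n_wx

  w_c <- config$channel_width
  n_strip <- max(3L, as.integer(round(w_c / dx)))
  dy_strip <- w_c / n_strip

  # Cavity depth conserves chamber volume: the chamber footprint
  # (width x length) minus the channel strip through the window.
  area <- geometry$chamber_width * geometry$chamber_length
  d_cav <- area / L_w - w_c
  if (d_cav < -1e-9) {
    stop("chamber volume smaller than the channel strip through it; ",
         "check geometry and channel_width", call. = FALSE)
  }
  if (d_cav > 1e-9) {
    n_cav <- max(4L, as.integer(round(d_cav / dx)))
    dy_cav <- d_cav / n_cav
  } else {
    n_cav <- 0L
    dy_cav <- numeric(0)
  }
  ny <- n_strip + n_cav
  h <- c(rep(dy_strip, n_strip), rep(dy_cav, n_cav))

  chamber_cols <- lapply(seq_len(n_chambers), function(j) {
    start <- j * n_sx + (j - 1L) * n_wx + 1L
    start:(start + n_wx - 1L)
  })
  window_col <- rep(FALSE, nx)
  for (cols in chamber_cols) window_col[cols] <- TRUE

  active <- matrix(FALSE, nx, ny)
  active[, seq_len(n_strip)] <- TRUE
  if (n_cav > 0L) active[window_col, n_strip + seq_len(n_cav)] <- TRUE

  list(dx = dx, nx = nx, ny = ny, h = h, n_strip = n_strip,
       n_cav = n_cav, chamber_cols = chamber_cols, active = active,
       u = config$inlet_speed * 1000,          # um/s
       D = config$diffusivity * 1e12)          # um^2/s
}

# Core explicit stepper. `direction` picks the inlet end; `sealed` closes
# both ends (pure diffusion, used for conservation checks). Returns the
# final field, spatial per-chamber volume-weighted means, the mass series
# (one entry per step, including t = 0) and cumulative boundary fluxes.
fv_simulate <- function(geometry, config, n_chambers,
                        direction = c("forward", "reverse"),
                        inlet_conc = 1, init = NULL, sealed = FALSE,
                        track_mass = FALSE) {
  direction <- match.arg(direction)
  g <- fv_grid(geometry, config, n_chambers)
  dx <- g$dx; h <- g$h; nx <- g$nx; ny <- g$ny
  S <- seq_len(g$n_strip)

  # stability limit: advective Courant and explicit-diffusion limits
  dt_adv <- dx / g$u
  min_h <- min(h)
  dt_diff <- 1 / (2 * g$D * (1 / dx^2 + 1 / min_h^2))
  dt_max <- min(dt_adv, dt_diff)
  if (!is.null(config$dt)) {
    if (config$dt > dt_max) {
      stop(sprintf(paste0("time step %.3g s violates the stability limit ",
                          "%.3g s (advective %.3g s, diffusive %.3g s); ",
                          "reduce dt or refine less"),
                   config$dt, dt_max, dt_adv, dt_diff), call. = FALSE)
    }
    dt <- config$dt
  } else {
    dt <- config$cfl * dt_max
  }
  n_steps <- max(1L, as.integer(ceiling(config$duration / dt)))
  dt <- config$duration / n_steps
  if (config$duration == 0) n_steps <- 0L

  # face conductances, zero across walls (inactive neighbours)
  act <- g$active
  Gx <- (g$D / dx) * outer(rep(1, nx - 1), h) *
    (act[-nx, , drop = FALSE] & act[-1, , drop = FALSE])
  if (ny > 1L) {
    dist <- (h[-ny] + h[-1]) / 2
    Gy <- g$D * dx * outer(rep(1, nx), 1 / dist) *
      (act[, -ny, drop = FALSE] & act[, -1, drop = FALSE])
  }

  vol <- outer(rep(dx, nx), h)
  C <- if (is.null(init)) matrix(0, nx, ny) else init
  stopifnot(all(dim(C) == c(nx, ny)))
  C[!act] <- 0

  uh <- g$u * h[S]                       # advective conductance per row
  mass <- if (track_mass) numeric(n_steps + 1L) else NULL
  if (track_mass) mass[1L] <- sum(C * vol)
  flux_in <- 0; flux_out <- 0

  for (step in seq_len(n_steps)) {
    # diffusion
    Fx <- Gx * (C[-1, , drop = FALSE] - C[-nx, , drop = FALSE])
    net <- rbind(Fx, 0) - rbind(0, Fx)
    if (ny > 1L) {
      Fy <- Gy * (C[, -1, drop = FALSE] - C[, -ny, drop = FALSE])
      net <- net + cbind(Fy, 0) - cbind(0, Fy)
    }
    # upwind advection along the channel strip
    if (!sealed) {
      Cs <- C[, S, drop = FALSE]
      if (direction == "forward") {
        up <- rbind(rep(inlet_conc, length(S)), Cs[-nx, , drop = FALSE])
        out_face <- Cs[nx, ]
      } else {
        up <- rbind(Cs[-1, , drop = FALSE], rep(inlet_conc, length(S)))
        out_face <- Cs[1, ]
      }
      adv <- sweep(up - Cs, 2, uh, "*")
      net[, S] <- net[, S] + adv
      flux_in <- flux_in + sum(uh * inlet_conc) * dt
      flux_out <- flux_out + sum(uh * out_face) * dt
    }
    C <- C + dt * net / vol
    if (track_mass) mass[step + 1L] <- sum(C * vol)
  }

  chamber_means <- vapply(g$chamber_cols, function(cols) {
    sum(C[cols, ] * vol[cols, ]) / sum(vol[cols, ][act[cols, ]])
  }, numeric(1))

  list(field = C, grid = g, dt = dt, n_steps = n_steps,
       chamber_means = chamber_means,   # spatial order, chamber 1 = leftmost
       mass = mass, flux_in = flux_in, flux_out = flux_out)
}

#' Simulate per-chamber replacement fractions from first principles
#'
#' Runs the depth-averaged finite-volume advection-diffusion solver for a
#' single pulse of unit inlet concentration into an initially drug-free
#' cascade and reports the per-chamber mean concentration after
#' `config$duration` as the replacement fraction. Fraction index 1 is the
#' chamber nearest the pulse entry.
#'
#' The result is a physics-based counterpart to the calibrated
#' [default_profile()]; mesh, diffusivity and exact device geometry are
#' not fully published, so agreement is expected at the tens-of-percent
#' level, not bit-exactly.
#'
#' @param geometry A [chamber_geometry()].
#' @param config A [solver_config()].
#' @param n_chambers Number of chambers in the cascade.
#' @return A [replacement_profile()] (boundary fractions of 0 or 1 are
#'   permitted in limiting cases).
#' @export
#' @examples
#' \donttest{
#' prof <- fv_replacement_fractions(chamber_geometry(), solver_config(), 5)
#' prof$fractions
#' }
fv_replacement_fractions <- function(geometry = chamber_geometry(),
                                     config = solver_config(),
                                     n_chambers = 5) {
  res <- fv_simulate(geometry, config, n_chambers, direction = "forward")
  replacement_profile(res$chamber_means,
                      flow_speed = config$inlet_speed,
                      duration = config$duration,
                      allow_boundary = TRUE)
}
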