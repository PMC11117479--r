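# Cell-response readouts. The observable is a per-cell boolean reporter
# call (Hes-5 fluorescence retained = still a stem cell); the stemness
# fraction of a chamber or condition is the proportion of reporter-positive
# cells. A synthetic cohort generator with a logistic dose-dependent
# differentiation probability provides end-to-end fixtures; it is a testing
# device, not a mechanistic model of the biology.

#' Per-cell observation table
#'
#' Cell tables are plain data frames with columns `array`, `chamber`,
#' `condition`, `time_h` and logical `hes5_positive`. This helper validates
#' and normalizes such a table.
#'
#' @param cells A data frame.
#' @return The validated data frame.
#' @export
as_cell_table <- function(cells) {
  stopifnot(is.data.frame(cells))
  needed <- c("array", "chamber", "condition", "time_h", "hes5_positive")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    stop("cell table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cells$hes5_positive <- as.logical(cells$hes5_positive)
  if (any(is.na(cells$hes5_positive))) {
    stop("`hes5_positive` must be interpretable as logical", call. = FALSE)
  }
  if (any(cells$time_h < 0)) stop("`time_h` must be >= 0", call. = FALSE)
  cells
}

#' Stemness fraction of a cell cohort
#'
#' Proportion of reporter-positive cells. Invariant to record order and to
#' array/chamber relabeling.
#'
#' @param cells A cell table (see [as_cell_table()]) or a logical vector of
#'   per-cell reporter calls.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' stemness_fraction(c(rep(TRUE, 10), rep(FALSE, 10)))
stemness_fraction <- function(cells) {
  calls <- if (is.data.frame(cells)) {
    as_cell_table(cells)$hes5_positive
  } else {
    as.logical(cells)
  }
  if (length(calls) == 0L) {
    stop("cannot compute a stemness fraction from an empty cohort",
         call. = FALSE)
  }
  if (any(is.na(calls))) stop("reporter calls contain NA", call. = FALSE)
  mean(calls)
}

#' Summarize a condition over repeats
#'
#' The condition-level stemness fraction is the mean of the per-repeat
#' fractions; dispersion is the sample (n-1) standard deviation across
#' repeats. Fewer than 5 repeats raises the `below_minimum` flag, the
#' device's stated minimum for reporting a standard deviation.
#'
#' @param groups List of per-repeat cohorts, each a cell table or logical
#'   vector; every repeat must be non-empty.
#' @param condition Condition label.
#' @param time Observation time in hours.
#' @return A `stemness_summary`: list with `condition`, `time`,
#'   `fraction_positive`, `sd`, `n_repeats`, `below_minimum`.
#' @export
#' @examples
#' reps <- list(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
#' summarize_condition(reps, "control", 48)
summarize_condition <- function(groups, condition, time) {
  stopifnot(is.list(groups))
  if (length(groups) == 0L) {
    stop("at least one repeat is required", call. = FALSE)
  }
  fractions <- vapply(groups, stemness_fraction, numeric(1))
  n <- length(fractions)
  structure(
    list(condition = condition,
         time = as.numeric(time),
         fraction_positive = mean(fractions),
         sd = if (n > 1L) stats::sd(fractions) else 0,
         n_repeats = n,
         below_minimum = n < 5L),
    class = "stemness_summary"
  )
}

#' @export
print.stemness_summary <- function(x, ...) {
  cat("<stemness_summary> ", x$condition, " at ", x$time, " h: ",
      sprintf("%.3f +/- %.3f", x$fraction_positive, x$sd),
      " (n = ", x$n_repeats, " repeats",
      if (x$below_minimum) "; below the 5-repeat minimum" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Logistic dose-response model for synthetic cohorts
#'
#' Differentiation probability
#' `p(dose) = baseline + (max - baseline) / (1 + exp(-steepness * (dose - dose_midpoint)))`.
#' Defaults emulate the qualitative readout of the reference experiments:
#' near-control differentiation at the low end of a gradient and a plateau
#' of about 50% differentiated cells at growth-factor overdose, with the
#' transition sitting mid-gradient.
#'
#' @param baseline_differentiation Differentiation probability at zero
#'   dose, in `[0, max]`.
#' @param max_differentiation High-dose plateau, in `[baseline, 1]`.
#' @param dose_midpoint Dose of half-maximal effect, ng/mL (> 0).
#' @param steepness Logistic slope, per ng/mL (> 0).
#' @param seed Integer seed making cohort generation deterministic.
#' @return A `response_model`.
#' @export
response_model <- function(baseline_differentiation = 0.05,
                           max_differentiation = 0.5,
                           dose_midpoint = 150,
                           steepness = 0.1,
                           seed = 1L) {
  stopifnot(is.numeric(baseline_differentiation),
            is.numeric(max_differentiation),
            is.numeric(dose_midpoint), is.numeric(steepness),
            is.numeric(seed), length(seed) == 1L)
  if (baseline_differentiation < 0 ||
      max_differentiation < baseline_differentiation ||
      max_differentiation > 1) {
    stop("need 0 <= baseline <= max <= 1", call. = FALSE)
  }
  if (dose_midpoint <= 0) stop("`dose_midpoint` must be > 0", call. = FALSE)
  if (steepness <= 0) stop("`steepness` must be > 0", call. = FALSE)
  structure(
    list(baseline_differentiation = baseline_differentiation,
         max_differentiation = max_differentiation,
         dose_midpoint = dose_midpoint,
         steepness = steepness,
         seed = as.integer(seed)),
    class = "response_model"
  )
}

#' Differentiation probability at given dose(s)
#'
#' @param model A [response_model()].
#' @param dose Dose(s) in ng/mL.
#' @return Probabilities in `[baseline, max]`.
#' @export
diff_probability <- function(model, dose) {
  stopifnot(inherits(model, "response_model"), is.numeric(dose))
  b <- model$baseline_differentiation
  m <- model$max_differentiation
  b + (m - b) / (1 + exp(-model$steepness * (dose - model$dose_midpoint)))
}

#' Generate a synthetic cell cohort for a planned dose matrix
#'
#' Per chamber, each cell independently differentiates (loses the Hes-5
#' reporter) with probability `diff_probability(model, dose)`, where the
#' chamber dose is the summed concentration of all drugs in that chamber.
#' Deterministic given the model seed; the caller's RNG state is left
#' untouched.
#'
#' @param dose_matrix A [combination_matrix()] result.
#' @param model A [response_model()].
#' @param cells_per_chamber Cells seeded per chamber (>= 1).
#' @param array Array index recorded in the output table.
#' @param time_h Observation time recorded in the output table.
#' @return A cell table (see [as_cell_table()]) with one row per cell.
#' @export
synth_cells <- function(dose_matrix, model, cells_per_chamber = 200,
                        array = 1L, time_h = 48) {
  stopifnot(inherits(dose_matrix, "dose_matrix"),
            inherits(model, "response_model"))
  check_count(cells_per_chamber, "cells_per_chamber")
  dose <- tapply(dose_matrix$concentration_ng_per_mL, dose_matrix$chamber,
                 sum)
  chambers <- as.integer(names(dose))
  codes <- attr(dose_matrix, "combo_codes")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(model$seed)

  out <- lapply(seq_along(chambers), function(i) {
    p <- diff_probability(model, dose[[i]])
    differentiated <- stats::runif(cells_per_chamber) < p
    data.frame(array = as.integer(array),
               chamber = chambers[i],
               condition = codes[chambers[i]],
               time_h = time_h,
               hes5_positive = !differentiated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the logistic dose-response model by maximum likelihood
#'
#' Fits all four parameters of the [response_model()] curve to binomial
#' counts of differentiated cells by dose, via BFGS on the binomial
#' log-likelihood under a box-free reparameterization (logit for the
#' plateaus, log for midpoint and steepness).
#'
#' @param dose Numeric vector of doses (ng/mL).
#' @param n_differentiated Differentiated-cell counts per dose.
#' @param n_total Total cell counts per dose.
#' @param start Optional `response_model` used as the starting point.
#' @return A list with `baseline_differentiation`, `max_differentiation`,
#'   `dose_midpoint`, `steepness`, `logLik` and `converged`.
#' @export
fit_response_model <- function(dose, n_differentiated, n_total,
                               start = NULL) {
  stopifnot(is.numeric(dose), length(dose) >= 3L,
            length(n_differentiated) == length(dose),
            length(n_total) == length(dose),
            all(n_total >= 1), all(n_differentiated >= 0),
            all(n_differentiated <= n_total))
  if (is.null(start)) {
    p_obs <- n_differentiated / n_total
    start <- response_model(
      baseline_differentiation = max(min(p_obs), 1e-3),
      max_differentiation = min(max(max(p_obs), min(p_obs) + 0.05), 0.999),
      dose_midpoint = stats::median(dose),
      steepness = 4 / max(diff(range(dose)), 1e-6)
    )
  }
  qlogis_safe <- function(p) stats::qlogis(min(max(p, 1e-6), 1 - 1e-6))
  theta0 <- c(qlogis_safe(start$baseline_differentiation),
              qlogis_safe(
                (start$max_differentiation -
                   start$baseline_differentiation) /
                  max(1 - start$baseline_differentiation, 1e-6)),
              log(start$dose_midpoint),
              log(start$steepness))
  unpack <- function(theta) {
    b <- stats::plogis(theta[1])
    m <- b + (1 - b) * stats::plogis(theta[2])
    list(b = b, m = m, d0 = exp(theta[3]), s = exp(theta[4]))
  }
  nll <- function(theta) {
    p <- unpack(theta)
    pr <- p$b + (p$m - p$b) / (1 + exp(-p$s * (dose - p$d0)))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(n_differentiated, n_total, pr, log = TRUE))
  }
  fit <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  p <- unpack(fit$par)
  list(baseline_differentiation = p$b,
       max_differentiation = p$m,
       dose_midpoint = p$d0,
       steepness = p$s,
       logLik = -fit$value,
       converged = fit$convergence == 0L)
}

#' Write / read cell tables and summaries as tab-delimited text
#'
#' @param cells A cell table.
#' @param path File path.
#' @return `read_cells()` returns a validated cell table.
#' @export
write_cells <- function(cells, path) {
  cells <- as_cell_table(cells)
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  as_cell_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Summarize every condition in a cell table
#'
#' Repeats are taken to be the distinct (array, chamber) cohorts observed
#' for each condition at each time point.
#'
#' @param cells A cell table.
#' @return A data frame with one row per condition and time: columns
#'   `condition`, `time_h`, `fraction_positive`, `sd`, `n_repeats`,
#'   `below_minimum`.
#' @export
summarize_cells <- function(cells) {
  cells <- as_cell_table(cells)
  keys <- unique(cells[, c("condition", "time_h")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- cells[cells$condition == keys$condition[i] &
                   cells$time_h == keys$time_h[i], , drop = FALSE]
    groups <- split(sub$hes5_positive,
                    interaction(sub$array, sub$chamber, drop = TRUE))
    s <- summarize_condition(groups, keys$condition[i], keys$time_h[i])
    data.frame(condition = s$condition, time_h = s$time,
               fraction_positive = s$fraction_positive, sd = s$sd,
               n_repeats = s$n_repeats, below_minimum = s$below_minimum,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
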