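# Path-directed dose planning: turn inlet drug specifications into
# per-chamber gradients, values at the device's reporting precision, and
# combination dose codes ("1+5+5" = high + low + low).

#' Drug specification
#'
#' @param name Drug identifier.
#' @param inlet_concentration Inlet concentration in ng/mL (> 0).
#' @param channel Feed-channel index within the array.
#' @return A `drug_spec`.
#' @export
#' @examples
#' drug_spec("EGF", 500, 1)
drug_spec <- function(name, inlet_concentration, channel = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(inlet_concentration) ||
      length(inlet_concentration) != 1L || inlet_concentration <= 0) {
    stop("`inlet_concentration` must be a single positive ng/mL value",
         call. = FALSE)
  }
  check_count(channel, "channel")
  structure(
    list(name = name,
         inlet_concentration = as.numeric(inlet_concentration),
         channel = as.integer(channel)),
    class = "drug_spec"
  )
}

#' Per-chamber concentrations of one drug gradient
#'
#' One pulse into drug-free chambers establishes the gradient: chamber i
#' receives `inlet_concentration * oriented_fractions(profile, path)[i]`.
#'
#' @param drug A [drug_spec()].
#' @param profile A [replacement_profile()].
#' @param path `"PATH1"` or `"PATH2"`.
#' @return Numeric vector of concentrations (ng/mL) in chamber order 1..m.
#' @export
#' @examples
#' chamber_concentrations(drug_spec("EGF", 500), default_profile(), "PATH1")
chamber_concentrations <- function(drug, profile = default_profile(),
                                   path = c("PATH1", "PATH2")) {
  stopifnot(inherits(drug, "drug_spec"))
  drug$inlet_concentration * oriented_fractions(profile, path)
}

#' Round a concentration to the device's reporting precision
#'
#' Chamber concentrations are reported to the nearest multiple of 1% of
#' the inlet concentration (half away from zero): a 500 ng/mL inlet is
#' reported on a 5 ng/mL raster, a 200 ng/mL inlet on 2 ng/mL, a
#' 1000 ng/mL inlet on 10 ng/mL. This reporting convention reproduces all
#' printed gradient values of the reference device; raw concentrations
#' should always be retained alongside.
#'
#' @param value Concentration(s) in ng/mL (>= 0); vectorized.
#' @param inlet_concentration The gradient's inlet concentration (> 0).
#' @return Rounded concentration(s), ng/mL.
#' @export
#' @examples
#' report_rounded(112.40, 500)   # 110
#' report_rounded(138.70, 1000)  # 140
report_rounded <- function(value, inlet_concentration) {
  if (!is.numeric(inlet_concentration) ||
      length(inlet_concentration) != 1L || inlet_concentration <= 0) {
    stop("`inlet_concentration` must be a single positive ng/mL value",
         call. = FALSE)
  }
  stopifnot(is.numeric(value), all(value >= 0))
  step <- inlet_concentration / 100
  floor(value / step + 0.5) * step   # half away from zero (values >= 0)
}

#' Combination dose matrix for several drugs
#'
#' Each drug flows on its own channel in a chosen direction; Path-1 puts
#' its highest dose in chamber 1, Path-2 in chamber m. The dose rank of
#' drug d in chamber r is r under Path-1 and m+1-r under Path-2 (rank 1 =
#' highest dose of that drug). A chamber's combo code is the `+`-joined
#' tuple of ranks in channel order, e.g. `"1+5+5"` for high + low + low.
#'
#' @param drugs List of [drug_spec()]s, each on a distinct channel.
#' @param paths Named character vector or list mapping every drug name to
#'   `"PATH1"` or `"PATH2"`.
#' @param profile A [replacement_profile()].
#' @return A `dose_matrix`: a long data frame with columns `chamber`,
#'   `drug`, `rank`, `concentration_ng_per_mL`, `reported_ng_per_mL`,
#'   `combo_code`, with attribute `combo_codes` (one code per chamber).
#' @export
#' @examples
#' drugs <- list(drug_spec("EGF", 500, 1), drug_spec("FGF", 200, 2),
#'               drug_spec("PDGF", 1000, 3))
#' dm <- combination_matrix(drugs,
#'   c(EGF = "PATH1", FGF = "PATH2", PDGF = "PATH2"))
#' attr(dm, "combo_codes")[1]
combination_matrix <- function(drugs, paths, profile = default_profile()) {
  stopifnot(is.list(drugs), length(drugs) >= 1L)
  lapply(drugs, function(d) stopifnot(inherits(d, "drug_spec")))
  channels <- vapply(drugs, function(d) d$channel, integer(1))
  if (anyDuplicated(channels)) {
    stop("each drug must occupy a distinct channel", call. = FALSE)
  }
  names_ <- vapply(drugs, function(d) d$name, "")
  paths <- unlist(paths)
  missing <- setdiff(names_, names(paths))
  if (length(missing)) {
    stop("no path given for drug(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drugs <- drugs[order(channels)]   # combo codes follow channel order
  names_ <- vapply(drugs, function(d) d$name, "")
  m <- length(profile$fractions)

  per_drug <- lapply(drugs, function(d) {
    p <- match.arg(paths[[d$name]], c("PATH1", "PATH2"))
    conc <- chamber_concentrations(d, profile, p)
    rank <- if (p == "PATH1") seq_len(m) else m + 1L - seq_len(m)
    data.frame(chamber = seq_len(m), drug = d$name, rank = rank,
               concentration_ng_per_mL = conc,
               reported_ng_per_mL =
                 report_rounded(conc, d$inlet_concentration),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_drug)
  ranks <- vapply(per_drug, function(x) x$rank, integer(m))
  codes <- apply(matrix(ranks, nrow = m), 1, paste, collapse = "+")
  tab$combo_code <- codes[tab$chamber]
  tab <- tab[order(tab$chamber), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, combo_codes = codes,
            class = c("dose_matrix", "data.frame"))
}

#' Assign experimental conditions to chip arrays
#'
#' Conditions are assigned injectively to arrays in listed order; leftover
#' arrays are marked `"idle"`.
#'
#' @param layout A [build_layout()].
#' @param conditions Character vector of condition labels (at most
#'   `n_arrays`).
#' @return A data frame with columns `array`, `condition`.
#' @export
plan_experiment <- function(layout, conditions) {
  stopifnot(inherits(layout, "chip_layout"), is.character(conditions))
  n <- layout$n_arrays
  if (length(conditions) > n) {
    stop("cannot assign ", length(conditions), " conditions to ", n,
         " arrays", call. = FALSE)
  }
  if (anyDuplicated(conditions)) {
    stop("condition labels must be unique", call. = FALSE)
  }
  data.frame(array = seq_len(n),
             condition = c(conditions,
                           rep("idle", n - length(conditions))),
             stringsAsFactors = FALSE)
}

#' Write / read a dose matrix as tab-delimited text
#'
#' @param dose_matrix A [combination_matrix()] result.
#' @param path File path.
#' @return `read_dose_matrix()` returns the `dose_matrix`.
#' @export
write_dose_matrix <- function(dose_matrix, path) {
  stopifnot(inherits(dose_matrix, "dose_matrix"))
  utils::write.table(dose_matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_matrix
#' @export
read_dose_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  codes <- tab$combo_code[!duplicated(tab$chamber)][order(unique(tab$chamber))]
  structure(tab, combo_codes = codes,
            class = c("dose_matrix", "data.frame"))
}
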