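# Shared fixtures: the reference device's drug panel and its printed
# per-chamber gradient values (ng/mL, chamber 1 = highest dose end).

reference_drugs <- function() {
  list(EGF = drug_spec("EGF", 500, 1),
       FGF = drug_spec("FGF", 200, 2),
       PDGF = drug_spec("PDGF", 1000, 3))
}

printed_gradients <- function() {
  list(EGF = c(110, 100, 85, 70, 55),
       FGF = c(44, 40, 34, 28, 22),
       PDGF = c(220, 200, 170, 140, 110))
}

# independent oracle for min_valves: count actual k-subsets instead of
# using choose()
min_valves_oracle <- function(n_channels, k) {
  n <- k
  repeat {
    if (length(utils::combn(n, k, simplify = FALSE)) >= n_channels) return(n)
    n <- n + 1
  }
}

# strip-only chamber: no stagnant cavity, chamber volume equals the channel
# strip through the window (used for analytic solver checks)
strip_geometry <- function(channel_width = 100, window = 790) {
  chamber_geometry(chamber_width = channel_width, chamber_length = window,
                   exchange_window_width = channel_width,
                   exchange_window_length = window)
}
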