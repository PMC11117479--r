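test_that("the calibrated default profile carries the measured fractions", {
  p <- default_profile()
  expect_identical(p$fractions, c(0.2248, 0.2003, 0.1716, 0.1387, 0.1128))
  expect_equal(p$flow_speed, 5)
  expect_equal(p$duration, 4)
  expect_true(all(diff(p$fractions) < 0))  # strictly decreasing
})

test_that("replacement_profile enforces its invariants", {
  expect_error(replacement_profile(c(0.3, 0.2, 1.1), 5, 4), "strictly in")
  expect_error(replacement_profile(c(0.3, 0, 0), 5, 4), "strictly in")
  expect_error(replacement_profile(c(0.1, 0.2), 5, 4), "non-increasing")
  expect_silent(replacement_profile(c(0.2, 0.2, 0.1), 5, 4))
})

test_that("oriented_fractions mirrors the cascade under Path-2", {
  p <- default_profile()
  expect_equal(oriented_fractions(p, "PATH1")[1], 0.2248)
  expect_equal(oriented_fractions(p, "PATH2")[1], 0.1128)
  expect_equal(oriented_fractions(p, "PATH2"), rev(p$fractions))
  # the only palindromic non-increasing profile is a constant one
  pal <- replacement_profile(c(0.2, 0.2, 0.2), 5, 4)
  expect_equal(oriented_fractions(pal, "PATH1"),
               oriented_fractions(pal, "PATH2"))
})

test_that("apply_pulse implements the convex mixing rule", {
  st <- concentration_state(5, c("EGF", "FGF"))
  out <- apply_pulse(st, pulse_event("EGF", 500, "PATH1"))
  expect_equal(out$concentrations[, "EGF"],
               c(112.40, 100.15, 85.80, 69.35, 56.40))
  expect_equal(out$concentrations[, "FGF"], rep(0, 5))  # independence
  expect_equal(out$time, 4)

  zero <- apply_pulse(st, pulse_event("EGF", 0, "PATH1"))
  expect_equal(zero$concentrations[, "EGF"], rep(0, 5))

  # two identical pulses, chamber 1: oracle = brute-force recurrence unroll
  two <- apply_pulse(out, pulse_event("EGF", 500, "PATH1"))
  expect_equal(unname(two$concentrations[1, "EGF"]), 199.53248,
               tolerance = 1e-12)

  expect_error(apply_pulse(st, pulse_event("VEGF", 100)), "not registered")
  st3 <- concentration_state(3, "EGF")
  expect_error(apply_pulse(st3, pulse_event("EGF", 100)), "chamber count")
})

test_that("run_schedule is the left fold of apply_pulse", {
  st <- concentration_state(5, "EGF")
  expect_identical(run_schedule(st, list()), list(st))

  p <- pulse_event("EGF", 500, "PATH1")
  traj <- run_schedule(st, list(p))
  expect_length(traj, 2)
  expect_equal(traj[[2]]$concentrations, apply_pulse(st, p)$concentrations)

  # alternating paths: the middle chamber's fraction is path-invariant
  f3 <- default_profile()$fractions[3]
  traj2 <- run_schedule(st, list(pulse_event("EGF", 500, "PATH1"),
                                 pulse_event("EGF", 500, "PATH2")))
  expect_equal(unname(traj2[[3]]$concentrations[3, "EGF"]),
               500 * (1 - (1 - f3)^2), tolerance = 1e-12)
  expect_length(traj2, 3)
})

test_that("n-fold pulses match the closed-form recurrence exactly", {
  st <- concentration_state(5, "EGF")
  p <- pulse_event("EGF", 500, "PATH1")
  for (n in c(0, 1, 3, 12, 50)) {
    folded <- st
    for (i in seq_len(n)) folded <- apply_pulse(folded, p)
    closed <- steady_state_limit(p, n)
    expect_equal(folded$concentrations[, "EGF"],
                 closed$concentrations[, "EGF"], tolerance = 1e-13)
  }
  # after 50 pulses every chamber is within 0.3% of the inlet
  c50 <- steady_state_limit(p, 50)$concentrations[, "EGF"]
  expect_true(all(abs(c50 - 500) / 500 < 0.003))
})

test_that("schedules respect boundedness, monotonicity and independence", {
  set.seed(7)
  for (rep in 1:10) {
    st <- concentration_state(5, c("A", "B"))
    inlets <- c(A = runif(1, 10, 1000), B = runif(1, 10, 1000))
    pulses <- lapply(1:8, function(i) {
      sp <- sample(c("A", "B"), 1)
      pulse_event(sp, inlets[[sp]], sample(c("PATH1", "PATH2"), 1))
    })
    traj <- run_schedule(st, pulses)
    final <- traj[[length(traj)]]$concentrations
    expect_true(all(final >= 0))
    expect_true(all(final[, "A"] <= inlets[["A"]] + 1e-12))
    expect_true(all(final[, "B"] <= inlets[["B"]] + 1e-12))
  }

  # repeated identical pulses: per-chamber non-decreasing, converging
  st <- concentration_state(5, "A")
  p <- pulse_event("A", 100, "PATH2")
  traj <- run_schedule(st, rep(list(p), 30))
  mat <- vapply(traj, function(s) s$concentrations[, "A"], numeric(5))
  expect_true(all(diff(t(mat)) >= 0))
  expect_true(all(abs(mat[, 31] - 100) < 100 * (1 - 0.1128)^30 + 1e-9))

  # pulsing A never moves B
  stAB <- concentration_state(5, c("A", "B"),
                              matrix(c(rep(3, 5), rep(9, 5)), 5, 2))
  outAB <- apply_pulse(stAB, pulse_event("A", 50))
  expect_equal(outAB$concentrations[, "B"], rep(9, 5))
})

test_that("trajectories flatten to a tidy long table", {
  st <- concentration_state(2, c("A", "B"))
  traj <- run_schedule(st, list(pulse_event(
    "A", 10, profile = replacement_profile(c(0.3, 0.2), 5, 4))))
  tab <- trajectory_table(traj)
  expect_identical(nrow(tab), 8L)  # 2 states x 2 chambers x 2 species
  expect_identical(names(tab),
                   c("time_s", "chamber", "species",
                     "concentration_ng_per_mL"))
  expect_equal(tab$concentration_ng_per_mL[tab$time_s == 4 &
                                             tab$species == "A"],
               c(3, 2))
})
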