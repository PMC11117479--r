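test_that("stemness_fraction is the positive-call proportion", {
  expect_equal(stemness_fraction(c(rep(TRUE, 10), rep(FALSE, 10))), 0.5)
  expect_equal(stemness_fraction(rep(TRUE, 7)), 1.0)
  expect_error(stemness_fraction(logical(0)), "empty")

  cells <- data.frame(array = 1, chamber = rep(1:2, 5), condition = "c",
                      time_h = 48,
                      hes5_positive = rep(c(TRUE, FALSE), 5))
  expect_equal(stemness_fraction(cells), 0.5)
  # order and relabeling invariance
  shuffled <- cells[sample(nrow(cells)), ]
  shuffled$array <- 9
  shuffled$chamber <- rev(shuffled$chamber)
  expect_equal(stemness_fraction(shuffled), stemness_fraction(cells))
})

test_that("summarize_condition averages repeats with sample sd", {
  same <- replicate(5, c(rep(TRUE, 3), FALSE), simplify = FALSE)
  s <- summarize_condition(same, "ctrl", 48)
  expect_equal(s$sd, 0)
  expect_false(s$below_minimum)

  reps <- list(c(rep(TRUE, 4), rep(FALSE, 6)),
               c(rep(TRUE, 5), rep(FALSE, 5)),
               c(rep(TRUE, 6), rep(FALSE, 4)),
               c(rep(TRUE, 5), rep(FALSE, 5)),
               c(rep(TRUE, 5), rep(FALSE, 5)))
  s2 <- summarize_condition(reps, "egf", 48)
  expect_equal(s2$fraction_positive, 0.5)
  expect_equal(s2$sd, 0.07071067812, tolerance = 1e-9)  # hand-computed
  expect_identical(s2$n_repeats, 5L)

  s3 <- summarize_condition(reps[1:3], "egf", 48)
  expect_true(s3$below_minimum)

  single <- summarize_condition(reps[2], "egf", 0)
  expect_equal(single$fraction_positive, 0.5)
  expect_equal(single$sd, 0)
  expect_true(single$below_minimum)

  expect_error(summarize_condition(list(), "x", 0), "at least one")
})

test_that("synthetic cohorts are seed-deterministic and leave the RNG alone", {
  dm <- combination_matrix(list(drug_spec("EGF", 500, 1)),
                           c(EGF = "PATH1"))
  m <- response_model(seed = 99)
  a <- synth_cells(dm, m, 50)
  b <- synth_cells(dm, m, 50)
  expect_identical(a, b)
  expect_false(identical(a, synth_cells(dm, response_model(seed = 100), 50)))

  set.seed(321)
  before <- .Random.seed
  invisible(synth_cells(dm, m, 50))
  expect_identical(.Random.seed, before)
})

test_that("cohort fractions track the configured differentiation model", {
  dm <- combination_matrix(list(drug_spec("PDGF", 1000, 1)),
                           c(PDGF = "PATH1"))
  # constant p = 0.5 model: fraction within 3 binomial SEs at n = 1000
  flat <- response_model(baseline_differentiation = 0.5,
                         max_differentiation = 0.5, seed = 5)
  cells <- synth_cells(dm, flat, 1000)
  ch1 <- cells[cells$chamber == 1, ]
  expect_lt(abs(stemness_fraction(ch1) - 0.5), 3 * sqrt(0.25 / 1000))

  # baseline limit at (near) zero dose
  low <- response_model(seed = 6)   # baseline 0.05, midpoint 150
  tiny_dm <- combination_matrix(list(drug_spec("X", 1, 1)),
                                c(X = "PATH1"))  # doses ~0.1-0.2 ng/mL
  cellsb <- synth_cells(tiny_dm, low, 2000)
  frac_diff <- 1 - stemness_fraction(cellsb)
  expect_lt(abs(frac_diff - 0.05), 3 * sqrt(0.05 * 0.95 / (5 * 2000)))

  # plateau at overdose approaches max_differentiation
  hot_dm <- combination_matrix(list(drug_spec("Y", 10000, 1)),
                               c(Y = "PATH1"))
  cellsm <- synth_cells(hot_dm, response_model(seed = 7), 2000)
  expect_lt(abs((1 - stemness_fraction(cellsm)) - 0.5),
            3 * sqrt(0.25 / (5 * 2000)))
})

test_that("maximum likelihood recovers the generating plateaus", {
  dm <- combination_matrix(list(drug_spec("PDGF", 1000, 1)),
                           c(PDGF = "PATH1"))
  model <- response_model(seed = 123)
  cells <- synth_cells(dm, model, 2000)
  counts <- vapply(split(cells$hes5_positive, cells$chamber),
                   function(x) sum(!x), numeric(1))
  fit <- fit_response_model(dm$concentration_ng_per_mL,
                            counts[as.character(1:5)], rep(2000, 5))
  expect_true(fit$converged)
  expect_lt(abs(fit$baseline_differentiation -
                  model$baseline_differentiation), 0.05)
  expect_lt(abs(fit$max_differentiation - model$max_differentiation), 0.05)
})

test_that("cell tables validate, summarize and round-trip", {
  dm <- combination_matrix(unname(reference_drugs()),
                           c(EGF = "PATH1", FGF = "PATH2", PDGF = "PATH2"))
  cells <- synth_cells(dm, response_model(seed = 2), 40)
  expect_identical(nrow(cells), 200L)
  expect_setequal(unique(cells$condition), attr(dm, "combo_codes"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_cells(cells, path)
  back <- read_cells(path)
  expect_equal(back$hes5_positive, cells$hes5_positive)

  summ <- summarize_cells(cells)
  expect_identical(nrow(summ), 5L)   # one row per combo code
  expect_true(all(summ$fraction_positive >= 0 &
                    summ$fraction_positive <= 1))
  expect_true(all(summ$below_minimum))  # single cohort per condition

  expect_error(as_cell_table(data.frame(a = 1)), "lacks column")
})
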