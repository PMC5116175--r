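test_that("individual draws are log-normal around the population medians", {
  pop <- table3_population()
  # zero variability returns the population means exactly
  popz <- pop; popz$omega[] <- 0
  inds <- draw_individuals(popz, 3, seed = 1)
  for (p in inds) expect_equal(unlist(p), theta3, tolerance = 1e-12)
  # identical seeds give identical draws
  a <- draw_individuals(pop, 5, seed = 7)
  b <- draw_individuals(pop, 5, seed = 7)
  expect_identical(attr(a, "eta"), attr(b, "eta"))
  # at large n the sample median of Cl approaches theta (log-normal median)
  big <- draw_individuals(pop, 10000, seed = 3)
  cls <- vapply(big, `[[`, 0, "Cl")
  expect_equal(stats::median(cls), 21109.2, tolerance = 0.02)
})

test_that("simulated percentile bands collapse to the closed form at zero omega", {
  pop <- table3_population()
  pop$omega[] <- 0
  sim <- simulate_replicates(pop, regimen = list(dose_times_h = 0), n_reps = 5,
                             seed = 2, design = list(grid_h = seq(0, 720, 12)))
  expected <- plasma_conc_closed(params3(), single_dose_88kg(), sim$grid)
  bands <- sim_bands(sim)
  pl <- bands[bands$matrix == "plasma", ]
  expect_equal(pl$p50, expected, tolerance = 1e-12)
  expect_equal(pl$p95, expected, tolerance = 1e-12)
})

test_that("replicate milk amounts approach the closed-form dose fraction", {
  pop <- table3_population()
  sim <- simulate_replicates(pop, regimen = list(dose_times_h = 0), n_reps = 20,
                             seed = 4, design = list(grid_h = seq(0, 6000, 12)))
  final <- sim$milk_amount[, ncol(sim$milk_amount)]
  # per replicate the cumulative amount is monotone and below its own limit
  for (i in seq_len(sim$n_reps)) {
    expect_true(all(diff(sim$milk_amount[i, ]) >= 0))
  }
  # the median replicate's final amount is near the theta-level limit scale
  limit <- 2.2e8 * 882.461 / (21109.2 + 882.461)
  expect_gt(stats::median(final), 0.3 * limit)
})

test_that("two-dose replicate trajectories are causal copies before the second dose", {
  pop <- table3_population()
  g <- seq(0, 1200, 12)
  s1 <- simulate_replicates(pop, regimen = list(dose_times_h = 0),
                            design = list(grid_h = g), n_reps = 10, seed = 9)
  s2 <- simulate_replicates(pop, regimen = list(dose_times_h = c(0, 168)),
                            design = list(grid_h = g), n_reps = 10, seed = 9)
  pre <- g < 168
  expect_equal(s2$plasma[, pre], s1$plasma[, pre], tolerance = 1e-15)
})

test_that("milk concentration reconstruction inverts the generator and conserves mass", {
  p <- params3()
  mt <- seq(12, 480, by = 12)
  vols <- rep(2400, length(mt))
  am <- milk_cumulative_closed(p, single_dose_88kg(), mt)
  rec <- milk_conc_from_amounts(mt, am, mt, vols)
  # telescoping: total reconstructed mass equals the final cumulative amount
  expect_equal(sum(rec$conc * vols), am[length(am)], tolerance = 1e-12)
  # constant excretion rate gives a constant concentration
  rate <- 5e3
  cum_lin <- rate * mt
  rec_lin <- milk_conc_from_amounts(mt, cum_lin, mt, vols)
  expect_equal(rec_lin$conc, rep(rate * 12 / 2400, length(mt)), tolerance = 1e-12)
  # round trip against the per-milking concentrations of a noiseless subject
  des <- study_design("singledose_lactating", n_subjects = 1)
  popz <- table3_population(); popz$omega[] <- 0
  ds <- generate_study(des, pop = popz, seed = 6, residual = FALSE)
  s <- ds$subjects[[1]]
  o <- s$observations[s$observations$kind == "milk_conc", ]
  cum <- milk_cumulative_closed(params3(), s$doses, o$time)
  rec2 <- milk_conc_from_amounts(o$time, cum, o$time, o$milk_volume)
  expect_equal(rec2$conc, o$value, tolerance = 1e-9)
  expect_error(milk_conc_from_amounts(mt, am, mt, rep(0, length(mt))), "positive")
})

test_that("withdrawal days respond monotonically to tolerance and dose", {
  pop <- table3_population()
  sim <- simulate_replicates(pop, regimen = list(dose_times_h = 0), n_reps = 50,
                             seed = 11)
  w <- lapply(c(0.5, 1.2, 5, 50), function(tol) {
    withdrawal_time(sim, "plasma", tolerance = tol)
  })
  days <- vapply(w, `[[`, 0, "days")
  expect_true(all(diff(days) <= 0))
  # a tolerance above the whole band gives day 0
  big <- withdrawal_time(sim, "plasma", tolerance = 1e6)
  expect_equal(big$days, 0)
  # doubling the dose cannot shorten the withdrawal
  sim2 <- simulate_replicates(pop, regimen = list(dose_times_h = 0,
                                                  dose_mg_per_kg = 5),
                              n_reps = 50, seed = 11)
  expect_gte(withdrawal_time(sim2, "plasma", 1.2)$days,
             withdrawal_time(sim, "plasma", 1.2)$days)
  # the 95th percentile band dominates the median everywhere
  bands <- sim_bands(sim)
  expect_true(all(bands$p95 >= bands$p50))
})

test_that("an unreachable tolerance yields an undefined, flagged estimate", {
  pop <- table3_population()
  sim <- simulate_replicates(pop, regimen = list(dose_times_h = 0), n_reps = 10,
                             seed = 3, design = list(grid_h = seq(0, 240, 12)))
  w <- withdrawal_time(sim, "plasma", tolerance = 1e-6)
  expect_false(w$defined)
  expect_true(is.na(w$days))
  # milk estimates carry the non-definitive flag
  wm <- withdrawal_time(sim, "milk", tolerance = 1e6)
  expect_false(wm$definitive)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  pop <- table3_population()
  s1 <- simulate_replicates(pop, regimen = list(dose_times_h = c(0, 168)),
                            n_reps = 20, seed = 123)
  s2 <- simulate_replicates(pop, regimen = list(dose_times_h = c(0, 168)),
                            n_reps = 20, seed = 123)
  expect_identical(s1$plasma, s2$plasma)
  expect_identical(s1$milk_conc, s2$milk_conc)
})
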