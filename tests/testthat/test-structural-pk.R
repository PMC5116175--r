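test_that("micro constants reproduce the clearance/volume algebra", {
  m <- micro_constants(params3())
  # frozen arithmetic on the published fixed effects
  expect_equal(m$k10, (21109.2 + 882.461) / 326627, tolerance = 1e-12)
  expect_equal(m$k10, 0.06733, tolerance = 1e-4)
  expect_equal(m$k21, 12550.5 / 676758, tolerance = 1e-12)
  expect_equal(m$k21, 0.018545, tolerance = 1e-4)
  # symmetric-function identities
  expect_equal(m$alpha + m$beta, m$k10 + m$k12 + m$k21, tolerance = 1e-12)
  expect_equal(m$alpha * m$beta, m$k10 * m$k21, tolerance = 1e-12)
  expect_true(m$alpha >= m$beta && m$beta > 0)
})

test_that("micro constants decouple when inter-compartmental clearance is zero", {
  p <- pk_params(V = 1e5, Cl = 5e3, V2 = 2e5, Cl2 = 0, CLmilk = 100, Ka = 0.4)
  m <- micro_constants(p)
  expect_equal(m$k12, 0)
  expect_equal(m$beta, min(m$k10, m$k21))
  expect_equal(m$alpha, max(m$k10, m$k21))
  set.seed(11)
  for (i in 1:20) {
    m <- micro_constants(random_params())
    expect_equal(m$alpha * m$beta - m$k10 * m$k21, 0, tolerance = 1e-12 * m$k10 * m$k21)
  }
})

test_that("closed-form plasma concentration handles no-dose and dose-time limits", {
  p <- params3()
  expect_equal(plasma_conc_closed(p, data.frame(time = numeric(), amount = numeric()),
                                  c(0, 10, 100)), c(0, 0, 0))
  # at tau = 0 the dose contributes nothing (A + B + G = 0)
  expect_equal(plasma_conc_closed(p, single_dose_88kg(), 0), 0, tolerance = 1e-12)
  expect_equal(plasma_conc_closed(p, two_dose_88kg(), 168),
               plasma_conc_closed(p, single_dose_88kg(), 168), tolerance = 1e-12)
  expect_error(plasma_conc_closed(p, single_dose_88kg(), -1), "negative")
})

test_that("closed form agrees with the ODE oracle on the published parameters", {
  p <- params3()
  ode <- solve_ode(p, single_dose_88kg(), c(0, 360))
  cc <- plasma_conc_closed(p, single_dose_88kg(), 360)
  expect_equal(cc, ode$C_plasma[2], tolerance = 1e-8)
})

test_that("closed forms agree with the ODE oracle across random parameter sets", {
  set.seed(42)
  grid <- sort(c(seq(0.25, 36, length.out = 10),
                 seq(75, 1536, length.out = 40)))
  doses <- two_dose_88kg()
  for (i in 1:10) {
    p <- random_params()
    ode <- solve_ode(p, doses, grid)
    cp <- plasma_conc_closed(p, doses, grid)
    am <- milk_cumulative_closed(p, doses, grid)
    keep <- ode$C_plasma >= pmax(1e-6 * max(ode$C_plasma), 1e-4 / p$V)
    expect_lt(max(abs(cp - ode$C_plasma)[keep] / ode$C_plasma[keep]), 1e-6)
    keepm <- ode$Amilk >= 1e-6 * max(ode$Amilk)
    expect_lt(max(abs(am - ode$Amilk)[keepm] / ode$Amilk[keepm]), 1e-6)
  }
})

test_that("dose mass is conserved across depot, compartments, milk and elimination", {
  p <- params3()
  grid <- seq(0, 1000, length.out = 40)
  ode <- solve_ode(p, two_dose_88kg(), grid)
  total_in <- 2.2e8 * (1 + (grid >= 168))
  balance <- ode$Aa + ode$A1 + ode$A2 + ode$Amilk + ode$Ael
  expect_lt(max(abs(balance - total_in) / total_in), 1e-6)
})

test_that("instantaneous absorption approaches the IV bolus limit", {
  p <- pk_params(V = 3e5, Cl = 2e4, V2 = 6e5, Cl2 = 1.2e4, CLmilk = 800, Ka = 1e4)
  ode <- solve_ode(p, single_dose_88kg(), c(0, 0.01))
  expect_equal(ode$A1[2] + ode$A2[2] + ode$Amilk[2] + ode$Ael[2], 2.2e8,
               tolerance = 1e-2)
  expect_lt(ode$Aa[2] / 2.2e8, 1e-6)
})

test_that("two-dose response is the superposition of shifted single doses", {
  p <- params3()
  t <- seq(0, 600, by = 24)
  both <- plasma_conc_closed(p, two_dose_88kg(), t)
  first <- plasma_conc_closed(p, single_dose_88kg(), t)
  second <- c(rep(0, sum(t < 168)),
              plasma_conc_closed(p, single_dose_88kg(), t[t >= 168] - 168))
  expect_equal(both, first + second, tolerance = 1e-12)
  # causality: before the second dose the trajectories are identical
  expect_equal(both[t < 168], first[t < 168], tolerance = 1e-15)
})

test_that("milk excretion accumulates to the clearance-ratio fraction of the dose", {
  p <- params3()
  expect_equal(milk_cumulative_closed(pk_params(V = 3e5, Cl = 2e4, V2 = 6e5,
                                                Cl2 = 1e4, CLmilk = 0, Ka = 0.3),
                                      single_dose_88kg(), c(10, 500)), c(0, 0))
  limit <- 2.2e8 * 882.461 / (21109.2 + 882.461)
  expect_equal(milk_cumulative_closed(p, single_dose_88kg(), 1e6), limit,
               tolerance = 1e-6)
  expect_equal(limit, 8.828e6, tolerance = 1e-4)
  am <- milk_cumulative_closed(p, single_dose_88kg(), seq(12, 2000, by = 12))
  expect_true(all(diff(am) > 0))
  expect_true(all(am < limit))
})

test_that("terminal half-life follows the slowest exponential, flip-flop aware", {
  expect_equal(terminal_halflife(params3()), log(2) / 0.01102286, tolerance = 1e-4)
  expect_equal(terminal_halflife(params3()), 62.9, tolerance = 1e-3)
  # absorption-limited (flip-flop) terminal phase
  p_ff <- pk_params(V = 326627, Cl = 21109.2, V2 = 676758, Cl2 = 12550.5,
                    CLmilk = 882.461, Ka = 0.001)
  expect_equal(terminal_halflife(p_ff), log(2) / 0.001, tolerance = 1e-9)
  # one-compartment limit: ln2 * V / Cl
  p1 <- pk_params(V = 1e5, Cl = 2e3, V2 = 1, Cl2 = 0, CLmilk = 0, Ka = 50)
  expect_equal(terminal_halflife(p1), log(2) * 1e5 / 2e3, tolerance = 1e-12)
})

test_that("absorption coincident with a disposition exponent is handled", {
  p <- params3()
  m <- micro_constants(p)
  p_coin <- pk_params(V = p$V, Cl = p$Cl, V2 = p$V2, Cl2 = p$Cl2,
                      CLmilk = p$CLmilk, Ka = m$beta)
  cc <- plasma_conc_closed(p_coin, single_dose_88kg(), c(24, 240))
  ode <- solve_ode(p_coin, single_dose_88kg(), c(0, 24, 240))
  expect_equal(cc, ode$C_plasma[2:3], tolerance = 1e-6)
})

test_that("three-compartment variant matches its ODE solution", {
  p <- pk_params(V = 3e5, Cl = 2e4, V2 = 6e5, Cl2 = 1.2e4, CLmilk = 800,
                 Ka = 0.3, V3 = 1e5, Cl3 = 2e3)
  grid <- seq(0, 720, length.out = 30)
  ode <- solve_ode(p, single_dose_88kg(), grid)
  cp <- plasma_conc_closed(p, single_dose_88kg(), grid)
  keep <- ode$C_plasma >= 1e-6 * max(ode$C_plasma)
  expect_lt(max(abs(cp - ode$C_plasma)[keep] / ode$C_plasma[keep]), 1e-6)
})
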