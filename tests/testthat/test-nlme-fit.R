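pop_plasma <- function(omega = NULL, sigma = c(prop = 0.2),
                       error = "proportional") {
  population_model(theta3, omega = omega,
                   sigma = list(plasma_conc = sigma),
                   error_model = list(plasma_conc = error),
                   structure = "2cpt")
}

test_that("the conditional -2LL matches its closed form for one observation", {
  p <- params3()
  f <- plasma_conc_closed(p, single_dose_88kg(), 48)
  s <- pk_subject("a", "market", 30, single_dose_88kg(),
                  data.frame(time = 48, kind = "plasma_conc", value = f,
                             milk_volume = NA_real_, bloq = FALSE))
  # y = f exactly, proportional error, no random effects
  expect_equal(individual_neg2ll(pop_plasma(), s),
               log(2 * pi) + log(0.2^2 * f^2), tolerance = 1e-12)
  # additive error
  expect_equal(individual_neg2ll(pop_plasma(sigma = c(add = 3), error = "additive"), s),
               log(2 * pi) + log(9), tolerance = 1e-12)
  # with an active random effect the Gaussian prior terms appear
  pope <- pop_plasma(omega = c(Cl = 0.04))
  eta <- c(Cl = 0.1)
  fe <- plasma_conc_closed(do.call(pk_params, modifyList(as.list(theta3),
                                                         list(Cl = theta3[["Cl"]] * exp(0.1)))),
                           single_dose_88kg(), 48)
  expected <- log(2 * pi) + log(0.2^2 * fe^2) + (f - fe)^2 / (0.2^2 * fe^2) +
    0.1^2 / 0.04 + log(0.04) + log(2 * pi)
  expect_equal(individual_neg2ll(pope, s, eta), expected, tolerance = 1e-10)
})

test_that("scaling observations shifts the proportional -2LL by a constant", {
  set.seed(21)
  s <- toy_plasma_subject(noise_sd = 0.15)
  pope <- pop_plasma(omega = c(Cl = 0.04))
  etas <- list(c(Cl = -0.2), c(Cl = 0), c(Cl = 0.15))
  base <- vapply(etas, function(e) individual_neg2ll(pope, s, e), 0)
  # scale observations and doses together: the system is linear, so every
  # prediction scales by the same constant and the proportional -2LL
  # shifts by 2 * n * log(k), identically for every eta
  kscale <- 10
  s2 <- s
  s2$observations$value <- s2$observations$value * kscale
  s2$doses$amount <- s2$doses$amount * kscale
  scaled <- vapply(etas, function(e) individual_neg2ll(pope, s2, e), 0)
  shifts <- scaled - base
  expect_equal(diff(shifts), c(0, 0), tolerance = 1e-9)
  expect_equal(shifts[1], 2 * length(s$observations$time) * log(kscale),
               tolerance = 1e-9)
  expect_equal(order(base), order(scaled))
})

test_that("the Laplace approximation tracks numerical quadrature on toy subjects", {
  set.seed(10)
  s <- toy_plasma_subject(times = c(12, 24), noise_sd = 0.15)
  sp <- milkpk:::prepare_subject(s)
  # one random effect
  pop1 <- pop_plasma(omega = c(Cl = 0.09))
  lap <- milkpk:::inner_laplace(pop1, sp)
  integrand <- Vectorize(function(e) exp(-0.5 * individual_neg2ll(pop1, s, c(Cl = e))))
  oracle <- -2 * log(stats::integrate(integrand, -3, 3, rel.tol = 1e-10)$value)
  expect_equal(lap$neg2ll, oracle, tolerance = 0.02)
  # two random effects, nested quadrature
  pop2 <- pop_plasma(omega = c(Cl = 0.09, V = 0.16))
  lap2 <- milkpk:::inner_laplace(pop2, sp)
  inner <- function(ev) {
    f1 <- Vectorize(function(ec) {
      exp(-0.5 * individual_neg2ll(pop2, s, c(Cl = ec, V = ev)))
    })
    stats::integrate(f1, -3, 3, rel.tol = 1e-9)$value
  }
  oracle2 <- -2 * log(stats::integrate(Vectorize(inner), -4, 4, rel.tol = 1e-8)$value)
  expect_equal(lap2$neg2ll, oracle2, tolerance = 0.02)
})

test_that("the FOCE objective reduces exactly to the pooled -2LL at zero omega", {
  set.seed(12)
  subjects <- lapply(1:4, function(i) {
    toy_plasma_subject(id = paste0("s", i), noise_sd = 0.1)
  })
  ds <- study_dataset(subjects)
  popz <- pop_plasma(omega = c(Cl = 0, V = 0))
  pooled <- sum(vapply(subjects, function(s) individual_neg2ll(popz, s), 0))
  expect_identical(as.numeric(foce_objective(popz, ds)), pooled)
  # permuting subjects leaves the objective unchanged
  ds_perm <- study_dataset(subjects[c(3, 1, 4, 2)])
  pop <- pop_plasma(omega = c(Cl = 0.04))
  expect_equal(as.numeric(foce_objective(pop, ds_perm)),
               as.numeric(foce_objective(pop, ds)), tolerance = 1e-10)
})

test_that("a pooled single-subject fit matches a direct least-squares oracle", {
  set.seed(33)
  times <- c(2, 6, 12, 24, 48, 96, 144, 192, 240, 300)
  p_true <- pk_params(V = 2.5e5, Cl = 1.8e4, V2 = 1, Cl2 = 0, CLmilk = 0, Ka = 0.4)
  doses <- single_dose_88kg()
  f <- plasma_conc_closed(p_true, doses, times)
  y <- f + rnorm(length(f), 0, 1.5)
  s <- pk_subject("one", "market", 30, doses,
                  data.frame(time = times, kind = "plasma_conc", value = pmax(y, 0.1),
                             milk_volume = NA_real_, bloq = FALSE))
  init <- population_model(c(V = 1e5, Cl = 1e4, V2 = 1, Cl2 = 0, CLmilk = 0, Ka = 1),
                           omega = NULL,
                           sigma = list(plasma_conc = c(add = 5)),
                           error_model = list(plasma_conc = "additive"),
                           structure = "1cpt")
  fit <- fit_population(study_dataset(list(s)), structure = "1cpt", init = init,
                        control = list(outer_rel_tol = 1e-12, outer_iter = 1000))
  # oracle: additive-error ML is ordinary least squares in the mean params
  sse <- function(lx) {
    pp <- pk_params(V = exp(lx[1]), Cl = exp(lx[2]), V2 = 1, Cl2 = 0,
                    CLmilk = 0, Ka = exp(lx[3]))
    sum((s$observations$value - plasma_conc_closed(pp, doses, times))^2)
  }
  ls <- stats::nlminb(log(c(1e5, 1e4, 1)), sse,
                      control = list(rel.tol = 1e-14, iter.max = 1000))
  expect_equal(unname(fit$estimates$theta[c("V", "Cl", "Ka")]),
               unname(exp(ls$par)), tolerance = 1e-4)
})

test_that("information-criterion identities hold and models rank by AIC", {
  set.seed(44)
  subjects <- lapply(1:3, function(i) {
    toy_plasma_subject(id = paste0("p", i),
                       times = c(1, 3, 8, 16, 32, 64, 128, 240), noise_sd = 0.1)
  })
  ds <- study_dataset(subjects)
  init2 <- population_model(c(V = 2e5, Cl = 1.5e4, V2 = 4e5, Cl2 = 8e3,
                              CLmilk = 0, Ka = 0.5),
                            omega = c(Cl = 0.05),
                            sigma = list(plasma_conc = c(prop = 0.2)),
                            structure = "2cpt")
  init1 <- population_model(c(V = 2e5, Cl = 1.5e4, V2 = 1, Cl2 = 0,
                              CLmilk = 0, Ka = 0.5),
                            omega = c(Cl = 0.05),
                            sigma = list(plasma_conc = c(prop = 0.2)),
                            structure = "1cpt")
  ctl <- list(outer_iter = 200, outer_rel_tol = 1e-7)
  fit2 <- fit_population(ds, "2cpt", init = init2, control = ctl)
  fit1 <- fit_population(ds, "1cpt", init = init1, control = ctl)
  for (f in list(fit1, fit2)) {
    expect_equal(f$aic, f$neg2ll + 2 * f$n_params, tolerance = 1e-12)
    expect_equal(f$bic, f$neg2ll + f$n_params * log(f$n_obs), tolerance = 1e-12)
  }
  # data were generated from the 2-compartment model
  cmp <- compare_models(list(fit1, fit2))
  expect_equal(cmp$structure[cmp$selected], "2cpt")
  expect_lt(fit2$aic, fit1$aic)
  # a single fit is returned as selected trivially
  cmp1 <- compare_models(list(fit2))
  expect_true(cmp1$selected)
  # mismatched datasets are rejected
  ds_other <- study_dataset(subjects[1:2])
  fit_other <- fit_population(ds_other, "1cpt", init = init1, control = ctl)
  expect_error(compare_models(list(fit2, fit_other)), "same dataset")
})

test_that("proportional noise is preferred by AIC over an additive fit", {
  set.seed(55)
  subjects <- lapply(1:4, function(i) {
    toy_plasma_subject(id = paste0("q", i),
                       times = c(2, 6, 12, 24, 48, 96, 168, 240), noise_sd = 0.25)
  })
  ds <- study_dataset(subjects)
  base <- c(V = 2e5, Cl = 1.5e4, V2 = 4e5, Cl2 = 8e3, CLmilk = 0, Ka = 0.5)
  ctl <- list(outer_iter = 200, outer_rel_tol = 1e-7)
  fit_prop <- fit_population(ds, "2cpt", control = ctl,
    init = population_model(base, omega = c(Cl = 0.05),
                            sigma = list(plasma_conc = c(prop = 0.2))))
  fit_add <- fit_population(ds, "2cpt", control = ctl,
    init = population_model(base, omega = c(Cl = 0.05),
                            sigma = list(plasma_conc = c(add = 20)),
                            error_model = list(plasma_conc = "additive")))
  expect_lt(fit_prop$aic, fit_add$aic)
})
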