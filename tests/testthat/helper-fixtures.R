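# Shared fixtures built in code.

# published final-model fixed effects (also available via table3_population)
theta3 <- c(V = 326627, Cl = 21109.2, V2 = 676758, Cl2 = 12550.5,
            CLmilk = 882.461, Ka = 0.295)

params3 <- function() do.call(pk_params, as.list(theta3))

single_dose_88kg <- function() data.frame(time = 0, amount = 2.5 * 88 * 1e6)
two_dose_88kg <- function() data.frame(time = c(0, 168), amount = 2.5 * 88 * 1e6)

# random strictly positive parameter sets spanning realistic ruminant ranges
random_params <- function() {
  pk_params(V = exp(runif(1, 8, 13)), Cl = exp(runif(1, 6, 11)),
            V2 = exp(runif(1, 8, 13)), Cl2 = exp(runif(1, 5, 10)),
            CLmilk = exp(runif(1, 3, 8)), Ka = exp(runif(1, -3, 1)))
}

# plasma-only toy subject sampled from the closed-form curve
toy_plasma_subject <- function(id = "s1", times = c(12, 24, 48, 96, 168),
                               params = params3(), doses = single_dose_88kg(),
                               noise_sd = 0, study = "market",
                               body_weight = 30) {
  f <- plasma_conc_closed(params, doses, times)
  y <- f * (1 + if (noise_sd > 0) rnorm(length(f), 0, noise_sd) else 0)
  pk_subject(id, study, body_weight, doses,
             data.frame(time = times, kind = "plasma_conc", value = y,
                        milk_volume = NA_real_, bloq = FALSE))
}
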