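# Monte Carlo population simulation and withdrawal-time estimation.

#' Draw individual parameter sets from the population model
#'
#' Exponential IIV: `P_i = theta * exp(eta_i)` with independent
#' `eta_i ~ N(0, omega)` per parameter (log-normal individual parameters,
#' median equal to `theta`).
#'
#' @param pop A [population_model()].
#' @param n Number of individuals.
#' @param seed Optional integer seed (draws are deterministic given it).
#' @return List of [pk_params()] objects; the matrix of etas is attached
#'   as attribute `"eta"`.
#' @export
draw_individuals <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nm <- names(pop$theta)
  sdv <- sqrt(ifelse(nm %in% names(pop$omega), pop$omega[nm], 0))
  eta <- matrix(stats::rnorm(n * length(nm)), n, length(nm),
                dimnames = list(NULL, nm))
  eta <- sweep(eta, 2, sdv, "*")
  out <- lapply(seq_len(n), function(i) {
    p <- as.list(pop$theta * exp(eta[i, ]))
    do.call(pk_params, p)
  })
  attr(out, "eta") <- eta
  out
}

#' Simulate replicate plasma and milk profiles under a dosing regimen
#'
#' One individual parameter set is drawn per replicate; plasma
#' concentration and cumulative milk amount come from the closed-form
#' structural model, and milk concentrations are reconstructed by dividing
#' per-interval excreted amounts by the milk volume produced in each
#' interval. The percentile band reflects inter-individual variability
#' only unless `residual = TRUE`, which adds the proportional residual
#' layer (applied to plasma concentrations and per-interval milk amounts,
#' preserving non-negativity and cumulative monotonicity).
#'
#' @param pop A [population_model()].
#' @param regimen List: `dose_times_h` (default 0), `dose_mg_per_kg`
#'   (2.5), `body_weight_kg` (88).
#' @param design List: `grid_h` (default 12-h grid to 120 days after the
#'   last dose), `milking_interval_h` (12), `daily_milk_yield_lbs` (10.8,
#'   split evenly across milkings), `density` (1.03 g/mL).
#' @param n_reps Number of replicates (>= 2).
#' @param seed Optional integer seed.
#' @param residual Add the residual-error layer.
#' @return A `pk_simulation`: time grid, replicate x time matrices
#'   (`plasma`, `milk_amount`, `milk_conc`), milking times and volumes,
#'   regimen, seed.
#' @export
simulate_replicates <- function(pop, regimen = list(), design = list(),
                                n_reps = 100, seed = NULL, residual = FALSE) {
  stopifnot(inherits(pop, "population_model"), n_reps >= 2)
  regimen <- utils::modifyList(list(dose_times_h = 0, dose_mg_per_kg = 2.5,
                                    body_weight_kg = 88), regimen)
  last_dose <- max(regimen$dose_times_h)
  design <- utils::modifyList(list(
    grid_h = seq(0, last_dose + 2880, by = 12),
    milking_interval_h = 12, daily_milk_yield_lbs = 10.8, density = 1.03),
    design)
  grid <- design$grid_h
  if (max(grid) < last_dose) stop("time grid shorter than the dosing regimen")
  if (!is.null(seed)) set.seed(seed)
  doses <- data.frame(time = regimen$dose_times_h,
                      amount = regimen$dose_mg_per_kg *
                        regimen$body_weight_kg * 1e6)
  inds <- draw_individuals(pop, n_reps, seed = NULL)
  milk_times <- seq(design$milking_interval_h, max(grid),
                    by = design$milking_interval_h)
  vol <- volume_from_weight(
    design$daily_milk_yield_lbs * design$milking_interval_h / 24, "lbs",
    density = design$density)
  volumes <- rep(vol, length(milk_times))
  plasma <- matrix(0, n_reps, length(grid))
  milk_amount <- matrix(0, n_reps, length(milk_times))
  milk_conc <- matrix(0, n_reps, length(milk_times))
  for (i in seq_len(n_reps)) {
    p <- inds[[i]]
    cp <- plasma_conc_closed(p, doses, grid)
    am <- milk_cumulative_closed(p, doses, milk_times)
    damt <- diff(c(0, am))
    if (residual) {
      sp <- pop$sigma$plasma_conc[["prop"]]
      sm <- pop$sigma$milk_cumamount[["prop"]]
      cp <- pmax(cp * (1 + stats::rnorm(length(cp), 0, sp)), 0)
      damt <- pmax(damt * (1 + stats::rnorm(length(damt), 0, sm)), 0)
      am <- cumsum(damt)
    }
    plasma[i, ] <- cp
    milk_amount[i, ] <- am
    milk_conc[i, ] <- damt / volumes
  }
  structure(list(grid = grid, plasma = plasma,
                 milk_times = milk_times, milk_amount = milk_amount,
                 milk_conc = milk_conc, volumes = volumes,
                 regimen = regimen, design = design, pop = pop,
                 n_reps = n_reps, seed = seed, residual = residual),
            class = "pk_simulation")
}

#' @export
print.pk_simulation <- function(x, ...) {
  cat("pk_simulation:", x$n_reps, "replicates, doses at",
      paste(x$regimen$dose_times_h, collapse = ", "), "h,",
      "grid to", max(x$grid), "h\n")
  invisible(x)
}

#' Reconstruct milk concentrations from a cumulative amount series
#'
#' Concentration at milking `k` is `(A(t_k) - A(t_(k-1))) / V_k`, the
#' amount excreted over the interval divided by the milk volume produced
#' in it; the first interval starts at `start_time` (the most recent dose
#' or 0). Mass is conserved exactly:
#' `sum(conc_k * V_k) = A(t_last) - A(start_time)`.
#'
#' @param amount_times,amounts The cumulative excreted-amount series (ng).
#' @param milking_times Milking times (h), within the series range; values
#'   not present in `amount_times` are linearly interpolated.
#' @param volumes Per-milking volumes (mL), `> 0`.
#' @param start_time Start of the first interval.
#' @return `data.frame` with columns `time` and `conc` (ng/mL).
#' @export
milk_conc_from_amounts <- function(amount_times, amounts, milking_times,
                                   volumes, start_time = 0) {
  stopifnot(length(amount_times) == length(amounts),
            length(milking_times) == length(volumes))
  if (any(volumes <= 0)) stop("milk volumes must be positive")
  if (min(milking_times) < min(c(amount_times, start_time)) ||
      max(milking_times) > max(amount_times)) {
    stop("milking times outside the amount series range")
  }
  at <- c(start_time, amount_times)
  av <- c(if (start_time %in% amount_times)
    amounts[match(start_time, amount_times)] else 0, amounts)
  o <- order(at)
  A <- stats::approx(at[o], av[o], xout = c(start_time, milking_times),
                     ties = "ordered")$y
  data.frame(time = milking_times, conc = diff(A) / volumes)
}

#' Withdrawal time from a simulated percentile band
#'
#' The smallest whole day `d` after the last dose such that the chosen
#' percentile of the simulated values stays below `tolerance` at every
#' grid time from day `d` on. Milk estimates are flagged non-definitive:
#' reconstructed milk concentrations fluctuate at the terminal phase
#' because the excreted amount is divided by finite milking volumes.
#'
#' @param sim A `pk_simulation`.
#' @param matrix `"plasma"` or `"milk"` (reconstructed milk
#'   concentrations).
#' @param tolerance Concentration limit (ng/mL), typically the assay LOD.
#' @param percentile Band percentile (default 95; 97.5 available).
#' @return A `pk_withdrawal`: `days` (integer days after the last dose,
#'   `NA` when the band never settles below tolerance inside the grid),
#'   `defined`, `definitive`, plus the settings.
#' @export
withdrawal_time <- function(sim, matrix = c("plasma", "milk"), tolerance,
                            percentile = 95) {
  stopifnot(inherits(sim, "pk_simulation"), tolerance > 0,
            percentile > 0, percentile < 100)
  matrix <- match.arg(matrix)
  if (matrix == "plasma") {
    times <- sim$grid; vals <- sim$plasma
  } else {
    times <- sim$milk_times; vals <- sim$milk_conc
  }
  band <- apply(vals, 2, stats::quantile, probs = percentile / 100)
  last_dose <- max(sim$regimen$dose_times_h)
  above <- times[band >= tolerance]
  if (band[length(band)] >= tolerance) {
    days <- NA_real_; defined <- FALSE
  } else {
    defined <- TRUE
    days <- if (!length(above)) 0 else floor((max(above) - last_dose) / 24) + 1
  }
  structure(list(matrix = matrix, tolerance = tolerance,
                 percentile = percentile, days = days, defined = defined,
                 definitive = matrix == "plasma",
                 regimen = sim$regimen, n_reps = sim$n_reps),
            class = "pk_withdrawal")
}

#' @export
print.pk_withdrawal <- function(x, ...) {
  if (x$defined) {
    cat("withdrawal (", x$matrix, "): ", x$days,
        " days after the last dose (", x$percentile, "th percentile < ",
        x$tolerance, " ng/mL)\n", sep = "")
  } else {
    cat("withdrawal (", x$matrix, "): band never settles below ",
        x$tolerance, " ng/mL within the simulated grid\n", sep = "")
  }
  if (!x$definitive) {
    cat("  note: milk concentrations fluctuate at the terminal phase;",
        "estimate is not definitive\n")
  }
  invisible(x)
}

#' Percentile band summary of a simulation
#'
#' @param sim A `pk_simulation`.
#' @param percentiles Percentiles to tabulate.
#' @return `data.frame` with columns `matrix`, `time_h` and one column per
#'   percentile (`p50`, `p95`, ...).
#' @export
sim_bands <- function(sim, percentiles = c(50, 95)) {
  stopifnot(inherits(sim, "pk_simulation"))
  one <- function(times, vals, label) {
    out <- data.frame(matrix = label, time_h = times)
    for (p in percentiles) {
      out[[paste0("p", p)]] <- apply(vals, 2, stats::quantile, probs = p / 100)
    }
    out
  }
  rbind(one(sim$grid, sim$plasma, "plasma"),
        one(sim$milk_times, sim$milk_amount, "milk_amount"),
        one(sim$milk_times, sim$milk_conc, "milk_conc"))
}
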