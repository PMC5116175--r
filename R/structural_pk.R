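# Structural model: mammillary disposition (1-3 compartments) with
# first-order absorption from a subcutaneous depot and a cumulative
# milk-excretion compartment fed by CLmilk * C.
#
#   dAa/dt    = -Ka * Aa
#   dA1/dt    =  Ka * Aa - Cl*C - Cl2*(C - C2) - CLmilk*C
#   dA2/dt    =  Cl2 * (C - C2)
#   dAmilk/dt =  CLmilk * C,   C = A1/V, C2 = A2/V2
#
# The system is linear, so multi-dose responses are superpositions of
# time-shifted single-dose responses, each a sum of exponentials.

#' Structural pharmacokinetic parameters
#'
#' @param V Central volume of distribution (mL).
#' @param Cl Central (systemic) clearance (mL/h).
#' @param V2 Peripheral volume (mL); must stay positive even in the
#'   one-compartment reduction (`Cl2 = 0`).
#' @param Cl2 Inter-compartmental clearance (mL/h); `0` gives the
#'   one-compartment reduction.
#' @param CLmilk Clearance from the central compartment into milk (mL/h).
#' @param Ka First-order absorption rate constant (1/h).
#' @param V3,Cl3 Optional second peripheral pair for the three-compartment
#'   variant.
#' @return A `pk_params` object (named numeric list).
#' @export
pk_params <- function(V, Cl, V2 = 1, Cl2 = 0, CLmilk = 0, Ka,
                      V3 = NULL, Cl3 = NULL) {
  p <- list(V = V, Cl = Cl, V2 = V2, Cl2 = Cl2, CLmilk = CLmilk, Ka = Ka)
  if (!is.null(Cl3) || !is.null(V3)) {
    if (is.null(Cl3) || is.null(V3)) stop("V3 and Cl3 must be supplied together")
    p$V3 <- V3; p$Cl3 <- Cl3
  }
  stopifnot(V > 0, V2 > 0, Cl > 0, Ka > 0, Cl2 >= 0, CLmilk >= 0)
  if (!is.null(p$V3)) stopifnot(p$V3 > 0, p$Cl3 >= 0)
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("pk_params:", paste(names(x), signif(unlist(x), 6), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Micro rate constants and hybrid exponents of the two-compartment model
#'
#' `k10 = (Cl + CLmilk)/V` (milk excretion is a parallel elimination path),
#' `k12 = Cl2/V`, `k21 = Cl2/V2`. `alpha >= beta > 0` satisfy
#' `alpha + beta = k10 + k12 + k21` and `alpha * beta = k10 * k21`.
#'
#' @param params A [pk_params()] object.
#' @return Named list `k10`, `k12`, `k21`, `alpha`, `beta`.
#' @export
micro_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$V <= 0 || params$V2 <= 0) stop("V and V2 must be positive")
  k10 <- (params$Cl + params$CLmilk) / params$V
  k12 <- params$Cl2 / params$V
  k21 <- params$Cl2 / params$V2
  s <- k10 + k12 + k21
  pr <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * pr, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

# Disposition exponents lambda_i and unit-bolus plasma coefficients c_i
# (1/mL), so that after an IV bolus D into the central compartment
# C(t) = D * sum_i c_i exp(-lambda_i t). Handles 1, 2 or 3 compartments.
disposition_terms <- function(params) {
  V <- params$V
  periph <- list()
  if (params$Cl2 > 0) periph <- c(periph, list(c(k1j = params$Cl2 / V,
                                                 kj1 = params$Cl2 / params$V2)))
  if (!is.null(params$Cl3) && params$Cl3 > 0) {
    periph <- c(periph, list(c(k1j = params$Cl3 / V, kj1 = params$Cl3 / params$V3)))
  }
  k10 <- (params$Cl + params$CLmilk) / V
  np <- length(periph)
  if (np == 0) return(list(lambda = k10, coef = 1 / V))
  if (np == 1) {
    # quadratic closed form (avoids eigen in the estimation hot path)
    k12 <- periph[[1]][["k1j"]]; k21 <- periph[[1]][["kj1"]]
    s <- k10 + k12 + k21
    disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
    alpha <- (s + disc) / 2; beta <- (s - disc) / 2
    return(list(lambda = c(alpha, beta),
                coef = c((alpha - k21) / (V * (alpha - beta)),
                         (k21 - beta) / (V * (alpha - beta)))))
  }
  # compartment matrix for amounts (column = source compartment)
  n <- np + 1
  K <- matrix(0, n, n)
  K[1, 1] <- -(k10 + sum(vapply(periph, `[[`, 0, "k1j")))
  for (j in seq_len(np)) {
    K[1, j + 1] <- periph[[j]][["kj1"]]
    K[j + 1, 1] <- periph[[j]][["k1j"]]
    K[j + 1, j + 1] <- -periph[[j]][["kj1"]]
  }
  lambda <- sort(-Re(eigen(K, only.values = TRUE)$values), decreasing = TRUE)
  kj1 <- vapply(periph, `[[`, 0, "kj1")
  coef <- vapply(seq_len(n), function(i) {
    num <- prod(kj1 - lambda[i])
    den <- prod(lambda[-i] - lambda[i])
    num / den / V
  }, 0)
  list(lambda = lambda, coef = coef)
}

# Guard: absorption rate coincident with a disposition exponent has a
# confluent (t * exp) solution on a measure-zero set; perturb Ka instead.
resolve_ka <- function(params, terms) {
  Ka <- params$Ka
  while (any(abs(Ka - terms$lambda) < 1e-9 * Ka)) Ka <- Ka * (1 + 1e-8)
  Ka
}

as_dose_df <- function(doses) {
  doses <- as.data.frame(doses)
  stopifnot(all(c("time", "amount") %in% names(doses)))
  doses[order(doses$time), , drop = FALSE]
}

#' Closed-form plasma concentration under multiple extravascular doses
#'
#' Single-dose response is `(D*Ka/V) * [A e^(-alpha tau) + B e^(-beta tau)
#' + G e^(-Ka tau)]` with the standard first-order-absorption coefficients;
#' responses superpose across doses (linear system). Generalises to 1 and 3
#' compartments through the disposition exponents.
#'
#' @param params [pk_params()].
#' @param doses `data.frame` with columns `time` (h) and `amount` (ng).
#' @param t Vector of non-negative times (h).
#' @return Plasma concentration (ng/mL) at each `t`.
#' @export
plasma_conc_closed <- function(params, doses, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) stop("negative time in t")
  doses <- as_dose_df(doses)
  out <- numeric(length(t))
  if (!nrow(doses)) return(out)
  terms <- disposition_terms(params)
  Ka <- resolve_ka(params, terms)
  for (d in seq_len(nrow(doses))) {
    tau <- t - doses$time[d]
    pos <- tau >= 0
    if (!any(pos)) next
    tp <- tau[pos]
    acc <- numeric(length(tp))
    for (i in seq_along(terms$lambda)) {
      acc <- acc + terms$coef[i] *
        (exp(-terms$lambda[i] * tp) - exp(-Ka * tp)) / (Ka - terms$lambda[i])
    }
    out[pos] <- out[pos] + doses$amount[d] * Ka * acc
  }
  out
}

#' Closed-form cumulative amount excreted into milk
#'
#' Termwise integral of `CLmilk * C(t)`; the limit as `t -> Inf` is
#' `Dose_total * CLmilk / (Cl + CLmilk)` — the fraction of dose excreted in
#' milk equals the clearance ratio.
#'
#' @inheritParams plasma_conc_closed
#' @return Cumulative excreted amount (ng) at each `t`.
#' @export
milk_cumulative_closed <- function(params, doses, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) stop("negative time in t")
  doses <- as_dose_df(doses)
  out <- numeric(length(t))
  if (!nrow(doses) || params$CLmilk == 0) return(out)
  terms <- disposition_terms(params)
  Ka <- resolve_ka(params, terms)
  for (d in seq_len(nrow(doses))) {
    tau <- t - doses$time[d]
    pos <- tau >= 0
    if (!any(pos)) next
    tp <- tau[pos]
    acc <- numeric(length(tp))
    for (i in seq_along(terms$lambda)) {
      li <- terms$lambda[i]
      acc <- acc + terms$coef[i] / (Ka - li) *
        ((1 - exp(-li * tp)) / li - (1 - exp(-Ka * tp)) / Ka)
    }
    out[pos] <- out[pos] + doses$amount[d] * Ka * params$CLmilk * acc
  }
  out
}

#' Numerically integrate the structural model
#'
#' Brute-force oracle for the closed forms. Integrates the depot, central,
#' peripheral and cumulative-milk amounts plus the eliminated integral
#' `int Cl*C dt` (for mass-balance checks) with `deSolve::lsoda`; doses are
#' instantaneous additions to the depot at their event times.
#'
#' @inheritParams plasma_conc_closed
#' @param times Sorted non-negative output grid (h).
#' @param rtol,atol Solver tolerances.
#' @return `data.frame` with columns `time`, `Aa`, `A1`, `A2` (and `A3`),
#'   `Amilk`, `Ael`, `C_plasma`.
#' @export
solve_ode <- function(params, doses, times, rtol = 1e-11, atol = 1e-6) {
  stopifnot(inherits(params, "pk_params"))
  if (is.unsorted(times) || any(times < 0)) stop("times must be sorted and non-negative")
  doses <- as_dose_df(doses)
  has3 <- !is.null(params$V3)
  # integration starts at the earliest dose so pre-grid doses age correctly
  t0 <- min(times[1], if (nrow(doses)) min(doses$time) else times[1])
  y0 <- c(Aa = sum(doses$amount[doses$time == t0]), A1 = 0, A2 = 0)
  if (has3) y0 <- c(y0, A3 = 0)
  y0 <- c(y0, Amilk = 0, Ael = 0)
  later <- doses[doses$time > t0, , drop = FALSE]
  evt <- NULL
  tgrid <- sort(unique(c(t0, times, later$time)))
  if (nrow(later)) {
    evt <- list(data = data.frame(var = "Aa", time = later$time,
                                  value = later$amount, method = "add"))
  }
  deriv <- function(t, y, p) {
    C <- y[["A1"]] / p$V
    C2 <- y[["A2"]] / p$V2
    dAa <- -p$Ka * y[["Aa"]]
    dA1 <- p$Ka * y[["Aa"]] - p$Cl * C - p$Cl2 * (C - C2) - p$CLmilk * C
    dA2 <- p$Cl2 * (C - C2)
    d <- c(dAa, dA1, dA2)
    if (!is.null(p$V3)) {
      C3 <- y[["A3"]] / p$V3
      d[2] <- d[2] - p$Cl3 * (C - C3)
      d <- c(d, p$Cl3 * (C - C3))
    }
    list(c(d, p$CLmilk * C, p$Cl * C))
  }
  sol <- try(deSolve::ode(y = y0, times = tgrid, func = deriv, parms = params,
                          method = "lsoda", rtol = rtol, atol = atol,
                          events = evt, maxsteps = 50000), silent = TRUE)
  if (inherits(sol, "try-error")) stop("ODE solver failure: ", attr(sol, "condition")$message)
  sol <- as.data.frame(sol)
  sol <- sol[sol$time %in% times, , drop = FALSE]
  sol$C_plasma <- sol$A1 / params$V
  rownames(sol) <- NULL
  sol
}

#' Terminal half-life implied by the structural parameters
#'
#' `ln 2` over the slowest of the disposition exponents and `Ka` — the
#' slowest exponential governs the terminal slope, so flip-flop kinetics
#' (absorption slower than elimination) are handled.
#'
#' @param params [pk_params()].
#' @return Half-life in hours.
#' @export
terminal_halflife <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  terms <- disposition_terms(params)
  log(2) / min(c(terms$lambda, params$Ka))
}

#' Export a closed-form trajectory to CSV
#'
#' @inheritParams solve_ode
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(params, doses, times, path) {
  sol <- solve_ode(params, doses, times)
  keep <- intersect(c("time", "C_plasma", "Aa", "A1", "A2", "A3", "Amilk"),
                    names(sol))
  out <- sol[, keep]
  names(out)[1] <- "time_h"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
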