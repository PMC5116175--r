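# Packaged fixtures: published average concentration-time curves and
# population parameter estimates for tulathromycin in lactating goats
# (two SC injections of 2.5 mg/kg, 7 days apart).

#' Average plasma and milk concentration-time curves (wide form)
#'
#' Transcription of the published average curves: plasma tulathromycin
#' (ng/mL, sampled 180-348 h, i.e. the first week after the second
#' injection) and milk marker-residue concentration (ng/mL, sampled
#' 12-1524 h). `NA` marks times with no sample.
#'
#' @return `data.frame` with columns `time_h`, `plasma`, `plasma_sd`,
#'   `milk`, `milk_sd`.
#' @export
table2_profiles <- function() {
  utils::read.csv(system.file("extdata", "table2_averages.csv",
                              package = "milkpk"))
}

#' Average-curve pseudo-subject dataset
#'
#' Wraps the average curves of [table2_profiles()] as a single
#' `twodose_lactating` pseudo-subject (88 kg, 2.5 mg/kg SC at 0 h and
#' 168 h). Per-milking volumes are a synthetic stand-in reconstructed from
#' the mean daily milk yield of 10.8 lbs/day spread over each sampling
#' interval (the study does not publish per-milking volumes), so milk
#' amounts derived from this dataset are approximate by construction;
#' concentrations are transcribed exactly.
#'
#' @param daily_milk_yield Mean daily milk yield (lbs/day) used to
#'   reconstruct per-milking volumes.
#' @return A `pk_study_dataset` with one subject `avg`.
#' @export
table2_dataset <- function(daily_milk_yield = 10.8) {
  tab <- table2_profiles()
  bw <- 88
  doses <- data.frame(time = c(0, 168), amount = 2.5 * bw * 1e6)
  assay <- default_assay_limits()
  pl <- tab[!is.na(tab$plasma), c("time_h", "plasma")]
  mk <- tab[!is.na(tab$milk), c("time_h", "milk")]
  interval_h <- diff(c(0, mk$time_h))
  vol <- volume_from_weight(daily_milk_yield * interval_h / 24, "lbs")
  obs <- rbind(
    data.frame(time = pl$time_h, kind = "plasma_conc", value = pl$plasma,
               milk_volume = NA_real_, bloq = pl$plasma < assay$plasma$lod),
    data.frame(time = mk$time_h, kind = "milk_conc", value = mk$milk,
               milk_volume = vol, bloq = mk$milk < assay$milk$lod))
  subj <- pk_subject("avg", "twodose_lactating", body_weight = bw,
                     doses = doses, observations = obs,
                     daily_milk_yield = daily_milk_yield)
  study_dataset(list(subj), assay = assay,
                note = "average-curve pseudo-subject (synthetic per-milking volumes)")
}

#' Published population parameter estimates
#'
#' Raw table of the final population model: fixed effects, interindividual
#' variability (IIV), bootstrap means and 95% percentile confidence
#' intervals, plus the proportional residual-error magnitudes for plasma
#' concentrations and cumulative milk amounts.
#'
#' @return `data.frame` with one row per parameter.
#' @export
table3_estimates <- function() {
  utils::read.csv(system.file("extdata", "table3_population.csv",
                              package = "milkpk"))
}

#' Published population model as a `population_model` object
#'
#' The printed IIV column does not state its scale; by default it is read
#' as the variance of the log-scale random effect of the exponential IIV
#' model (`P_i = theta * exp(eta_i)`), which is consistent with the
#' published withdrawal simulations. `iiv_scale = "sd"` reads it as the
#' standard deviation instead.
#'
#' @param iiv_scale `"variance"` (default) or `"sd"`.
#' @return A [population_model()].
#' @export
table3_population <- function(iiv_scale = c("variance", "sd")) {
  iiv_scale <- match.arg(iiv_scale)
  tab <- table3_estimates()
  row <- function(p) tab[tab$parameter == p, ]
  theta <- c(V = row("V")$population_mean, Cl = row("Cl")$population_mean,
             V2 = row("V2")$population_mean, Cl2 = row("Cl2")$population_mean,
             CLmilk = row("CLmilk")$population_mean, Ka = row("Ka")$population_mean)
  omega <- c(V = row("V")$iiv, Cl = row("Cl")$iiv, V2 = row("V2")$iiv,
             Cl2 = row("Cl2")$iiv, CLmilk = row("CLmilk")$iiv, Ka = row("Ka")$iiv)
  population_model(
    theta = theta, omega = omega,
    sigma = list(plasma_conc = c(prop = row("sigma_plasma")$population_mean),
                 milk_cumamount = c(prop = row("sigma_milk")$population_mean)),
    error_model = list(plasma_conc = "proportional",
                       milk_cumamount = "proportional"),
    structure = "2cpt", iiv_scale = iiv_scale)
}
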