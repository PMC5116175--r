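# Synthetic study generator: emulates the three source study designs so
# the whole pipeline is testable without the (unpublished) raw
# individual-animal data.

#' Sampling design of one of the three source studies
#'
#' * `twodose_lactating`: 8 lactating goats, 73-109 kg, 2.5 mg/kg SC at
#'   0 h and 168 h; milk sampled twice daily (12-h grid) through day 21,
#'   every 48 h days 22-36, every 72 h days 37-64 (12-1536 h); plasma
#'   twice daily during the first 7 days after the second injection
#'   (180-348 h).
#' * `singledose_lactating`: 8 lactating goats, 72.5-89 kg, one dose at
#'   0 h; milk twice daily days 1-14, every 48 h days 14-28, every 72 h
#'   days 28-45 (12-1080 h); plasma twice daily days 1-7.
#' * `market`: 10 market-age goats, plasma only, dense early sampling
#'   (1-10 min, 0.25-12 h, then daily to 360 h; 28 samples); body weight
#'   is not published for this study — the default of 30 kg is a
#'   modelling assumption, configurable via `market_body_weight_kg`.
#'
#' Milking times use an even 12-h clock anchored 12 h post-dose rather
#' than literal morning/evening clock times.
#'
#' @param name Design name.
#' @param n_subjects Optional override of the design's subject count.
#' @param market_body_weight_kg Assumed market-goat body weight (kg).
#' @return A `pk_design` object.
#' @export
study_design <- function(name = c("twodose_lactating", "singledose_lactating",
                                  "market"),
                         n_subjects = NULL, market_body_weight_kg = 30) {
  name <- match.arg(name)
  d <- switch(name,
    twodose_lactating = list(
      name = name, n_subjects = 8, body_weight_range = c(73, 109),
      dose_times_h = c(0, 168), dose_mg_per_kg = 2.5,
      plasma_times_h = seq(180, 348, by = 12),
      milk_times_h = c(seq(12, 504, by = 12), seq(552, 864, by = 48),
                       seq(888, 1536, by = 72)),
      milk_yield_range_lbs = c(7, 14)),
    singledose_lactating = list(
      name = name, n_subjects = 8, body_weight_range = c(72.5, 89),
      dose_times_h = 0, dose_mg_per_kg = 2.5,
      plasma_times_h = seq(12, 168, by = 12),
      milk_times_h = c(seq(12, 336, by = 12), seq(384, 672, by = 48),
                       seq(720, 1080, by = 72)),
      milk_yield_range_lbs = c(7, 14)),
    market = list(
      name = name, n_subjects = 10,
      body_weight_range = rep(market_body_weight_kg, 2),
      dose_times_h = 0, dose_mg_per_kg = 2.5,
      plasma_times_h = c(c(1, 2, 4, 6, 8, 10) / 60,
                         c(0.25, 0.5, 1, 2, 4, 8, 12), seq(24, 360, by = 24)),
      milk_times_h = numeric(0),
      milk_yield_range_lbs = c(NA_real_, NA_real_)))
  if (!is.null(n_subjects)) d$n_subjects <- n_subjects
  structure(d, class = "pk_design")
}

#' Generate a synthetic study dataset from a population model
#'
#' Per subject: body weight and daily milk yield are drawn uniformly
#' within the design's published ranges; individual parameters come from
#' [draw_individuals()]; plasma observations are the closed-form
#' concentration with proportional residual noise; milk concentrations
#' are reconstructed from per-interval excreted amounts (proportional
#' noise applied to the cumulative amounts, floored at zero per interval)
#' divided by the per-interval milk volume implied by the daily yield.
#' Below-LOD flags are set from the assay limits. Deterministic given
#' `seed`.
#'
#' @param design A [study_design()].
#' @param pop A [population_model()]; defaults to the published final
#'   model, [table3_population()].
#' @param seed Optional integer seed.
#' @param residual Apply the residual-noise layer (`TRUE` emulates the
#'   assay; `FALSE` gives noiseless model curves).
#' @param assay Assay limits used for BLOQ flagging.
#' @return A `pk_study_dataset`.
#' @export
generate_study <- function(design, pop = table3_population(), seed = NULL,
                           residual = TRUE, assay = default_assay_limits()) {
  stopifnot(inherits(design, "pk_design"), inherits(pop, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  inds <- draw_individuals(pop, n, seed = NULL)
  sp <- pop$sigma$plasma_conc[["prop"]]
  sm <- pop$sigma$milk_cumamount[["prop"]]
  prefix <- switch(design$name, twodose_lactating = "td",
                   singledose_lactating = "sd", market = "mk")
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    bw <- stats::runif(1, design$body_weight_range[1], design$body_weight_range[2])
    lactating <- length(design$milk_times_h) > 0
    yield <- if (lactating) {
      stats::runif(1, design$milk_yield_range_lbs[1], design$milk_yield_range_lbs[2])
    } else NA_real_
    doses <- data.frame(time = design$dose_times_h,
                        amount = design$dose_mg_per_kg * bw * 1e6)
    p <- inds[[i]]
    fpl <- plasma_conc_closed(p, doses, design$plasma_times_h)
    vpl <- if (residual) pmax(fpl * (1 + stats::rnorm(length(fpl), 0, sp)), 0) else fpl
    obs <- data.frame(time = design$plasma_times_h, kind = "plasma_conc",
                      value = vpl, milk_volume = NA_real_,
                      bloq = vpl < assay$plasma$lod)
    if (lactating) {
      mt <- design$milk_times_h
      interval_h <- diff(c(0, mt))
      vol <- volume_from_weight(yield * interval_h / 24, "lbs")
      cum <- milk_cumulative_closed(p, doses, mt)
      if (residual) cum <- cum * (1 + stats::rnorm(length(cum), 0, sm))
      damt <- pmax(diff(c(0, cum)), 0)
      conc <- damt / vol
      obs <- rbind(obs, data.frame(time = mt, kind = "milk_conc", value = conc,
                                   milk_volume = vol,
                                   bloq = conc < assay$milk$lod))
    }
    subjects[[i]] <- pk_subject(id = sprintf("%s%02d", prefix, i),
                                study = design$name, body_weight = bw,
                                daily_milk_yield = yield, doses = doses,
                                observations = obs)
  }
  study_dataset(subjects, assay = assay,
                note = sprintf("synthetic %s (seed %s, residual %s)",
                               design$name, format(seed), residual))
}

#' Generate the combined three-study dataset
#'
#' Convenience wrapper reproducing the pooled analysis population: the
#' two-dose lactating study, the single-dose lactating study and the
#' market-goat plasma study (26 subjects by default), generated in that
#' order from one seed.
#'
#' @inheritParams generate_study
#' @param designs List of [study_design()] objects.
#' @return A `pk_study_dataset`.
#' @export
generate_combined_study <- function(pop = table3_population(), seed = NULL,
                                    residual = TRUE,
                                    designs = list(
                                      study_design("twodose_lactating"),
                                      study_design("singledose_lactating"),
                                      study_design("market")),
                                    assay = default_assay_limits()) {
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(designs, function(d) {
    generate_study(d, pop = pop, seed = NULL, residual = residual, assay = assay)
  })
  subjects <- unlist(lapply(parts, `[[`, "subjects"), recursive = FALSE)
  study_dataset(unname(subjects), assay = assay,
                note = sprintf("synthetic combined study (seed %s)", format(seed)))
}
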