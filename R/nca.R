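# Noncompartmental analysis: terminal-phase selection, trapezoidal AUC and
# the standard summary quantities (Cmax, Tmax, lambda-z, half-life,
# AUClast, AUCinf).

#' Select the terminal log-linear phase of a profile
#'
#' Best-fit rule: among all contiguous terminal windows of at least three
#' positive concentrations that start after the observed Tmax, choose the
#' window maximising the adjusted R-squared of the log-linear regression;
#' windows whose adjusted R-squared is within `1e-4` of the best and that
#' contain more points are preferred (ties go to more points). Windows with
#' a non-negative slope are unusable.
#'
#' @param time,conc Numeric vectors (same length), the profile.
#' @param dose_time Dose time (h); points at or before it are ignored.
#' @return List with `points` (indices into the profile), `lambda_z` (1/h),
#'   `adjusted_r2`, `n_points`.
#' @export
select_terminal_phase <- function(time, conc, dose_time = 0) {
  stopifnot(length(time) == length(conc))
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  use <- which(time > dose_time)
  if (!length(use)) stop("terminal phase undeterminable: no points after dose")
  tmax_idx <- use[which.max(conc[use])]
  cand <- use[use > tmax_idx & conc[use] > 0]
  if (length(cand) < 3) stop("terminal phase undeterminable: fewer than 3 positive points after Tmax")
  best <- NULL
  for (start in seq_len(length(cand) - 2)) {
    idx <- cand[start:length(cand)]
    x <- time[idx]; ly <- log(conc[idx]); n <- length(idx)
    sxx <- sum((x - mean(x))^2)
    syy <- sum((ly - mean(ly))^2)
    sxy <- sum((x - mean(x)) * (ly - mean(ly)))
    slope <- sxy / sxx
    if (!is.finite(slope) || slope >= 0) next
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
    ar2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || ar2 > best$adjusted_r2 + 1e-4 ||
        (ar2 >= best$adjusted_r2 - 1e-4 && n > best$n_points)) {
      best <- list(points = ord[idx], lambda_z = -slope,
                   adjusted_r2 = ar2, n_points = n)
    }
  }
  if (is.null(best)) stop("terminal phase undeterminable: no window with negative slope")
  best
}

#' Trapezoidal area under the concentration-time curve to the last sample
#'
#' For extravascular profiles lacking a sample at the dose time, a zero
#' concentration is inserted at `dose_time`. `"linear"` applies the linear
#' trapezoid everywhere; `"linup_logdown"` applies the logarithmic rule
#' `dt * (c1 - c2) / log(c1/c2)` on strictly decreasing positive segments
#' (exact for mono-exponential decay) and falls back to the linear rule on
#' rising, flat or non-positive segments.
#'
#' @param time,conc The profile (sorted by time after ordering).
#' @param dose_time Dose time (h), at or before the first sample; `NULL`
#'   suppresses origin insertion.
#' @param method `"linear"` or `"linup_logdown"`.
#' @return AUC in h*ng/mL.
#' @export
auc_trapezoidal <- function(time, conc, dose_time = NULL,
                            method = c("linear", "linup_logdown")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(conc))
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  if (!is.null(dose_time)) {
    if (dose_time > time[1]) stop("dose_time must not exceed the first sample time")
    if (dose_time < time[1]) {
      time <- c(dose_time, time); conc <- c(0, conc)
    }
  }
  if (length(time) < 2) return(0)
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- dt * (c1 + c2) / 2
  if (method == "linear") return(sum(lin))
  logok <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- lin
  seg[logok] <- dt[logok] * (c1[logok] - c2[logok]) / log(c1[logok] / c2[logok])
  sum(seg)
}

#' Noncompartmental summary of a concentration-time profile
#'
#' Cmax/Tmax come from the observed points (Tmax reported relative to
#' `dose_time`); lambda-z from [select_terminal_phase()]; `auc_inf =
#' auc_last + c_last / lambda_z`. When the terminal phase is
#' undeterminable, `lambda_z`, `t_half` and `auc_inf` are `NA` and the
#' result is flagged.
#'
#' @param time,conc The profile.
#' @param dose_time Dose time (h).
#' @param method AUC method passed to [auc_trapezoidal()].
#' @return An `nca_result` (named list): `cmax_obs`, `tmax_obs`,
#'   `lambda_z`, `t_half`, `auc_last`, `auc_inf`, `n_terminal_points`,
#'   `adjusted_r2`, `lambda_z_flag`.
#' @export
nca_summary <- function(time, conc, dose_time = 0,
                        method = c("linear", "linup_logdown")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(conc), length(time) >= 1)
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  imax <- which.max(conc)
  auc_last <- auc_trapezoidal(time, conc, dose_time = dose_time, method = method)
  term <- tryCatch(select_terminal_phase(time, conc, dose_time),
                   error = function(e) e)
  failed <- inherits(term, "error")
  lambda_z <- if (failed) NA_real_ else term$lambda_z
  c_last <- conc[length(conc)]
  res <- list(
    cmax_obs = conc[imax],
    tmax_obs = time[imax] - dose_time,
    lambda_z = lambda_z,
    t_half = if (failed) NA_real_ else log(2) / lambda_z,
    auc_last = auc_last,
    auc_inf = if (failed) NA_real_ else auc_last + c_last / lambda_z,
    n_terminal_points = if (failed) NA_integer_ else term$n_points,
    adjusted_r2 = if (failed) NA_real_ else term$adjusted_r2,
    lambda_z_flag = if (failed) conditionMessage(term) else NA_character_
  )
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("nca_result:\n")
  for (f in c("cmax_obs", "tmax_obs", "lambda_z", "t_half", "auc_last", "auc_inf")) {
    cat(sprintf("  %-10s %s\n", f, format(signif(x[[f]], 6))))
  }
  if (!is.na(x$lambda_z_flag)) cat("  flag:", x$lambda_z_flag, "\n")
  invisible(x)
}

#' Per-subject NCA table for a dataset
#'
#' Runs [nca_summary()] on each subject's plasma profile (relative to the
#' last dose) and, for lactating subjects, on the first-injection milk
#' concentration window (truncated at the second dose when present), and
#' summarises mean/SD across subjects in a long table.
#'
#' @param dataset A `pk_study_dataset`.
#' @param method AUC method.
#' @return `data.frame` with columns `profile`, `parameter`, `mean`, `sd`,
#'   `n`.
#' @export
nca_table <- function(dataset, method = "linear") {
  stopifnot(inherits(dataset, "pk_study_dataset"))
  fields <- c("cmax_obs", "tmax_obs", "lambda_z", "t_half", "auc_last", "auc_inf")
  per <- list()
  for (s in dataset$subjects) {
    o <- s$observations
    pl <- o[o$kind == "plasma_conc", , drop = FALSE]
    if (nrow(pl) >= 3) {
      dtime <- max(s$doses$time[s$doses$time <= min(pl$time)], 0)
      r <- nca_summary(pl$time, pl$value, dose_time = dtime, method = method)
      per[[length(per) + 1]] <- c(profile = "plasma", unlist(r[fields]))
    }
    mk <- o[o$kind == "milk_conc", , drop = FALSE]
    if (nrow(mk) >= 3) {
      second <- if (nrow(s$doses) > 1) s$doses$time[2] else Inf
      w <- mk[mk$time <= second, , drop = FALSE]
      if (nrow(w) >= 3) {
        r <- nca_summary(w$time, w$value, dose_time = s$doses$time[1], method = method)
        per[[length(per) + 1]] <- c(profile = "milk_injection1", unlist(r[fields]))
      }
    }
  }
  if (!length(per)) stop("no profiles with enough points for NCA")
  tab <- as.data.frame(do.call(rbind, per), stringsAsFactors = FALSE)
  for (f in fields) tab[[f]] <- as.numeric(tab[[f]])
  out <- do.call(rbind, lapply(split(tab, tab$profile), function(d) {
    do.call(rbind, lapply(fields, function(f) {
      data.frame(profile = d$profile[1], parameter = f,
                 mean = mean(d[[f]], na.rm = TRUE),
                 sd = stats::sd(d[[f]], na.rm = TRUE),
                 n = sum(!is.na(d[[f]])))
    }))
  }))
  rownames(out) <- NULL
  out
}
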