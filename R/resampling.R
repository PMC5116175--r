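# Nonparametric subject bootstrap of the population fit.

#' Bootstrap percentile confidence intervals for the population fit
#'
#' Each replicate resamples subjects with replacement, stratified by study
#' label so that the per-study subject counts of the original dataset are
#' preserved exactly, then refits the model. Confidence intervals are
#' empirical 2.5/97.5 percentiles (linear interpolation) over the
#' converged replicates. Deterministic given `seed`: all resampling
#' indices are drawn up front so replicate failures do not shift the
#' random stream.
#'
#' @param data A `pk_study_dataset`.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param structure,init,fixed,bloq_policy,control Passed to
#'   [fit_population()].
#' @return A `pk_bootstrap`: `replicates` (parameter table, one row per
#'   converged replicate), `ci` (parameter, 2.5%, 97.5%), `n_requested`,
#'   `n_failed`, `seed`.
#' @export
bootstrap_ci <- function(data, n_reps = 100, seed = NULL, structure = "2cpt",
                         init = NULL, fixed = character(0),
                         bloq_policy = "exclude", control = list()) {
  stopifnot(inherits(data, "pk_study_dataset"), n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  subjects <- data$subjects
  strata <- split(seq_along(subjects), vapply(subjects, `[[`, "", "study"))
  draws <- lapply(seq_len(n_reps), function(r) {
    unlist(lapply(strata, function(idx) {
      idx[sample.int(length(idx), length(idx), replace = TRUE)]
    }), use.names = FALSE)
  })
  rows <- list()
  n_failed <- 0
  for (r in seq_len(n_reps)) {
    idx <- draws[[r]]
    boot_subjects <- lapply(seq_along(idx), function(j) {
      s <- subjects[[idx[j]]]
      s$id <- paste0(s$id, "#", j)  # resampled copies must stay distinct
      s
    })
    boot_data <- study_dataset(boot_subjects, assay = data$assay,
                               note = paste0(data$note, " [bootstrap ", r, "]"))
    fit <- tryCatch(fit_population(boot_data, structure = structure,
                                   init = init, fixed = fixed,
                                   bloq_policy = bloq_policy,
                                   control = control),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1
      next
    }
    est <- fit$estimates
    row <- c(est$theta,
             stats::setNames(est$omega, paste0("omega_", names(est$omega))))
    for (k in names(est$sigma)) {
      row <- c(row, stats::setNames(est$sigma[[k]],
                                    paste0("sigma_", k, "_",
                                           names(est$sigma[[k]]))))
    }
    rows[[length(rows) + 1]] <- c(replicate = r, row)
  }
  if (n_failed > n_reps / 2) {
    stop("more than half of the bootstrap replicates failed to converge (",
         n_failed, "/", n_reps, ")")
  }
  reps <- as.data.frame(do.call(rbind, rows))
  pars <- setdiff(names(reps), "replicate")
  ci <- do.call(rbind, lapply(pars, function(p) {
    q <- stats::quantile(reps[[p]], c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, ci_lower = q[1], ci_upper = q[2])
  }))
  structure(list(replicates = reps, ci = ci, n_requested = n_reps,
                 n_failed = n_failed, seed = seed, draws = draws,
                 subject_studies = vapply(subjects, `[[`, "", "study")),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat("pk_bootstrap:", x$n_requested, "replicates requested,",
      x$n_failed, "failed\n")
  print(x$ci, row.names = FALSE)
  invisible(x)
}

#' Write a bootstrap summary CSV
#'
#' @param boot A `pk_bootstrap`.
#' @param fit Optional `pk_fit` supplying point estimates.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_report <- function(boot, fit = NULL, path) {
  out <- boot$ci
  if (!is.null(fit)) {
    est <- fit$estimates
    point <- c(est$theta,
               stats::setNames(est$omega, paste0("omega_", names(est$omega))))
    for (k in names(est$sigma)) {
      point <- c(point, stats::setNames(est$sigma[[k]],
                                        paste0("sigma_", k, "_",
                                               names(est$sigma[[k]]))))
    }
    out$point_estimate <- unname(point[out$parameter])
    out <- out[, c("parameter", "point_estimate", "ci_lower", "ci_upper")]
  }
  out$n_converged <- boot$n_requested - boot$n_failed
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
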