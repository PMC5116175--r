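# Domain types and tabular I/O for depletion-study datasets.
#
# Internal conventions: time in hours since the first injection, amounts in
# ng, volumes in mL, so concentrations are natively ng/mL.

OBS_KINDS <- c("plasma_conc", "milk_conc", "milk_cumamount")
STUDY_LABELS <- c("twodose_lactating", "singledose_lactating", "market")

#' Assay detection and quantification limits for one matrix
#'
#' @param matrix `"plasma"` or `"milk"`.
#' @param lod Limit of detection (ng/mL), must satisfy `0 < lod <= loq`.
#' @param loq Limit of quantification (ng/mL).
#' @return An `assay_limits` object.
#' @export
assay_limits <- function(matrix = c("plasma", "milk"), lod, loq) {
  matrix <- match.arg(matrix)
  stopifnot(is.numeric(lod), is.numeric(loq), length(lod) == 1, length(loq) == 1)
  if (!(lod > 0 && lod <= loq)) {
    stop("assay limits must satisfy 0 < lod <= loq, got lod=", lod, ", loq=", loq)
  }
  structure(list(matrix = matrix, lod = lod, loq = loq), class = "assay_limits")
}

#' Default assay limits (LC-MS tulathromycin assay)
#'
#' Plasma LOD 1.2 / LOQ 4.0 ng/mL; milk (marker residue) LOD 1.8 / LOQ
#' 5.0 ng/mL.
#'
#' @return Named list with `plasma` and `milk` [assay_limits()] entries.
#' @export
default_assay_limits <- function() {
  list(plasma = assay_limits("plasma", 1.2, 4.0),
       milk   = assay_limits("milk",   1.8, 5.0))
}

#' Construct a study subject
#'
#' A subject carries its dose events and time-stamped observations. Milk
#' concentration observations require the per-milking volume; market
#' (non-lactating) subjects must not carry milk observations.
#'
#' @param id Subject identifier (unique within a dataset).
#' @param study One of `"twodose_lactating"`, `"singledose_lactating"`,
#'   `"market"`.
#' @param body_weight Body weight in kg (`> 0`).
#' @param doses `data.frame` with columns `time` (h) and `amount` (ng);
#'   times must be non-negative and strictly increasing.
#' @param observations `data.frame` with columns `time` (h), `kind`
#'   (`plasma_conc`, `milk_conc` or `milk_cumamount`), `value` (ng/mL or
#'   ng), `milk_volume` (mL; `NA` except for `milk_conc`) and logical
#'   `bloq`. Sorted by time on construction.
#' @param daily_milk_yield Daily milk yield in lbs/day (lactating subjects).
#' @return A `pk_subject` object.
#' @export
pk_subject <- function(id, study, body_weight, doses, observations = NULL,
                       daily_milk_yield = NA_real_) {
  study <- match.arg(study, STUDY_LABELS)
  stopifnot(length(id) == 1, is.numeric(body_weight), body_weight > 0)
  doses <- as.data.frame(doses)
  stopifnot(all(c("time", "amount") %in% names(doses)))
  if (any(doses$amount <= 0)) stop("dose amounts must be > 0 for subject ", id)
  if (any(doses$time < 0)) stop("dose times must be non-negative for subject ", id)
  if (nrow(doses) > 1 && any(diff(doses$time) <= 0)) {
    stop("dose times must be strictly increasing for subject ", id)
  }
  if (is.null(observations)) {
    observations <- data.frame(time = numeric(), kind = character(),
                               value = numeric(), milk_volume = numeric(),
                               bloq = logical())
  }
  observations <- as.data.frame(observations)
  need <- c("time", "kind", "value")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(observations$milk_volume)) observations$milk_volume <- NA_real_
  if (is.null(observations$bloq)) observations$bloq <- FALSE
  bad <- setdiff(unique(observations$kind), OBS_KINDS)
  if (length(bad)) stop("unknown observation kind(s): ", paste(bad, collapse = ", "))
  if (any(observations$time < 0)) {
    stop("negative observation time for subject ", id, " at row ",
         which(observations$time < 0)[1])
  }
  if (any(observations$value < 0, na.rm = TRUE)) {
    stop("negative observation value for subject ", id, " at row ",
         which(observations$value < 0)[1])
  }
  is_mc <- observations$kind == "milk_conc"
  if (any(is_mc & (is.na(observations$milk_volume) | observations$milk_volume <= 0))) {
    stop("milk_conc observation without positive milk_volume for subject ", id)
  }
  if (study == "market" && any(observations$kind %in% c("milk_conc", "milk_cumamount"))) {
    stop("market subjects must not carry milk observations (subject ", id, ")")
  }
  observations <- observations[order(observations$time), , drop = FALSE]
  rownames(observations) <- NULL
  structure(list(id = as.character(id), study = study,
                 body_weight = body_weight,
                 daily_milk_yield = daily_milk_yield,
                 doses = doses, observations = observations),
            class = "pk_subject")
}

#' Construct a study dataset
#'
#' @param subjects List of [pk_subject()] objects with unique ids.
#' @param assay Named list of [assay_limits()] per matrix, defaults to
#'   [default_assay_limits()].
#' @param note Free-text provenance note.
#' @return A `pk_study_dataset` object.
#' @export
study_dataset <- function(subjects, assay = default_assay_limits(), note = "") {
  stopifnot(is.list(subjects), all(vapply(subjects, inherits, TRUE, "pk_subject")))
  ids <- vapply(subjects, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(subjects) <- ids
  structure(list(subjects = subjects, assay = assay, note = note),
            class = "pk_study_dataset")
}

#' @export
print.pk_study_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$observations), 0L))
  cat("pk_study_dataset:", length(x$subjects), "subjects,", nobs, "observations\n")
  tab <- table(vapply(x$subjects, `[[`, "", "study"))
  for (s in names(tab)) cat(" ", s, ":", tab[[s]], "subjects\n")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# canonical long CSV schema
DATASET_COLUMNS <- c("subject_id", "study", "time_h", "kind", "value",
                     "milk_volume_ml", "amt_ng", "evid", "bloq")

#' Load a study dataset from a long-format CSV file
#'
#' Expected columns (renameable through `schema`): `subject_id`, `study`,
#' `time_h`, `kind`, `value`, `milk_volume_ml`, `amt_ng`, `evid`, `bloq`,
#' plus optional `body_weight_kg` and `daily_milk_yield_lbs`. Rows with
#' `evid = 1` are dose events carrying `amt_ng`; rows with `evid = 0` are
#' observations carrying `value` (ng/mL for concentrations, ng for
#' cumulative milk amounts).
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(subject_id = "ID")`.
#' @param assay Assay limits attached to the dataset.
#' @param note Provenance note (defaults to the file name).
#' @return A `pk_study_dataset`.
#' @export
load_dataset <- function(path, schema = NULL, assay = default_assay_limits(),
                         note = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop("schema error: column '", schema[[canon]], "' (for '", canon,
             "') not present in ", path)
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  required <- c("subject_id", "study", "time_h", "kind", "value", "evid")
  missing <- setdiff(required, names(raw))
  if (length(missing)) stop("schema error: missing column(s) ",
                            paste(missing, collapse = ", "))
  if (is.null(raw$milk_volume_ml)) raw$milk_volume_ml <- NA_real_
  if (is.null(raw$amt_ng)) raw$amt_ng <- NA_real_
  if (is.null(raw$bloq)) raw$bloq <- FALSE
  raw$bloq <- as.logical(raw$bloq)
  if (any(raw$time_h < 0, na.rm = TRUE)) {
    stop("validation error: negative time at row ", which(raw$time_h < 0)[1])
  }
  obs <- raw[raw$evid == 0, , drop = FALSE]
  if (any(obs$value < 0, na.rm = TRUE)) {
    stop("validation error: negative value at row ",
         rownames(obs)[which(obs$value < 0)[1]])
  }
  bad <- setdiff(unique(obs$kind), OBS_KINDS)
  if (length(bad)) stop("validation error: unknown observation kind(s) ",
                        paste(bad, collapse = ", "))
  mc <- obs$kind == "milk_conc"
  if (any(mc & (is.na(obs$milk_volume_ml) | obs$milk_volume_ml <= 0))) {
    stop("validation error: milk_conc row without positive milk_volume_ml (row ",
         rownames(obs)[which(mc & (is.na(obs$milk_volume_ml) | obs$milk_volume_ml <= 0))[1]],
         ")")
  }
  subjects <- lapply(split(raw, raw$subject_id), function(d) {
    doses <- d[d$evid == 1, , drop = FALSE]
    od <- d[d$evid == 0, , drop = FALSE]
    bw <- if (!is.null(d$body_weight_kg)) d$body_weight_kg[1] else NA_real_
    yield <- if (!is.null(d$daily_milk_yield_lbs)) d$daily_milk_yield_lbs[1] else NA_real_
    if (is.na(bw)) bw <- 1  # body weight optional when doses carry absolute ng
    pk_subject(id = d$subject_id[1], study = d$study[1], body_weight = bw,
               daily_milk_yield = yield,
               doses = data.frame(time = doses$time_h, amount = doses$amt_ng),
               observations = data.frame(time = od$time_h, kind = od$kind,
                                         value = od$value,
                                         milk_volume = od$milk_volume_ml,
                                         bloq = od$bloq))
  })
  if (is.null(note)) note <- basename(path)
  study_dataset(unname(subjects), assay = assay, note = note)
}

#' Write a study dataset to the canonical long CSV schema
#'
#' Inverse of [load_dataset()]: `load -> write -> load` round-trips values
#' and flags exactly.
#'
#' @param dataset A `pk_study_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_study_dataset"))
  rows <- lapply(dataset$subjects, function(s) {
    d1 <- if (nrow(s$doses)) data.frame(
      subject_id = s$id, study = s$study, time_h = s$doses$time,
      kind = "", value = NA_real_, milk_volume_ml = NA_real_,
      amt_ng = s$doses$amount, evid = 1L, bloq = FALSE,
      body_weight_kg = s$body_weight, daily_milk_yield_lbs = s$daily_milk_yield)
    o <- s$observations
    d0 <- if (nrow(o)) data.frame(
      subject_id = s$id, study = s$study, time_h = o$time,
      kind = o$kind, value = o$value, milk_volume_ml = o$milk_volume,
      amt_ng = NA_real_, evid = 0L, bloq = o$bloq,
      body_weight_kg = s$body_weight, daily_milk_yield_lbs = s$daily_milk_yield)
    rbind(d1, d0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Convert a milk weight to a volume
#'
#' Milk weights are converted to volumes with a fixed milk density
#' (default 1.03 g/mL); 1 lb = 453.592 g.
#'
#' @param weight_value Non-negative weight.
#' @param unit `"g"`, `"kg"` or `"lbs"`.
#' @param density Milk density in g/mL.
#' @return Volume in mL.
#' @export
volume_from_weight <- function(weight_value, unit = c("g", "kg", "lbs"),
                               density = 1.03) {
  unit <- match.arg(unit)
  stopifnot(all(weight_value >= 0), density > 0)
  grams <- switch(unit, g = weight_value, kg = 1000 * weight_value,
                  lbs = 453.592 * weight_value)
  grams / density
}

#' Cumulative milk-excreted amount series for a subject
#'
#' Per-milking excreted amount = concentration x milk volume; the series is
#' the running sum in time order and is non-decreasing for non-negative
#' inputs. This is the quantity the population model fits.
#'
#' @param subject A `pk_subject` with at least one `milk_conc` observation.
#' @return `data.frame` with columns `time` (h) and `amount` (ng).
#' @export
build_milk_cumulative <- function(subject) {
  stopifnot(inherits(subject, "pk_subject"))
  o <- subject$observations
  o <- o[o$kind == "milk_conc", , drop = FALSE]
  if (!nrow(o)) stop("subject ", subject$id, " has no milk_conc observations")
  if (anyDuplicated(o$time)) stop("duplicate milking times for subject ", subject$id)
  if (any(is.na(o$milk_volume) | o$milk_volume <= 0)) {
    stop("missing milk volume for subject ", subject$id)
  }
  o <- o[order(o$time), , drop = FALSE]
  data.frame(time = o$time, amount = cumsum(o$value * o$milk_volume))
}

#' Apply a below-limit-of-detection handling policy
#'
#' `exclude` drops flagged rows from the dataset (M1-style exclusion, the
#' default used for fitting), `zero` keeps them with value 0, `half_lod`
#' replaces the value with the matrix LOD/2. The input dataset is not
#' modified.
#'
#' @param dataset A `pk_study_dataset`.
#' @param policy `"exclude"`, `"zero"` or `"half_lod"`.
#' @return A new `pk_study_dataset`.
#' @export
apply_bloq_policy <- function(dataset, policy = c("exclude", "zero", "half_lod")) {
  stopifnot(inherits(dataset, "pk_study_dataset"))
  policy <- match.arg(policy)
  lod_for <- function(kind) {
    if (kind == "plasma_conc") dataset$assay$plasma$lod else dataset$assay$milk$lod
  }
  subjects <- lapply(dataset$subjects, function(s) {
    o <- s$observations
    flag <- o$bloq %in% TRUE
    if (any(flag)) {
      if (policy == "exclude") {
        o <- o[!flag, , drop = FALSE]
      } else if (policy == "zero") {
        o$value[flag] <- 0
      } else {
        o$value[flag] <- vapply(o$kind[flag], lod_for, 0) / 2
      }
    }
    s$observations <- o
    s
  })
  study_dataset(unname(subjects), assay = dataset$assay,
                note = paste0(dataset$note, " [bloq=", policy, "]"))
}

#' Count fitted observations per kind
#'
#' @param dataset A `pk_study_dataset`.
#' @return Named integer vector of observation counts per kind.
#' @export
count_observations <- function(dataset) {
  kinds <- unlist(lapply(dataset$subjects, function(s) s$observations$kind))
  tab <- table(factor(kinds, levels = OBS_KINDS))
  stats::setNames(as.integer(tab), names(tab))
}
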