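#' Risk set at a calendar time
#'
#' Members of the cohort still at risk of distant metastasis at calendar
#' time `T`: diagnosed on or before `T`, still under follow-up strictly
#' after `T`, and free of any distant-metastasis event on or before `T`.
#' The convention is half-open: a patient whose own event or exit falls
#' exactly on day `T` is not at risk at `T`. Cases are therefore eligible
#' as controls for earlier cases' sets, as incidence-density sampling
#' requires.
#'
#' @param cohort Data frame with columns `patient_id`, `diagnosis_date`,
#'   `exit_date` (integer calendar day indices) and `event_date` (calendar
#'   day of first distant metastasis, `NA` when none).
#' @param T Calendar day index.
#' @param exclude Optional patient id(s) to drop (typically the case).
#'
#' @return Character vector of patient ids (possibly empty).
#' @export
risk_set <- function(cohort, T, exclude = NULL) {
  stopifnot(nrow(cohort) > 0)
  ok <- cohort$diagnosis_date <= T &
    cohort$exit_date > T &
    (is.na(cohort$event_date) | cohort$event_date > T)
  ids <- cohort$patient_id[ok]
  as.character(setdiff(ids, exclude))
}

#' Sample matched controls for one case
#'
#' At the case's event date `T`, draws up to `m` controls uniformly without
#' replacement from [risk_set()] (the case itself excluded). If fewer than
#' `m` patients are at risk, all of them are returned and the deficit is
#' flagged; an empty risk set yields an unmatched, flagged set.
#'
#' Sampling uses R's global random stream; call `set.seed()` for
#' reproducibility.
#'
#' @inheritParams risk_set
#' @param case_id Patient id of the case; must have a non-missing
#'   `event_date` in `cohort`.
#' @param m Number of controls to draw (default 3).
#'
#' @return A one-row tibble: `case_id`, `index_time`, `control_ids`
#'   (list-column of character vectors), `n_controls`, `deficit` (logical:
#'   fewer than `m` controls available).
#' @export
sample_case_controls <- function(cohort, case_id, m = 3) {
  stopifnot(m >= 1)
  row <- cohort[cohort$patient_id == case_id, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("case_id not found (or duplicated) in cohort: ", case_id,
         call. = FALSE)
  }
  if (is.na(row$event_date)) {
    stop("patient ", case_id, " has no distant-metastasis event and cannot ",
         "be a case", call. = FALSE)
  }
  T <- row$event_date
  rs <- risk_set(cohort, T, exclude = case_id)
  k <- min(m, length(rs))
  controls <- if (k > 0) sample(rs, k) else character(0)
  tibble::tibble(
    case_id = as.character(case_id),
    index_time = T,
    control_ids = list(controls),
    n_controls = k,
    deficit = k < m
  )
}

#' Build an incidence-density case-control series
#'
#' Selects a uniform random subset of `n_cases` cases with the requested
#' first-metastasis pattern and matches each by calendar time of event via
#' [sample_case_controls()]. A patient may serve as a control in several
#' sets and later become a case; controls are drawn without replacement
#' within a set but independently across sets.
#'
#' @inheritParams risk_set
#' @param series One of `"V"`, `"BV"`, `"B"`, selecting cases with pattern
#'   `visceral_only`, `bone_and_visceral` or `bone_only`; `cohort` must
#'   carry a `pattern` column.
#' @param n_cases Number of cases to sample; if more than are eligible, all
#'   eligible cases are used with a warning.
#' @param m Controls per case (default 3).
#'
#' @return Tibble of case-control sets (one row per case) as returned by
#'   [sample_case_controls()], with a `series` column prepended.
#' @export
build_case_control_series <- function(cohort, series = c("V", "BV", "B"),
                                      n_cases = Inf, m = 3) {
  series <- match.arg(series)
  want <- c(V = "visceral_only", BV = "bone_and_visceral",
            B = "bone_only")[[series]]
  if (!"pattern" %in% names(cohort)) {
    stop("cohort must carry a `pattern` column (see classify_patterns)",
         call. = FALSE)
  }
  eligible <- cohort$patient_id[cohort$pattern == want &
                                  !is.na(cohort$event_date)]
  if (length(eligible) == 0) {
    stop("no eligible cases with pattern ", want, call. = FALSE)
  }
  if (n_cases > length(eligible)) {
    if (is.finite(n_cases)) {
      warning("only ", length(eligible), " eligible cases for series ",
              series, "; using all of them", call. = FALSE)
    }
    chosen <- sample(eligible, length(eligible))
  } else {
    chosen <- sample(eligible, n_cases)
  }
  sets <- purrr::map(chosen,
                     \(id) sample_case_controls(cohort, id, m = m))
  dplyr::bind_rows(sets) |>
    dplyr::mutate(series = series, .before = 1)
}

#' Reduce case-control sets to 1:1 matched pairs
#'
#' Chooses one control uniformly at random from each set's available
#' controls; sets with no controls are dropped with a warning. Pairs retain
#' the series label and index time.
#'
#' @param sets Tibble of case-control sets from
#'   [build_case_control_series()] or [sample_case_controls()].
#'
#' @return Tibble with columns `series` (if present in `sets`), `case_id`,
#'   `control_id`, `index_time`.
#' @export
reduce_to_pairs <- function(sets) {
  empty <- lengths(sets$control_ids) == 0
  if (any(empty)) {
    warning(sum(empty), " set(s) with no controls dropped", call. = FALSE)
    sets <- sets[!empty, , drop = FALSE]
  }
  pick <- purrr::map_chr(sets$control_ids,
                         \(ids) ids[[sample.int(length(ids), 1)]])
  out <- tibble::tibble(
    case_id = sets$case_id,
    control_id = pick,
    index_time = sets$index_time
  )
  if ("series" %in% names(sets)) {
    out <- dplyr::mutate(out, series = sets$series, .before = 1)
  }
  out
}
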