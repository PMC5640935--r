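#' Organ-site vocabulary
#'
#' Recognised organ-site codes for distant-recurrence events, and the
#' bone/visceral category each belongs to. Bone metastasis covers bone or
#' bone marrow involvement, spinal cord compression, pathological fracture
#' and hypercalcaemia of malignancy; visceral metastasis covers lung, liver,
#' brain and malignant ascites. Any other distant site is carried through
#' but ignored by pattern classification.
#'
#' @format A named character vector mapping site code to category
#'   (`"bone"`, `"visceral"` or `"ignored"`).
#' @export
organ_site_categories <- c(
  bone                    = "bone",
  bone_marrow             = "bone",
  spinal_cord_compression = "bone",
  pathological_fracture   = "bone",
  hypercalcaemia          = "bone",
  lung                    = "visceral",
  liver                   = "visceral",
  brain                   = "visceral",
  ascites                 = "visceral",
  other                   = "ignored"
)

#' Categorise organ sites as bone, visceral or ignored
#'
#' @param site Character vector of organ-site codes; see
#'   [organ_site_categories] for the accepted vocabulary.
#'
#' @return Character vector the same length as `site`, each element one of
#'   `"bone"`, `"visceral"`, `"ignored"`.
#' @examples
#' categorize_site(c("hypercalcaemia", "ascites", "other"))
#' @export
categorize_site <- function(site) {
  site <- as.character(site)
  bad <- setdiff(unique(site), names(organ_site_categories))
  if (length(bad) > 0) {
    stop("unknown organ site code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(organ_site_categories[site])
}

#' Classify first-metastasis patterns from organ-site event timelines
#'
#' Classifies each patient's distant-recurrence timeline into one of four
#' first-metastasis patterns: `bone_only` (first recurrence to bone with no
#' visceral site within the metasynchronicity window), `visceral_only`
#' (symmetric), `bone_and_visceral` (recurrence to both categories within
#' the window, in either order) and `none` (no bone or visceral event).
#' The window defaults to 183 days (six months) and the boundary is
#' inclusive: a gap of exactly `window_days` counts as metasynchronous.
#' Events whose site category is `ignored` never influence the result.
#'
#' @param events Data frame with columns `patient_id`, `site` and
#'   `days_since_diagnosis` (non-negative event times). A patient may have
#'   any number of rows, including zero.
#' @param window_days Positive metasynchronicity window in days
#'   (default 183).
#' @param patients Optional vector of patient ids that must appear in the
#'   output; patients with no (bone/visceral) events are labelled `none`.
#'   Defaults to the ids present in `events`.
#'
#' @return A tibble with one row per patient: `patient_id`, `pattern`
#'   (factor with levels `bone_only`, `visceral_only`, `bone_and_visceral`,
#'   `none`), `t_first` (days of first bone/visceral metastasis; `NA` for
#'   `none`) and `t_other_site` (days of the first other-category event
#'   beyond the window for single-site patterns; otherwise `NA`).
#' @examples
#' ev <- data.frame(
#'   patient_id = c("p1", "p1", "p2"),
#'   site = c("bone", "liver", "hypercalcaemia"),
#'   days_since_diagnosis = c(365, 485, 150)
#' )
#' classify_patterns(ev)
#' @export
classify_patterns <- function(events, window_days = 183, patients = NULL) {
  stopifnot(is.numeric(window_days), length(window_days) == 1,
            window_days > 0)
  req <- c("patient_id", "site", "days_since_diagnosis")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    stop("events is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) > 0 && any(!is.finite(events$days_since_diagnosis))) {
    stop("event times must be finite", call. = FALSE)
  }
  if (nrow(events) > 0 && any(events$days_since_diagnosis < 0)) {
    stop("event times must be non-negative", call. = FALSE)
  }
  if (is.null(patients)) patients <- unique(events$patient_id)

  ev <- tibble::as_tibble(events)
  ev$category <- if (nrow(ev)) categorize_site(ev$site) else character(0)
  ev <- dplyr::filter(ev, .data$category != "ignored")
  firsts <- if (nrow(ev) > 0) {
    ev |>
      dplyr::group_by(.data$patient_id, .data$category) |>
      dplyr::summarise(t = min(.data$days_since_diagnosis),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "category", values_from = "t")
  } else {
    tibble::tibble(patient_id = ev$patient_id)
  }
  for (col in c("bone", "visceral")) {
    if (!col %in% names(firsts)) firsts[[col]] <- NA_real_
  }

  out <- tibble::tibble(patient_id = patients) |>
    dplyr::left_join(firsts, by = "patient_id")
  t_b <- out$bone
  t_v <- out$visceral
  pattern <- dplyr::case_when(
    is.na(t_b) & is.na(t_v) ~ "none",
    !is.na(t_b) & !is.na(t_v) & abs(t_b - t_v) <= window_days ~
      "bone_and_visceral",
    !is.na(t_b) & (is.na(t_v) | t_v - t_b > window_days) ~ "bone_only",
    TRUE ~ "visceral_only"
  )
  t_first <- pmin(t_b, t_v, na.rm = TRUE)
  t_first[pattern == "none"] <- NA_real_
  t_other <- dplyr::case_when(
    pattern == "bone_only" & !is.na(t_v) ~ t_v,
    pattern == "visceral_only" & !is.na(t_b) ~ t_b,
    TRUE ~ NA_real_
  )
  tibble::tibble(
    patient_id = out$patient_id,
    pattern = factor(pattern, levels = c("bone_only", "visceral_only",
                                         "bone_and_visceral", "none")),
    t_first = t_first,
    t_other_site = t_other
  )
}

#' Classify a single patient's timeline
#'
#' Convenience wrapper around [classify_patterns()] for one patient's
#' events, returned as a one-row tibble.
#'
#' @param events Data frame with columns `site` and `days_since_diagnosis`
#'   (a `patient_id` column is optional and must be constant).
#' @inheritParams classify_patterns
#' @return One-row tibble as in [classify_patterns()].
#' @export
classify_first_pattern <- function(events, window_days = 183) {
  if (!"patient_id" %in% names(events)) {
    events <- tibble::as_tibble(events)
    events$patient_id <- if (nrow(events)) "patient" else character(0)
  }
  if (length(unique(events$patient_id)) > 1) {
    stop("events must belong to a single patient", call. = FALSE)
  }
  pid <- if (nrow(events)) unique(events$patient_id) else "patient"
  classify_patterns(events, window_days = window_days, patients = pid)
}
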