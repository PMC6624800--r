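#' Build a trial cohort table
#'
#' A cohort is a tibble with one row per two-arm randomized trial and the
#' framework-relevant flags the award algorithms consume. Survival curves are
#' carried in list-columns (`curve_os_test`, `curve_os_control`,
#' `curve_pfs_test`, `curve_pfs_control`), each a [step_curve()] or `NULL`.
#'
#' Required columns:
#' `trial_id` (unique), `therapy_class` (`"ICI"` / `"non-ICI"`),
#' `therapy_subclass` (chemotherapy | targeted | hormone | radiopharmaceutical
#' | ICI), `disease_site`, `hematological` (logical), `primary_endpoint`
#' (`"OS"`, `"PFS"` or `"OS+PFS"`), `primary_significant` (logical),
#' `os_reported`, `os_obscured_by_crossover`, `pfs_reported` (logical).
#' Optional: `plateau_override_os`, `plateau_override_pfs` (logical, `NA` =
#' no override), `ltp_form_override` (`"OS"`/`"PFS"`/`NA`, routes coprimary
#' trials), `provenance` (free text, unused by computation).
#'
#' @param trials A data frame with the columns above (curve list-columns
#'   optional; missing ones are filled with `NULL`s).
#' @return A validated cohort tibble (class `tc_cohort`).
#' @export
cohort <- function(trials) {
  trials <- as_tibble(trials)
  for (col in c("plateau_override_os", "plateau_override_pfs")) {
    if (!col %in% names(trials)) trials[[col]] <- NA
    trials[[col]] <- as.logical(trials[[col]])
  }
  if (!"ltp_form_override" %in% names(trials)) {
    trials$ltp_form_override <- NA_character_
  }
  if (!"provenance" %in% names(trials)) trials$provenance <- NA_character_
  for (col in curve_columns()) {
    if (!col %in% names(trials)) {
      trials[[col]] <- vector("list", nrow(trials))
    }
  }
  out <- validate_cohort(trials)
  class(out) <- c("tc_cohort", class(tibble()))
  out
}

curve_columns <- function() {
  c("curve_os_test", "curve_os_control", "curve_pfs_test", "curve_pfs_control")
}

cohort_required_columns <- function() {
  c("trial_id", "therapy_class", "therapy_subclass", "disease_site",
    "hematological", "primary_endpoint", "primary_significant",
    "os_reported", "os_obscured_by_crossover", "pfs_reported")
}

validate_cohort <- function(trials) {
  missing_cols <- setdiff(cohort_required_columns(), names(trials))
  if (length(missing_cols) > 0L) {
    abort(sprintf("cohort table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(trials$trial_id)) {
    dup <- unique(trials$trial_id[duplicated(trials$trial_id)])
    abort(sprintf("duplicated trial_id: %s", paste(dup, collapse = ", ")))
  }
  bad_class <- !trials$therapy_class %in% c("ICI", "non-ICI")
  if (any(bad_class)) {
    abort(sprintf("trial %s: therapy_class must be 'ICI' or 'non-ICI'",
                  trials$trial_id[bad_class][1]))
  }
  bad_ep <- !trials$primary_endpoint %in% c("OS", "PFS", "OS+PFS")
  if (any(bad_ep)) {
    abort(sprintf("trial %s: primary_endpoint must be OS, PFS or OS+PFS",
                  trials$trial_id[bad_ep][1]))
  }
  for (col in c("hematological", "primary_significant", "os_reported",
                "os_obscured_by_crossover", "pfs_reported")) {
    if (!is.logical(trials[[col]]) || anyNA(trials[[col]])) {
      abort(sprintf("cohort column `%s` must be logical without missing values", col))
    }
  }
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    check_curve_pair <- function(reported, test_col, ctrl_col, endpoint) {
      if (reported) {
        for (col in c(test_col, ctrl_col)) {
          cv <- trials[[col]][[i]]
          if (is.null(cv)) {
            abort(sprintf("trial %s: %s reported but `%s` curve is missing",
                          id, endpoint, col))
          }
          if (!is_step_curve(cv)) {
            abort(sprintf("trial %s: `%s` is not a step_curve", id, col))
          }
        }
      }
    }
    check_curve_pair(trials$os_reported[i], "curve_os_test",
                     "curve_os_control", "OS")
    check_curve_pair(trials$pfs_reported[i], "curve_pfs_test",
                     "curve_pfs_control", "PFS")
  }
  trials
}

#' ESMO-MCBS eligibility for the long-term-plateau adjustment
#'
#' Trials without a statistically significant primary endpoint, and trials of
#' hematological anticancer agents, are not assessed under ESMO-MCBS v1.1.
#' The ASCO-VF tail-of-the-curve bonus has no such gate, so eligibility lives
#' on the ESMO path only.
#'
#' @param trials A cohort tibble (or any data frame with
#'   `primary_significant` and `hematological` columns).
#' @return Logical vector, one element per trial.
#' @export
esmo_eligible <- function(trials) {
  trials$primary_significant & !trials$hematological
}

esmo_ineligible_reason <- function(trials) {
  dplyr::case_when(
    !trials$primary_significant & trials$hematological ~
      "primary endpoint not significant; hematological agent",
    !trials$primary_significant ~ "primary endpoint not significant",
    trials$hematological ~ "hematological agent",
    TRUE ~ NA_character_
  )
}

curve_file_name <- function(trial_id, endpoint, arm) {
  sprintf("%s__%s__%s.tsv", trial_id, endpoint, arm)
}

#' Read and write trial cohorts
#'
#' The on-disk layout is a trial table (CSV, or a JSON array of objects with
#' identical field names) plus a curve directory holding one step-curve TSV
#' per arm per reported endpoint, named `<trial_id>__<OS|PFS>__<test|control>.tsv`.
#' Every cohort invariant is checked on load; a missing curve file, duplicate
#' trial id or schema violation is an error naming the trial and field.
#'
#' @param trial_table Path to the trial table (`.csv` or `.json`).
#' @param curve_dir Directory containing the curve TSVs.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` invisibly returns `trial_table`.
#' @export
read_cohort <- function(trial_table, curve_dir) {
  if (!file.exists(trial_table)) {
    abort(sprintf("trial table not found: %s", trial_table))
  }
  tab <- if (grepl("\\.json$", trial_table, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(trial_table))
  } else {
    readr::read_csv(trial_table, show_col_types = FALSE, progress = FALSE)
  }
  missing_cols <- setdiff(cohort_required_columns(), names(tab))
  if (length(missing_cols) > 0L) {
    abort(sprintf("trial table %s is missing columns: %s", trial_table,
                  paste(missing_cols, collapse = ", ")))
  }
  load_curve <- function(id, reported, endpoint, arm) {
    if (!reported) return(NULL)
    path <- file.path(curve_dir, curve_file_name(id, endpoint, arm))
    if (!file.exists(path)) {
      abort(sprintf("trial %s: missing curve file %s", id, path))
    }
    read_curve_tsv(path)
  }
  tab$curve_os_test <- purrr::map2(tab$trial_id, tab$os_reported,
                                   ~ load_curve(.x, .y, "OS", "test"))
  tab$curve_os_control <- purrr::map2(tab$trial_id, tab$os_reported,
                                      ~ load_curve(.x, .y, "OS", "control"))
  tab$curve_pfs_test <- purrr::map2(tab$trial_id, tab$pfs_reported,
                                    ~ load_curve(.x, .y, "PFS", "test"))
  tab$curve_pfs_control <- purrr::map2(tab$trial_id, tab$pfs_reported,
                                       ~ load_curve(.x, .y, "PFS", "control"))
  cohort(tab)
}

#' @rdname read_cohort
#' @param trials A cohort tibble as produced by [cohort()] or
#'   [simulate_cohort()].
#' @export
write_cohort <- function(trials, trial_table, curve_dir) {
  trials <- cohort(trials)
  dir.create(curve_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- dplyr::select(trials, -dplyr::all_of(curve_columns()))
  if (grepl("\\.json$", trial_table, ignore.case = TRUE)) {
    jsonlite::write_json(flat, trial_table, auto_unbox = FALSE, digits = NA,
                         na = "null")
  } else {
    readr::write_csv(flat, trial_table, progress = FALSE)
  }
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    specs <- list(
      list("curve_os_test", "OS", "test"), list("curve_os_control", "OS", "control"),
      list("curve_pfs_test", "PFS", "test"), list("curve_pfs_control", "PFS", "control")
    )
    for (sp in specs) {
      cv <- trials[[sp[[1]]]][[i]]
      if (!is.null(cv)) {
        write_curve_tsv(cv, file.path(curve_dir, curve_file_name(id, sp[[2]], sp[[3]])))
      }
    }
  }
  invisible(trial_table)
}

trial_curves <- function(trial, endpoint) {
  stopifnot(nrow(trial) == 1L)
  if (endpoint == "OS") {
    list(test = trial$curve_os_test[[1]], control = trial$curve_os_control[[1]])
  } else {
    list(test = trial$curve_pfs_test[[1]], control = trial$curve_pfs_control[[1]])
  }
}
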