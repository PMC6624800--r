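#' Read and write survival-curve files
#'
#' Two plain-text formats are supported, one file per arm per endpoint:
#'
#' * **Step-curve TSV** — columns `time_months`, `survival`, `at_risk`: a
#'   digitised Kaplan-Meier table. Validated on load against the
#'   [step_curve()] invariants; violations (rising survival, unsorted times,
#'   growing risk sets) are errors, never repaired.
#' * **Raw-times TSV** — columns `time_months`, `event` (`0` censored,
#'   `1` event): per-subject follow-up, turned into a curve by
#'   [km_estimate()].
#'
#' @param path File path.
#' @return A [step_curve()].
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
read_curve_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("curve file not found: %s", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_months", "survival", "at_risk")
  if (!all(need %in% names(tab))) {
    abort(sprintf("curve file %s must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  step_curve(tab$time_months, tab$survival, tab$at_risk)
}

#' @rdname curve_io
#' @param curve A [step_curve()] to write.
#' @export
write_curve_tsv <- function(curve, path) {
  assert_step_curve(curve)
  readr::write_tsv(as_tibble(curve), path, progress = FALSE)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_raw_times_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("raw-times file not found: %s", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_months", "event")
  if (!all(need %in% names(tab))) {
    abort(sprintf("raw-times file %s must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  if (!all(tab$event %in% c(0, 1))) {
    abort(sprintf("raw-times file %s: `event` must be 0 or 1", path))
  }
  km_estimate(tab$time_months, tab$event == 1)
}
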