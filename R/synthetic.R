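# Synthetic patient-level data from the three-state progression process.
# Stands in for trial individual-patient data (which is not public) so the
# Kaplan-Meier -> calibration pipeline can be exercised end to end.

#' Simulate pseudo-patients from the monthly progression chain
#'
#' Each patient starts progression-free and walks the chain month by month:
#' time to leaving PFS is geometric with exit probability
#' `pfs_pd + pfs_death`; the exit is death with probability
#' `pfs_death / (pfs_pd + pfs_death)`, otherwise the patient enters PD and
#' survives there a further geometric number of months with event
#' probability `pd_death`. Times are on the integer-month grid, the chain's
#' native resolution. Follow-up ends at `max_months` (and optionally at an
#' administrative `censor_month`); later events are censored.
#'
#' @param matrix A [transition_matrix()].
#' @param n_patients Number of patients.
#' @param max_months Maximum follow-up in months.
#' @param censor_month Optional administrative censoring month.
#' @param seed Integer seed (required; the caller's RNG state is restored).
#' @return A `pseudo_cohort` data frame: `pfs_time`, `os_time`,
#'   `progressed`, `censored_pfs`, `censored_os`.
#' @examples
#' head(simulate_cohort(transition_matrix(0.849, 0.091, 0.06, 0.897, 0.103),
#'                      5, 60, seed = 1))
#' @export
simulate_cohort <- function(matrix, n_patients, max_months = 60,
                            censor_month = NULL, seed) {
  if (!is_transition_matrix(matrix))
    stop_validation("`matrix` must be a transition_matrix")
  if (missing(seed)) stop_validation("`seed` is required for simulate_cohort")
  assert_scalar_number(n_patients, "n_patients", 1)
  assert_scalar_number(max_months, "max_months", 1)
  if (!is.null(censor_month))
    assert_scalar_number(censor_month, "censor_month", 1)
  n <- as.integer(n_patients)
  cutoff <- min(max_months, censor_month %||% Inf)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(as.integer(seed))

  p_exit <- matrix$pfs_pd + matrix$pfs_death
  exit_month <- if (p_exit > 0) 1L + stats::rgeom(n, p_exit) else rep(Inf, n)
  death_exit <- if (p_exit > 0)
    stats::runif(n) < matrix$pfs_death / p_exit else rep(FALSE, n)
  pd_months <- if (matrix$pd_death > 0)
    1L + stats::rgeom(n, matrix$pd_death) else rep(Inf, n)
  death_month <- ifelse(death_exit, exit_month, exit_month + pd_months)

  censored_pfs <- exit_month > cutoff
  censored_os <- death_month > cutoff
  data.frame(
    pfs_time = pmin(exit_month, cutoff),
    os_time = pmin(death_month, cutoff),
    progressed = !death_exit & !censored_pfs,
    censored_pfs = censored_pfs,
    censored_os = censored_os) -> out
  class(out) <- c("pseudo_cohort", "data.frame")
  out
}

#' Write a pseudo-cohort as CSV
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Kaplan-Meier estimate from a pseudo-cohort
#'
#' Product-limit estimate of OS (time to death) or PFS (time to first exit
#' from the progression-free state) on the integer-month grid, via
#' [survival::survfit()]. Censored observations contribute risk time only.
#'
#' @param cohort A [simulate_cohort()] result (or data frame with the same
#'   columns).
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A [survival_curve()] on months `0..max(observed time)`.
#' @export
km_estimate <- function(cohort, endpoint = c("OS", "PFS")) {
  endpoint <- match_choice(endpoint[1], c("OS", "PFS"), "endpoint")
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_validation("`cohort` must be a non-empty data frame")
  need <- c("pfs_time", "os_time", "censored_pfs", "censored_os")
  if (!all(need %in% names(cohort)))
    stop_validation("cohort must have columns: %s", paste(need, collapse = ", "))
  time <- if (endpoint == "OS") cohort$os_time else cohort$pfs_time
  event <- if (endpoint == "OS") !cohort$censored_os else !cohort$censored_pfs
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  months <- 0:max(time)
  s <- summary(fit, times = months, extend = TRUE)$surv
  survival_curve(months, s, endpoint)
}
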