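#' Survival curve on a monthly grid
#'
#' @param month Integer months `>= 0`, strictly increasing; month 0 with
#'   survival 1 is added if absent.
#' @param survival Survival fractions in `[0, 1]`, non-increasing.
#' @param kind `"OS"` or `"PFS"`.
#' @return A `survival_curve` data frame with columns `month`, `survival`.
#' @export
survival_curve <- function(month, survival, kind = c("OS", "PFS")) {
  kind <- match_choice(kind[1], c("OS", "PFS"), "kind")
  if (length(month) != length(survival))
    stop_validation("month and survival must have equal length")
  o <- order(month)
  month <- month[o]; survival <- survival[o]
  if (any(month < 0)) stop_validation("months must be >= 0")
  if (anyDuplicated(month)) stop_validation("duplicate months in curve")
  if (any(survival < 0 | survival > 1))
    stop_validation("survival values must lie in [0, 1]")
  if (any(diff(survival) > 1e-12))
    stop_validation("%s curve is not non-increasing in time", kind)
  if (!any(month == 0)) { month <- c(0, month); survival <- c(1, survival) }
  if (abs(survival[month == 0] - 1) > 1e-12)
    stop_validation("survival at month 0 must be 1")
  structure(data.frame(month = month, survival = survival),
            kind = kind, class = c("survival_curve", "data.frame"))
}

curve_kind <- function(x) attr(x, "kind")

#' Model-predicted OS and PFS curves
#'
#' With everyone starting progression-free, the progression-free fraction
#' after `t` cycles is `pfs_pfs^t` and overall survival is one minus the
#' death occupancy of the cohort trace.
#'
#' @param matrix A [transition_matrix()].
#' @param horizon Number of monthly cycles.
#' @return List with `os` and `pfs` [survival_curve()]s on months
#'   `0..horizon`.
#' @export
predict_curves <- function(matrix, horizon = 60L) {
  trace <- build_trace(matrix, model_config(horizon = horizon,
                                            annual_discount_rate = 0))
  months <- 0:horizon
  list(os = survival_curve(months, 1 - trace[, "DEATH"], "OS"),
       pfs = survival_curve(months, matrix$pfs_pfs^months, "PFS"))
}

#' Linear interpolation of a survival curve onto integer months
#'
#' Opt-in utility for curves digitised at arbitrary times; the calibrator
#' itself requires integer-month input.
#'
#' @param time,survival Observed (time, survival) pairs, time in months.
#' @param months Integer grid to interpolate onto (default `0:floor(max)`).
#' @param kind `"OS"` or `"PFS"`.
#' @return A [survival_curve()].
#' @export
interpolate_curve <- function(time, survival, months = NULL,
                              kind = c("OS", "PFS")) {
  if (is.null(months)) months <- 0:floor(max(time))
  s <- stats::approx(c(0, time), c(1, survival), xout = months,
                     method = "linear", rule = 2)$y
  survival_curve(months, cummin(s), kind)
}

# map (pfs_pfs, death share of PFS exits, pd_pd) <-> unconstrained scale
logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

params_to_matrix <- function(stay_pfs, death_share, stay_pd) {
  exit <- 1 - stay_pfs
  transition_matrix(stay_pfs, exit * (1 - death_share), exit * death_share,
                    stay_pd, 1 - stay_pd)
}

#' Calibrate monthly transition probabilities to OS/PFS curves
#'
#' Fits the three free parameters of the progression model (monthly
#' probability of remaining progression-free; the share of PFS exits that go
#' to death rather than progression; monthly probability of remaining alive
#' in PD) by least squares against the supplied curves, minimising
#' `sum((OS_obs - OS_model)^2) + sum((PFS_obs - PFS_model)^2)` on the common
#' monthly grid.
#'
#' The procedure is deterministic: the PFS stay probability is initialised
#' by the log-linear closed form `exp(mean(diff(log(PFS))))` and refined
#' one-dimensionally against the PFS curve alone; the two OS-linked
#' parameters are then scanned on a coarse grid (step 0.05) and the best
#' start is polished with Nelder-Mead on the unconstrained (log-odds) scale,
#' followed by a joint three-parameter polish. Ties on the grid are broken
#' by lexicographic parameter order. The best objective value seen is
#' tracked and never increases.
#'
#' @param os,pfs [survival_curve()]s of kind `"OS"` and `"PFS"` sharing a
#'   common integer-month grid with at least 3 points beyond month 0.
#' @param max_eval Maximum objective evaluations for the local polish.
#' @param tol Convergence tolerance on the objective.
#' @return A `calibration_result`: list with `matrix`
#'   ([transition_matrix()]), `sse_os`, `sse_pfs`, `sse` (their sum),
#'   `converged`, and `diagnostic` (message when not converged).
#' @examples
#' m <- transition_matrix(0.849, 0.091, 0.060, 0.897, 0.103)
#' cv <- predict_curves(m, 24)
#' calibrate_transitions(cv$os, cv$pfs)$matrix
#' @export
calibrate_transitions <- function(os, pfs, max_eval = 10000, tol = 1e-10) {
  for (x in list(os, pfs)) if (!inherits(x, "survival_curve"))
    stop_validation("inputs must be survival_curve objects")
  if (curve_kind(os) != "OS" || curve_kind(pfs) != "PFS")
    stop_validation("expected one OS and one PFS curve (in that order)")
  months <- intersect(os$month, pfs$month)
  months <- sort(months[months > 0])
  if (length(months) < 3)
    stop_validation("curves must share >= 3 integer months beyond month 0")
  if (any(months != round(months)))
    stop_validation("curves must be tabulated at integer months; see interpolate_curve()")
  os_obs <- os$survival[match(months, os$month)]
  pfs_obs <- pfs$survival[match(months, pfs$month)]
  horizon <- max(months)

  # degenerate input: no PFS exits observed -> nothing identifies PD or death
  if (all(pfs_obs >= 1 - 1e-12)) {
    return(structure(list(
      matrix = transition_matrix(1, 0, 0, 1, 0),
      sse_os = sum((os_obs - 1)^2), sse_pfs = 0,
      sse = sum((os_obs - 1)^2), converged = FALSE,
      diagnostic = "flat PFS curve: no exits observed, PD and death parameters unidentifiable"),
      class = "calibration_result"))
  }

  sse_pfs_of <- function(stay) sum((pfs_obs - stay^months)^2)
  # closed-form log-linear initialiser, then 1-D refinement on PFS alone
  pos <- pfs_obs > 0
  init_stay <- if (any(pos))
    min(max(exp(mean(diff(log(c(1, pfs_obs[pos]))))), 1e-6), 1 - 1e-6)
  else 0.5
  opt1 <- stats::optimize(sse_pfs_of, c(0, 1), tol = 1e-12)
  stay_pfs <- if (sse_pfs_of(init_stay) < opt1$objective) init_stay
              else opt1$minimum

  os_model <- function(stay, share, stay_pd) {
    # death occupancy via the trace of the candidate matrix
    m <- params_to_matrix(stay, share, stay_pd)
    tr <- build_trace(m, model_config(horizon = horizon,
                                      annual_discount_rate = 0))
    1 - tr[months + 1L, "DEATH"]
  }
  objective <- function(stay, share, stay_pd)
    sum((os_obs - os_model(stay, share, stay_pd))^2) + sse_pfs_of(stay)

  # coarse deterministic grid over the two OS-linked parameters
  grid <- seq(0.05, 0.95, by = 0.05)
  best <- list(val = Inf, share = NA, stay_pd = NA)
  for (share in grid) for (stay_pd in grid) {
    v <- objective(stay_pfs, share, stay_pd)
    if (v < best$val - 1e-15) best <- list(val = v, share = share,
                                           stay_pd = stay_pd)
  }
  trace_best <- best$val  # monotone-descent tracker

  clamp01 <- function(p) pmin(pmax(p, 1e-8), 1 - 1e-8)
  # local polish: first the OS-linked pair, then all three jointly
  o2 <- stats::optim(logit(c(best$share, best$stay_pd)), function(th)
    objective(stay_pfs, expit(th[1]), expit(th[2])),
    method = "Nelder-Mead",
    control = list(maxit = max_eval %/% 2, reltol = tol))
  if (o2$value <= trace_best) {
    trace_best <- o2$value
    best$share <- expit(o2$par[1]); best$stay_pd <- expit(o2$par[2])
  }
  o3 <- stats::optim(logit(clamp01(c(stay_pfs, best$share, best$stay_pd))),
    function(th) objective(expit(th[1]), expit(th[2]), expit(th[3])),
    method = "Nelder-Mead",
    control = list(maxit = max_eval %/% 2, reltol = tol))
  if (o3$value <= trace_best) {
    trace_best <- o3$value
    stay_pfs <- expit(o3$par[1])
    best$share <- expit(o3$par[2]); best$stay_pd <- expit(o3$par[3])
  }

  m <- params_to_matrix(stay_pfs, best$share, best$stay_pd)
  sse_pfs_v <- sse_pfs_of(stay_pfs)
  sse_os_v <- trace_best - sse_pfs_v
  structure(list(matrix = m, sse_os = max(sse_os_v, 0), sse_pfs = sse_pfs_v,
                 sse = trace_best, converged = TRUE, diagnostic = NA_character_),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration %s (SSE %.3g: OS %.3g + PFS %.3g)\n",
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$sse, x$sse_os, x$sse_pfs))
  if (!x$converged) cat("  ", x$diagnostic, "\n")
  print(x$matrix)
  invisible(x)
}

#' Read / write survival curves as delimited text
#'
#' Two-column tab-delimited text with header `month<TAB>survival`.
#'
#' @param path File path.
#' @param kind `"OS"` or `"PFS"` (on read).
#' @param curve A [survival_curve()] (on write).
#' @return `read_survival_curve()` returns a [survival_curve()];
#'   `write_survival_curve()` returns `path` invisibly.
#' @export
read_survival_curve <- function(path, kind = c("OS", "PFS")) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  d <- utils::read.delim(path, header = TRUE)
  if (!all(c("month", "survival") %in% names(d)))
    stop_validation("'%s' must have header columns 'month' and 'survival'", path)
  survival_curve(d$month, d$survival, kind)
}

#' @rdname read_survival_curve
#' @export
write_survival_curve <- function(curve, path) {
  if (!inherits(curve, "survival_curve"))
    stop_validation("`curve` must be a survival_curve")
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a calibrated matrix as a config transitions block
#'
#' Writes the fitted transition probabilities in the same YAML shape the
#' packaged subgroup configs use, ready to paste into a `transitions:` block.
#'
#' @param result A `calibration_result`.
#' @param path Output YAML path.
#' @param arm Arm name to key the block by.
#' @return `path`, invisibly.
#' @export
write_calibration_config <- function(result, path, arm = "calibrated") {
  if (!inherits(result, "calibration_result"))
    stop_validation("`result` must be a calibration_result")
  m <- result$matrix
  yaml::write_yaml(list(transitions = stats::setNames(list(list(
    pfs_pfs = m$pfs_pfs, pfs_pd = m$pfs_pd, pfs_death = m$pfs_death,
    pd_pd = m$pd_pd, pd_death = m$pd_death)), arm)), path)
  invisible(path)
}
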