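#' Run the cohort through the transition matrix
#'
#' Starting with the whole cohort progression-free, applies the monthly
#' transition matrix for `config$horizon` cycles and records state occupancy
#' at every cycle boundary.
#'
#' @param matrix A [transition_matrix()].
#' @param config A [model_config()].
#' @return A `cohort_trace`: numeric matrix with rows `0..horizon` and
#'   columns `PFS`, `PD`, `DEATH`; every row sums to 1 and the death column
#'   is non-decreasing.
#' @examples
#' tr <- build_trace(transition_matrix(0.781, 0.130, 0.089, 0.9, 0.1),
#'                   model_config(horizon = 12))
#' tr[2, ]  # occupancy after one cycle: 0.781, 0.130, 0.089
#' @export
build_trace <- function(matrix, config = model_config()) {
  if (!is_transition_matrix(matrix))
    stop_validation("`matrix` must be a transition_matrix")
  if (!inherits(config, "model_config"))
    stop_validation("`config` must be a model_config")
  P <- as.matrix(matrix)
  T <- config$horizon
  occ <- base::matrix(0, nrow = T + 1L, ncol = 3L,
                      dimnames = list(cycle = 0:T, state = health_states()))
  occ[1L, ] <- c(1, 0, 0)
  for (t in seq_len(T)) occ[t + 1L, ] <- occ[t, ] %*% P
  structure(occ, class = c("cohort_trace", "matrix", "array"))
}

#' Discount factor for a model cycle
#'
#' Cycle 0 is undiscounted. With `"compound"` compounding the factor is
#' `(1 + annual)^(-cycle/12)`; with `"simple"` it is
#' `(1 + annual/12)^(-cycle)`.
#'
#' @param cycle Cycle index (vectorised), `>= 0`.
#' @param config A [model_config()].
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle, config = model_config()) {
  if (any(cycle < 0)) stop_validation("`cycle` must be >= 0")
  r <- config$annual_discount_rate
  rm <- if (config$discount_compounding == "compound")
    (1 + r)^(1 / 12) - 1 else r / 12
  (1 + rm)^(-cycle)
}

#' Accumulate discounted costs and QALYs over a trace
#'
#' Per-cycle rewards are the monthly state costs ([cost_inputs()]) and the
#' annual utilities divided by 12 ([utility_set()]). With half-cycle
#' correction the cohort is credited with the trapezoid average of the
#' occupancy at the start and end of each cycle; without it, start-of-cycle
#' occupancy is used. Rewards for cycle `t` (spanning cycle boundaries `t`
#' to `t + 1`) are discounted with [discount_factor()] at `t`, and summed
#' over `t = 0 .. horizon - 1`.
#'
#' @param trace A [build_trace()] result whose horizon matches `config`.
#' @param costs A [cost_inputs()].
#' @param utilities A [utility_set()].
#' @param config A [model_config()].
#' @return An `econ_result`: list with `cost_pfs`, `cost_pd`, `cost_total`,
#'   `qaly_pfs`, `qaly_pd`, `qaly_total` (discounted USD / QALYs).
#' @export
accumulate <- function(trace, costs, utilities, config = model_config()) {
  if (!inherits(trace, "cohort_trace"))
    stop_validation("`trace` must be a cohort_trace")
  if (!inherits(costs, "cost_inputs"))
    stop_validation("`costs` must be a cost_inputs")
  if (!inherits(utilities, "utility_set"))
    stop_validation("`utilities` must be a utility_set")
  T <- config$horizon
  if (nrow(trace) != T + 1L)
    stop_validation("trace has %d cycles but config horizon is %d",
                    nrow(trace) - 1L, T)
  occ <- unclass(trace)
  w <- if (config$half_cycle_correction)
    (occ[1:T, , drop = FALSE] + occ[2:(T + 1L), , drop = FALSE]) / 2
  else occ[1:T, , drop = FALSE]
  disc <- discount_factor(0:(T - 1L), config)
  person_time <- colSums(w * disc)  # discounted person-cycles per state
  cvec <- per_cycle_costs(costs)
  uvec <- c(utilities$pfs, utilities$pd, utilities$death) *
    config$cycle_length / 12
  structure(list(
    cost_pfs = person_time[["PFS"]] * cvec[["PFS"]],
    cost_pd = person_time[["PD"]] * cvec[["PD"]],
    cost_total = person_time[["PFS"]] * cvec[["PFS"]] +
      person_time[["PD"]] * cvec[["PD"]],
    qaly_pfs = person_time[["PFS"]] * uvec[1],
    qaly_pd = person_time[["PD"]] * uvec[2],
    qaly_total = person_time[["PFS"]] * uvec[1] + person_time[["PD"]] * uvec[2]),
    class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("Discounted cost  : %10.2f USD (PFS %.2f, PD %.2f)\n",
              x$cost_total, x$cost_pfs, x$cost_pd))
  cat(sprintf("Discounted QALYs : %10.4f     (PFS %.4f, PD %.4f)\n",
              x$qaly_total, x$qaly_pfs, x$qaly_pd))
  invisible(x)
}

#' Run one treatment arm end to end
#'
#' @param params A single-arm parameter list as returned by
#'   [load_subgroup_params()].
#' @return An `econ_result`.
#' @export
run_arm <- function(params) {
  trace <- build_trace(params$transitions, params$config)
  accumulate(trace, params$costs, params$utilities, params$config)
}

#' Incremental cost-effectiveness ratio
#'
#' Differences are taken on full-precision totals. When the intervention is
#' both cheaper and more effective (or the reverse) the ratio is not
#' interpretable and a dominance flag is set instead; a ratio is also
#' withheld when the QALY difference is numerically zero.
#'
#' @param intervention,comparator `econ_result`s from the same config.
#' @return A `ce_result`: list with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when flagged) and `dominance` (`"none"`,
#'   `"intervention_dominates"`, `"intervention_dominated"`,
#'   `"undefined"`).
#' @export
compute_icer <- function(intervention, comparator) {
  for (x in list(intervention, comparator))
    if (!inherits(x, "econ_result"))
      stop_validation("inputs must be econ_result objects")
  dc <- intervention$cost_total - comparator$cost_total
  dq <- intervention$qaly_total - comparator$qaly_total
  dominance <- "none"
  icer <- NA_real_
  if (abs(dq) < 1e-12) {
    dominance <- if (abs(dc) < 1e-9) "none" else "undefined"
  } else if (dq > 0 && dc <= 0) {
    dominance <- "intervention_dominates"
  } else if (dq < 0 && dc >= 0) {
    dominance <- "intervention_dominated"
  } else {
    icer <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental cost : %10.2f USD\n", x$delta_cost))
  cat(sprintf("Incremental QALY : %10.4f\n", x$delta_qaly))
  if (x$dominance == "none")
    cat(sprintf("ICER             : %10.2f USD/QALY\n", x$icer))
  else cat(sprintf("Dominance        : %s\n", x$dominance))
  invisible(x)
}

# Registry of scenario / sensitivity parameters. Each entry knows how to
# read its baseline from a subgroup_config and how to write a new value back.
scenario_parameters <- function() {
  cost_field <- function(arm, field) list(
    get = function(sc) sc$costs[[arm]][[field]],
    set = function(sc, v) { sc$costs[[arm]][[field]] <- v; sc })
  util_field <- function(field) list(
    get = function(sc) sc$utilities[[field]],
    set = function(sc, v) { sc$utilities[[field]] <- v; sc })
  list(
    drug_cost_pembrolizumab = cost_field("pembrolizumab", "drug"),
    drug_cost_chemotherapy = cost_field("chemotherapy", "drug"),
    test_cost_pembrolizumab = cost_field("pembrolizumab", "tests"),
    test_cost_chemotherapy = cost_field("chemotherapy", "tests"),
    ae_cost_pembrolizumab = cost_field("pembrolizumab", "ae"),
    ae_cost_chemotherapy = cost_field("chemotherapy", "ae"),
    subsequent_cost_pembrolizumab = cost_field("pembrolizumab", "subsequent"),
    subsequent_cost_chemotherapy = cost_field("chemotherapy", "subsequent"),
    utility_pfs = util_field("pfs"),
    utility_pd = util_field("pd"),
    discount_rate = list(
      get = function(sc) sc$config$annual_discount_rate,
      set = function(sc, v) {
        sc$config$annual_discount_rate <- min(max(v, 0), 1 - 1e-9); sc }))
}

#' Names of parameters available to scenarios, OWSA and PSA
#'
#' @return Character vector of registered parameter names, in registration
#'   order (drug, test, AE and subsequent-therapy costs per arm, the two
#'   living-state utilities, and the annual discount rate).
#' @export
scenario_parameter_names <- function() names(scenario_parameters())

apply_overrides <- function(sc, overrides) {
  reg <- scenario_parameters()
  bad <- setdiff(names(overrides), names(reg))
  if (length(bad))
    stop_validation("unknown parameter(s) %s; valid names: %s",
                    paste(bad, collapse = ", "),
                    paste(names(reg), collapse = ", "))
  for (nm in names(overrides)) {
    assert_scalar_number(overrides[[nm]], nm, min = 0)
    sc <- reg[[nm]]$set(sc, reg[[nm]]$get(sc) * overrides[[nm]])
  }
  # overrides may push utilities outside the base-case ordering (a one-way
  # range on u_pfs legitimately drops below u_pd); only the [0, 1] support
  # is enforced here
  sc$utilities <- structure(list(pfs = min(sc$utilities$pfs, 1),
                                 pd = min(sc$utilities$pd, 1), death = 0),
                            class = "utility_set")
  sc
}

run_config_arms <- function(sc) {
  lapply(stats::setNames(arms(), arms()), function(a)
    run_arm(list(transitions = sc$transitions[[a]], costs = sc$costs[[a]],
                 utilities = sc$utilities, config = sc$config)))
}

#' Run a two-arm comparison, optionally under parameter overrides
#'
#' `run_comparison()` evaluates both arms of a subgroup and returns the
#' incremental result; `run_scenario()` first multiplies named parameters by
#' the given factors (e.g. the pembrolizumab assistance program that funds
#' two cycles for every two bought is `drug_cost_pembrolizumab = 0.5`).
#'
#' @param subgroup Subgroup id or config path (see [load_subgroup_config()]),
#'   or a `subgroup_config` object.
#' @param overrides Named numeric vector/list of multiplicative overrides on
#'   parameters in [scenario_parameter_names()].
#' @return A `comparison_result`: list with per-arm `econ_result`s
#'   (`$arms`), the `ce_result` (`$ce`) and the `subgroup_config` used.
#' @examples
#' run_scenario("cps10", c(drug_cost_pembrolizumab = 0.5))$ce
#' @export
run_comparison <- function(subgroup) {
  sc <- if (inherits(subgroup, "subgroup_config")) subgroup
        else load_subgroup_config(subgroup)
  res <- run_config_arms(sc)
  structure(list(arms = res,
                 ce = compute_icer(res$pembrolizumab, res$chemotherapy),
                 config = sc),
            class = "comparison_result")
}

#' @rdname run_comparison
#' @export
run_scenario <- function(subgroup, overrides = NULL) {
  sc <- if (inherits(subgroup, "subgroup_config")) subgroup
        else load_subgroup_config(subgroup)
  if (!is.null(overrides) && length(overrides))
    sc <- apply_overrides(sc, as.list(overrides))
  run_comparison(sc)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Subgroup: %s\n-- pembrolizumab --\n", x$config$subgroup))
  print(x$arms$pembrolizumab)
  cat("-- chemotherapy --\n")
  print(x$arms$chemotherapy)
  cat("-- incremental --\n")
  print(x$ce)
  invisible(x)
}
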