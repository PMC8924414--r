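#' Per-cycle cost components
#'
#' Monthly cost inputs for one treatment arm. The cost charged while
#' progression-free is `drug + tests + ae` (drug acquisition, monitoring
#' tests, expected grade >= 3 adverse-event management); the cost charged
#' while in progressive disease is `subsequent` (subsequent-line therapy).
#'
#' @param drug,tests,ae,subsequent Non-negative USD per month.
#' @return A `cost_inputs` object.
#' @export
cost_inputs <- function(drug, tests, ae, subsequent) {
  for (nm in c("drug", "tests", "ae", "subsequent"))
    assert_scalar_number(get(nm), nm, min = 0)
  structure(list(drug = drug, tests = tests, ae = ae, subsequent = subsequent),
            class = "cost_inputs")
}

#' @export
print.cost_inputs <- function(x, ...) {
  cat(sprintf(
    "Monthly costs (USD): drug %.2f + tests %.2f + AE %.2f in PFS; %.2f in PD\n",
    x$drug, x$tests, x$ae, x$subsequent))
  invisible(x)
}

per_cycle_costs <- function(x) {
  c(PFS = x$drug + x$tests + x$ae, PD = x$subsequent, DEATH = 0)
}

#' Health-state utilities
#'
#' Annual utility weights for quality-adjustment; a one-month cycle spent in
#' a state contributes utility/12 QALYs before discounting. Death has
#' utility 0 and PD cannot exceed PFS.
#'
#' @param pfs,pd Utilities per year in `[0, 1]` with `pd <= pfs`.
#' @return A `utility_set` object with components `pfs`, `pd`, `death`.
#' @export
utility_set <- function(pfs = 0.75, pd = 0.67) {
  assert_scalar_number(pfs, "pfs", 0, 1)
  assert_scalar_number(pd, "pd", 0, 1)
  if (pd > pfs)
    stop_validation("utility of PD (%g) must not exceed utility of PFS (%g)",
                    pd, pfs)
  structure(list(pfs = pfs, pd = pd, death = 0), class = "utility_set")
}

#' Model run configuration
#'
#' @param horizon Number of monthly cycles (default 60 = 5 years).
#' @param cycle_length Cycle length in months (the engine is written for the
#'   native 1-month cycle).
#' @param annual_discount_rate Annual discount rate applied to both costs and
#'   effectiveness (default 0.03).
#' @param discount_compounding `"compound"` converts the annual rate to a
#'   monthly rate as `(1 + r)^(1/12) - 1`, so the per-cycle factor is
#'   `(1 + r)^(-t/12)`; `"simple"` uses `r/12` per month.
#' @param half_cycle_correction Apply the trapezoid half-cycle correction
#'   when accumulating rewards (default `TRUE`).
#' @param wtp Willingness-to-pay threshold, USD per QALY (default 11105.8,
#'   one times 2020 China GDP per capita).
#' @param cny_per_usd Exchange-rate metadata (default 6.4831); all amounts in
#'   the package are stored in USD.
#' @return A `model_config` object.
#' @export
model_config <- function(horizon = 60L, cycle_length = 1,
                         annual_discount_rate = 0.03,
                         discount_compounding = c("compound", "simple"),
                         half_cycle_correction = TRUE,
                         wtp = 11105.8, cny_per_usd = 6.4831) {
  assert_scalar_number(horizon, "horizon", 1)
  if (horizon != round(horizon))
    stop_validation("`horizon` must be a whole number of cycles")
  assert_scalar_number(cycle_length, "cycle_length", min = 1e-9)
  assert_scalar_number(annual_discount_rate, "annual_discount_rate", 0, 1 - 1e-12)
  discount_compounding <- match_choice(discount_compounding[1],
                                       c("compound", "simple"),
                                       "discount_compounding")
  if (!is.logical(half_cycle_correction) || length(half_cycle_correction) != 1L)
    stop_validation("`half_cycle_correction` must be TRUE or FALSE")
  assert_scalar_number(wtp, "wtp", min = 0)
  assert_scalar_number(cny_per_usd, "cny_per_usd", min = 0)
  structure(list(horizon = as.integer(horizon), cycle_length = cycle_length,
                 annual_discount_rate = annual_discount_rate,
                 discount_compounding = discount_compounding,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 wtp = wtp, cny_per_usd = cny_per_usd),
            class = "model_config")
}

#' Subgroups and arms packaged with the model
#'
#' @return Character vector of subgroup (or arm) identifiers.
#' @export
subgroups <- function() c("total", "cps10", "scc")

#' @rdname subgroups
#' @export
arms <- function() c("pembrolizumab", "chemotherapy")

config_path <- function(subgroup) {
  subgroup <- match_choice(subgroup, subgroups(), "subgroup")
  system.file("extdata", "params", paste0(subgroup, ".yaml"),
              package = "markovcea", mustWork = TRUE)
}

#' Load a packaged two-arm parameter set
#'
#' Reads one of the shipped subgroup configuration files (or a user file in
#' the same YAML schema) and returns validated model objects for both arms.
#'
#' @param subgroup One of `"total"`, `"cps10"` (PD-L1 combined positive
#'   score >= 10) or `"scc"` (squamous cell carcinoma), or a path to a YAML
#'   file following the packaged schema.
#' @return A `subgroup_config`: list with `subgroup`, `config`
#'   ([model_config()]), `utilities` ([utility_set()]) and per-arm
#'   `transitions` and `costs`.
#' @seealso [load_subgroup_params()] for a single arm.
#' @export
load_subgroup_config <- function(subgroup) {
  path <- if (file.exists(subgroup) && !(subgroup %in% subgroups()))
    subgroup else config_path(subgroup)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_validation("cannot parse config '%s': %s", path, conditionMessage(e)))
  for (block in c("model", "utilities", "transitions", "costs"))
    if (is.null(raw[[block]]))
      stop_validation("config '%s' is missing the '%s' block", path, block)
  m <- raw$model
  cfg <- model_config(
    horizon = m$horizon_cycles %||% 60L,
    cycle_length = m$cycle_length_months %||% 1,
    annual_discount_rate = m$annual_discount_rate %||% 0.03,
    discount_compounding = m$discount_compounding %||% "compound",
    half_cycle_correction = m$half_cycle_correction %||% TRUE,
    wtp = m$wtp_usd_per_qaly %||% 11105.8,
    cny_per_usd = m$cny_per_usd %||% 6.4831)
  if (is.null(raw$utilities$pfs) || is.null(raw$utilities$pd))
    stop_validation("config '%s': utilities block must give 'pfs' and 'pd'", path)
  util <- utility_set(pfs = raw$utilities$pfs, pd = raw$utilities$pd)
  read_arm <- function(block, arm, fn) {
    b <- raw[[block]][[arm]]
    if (is.null(b))
      stop_validation("config '%s': missing %s for arm '%s'", path, block, arm)
    fn(b)
  }
  trans <- lapply(stats::setNames(arms(), arms()), function(a)
    read_arm("transitions", a, function(b)
      transition_matrix(b$pfs_pfs, b$pfs_pd, b$pfs_death, b$pd_pd, b$pd_death)))
  costs <- lapply(stats::setNames(arms(), arms()), function(a)
    read_arm("costs", a, function(b)
      cost_inputs(b$drug, b$tests, b$ae, b$subsequent)))
  structure(list(subgroup = raw$subgroup %||% subgroup, config = cfg,
                 utilities = util, transitions = trans, costs = costs),
            class = "subgroup_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged parameters for one subgroup and arm
#'
#' Convenience accessor returning the transition matrix, monthly costs,
#' utilities, and run configuration for a single treatment arm of one of the
#' three packaged KEYNOTE-181 populations. Values are read from the shipped
#' config files; repeated calls return identical values.
#'
#' @param subgroup `"total"`, `"cps10"` or `"scc"`.
#' @param arm `"pembrolizumab"` or `"chemotherapy"`.
#' @return List with elements `transitions`, `costs`, `utilities`, `config`.
#' @examples
#' p <- load_subgroup_params("cps10", "pembrolizumab")
#' p$transitions$pfs_pfs   # 0.849
#' @export
load_subgroup_params <- function(subgroup, arm) {
  arm <- match_choice(arm, arms(), "arm")
  sc <- load_subgroup_config(subgroup)
  list(transitions = sc$transitions[[arm]], costs = sc$costs[[arm]],
       utilities = sc$utilities, config = sc$config)
}
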