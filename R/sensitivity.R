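# One-way and probabilistic sensitivity analysis.

owsa_icer <- function(res) if (res$ce$dominance == "none") res$ce$icer else
  sign(res$ce$delta_cost) * Inf

#' One-way sensitivity analysis with tornado ordering
#'
#' Each registered parameter is varied one at a time to `base * (1 - f)` and
#' `base * (1 + f)` with all others at baseline, both arms are rerun, and
#' rows are ordered by the absolute ICER spread (ties by registration
#' order; zero-spread rows last).
#'
#' @param subgroup Subgroup id, config path or `subgroup_config`.
#' @param parameters Parameter names (default: all of
#'   [scenario_parameter_names()]).
#' @param range_fraction Half-width of the relative range (default 0.20).
#' @return An `owsa_result` data frame: `parameter`, `low_value`,
#'   `high_value`, `icer_at_low`, `icer_at_high`, `spread`; the base-case
#'   ICER is attached as attribute `base_icer`.
#' @examples
#' head(run_owsa("cps10"), 3)
#' @export
run_owsa <- function(subgroup, parameters = scenario_parameter_names(),
                     range_fraction = 0.20) {
  assert_scalar_number(range_fraction, "range_fraction", 0, 1)
  sc <- if (inherits(subgroup, "subgroup_config")) subgroup
        else load_subgroup_config(subgroup)
  reg <- scenario_parameters()
  bad <- setdiff(parameters, names(reg))
  if (length(bad))
    stop_validation("unknown parameter(s) %s; valid names: %s",
                    paste(bad, collapse = ", "),
                    paste(names(reg), collapse = ", "))
  base_icer <- owsa_icer(run_comparison(sc))
  rows <- lapply(parameters, function(nm) {
    base <- reg[[nm]]$get(sc)
    lo <- owsa_icer(run_scenario(sc, stats::setNames(1 - range_fraction, nm)))
    hi <- owsa_icer(run_scenario(sc, stats::setNames(1 + range_fraction, nm)))
    data.frame(parameter = nm,
               low_value = base * (1 - range_fraction),
               high_value = base * (1 + range_fraction),
               icer_at_low = lo, icer_at_high = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  reg_order <- match(out$parameter, names(reg))
  out <- out[order(out$spread == 0, -out$spread, reg_order), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer,
            class = c("owsa_result", "data.frame"))
}

# deterministic 31-bit polynomial hash of a parameter name, used to derive
# an independent RNG substream per parameter from the root seed
name_hash <- function(name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  h
}

child_seed <- function(seed, name) (seed + name_hash(name)) %% 2147483647

draw_gamma <- function(n, mean, se_fraction) {
  if (mean == 0 || se_fraction == 0) return(rep(mean, n))
  shape <- 1 / se_fraction^2
  stats::rgamma(n, shape = shape, scale = mean * se_fraction^2)
}

draw_beta <- function(n, mean, se_fraction, name) {
  if (mean == 0 || se_fraction == 0) return(rep(mean, n))
  v <- (se_fraction * mean)^2
  if (mean * (1 - mean) <= v)
    stop_validation(
      "se_fraction %g gives invalid beta moments for '%s' (mean %g)",
      se_fraction, name, mean)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, shape1 = mean * k, shape2 = (1 - mean) * k)
}

psa_parameter_kinds <- function() {
  nms <- scenario_parameter_names()
  kinds <- ifelse(grepl("^utility_", nms), "beta",
                  ifelse(nms == "discount_rate", "fixed", "gamma"))
  stats::setNames(kinds, nms)
}

#' Probabilistic sensitivity analysis
#'
#' Draws cost parameters from gamma distributions and utilities from beta
#' distributions, each with mean at baseline and standard deviation
#' `se_fraction * mean` (method of moments), reruns both arms per draw, and
#' returns one row per draw. Transition probabilities and the discount rate
#' stay at baseline. Each parameter gets its own RNG substream seeded by a
#' stable hash of its name combined with `seed`, so draws are reproducible
#' and adding a parameter does not perturb the others.
#'
#' @param subgroup Subgroup id, config path or `subgroup_config`.
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Integer root seed (required).
#' @param se_fraction Relative standard deviation (default 0.20).
#' @return A `psa_result` data frame: `draw`, one column per sampled
#'   parameter, `cost_pembrolizumab`, `qaly_pembrolizumab`,
#'   `cost_chemotherapy`, `qaly_chemotherapy`, `delta_cost`, `delta_qaly`;
#'   attributes `seed`, `n_draws`, `se_fraction`.
#' @export
run_psa <- function(subgroup, n_draws = 10000, seed, se_fraction = 0.20) {
  if (missing(seed)) stop_validation("`seed` is required for run_psa")
  assert_scalar_number(seed, "seed", 0)
  assert_scalar_number(n_draws, "n_draws", 1)
  assert_scalar_number(se_fraction, "se_fraction", 0, 1)
  sc <- if (inherits(subgroup, "subgroup_config")) subgroup
        else load_subgroup_config(subgroup)
  reg <- scenario_parameters()
  kinds <- psa_parameter_kinds()
  varied <- names(kinds)[kinds != "fixed"]

  draws <- lapply(stats::setNames(varied, varied), function(nm) {
    base <- reg[[nm]]$get(sc)
    seed_nm <- child_seed(seed, nm)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed_nm)
    if (kinds[[nm]] == "gamma") draw_gamma(n_draws, base, se_fraction)
    else draw_beta(n_draws, base, se_fraction, nm)
  })
  # utilities: enforce pd <= pfs and the [0,1] support draw-wise by pairwise
  # min; beta draws already lie in (0,1)
  draws$utility_pd <- pmin(draws$utility_pd, draws$utility_pfs)

  # transitions are fixed across draws, so discounted half-cycle-corrected
  # person-time per state is a per-arm constant and totals are dot products
  pt <- lapply(sc$transitions, function(m) {
    trace <- build_trace(m, sc$config)
    T <- sc$config$horizon
    occ <- unclass(trace)
    w <- if (sc$config$half_cycle_correction)
      (occ[1:T, ] + occ[2:(T + 1L), ]) / 2 else occ[1:T, ]
    colSums(w * discount_factor(0:(T - 1L), sc$config))
  })
  umul <- sc$config$cycle_length / 12
  cost_arm <- function(arm) {
    p <- function(stub) draws[[paste0(stub, "_", arm)]]
    pt[[arm]][["PFS"]] * (p("drug_cost") + p("test_cost") + p("ae_cost")) +
      pt[[arm]][["PD"]] * p("subsequent_cost")
  }
  qaly_arm <- function(arm)
    (pt[[arm]][["PFS"]] * draws$utility_pfs +
     pt[[arm]][["PD"]] * draws$utility_pd) * umul

  out <- data.frame(draw = seq_len(n_draws), draws,
                    cost_pembrolizumab = cost_arm("pembrolizumab"),
                    qaly_pembrolizumab = qaly_arm("pembrolizumab"),
                    cost_chemotherapy = cost_arm("chemotherapy"),
                    qaly_chemotherapy = qaly_arm("chemotherapy"))
  out$delta_cost <- out$cost_pembrolizumab - out$cost_chemotherapy
  out$delta_qaly <- out$qaly_pembrolizumab - out$qaly_chemotherapy
  structure(out, seed = seed, n_draws = n_draws, se_fraction = se_fraction,
            class = c("psa_result", "data.frame"))
}

#' Default willingness-to-pay grid
#'
#' 0 to 250,000 USD/QALY in steps of 2,500, always including the 11,105.8
#' threshold (one times 2020 China GDP per capita).
#'
#' @return Sorted numeric vector.
#' @export
default_wtp_grid <- function() sort(unique(c(seq(0, 250000, by = 2500), 11105.8)))

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the intervention is counted
#' cost-effective in a draw when its incremental net monetary benefit
#' `lambda * delta_qaly - delta_cost` is strictly positive (ties go to the
#' comparator); probabilities across the two strategies sum to 1.
#'
#' @param samples A [run_psa()] result (or any data frame with `delta_cost`
#'   and `delta_qaly`).
#' @param wtp_grid Ascending willingness-to-pay values (default
#'   [default_wtp_grid()]).
#' @return A `ceac_curve` data frame: `wtp`, `prob_pembrolizumab`,
#'   `prob_chemotherapy`.
#' @export
ceac <- function(samples, wtp_grid = default_wtp_grid()) {
  if (!is.data.frame(samples) || nrow(samples) == 0L)
    stop_validation("`samples` must be a non-empty data frame of PSA draws")
  if (!all(c("delta_cost", "delta_qaly") %in% names(samples)))
    stop_validation("`samples` must have delta_cost and delta_qaly columns")
  if (is.unsorted(wtp_grid))
    stop_validation("`wtp_grid` must be sorted ascending")
  p_int <- vapply(wtp_grid, function(l)
    mean(l * samples$delta_qaly - samples$delta_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_pembrolizumab = p_int,
                       prob_chemotherapy = 1 - p_int),
            class = c("ceac_curve", "data.frame"))
}
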