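test_that("trace follows the chain and satisfies conservation", {
  cfg <- model_config(horizon = 12)

  # absorbing PFS keeps the whole cohort progression-free
  tr <- build_trace(transition_matrix(1, 0, 0, 0.9, 0.1), cfg)
  expect_equal(unname(tr[, "PFS"]), rep(1, 13))

  m <- transition_matrix(0.781, 0.130, 0.089, 0.900, 0.100)
  tr <- build_trace(m, cfg)
  expect_equal(unname(tr[1, ]), c(1, 0, 0))
  expect_equal(unname(tr[2, ]), c(0.781, 0.130, 0.089))
  # hand matrix multiplication for cycle 2 PD occupancy
  expect_equal(tr[3, "PD"][[1]], 0.130 * 0.900 + 0.781 * 0.130,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(tr)), rep(1, 13), tolerance = 1e-9)
  expect_true(all(diff(tr[, "DEATH"]) >= -1e-12))
})

test_that("discount factors follow the selected compounding convention", {
  cfg <- model_config()
  expect_equal(discount_factor(0, cfg), 1)
  expect_equal(discount_factor(12, cfg), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(12, model_config(annual_discount_rate = 0)), 1)
  simple <- model_config(discount_compounding = "simple")
  expect_equal(discount_factor(1, simple), 1 / (1 + 0.03 / 12), tolerance = 1e-12)
  expect_error(discount_factor(-1, cfg), class = "cea_validation_error")
})

test_that("accumulate reproduces hand-computed trapezoid sums", {
  # 2-cycle toy: PFS occupancy 1, 0.5, 0.25; cost 100/cycle, no discounting
  cfg <- model_config(horizon = 2, annual_discount_rate = 0)
  m <- transition_matrix(0.5, 0.25, 0.25, 0.5, 0.5)
  res <- accumulate(build_trace(m, cfg), toy_costs(100), utility_set(), cfg)
  expect_equal(res$cost_total, 100 * (1 + 0.5) / 2 + 100 * (0.5 + 0.25) / 2)

  # all-zero rewards give an all-zero result
  z <- accumulate(build_trace(m, cfg), toy_costs(0), utility_set(0, 0), cfg)
  expect_equal(unlist(z), c(cost_pfs = 0, cost_pd = 0, cost_total = 0,
                            qaly_pfs = 0, qaly_pd = 0, qaly_total = 0))

  # horizons must agree
  expect_error(accumulate(build_trace(m, model_config(horizon = 3)),
                          toy_costs(), utility_set(), cfg),
               "horizon", class = "cea_validation_error")
})

test_that("accumulate matches brute-force path enumeration", {
  withr::with_seed(707, {
    for (rep in 1:20) {
      T <- sample(2:5, 1)
      cfg <- model_config(horizon = T,
                          annual_discount_rate = stats::runif(1, 0, 0.1),
                          half_cycle_correction = sample(c(TRUE, FALSE), 1))
      m <- random_matrix()
      costs <- cost_inputs(stats::runif(1, 0, 5000), stats::runif(1, 0, 1000),
                           stats::runif(1, 0, 100), stats::runif(1, 0, 500))
      util <- utility_set(stats::runif(1, 0.5, 1), stats::runif(1, 0, 0.5))
      got <- accumulate(build_trace(m, cfg), costs, util, cfg)
      want <- brute_force_accumulate(m, costs, util, cfg)
      expect_equal(got$cost_total, want$cost, tolerance = 1e-9)
      expect_equal(got$qaly_total, want$qaly, tolerance = 1e-9)
      expect_equal(got$cost_total, got$cost_pfs + got$cost_pd, tolerance = 1e-6)
      expect_equal(got$qaly_total, got$qaly_pfs + got$qaly_pd, tolerance = 1e-6)
    }
  })
})

test_that("discounting never increases totals and vanishes at rate zero", {
  withr::with_seed(11, {
    m <- random_matrix()
    costs <- toy_costs(500, 50, 5, 200)
    disc <- accumulate(build_trace(m, model_config(horizon = 24)),
                       costs, utility_set(),
                       model_config(horizon = 24))
    undisc_cfg <- model_config(horizon = 24, annual_discount_rate = 0)
    undisc <- accumulate(build_trace(m, undisc_cfg), costs, utility_set(),
                         undisc_cfg)
    expect_lt(disc$cost_total, undisc$cost_total)
    expect_lt(disc$qaly_total, undisc$qaly_total)
  })
})

test_that("ICER handles ratios, dominance and degenerate QALY differences", {
  mk <- function(cost, qaly) structure(
    list(cost_pfs = cost, cost_pd = 0, cost_total = cost,
         qaly_pfs = qaly, qaly_pd = 0, qaly_total = qaly),
    class = "econ_result")
  expect_equal(compute_icer(mk(300, 1.0), mk(200, 0.5))$icer, 200)

  dom <- compute_icer(mk(100, 1.0), mk(200, 0.5))
  expect_identical(dom$dominance, "intervention_dominates")
  expect_true(is.na(dom$icer))
  dominated <- compute_icer(mk(300, 0.5), mk(200, 1.0))
  expect_identical(dominated$dominance, "intervention_dominated")

  undef <- compute_icer(mk(300, 0.5), mk(200, 0.5))
  expect_identical(undef$dominance, "undefined")
  expect_true(is.na(undef$icer))
})

test_that("ICER scales exactly with a common currency rescaling of costs", {
  withr::with_seed(23, {
    for (k in c(0.1, 6.4831, 42)) {
      sc <- load_subgroup_config("total")
      base <- run_comparison(sc)
      for (a in arms()) {
        sc$costs[[a]]$drug <- sc$costs[[a]]$drug * k
        sc$costs[[a]]$tests <- sc$costs[[a]]$tests * k
        sc$costs[[a]]$ae <- sc$costs[[a]]$ae * k
        sc$costs[[a]]$subsequent <- sc$costs[[a]]$subsequent * k
      }
      scaled <- run_comparison(sc)
      expect_equal(scaled$ce$icer, base$ce$icer * k, tolerance = 1e-12)
    }
  })
})

test_that("scenario overrides multiply the named parameters only", {
  base <- run_comparison("cps10")
  same <- run_scenario("cps10", c(drug_cost_pembrolizumab = 1.0))
  expect_equal(same$ce$icer, base$ce$icer, tolerance = 1e-12)

  half <- run_scenario("cps10", c(drug_cost_pembrolizumab = 0.5))
  expect_lt(half$ce$icer, base$ce$icer)
  # chemotherapy arm untouched
  expect_equal(half$arms$chemotherapy$cost_total,
               base$arms$chemotherapy$cost_total, tolerance = 1e-12)
  expect_error(run_scenario("cps10", c(not_a_parameter = 0.5)),
               "drug_cost_pembrolizumab", class = "cea_validation_error")
})

test_that("trace exports as a cycle-indexed CSV", {
  path <- file.path(tempdir(), "trace.csv")
  tr <- build_trace(transition_matrix(0.781, 0.130, 0.089, 0.9, 0.1),
                    model_config(horizon = 6))
  write_trace(tr, path)
  d <- utils::read.csv(path)
  expect_equal(names(d), c("cycle", "PFS", "PD", "DEATH"))
  expect_equal(nrow(d), 7)
  expect_equal(d$PFS[2], 0.781)
})
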