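test_that("zero-range OWSA collapses every row to the base-case ICER", {
  base <- run_comparison("total")$ce$icer
  res <- run_owsa("total", parameters = c("utility_pfs", "drug_cost_pembrolizumab"),
                  range_fraction = 0)
  expect_equal(res$icer_at_low, rep(base, 2), tolerance = 1e-12)
  expect_equal(res$icer_at_high, rep(base, 2), tolerance = 1e-12)
  expect_equal(res$spread, c(0, 0))
  # zero-spread rows keep registration order
  expect_equal(res$parameter, c("drug_cost_pembrolizumab", "utility_pfs"))
})

test_that("OWSA brackets the base case and orders rows by spread", {
  res <- run_owsa("cps10")
  expect_gte(nrow(res), 7)
  expect_true(all(diff(res$spread[res$spread > 0]) <= 1e-9))
  base <- attr(res, "base_icer")
  for (i in seq_len(nrow(res))) {
    lo <- min(res$icer_at_low[i], res$icer_at_high[i])
    hi <- max(res$icer_at_low[i], res$icer_at_high[i])
    expect_true(lo <= base + 1e-6 && base <= hi + 1e-6)
  }
  expect_error(run_owsa("cps10", parameters = "bogus"),
               class = "cea_validation_error")
})

test_that("tornado leaders match the populations' known drivers", {
  expect_equal(run_owsa("cps10")$parameter[1], "drug_cost_pembrolizumab")
  expect_equal(run_owsa("scc")$parameter[1], "drug_cost_pembrolizumab")
  expect_equal(run_owsa("total")$parameter[1], "utility_pd")
})

test_that("PSA is seed-reproducible and collapses at zero variance", {
  a <- run_psa("cps10", n_draws = 200, seed = 42)
  b <- run_psa("cps10", n_draws = 200, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_psa("cps10", n_draws = 200, seed = 43)
  expect_false(identical(a$delta_cost, c$delta_cost))

  base <- run_comparison("cps10")
  z <- run_psa("cps10", n_draws = 5, seed = 1, se_fraction = 0)
  expect_equal(z$delta_cost, rep(base$ce$delta_cost, 5), tolerance = 1e-9)
  expect_equal(z$delta_qaly, rep(base$ce$delta_qaly, 5), tolerance = 1e-9)
  expect_equal(z$cost_pembrolizumab,
               rep(base$arms$pembrolizumab$cost_total, 5), tolerance = 1e-9)

  expect_error(run_psa("cps10", n_draws = 5), class = "cea_validation_error")
})

test_that("PSA draws respect their supports and stay mean-consistent", {
  s <- run_psa("total", n_draws = 2000, seed = 8)
  cost_cols <- grep("cost_", names(s), value = TRUE)
  expect_true(all(as.matrix(s[cost_cols]) >= 0))
  expect_true(all(s$utility_pfs >= 0 & s$utility_pfs <= 1))
  expect_true(all(s$utility_pd <= s$utility_pfs))
  expect_equal(mean(s$drug_cost_pembrolizumab), 7370.14, tolerance = 0.02)

  # adding a parameter must not perturb another parameter's stream:
  # the drug-cost column depends only on (seed, its own name)
  full <- run_psa("total", n_draws = 50, seed = 8)
  expect_equal(full$drug_cost_pembrolizumab[1:50],
               run_psa("total", n_draws = 50, seed = 8)$drug_cost_pembrolizumab)
})

test_that("gamma and beta samplers hit their target moments", {
  withr::with_seed(77, {
    g <- markovcea:::draw_gamma(1e5, mean = 7370.14, se_fraction = 0.2)
    expect_equal(mean(g), 7370.14, tolerance = 0.02)
    expect_equal(stats::sd(g), 0.2 * 7370.14, tolerance = 0.02)
    b <- markovcea:::draw_beta(1e5, mean = 0.67, se_fraction = 0.2, "u")
    expect_equal(mean(b), 0.67, tolerance = 0.02)
    expect_equal(stats::sd(b), 0.2 * 0.67, tolerance = 0.02)
  })
  expect_error(markovcea:::draw_beta(10, mean = 0.9, se_fraction = 0.5, "u_pfs"),
               "u_pfs", class = "cea_validation_error")
})

test_that("CEAC steps at the draw ICER and is monotone for QALY-gaining draws", {
  one <- data.frame(delta_cost = 100, delta_qaly = 0.5)
  cv <- ceac(one, wtp_grid = c(0, 100, 199, 200, 201, 400))
  expect_equal(cv$prob_pembrolizumab, c(0, 0, 0, 0, 1, 1))  # ties to comparator
  expect_equal(cv$prob_pembrolizumab + cv$prob_chemotherapy, rep(1, 6))

  s <- run_psa("cps10", n_draws = 500, seed = 21)
  curve <- ceac(s)
  if (all(s$delta_qaly > 0)) expect_true(all(diff(curve$prob_pembrolizumab) >= 0))
  expect_true(all(curve$prob_pembrolizumab >= 0 & curve$prob_pembrolizumab <= 1))
  expect_true(11105.8 %in% curve$wtp)

  expect_error(ceac(one[0, ]), class = "cea_validation_error")
  expect_error(ceac(one, wtp_grid = c(10, 5)), class = "cea_validation_error")
})

test_that("a zero-variance PSA flips from 0 to 1 exactly at the base ICER", {
  base <- run_comparison("scc")$ce
  z <- run_psa("scc", n_draws = 3, seed = 1, se_fraction = 0)
  eps <- 1e-6 * base$icer
  cv <- ceac(z, wtp_grid = c(base$icer - eps, base$icer + eps))
  expect_equal(cv$prob_pembrolizumab, c(0, 1))
})
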