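test_that("degenerate one-way sweeps reproduce the base case", {
  p <- ref_params()
  base <- ref_fit()$ce$icer_per_qaly
  v <- get_param(p, "rates.apixaban.ischemic_stroke")
  sw <- univariate_sweep(p, "rates.apixaban.ischemic_stroke", v, v)
  expect_equal(sw$icer_low, base)
  expect_equal(sw$icer_high, base)
  expect_error(univariate_sweep(p, "rates.apixaban.ischemic_stroke", 2, 1),
               class = "nvafce_domain_error")
  expect_error(univariate_sweep(p, "no.such.param", 0, 1),
               class = "nvafce_domain_error")
})

test_that("a pure cost parameter moves the ICER monotonically", {
  p <- ref_params()
  base <- ref_fit()$ce$icer_per_qaly
  v <- get_param(p, "costs.drug_per_cycle.apixaban")
  sw <- univariate_sweep(p, "costs.drug_per_cycle.apixaban", v, v * 1.1)
  expect_equal(sw$icer_low, base)
  expect_gt(sw$icer_high, base)
})

test_that("the default tornado sweeps the named key inputs", {
  p <- ref_params()
  set_ <- default_tornado_set(p)
  expect_true(all(c("rates.apixaban.ischemic_stroke",
                    "rates.apixaban.other_discontinuation",
                    "rates.vka.other_discontinuation",
                    "rates.vka.ich") %in% set_))
  tw <- tornado(p, c("rates.apixaban.ischemic_stroke",
                     "costs.drug_per_cycle.apixaban"))
  expect_s3_class(tw, "nvaf_tornado")
  expect_identical(nrow(tw), 2L)
  base <- attr(tw, "base_icer")
  # monotone parameters bracket the base case
  for (i in seq_len(nrow(tw)))
    expect_true(min(tw$icer_low[i], tw$icer_high[i]) <= base + 1e-9 &&
                  max(tw$icer_low[i], tw$icer_high[i]) >= base - 1e-9)
})

test_that("method-of-moments draws have the assigned families and moments", {
  set.seed(99)
  g <- replicate(20000, nvafce:::moment_draw("gamma", 1.0, 0.2))
  # shape 25, scale 0.04: mean 1, sd 0.2
  expect_lt(abs(mean(g) - 1), 3 * 0.2 / sqrt(20000))
  expect_lt(abs(stats::sd(g) - 0.2), 0.01)
  expect_true(all(g > 0))
  b <- replicate(20000, nvafce:::moment_draw("beta", 0.8, 0.05))
  expect_lt(abs(mean(b) - 0.8), 3 * 0.05 / sqrt(20000))
  expect_true(all(b > 0 & b < 1))
  l <- replicate(20000, nvafce:::moment_draw("lognormal", 500, 125))
  expect_lt(abs(mean(l) - 500), 3 * 125 / sqrt(20000))
  expect_true(all(l > 0))
  expect_identical(nvafce:::moment_draw("gamma", 3, 0), 3)
  expect_error(nvafce:::moment_draw("beta", 1.4, 0.1),
               class = "nvafce_domain_error")
  expect_error(nvafce:::moment_draw("cauchy", 1, 1),
               class = "nvafce_domain_error")
})

zero_se_params <- function() {
  p <- ref_params()
  p$uncertainty <- lapply(p$uncertainty, function(d) { d$se <- 0; d })
  p
}

test_that("zero-variance draws return the base parameters exactly", {
  p0 <- zero_se_params()
  expect_identical(draw_psa_sample(p0, seed = 5, iteration = 3), p0)
})

test_that("probabilistic draws are seed-deterministic and parameter-local", {
  p <- ref_params()
  a <- draw_psa_sample(p, seed = 7, iteration = 1)
  b <- draw_psa_sample(p, seed = 7, iteration = 1)
  expect_identical(a, b)
  c2 <- draw_psa_sample(p, seed = 7, iteration = 2)
  expect_false(identical(a, c2))
  # dropping a descriptor leaves the remaining parameters' draws unchanged
  p_less <- p
  keep <- vapply(p$uncertainty, function(d)
    d$path != "costs.routine_care_per_cycle", logical(1))
  p_less$uncertainty <- p$uncertainty[keep]
  d_full <- draw_psa_sample(p, seed = 7, iteration = 1)
  d_less <- draw_psa_sample(p_less, seed = 7, iteration = 1)
  expect_identical(get_param(d_full, "rates.vka.ischemic_stroke"),
                   get_param(d_less, "rates.vka.ischemic_stroke"))
  expect_identical(get_param(d_full, "utilities.af_baseline"),
                   get_param(d_less, "utilities.af_baseline"))
})

test_that("zero-variance PSA equals the deterministic result exactly", {
  p0 <- zero_se_params()
  ps <- run_psa(p0, iterations = 2, seed = 3)
  ce <- ref_fit()$ce
  expect_identical(ps$draws$d_cost, rep(ce$d_cost, 2))
  expect_identical(ps$draws$d_qaly, rep(ce$d_qaly, 2))
})

test_that("the same seed reproduces a PSA bit for bit", {
  p <- ref_params()
  a <- run_psa(p, iterations = 5, seed = 42)
  b <- run_psa(p, iterations = 5, seed = 42)
  expect_identical(a, b)
  c2 <- run_psa(p, iterations = 5, seed = 43)
  expect_false(identical(a$draws, c2$draws))
})

test_that("CEAC counts strictly positive net monetary benefit", {
  hand <- list(draws = data.frame(
    d_cost = c(100, -50, 200, 0), d_qaly = c(0.01, 0.02, -0.01, 0)))
  cv <- ceac(hand, 20000)
  expect_equal(cv$probability, 0.5)
  expect_equal(ceac(hand, 0)$probability, mean(hand$draws$d_cost < 0))
  dominant <- list(draws = data.frame(d_cost = c(-10, -5), d_qaly = c(0.1, 0.2)))
  cv2 <- ceac(dominant, c(0, 20000, 30000))
  expect_equal(cv2$probability, c(1, 1, 1))
  expect_error(ceac(hand, numeric(0)), class = "nvafce_domain_error")
})

test_that("PSA output carries the configured WTP grid and iteration count", {
  p <- ref_params()
  ps <- run_psa(p, iterations = 4, seed = 1)
  expect_identical(nrow(ps$draws), 4L)
  expect_equal(ps$ceac$wtp, c(20000, 30000))
  expect_true(all(ps$ceac$probability >= 0 & ps$ceac$probability <= 1))
})

test_that("scenario grid echoes adjusted rates with exact incrementals", {
  p <- ref_params()
  sc <- run_scenarios(p)
  expect_identical(nrow(sc), 8L)  # four scenarios x two arms
  fits <- attr(sc, "fits")
  expect_identical(length(fits), 4L)
  for (id in names(fits)) {
    fit <- fits[[id]]
    row <- sc[sc$scenario == id & sc$treatment == "vka", ]
    a <- fit$arms$apixaban; v <- fit$arms$vka
    expect_identical(row$d_cost, a$cost$total - v$cost$total)
    expect_identical(row$d_qaly, a$qaly - v$qaly)
    expect_identical(row$d_ly, a$ly - v$ly)
  }
  # the low-control stratum echoes its printed inputs
  low <- sc[sc$scenario == "cTTR<52.38%", ]
  expect_equal(low$is_rate[low$treatment == "vka"], 1.787)
  expect_equal(low$is_rate[low$treatment == "apixaban"], 1.213)
})

test_that("a scenario at the base-case stratum reproduces the base case", {
  p <- ref_params()
  sc <- run_scenarios(p, list(list(id = "base",
                                   policy = list(type = "population_ttr"))))
  fit <- ref_fit()
  row <- sc[sc$treatment == "vka", ]
  expect_equal(row$cost, fit$arms$vka$cost$total)
  expect_equal(row$d_cost, fit$ce$d_cost)
  expect_equal(row$icer_per_qaly, fit$ce$icer_per_qaly)
})

test_that("numerically identical arms are labelled equal", {
  p <- symmetric_params()
  sc <- run_scenarios(p, list(list(id = "sym",
                                   policy = list(type = "population_ttr"))))
  expect_equal(sc$d_cost[sc$treatment == "vka"], 0)
  expect_equal(sc$d_qaly[sc$treatment == "vka"], 0)
  expect_identical(attr(sc, "fits")$sym$ce$dominance, "equal")
})
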