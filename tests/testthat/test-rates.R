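make_inputs <- function(...) {
  defaults <- list(dpm_T = 98600, dpm_K = 500, mmol_substrate = 0.1213,
                   dpm_added = 1.1766e7, gdw = 0.020, wt_pct_C = 9.11,
                   t_hours = 1)
  do.call(rate_inputs, modifyList(defaults, list(...)))
}

test_that("the rate equation reproduces its hand-evaluated worked example", {
  # net 98,100 DPM from a 5.3 uCi spike in a 0.1213 mmol DIC pool, 20 mg
  # dry mat at 9.11 wt% C, 1 h: hand evaluation gives 7.00 mg C (g C)-1 h-1
  res <- assimilation_rate(make_inputs())
  expect_equal(res$net_dpm, 98100)
  expect_equal(res$rate, 7.0, tolerance = 1e-3)
  expect_true(res$distinguishable_from_zero)
})

test_that("equal treatment and killed DPM give a zero rate with its error", {
  res <- assimilation_rate(make_inputs(dpm_T = 500, dpm_T_sd = 40,
                                       dpm_K_sd = 30))
  expect_equal(res$rate, 0)
  expect_equal(res$net_dpm, 0)
  expect_gt(res$se, 0)
  expect_false(res$distinguishable_from_zero)
})

test_that("rate is exactly linear in net DPM, pool size, alpha, and 1/F_s", {
  base <- assimilation_rate(make_inputs())$rate
  # doubling the net DPM doubles the rate
  doubled_net <- make_inputs(dpm_T = 500 + 2 * 98100)
  expect_equal(assimilation_rate(doubled_net)$rate, 2 * base,
               tolerance = 1e-12)
  expect_equal(assimilation_rate(make_inputs(mmol_substrate = 3 * 0.1213))$rate,
               3 * base, tolerance = 1e-12)
  r100 <- assimilation_rate(make_inputs(alpha = 1.00))$rate
  expect_equal(assimilation_rate(make_inputs(alpha = 1.05))$rate,
               1.05 * r100, tolerance = 1e-12)
  expect_equal(assimilation_rate(make_inputs(F_s = 0.5))$rate, 2 * base,
               tolerance = 1e-12)
})

test_that("dissimilation variant equals the assimilation estimator at 1/F_s scale", {
  a <- assimilation_rate(make_inputs(F_s = 1))
  d <- dissimilation_rate(make_inputs(F_s = 0.25))
  expect_equal(d$rate, 4 * a$rate, tolerance = 1e-12)
  # killed control exceeding the treatment: negative rate, flagged
  neg <- dissimilation_rate(make_inputs(dpm_T = 300, F_s = 0.25,
                                        dpm_T_sd = 20))
  expect_lt(neg$rate, 0)
  expect_false(neg$distinguishable_from_zero)
})

test_that("the estimator matches a brute-force oracle on random inputs", {
  set.seed(11)
  for (i in 1:12) {
    dpm_K <- runif(1, 100, 2000)
    args <- list(dpm_T = dpm_K + runif(1, -500, 2e5),
                 dpm_K = dpm_K,
                 mmol_substrate = runif(1, 1e-5, 0.5),
                 dpm_added = runif(1, 1e6, 2e7),
                 gdw = runif(1, 0.005, 0.1),
                 wt_pct_C = runif(1, 1, 40),
                 t_hours = runif(1, 0.5, 4),
                 F_s = runif(1, 0.1, 1),
                 nu_C = sample(1:2, 1),
                 alpha = runif(1, 1, 1.1))
    got <- do.call(rate_inputs, args)
    expect_equal(assimilation_rate(got)$rate, do.call(oracle_rate, args),
                 tolerance = 1e-10)
  }
})

test_that("first-order propagated error matches Monte-Carlo within 10%", {
  inp <- make_inputs(dpm_T_sd = 5000, dpm_K_sd = 50,
                     mmol_substrate_sd = 0.006, dpm_added_sd = 1.2e5,
                     gdw_sd = 0.002, wt_pct_C_sd = 0.5)
  prop <- assimilation_rate(inp)$se
  mc <- oracle_mc_rate_sd(inp)
  expect_equal(prop, mc, tolerance = 0.1)
})

test_that("headspace fraction follows the bottle-volume geometry", {
  expect_equal(headspace_fraction(bottle_volume = 20, liquid_solid_volume = 5,
                                  syringe_volume = 5), 0.25)
  # gravimetric route: 26.3 mL bottle, 11.3 mL contents, 5 mL syringe
  expect_equal(headspace_fraction(bottle_full_mass = 50 + 26.3 * 0.9982,
                                  bottle_empty_mass = 50,
                                  liquid_solid_volume = 11.3,
                                  syringe_volume = 5), 0.25,
               tolerance = 1e-10)
  # in the infinite-syringe limit the whole headspace is sampled
  expect_equal(headspace_fraction(bottle_volume = 26.3,
                                  liquid_solid_volume = 11.3,
                                  syringe_volume = 1e9), 1, tolerance = 1e-7)
  expect_error(headspace_fraction(bottle_volume = 10, liquid_solid_volume = 11,
                                  syringe_volume = 5), "headspace")
})

test_that("the substrate pool combines native and spike amounts correctly", {
  # trace acetate: 0.83 uM in 11 mL plus 0.71 uCi at 110 mCi/mmol, diluted
  # into 11.2 mL total liquid, is 1.4 uM
  pool <- total_substrate_mmol(0.83e-6, 11, 0.71, 110)
  expect_equal(pool[["mmol"]], 9.13e-6 + 6.4545e-6, tolerance = 1e-4)
  expect_equal(pool[["mmol"]] / 11.2 * 1e6, 1.4, tolerance = 0.01)
  # zero spike leaves the native amount unchanged
  expect_equal(total_substrate_mmol(11e-3, 11, 0, 54)[["mmol"]], 0.121)
  # DIC assay: the spike is a trace addition to a large pool
  dic <- total_substrate_mmol(11e-3, 11, 5.3, 54)
  expect_equal(dic[["mmol"]], 0.121 + 5.3e-3 / 54, tolerance = 1e-6)
  expect_lt((dic[["mmol"]] - 0.121) / dic[["mmol"]], 0.001)
  expect_error(total_substrate_mmol(-1e-3, 11, 5.3, 54), ">= 0")
})

test_that("light-driven rate is the difference with errors in quadrature", {
  l <- assimilation_rate(make_inputs(dpm_T_sd = 3000))
  d <- assimilation_rate(make_inputs(dpm_T = 3000, dpm_T_sd = 500))
  ld <- light_driven_rate(l, d)
  expect_equal(ld[["rate"]], l$rate - d$rate)
  expect_equal(ld[["se"]], sqrt(l$se^2 + d$se^2))
  # identical results difference to exactly zero
  expect_equal(light_driven_rate(l, l)[["rate"]], 0)
  # dark above light: negative, not clipped
  expect_lt(light_driven_rate(d, l)[["rate"]], 0)
  # mismatched assays are refused
  other <- assimilation_rate(make_inputs(mmol_substrate = 0.05))
  expect_error(light_driven_rate(l, other), "different assays")
})

test_that("quadrature combination matches the 9+/-1.5 vs 2+/-1.3 example", {
  expect_equal(sqrt(1.5^2 + 1.3^2), 1.985, tolerance = 1e-3)
  l <- assimilation_rate(make_inputs(dpm_T_sd = 1.5 / 7 * 98100))
  d <- assimilation_rate(make_inputs(dpm_T_sd = 1.3 / 7 * 98100))
  expect_equal(light_driven_rate(l, d)[["se"]],
               sqrt(l$se^2 + d$se^2), tolerance = 1e-12)
})

test_that("the light-vs-dark Welch contrast behaves across regimes", {
  # identical groups: one-sided p = 0.5, not significant
  same <- compare_treatments(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 0.5)
  expect_false(same$significant)
  # textbook separation: hand Welch t = 8 / sqrt(2/3) on ~4 df
  res <- compare_treatments(c(9, 10, 11), c(1, 2, 3))
  t_hand <- (10 - 2) / sqrt(1 / 3 + 1 / 3)
  expect_equal(res$p, pt(t_hand, df = 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(res$significant)
  # zero-variance groups must not divide by zero
  expect_equal(compare_treatments(c(2, 2), c(2, 2))$p, 0.5)
  expect_equal(compare_treatments(c(3, 3), c(2, 2))$p, 0)
  expect_equal(compare_treatments(c(1, 1), c(2, 2))$p, 1)
  expect_error(compare_treatments(5, c(1, 2)), "two replicates")
})

test_that("rate_inputs rejects invalid configurations", {
  expect_error(make_inputs(t_hours = 0), "positive")
  expect_error(make_inputs(F_s = 0), "\\(0, 1\\]")
  expect_error(make_inputs(F_s = 1.2), "\\(0, 1\\]")
  expect_error(make_inputs(gdw = 0), "positive")
  expect_error(make_inputs(nu_C = 3), "1 or 2")
  expect_error(make_inputs(gdw_sd = -1), ">= 0")
})
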