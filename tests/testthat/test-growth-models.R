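# Closed forms, ODE/closed-form equivalence, and the coupled two-tumor
# conservation properties.

test_that("closed forms satisfy fixed points, initial conditions and hand values", {
  # fixed points and t = 0
  expect_equal(gompertz_closed_form(500, 0.3, 500, c(0, 5, 50)),
               rep(500, 3))
  expect_equal(logistic_closed_form(500, 0.3, 500, c(0, 5, 50)), rep(500, 3))
  expect_equal(gompertz_closed_form(2.5, 0.11, 900, 0), 2.5)
  expect_equal(logistic_closed_form(2.5, 0.11, 900, 0), 2.5)
  expect_equal(exponential_closed_form(7, 0.2, 0), 7)
  expect_equal(exponential_closed_form(7, 0, 13), 7)

  # hand-evaluated values, written out from the formulas independently
  expect_equal(gompertz_closed_form(1, 0.085, 7740, 10),
               7740 * exp(log(1 / 7740) * exp(-0.85)))
  expect_equal(logistic_closed_form(50, 0.2, 100, log(3) / 0.2), 75)
  expect_equal(exponential_closed_form(2, 0.1, 10), 2 * exp(1))

  # domain errors
  expect_error(gompertz_closed_form(0, 0.1, 10, 1), "positive")
  expect_error(logistic_closed_form(1, 0.1, -1, 1), "positive")
})

test_that("ODE integration matches the closed forms to 1e-6 on dense grids", {
  times <- seq(0, 30, length.out = 60)
  tr_g <- simulate_single("gompertz", 1, 0.12, 800, times = times)
  expect_lt(max(abs(tr_g$T1 / gompertz_closed_form(1, 0.12, 800, times) - 1)),
            1e-6)
  tr_l <- simulate_single("logistic", 5, 0.2, 400, times = times)
  expect_lt(max(abs(tr_l$T1 / logistic_closed_form(5, 0.2, 400, times) - 1)),
            1e-6)
  tr_e <- simulate_single("exponential", 1, 0.1, times = times)
  expect_lt(max(abs(tr_e$T1 / exp(0.1 * times) - 1)), 1e-6)
  expect_true(all(tr_g$T2 == 0))
})

test_that("two-tumor system reduces, symmetrizes, and conserves the ratio", {
  times <- seq(0, 40, length.out = 80)

  # T2_0 = 0 reduces exactly to the single-tumor law
  p0 <- two_tumor_params(r1 = 0.09, K = 1000, T1_0 = 1, T2_0 = 0)
  tr0 <- simulate_two_tumor("gompertz", p0, times)
  single <- simulate_single("gompertz", 1, 0.09, 1000, times = times)
  expect_identical(tr0$T2, rep(0, length(times)))
  expect_equal(tr0$T1, single$T1)

  # symmetric initial sizes stay identical and approach K/2
  ps <- two_tumor_params(r1 = 0.15, K = 600, T1_0 = 2, T2_0 = 2)
  trs <- simulate_two_tumor("gompertz", ps, seq(0, 200, length.out = 100))
  expect_equal(trs$T1, trs$T2)
  expect_lt(abs(trs$T1[100] / 300 - 1), 1e-3)

  # equal rates, shared K: ratio conservation at 1e-6 for both laws
  for (law in c("gompertz", "logistic")) {
    p <- two_tumor_params(r1 = 0.1, K = 900, T1_0 = 1, phi = 0.4)
    tr <- simulate_two_tumor(law, p, times)
    expect_lt(max(abs(tr$T2 / tr$T1 - 0.4)) / 0.4, 1e-6)
    # and the summed burden collapses to the single-tumor closed form
    cf <- switch(law, gompertz = gompertz_closed_form,
                 logistic = logistic_closed_form)
    expect_lt(max(abs((tr$T1 + tr$T2) / cf(1.4, 0.1, 900, times) - 1)), 1e-5)
  }
})

test_that("shared-capacity ordering and boundedness hold along trajectories", {
  times <- seq(0, 60, length.out = 120)
  p <- two_tumor_params(r1 = 0.12, K = 500, T1_0 = 1, phi = 0.6)
  tr <- simulate_two_tumor("gompertz", p, times)
  # with T1 > T2 and equal rates the larger tumor always grows faster
  dT1 <- diff(tr$T1); dT2 <- diff(tr$T2)
  expect_true(all(dT1 > dT2))
  # the summed burden is nondecreasing and stays below K
  S <- tr$T1 + tr$T2
  expect_true(all(diff(S) >= 0))
  expect_true(all(S < 500))
})

test_that("unequal rates and individual capacities are simulated", {
  times <- seq(0, 50, length.out = 51)
  p <- two_tumor_params(r1 = 0.1, r2 = 0.07, capacity_mode = "individual_unequal",
                        K1 = 800, K2 = 300, T1_0 = 1, T2_0 = 1)
  tr <- simulate_two_tumor("gompertz", p, times)
  expect_lt(max(abs(tr$T1 / gompertz_closed_form(1, 0.1, 800, times) - 1)),
            1e-6)
  expect_lt(max(abs(tr$T2 / gompertz_closed_form(1, 0.07, 300, times) - 1)),
            1e-6)
  # shared capacity with unequal rates: ratio is NOT constant
  pu <- two_tumor_params(r1 = 0.12, r2 = 0.06, capacity_mode = "shared",
                         K = 800, T1_0 = 1, T2_0 = 1)
  tru <- simulate_two_tumor("gompertz", pu, times)
  expect_gt(diff(range(tru$T2 / tru$T1)), 0.1)
})

test_that("parameter validation catches invalid inputs", {
  expect_error(two_tumor_params(r1 = -1, K = 10), "positive")
  expect_error(two_tumor_params(r1 = 0.1, K = 10, T1_0 = 1, T2_0 = 2),
               "larger")
  expect_error(two_tumor_params(r1 = 0.1, K = 10, T1_0 = 1, T2_0 = 0.5,
                                phi = 0.5), "not both")
  expect_error(two_tumor_params(r1 = 0.1, capacity_mode = "individual_unequal",
                                K = 10), "K1")
  expect_error(simulate_single("gompertz", 1, 0.1, 100, times = c(0, 0, 1)),
               "increasing")
  p <- two_tumor_params(r1 = 0.1, K = 10)
  expect_error(simulate_two_tumor("gompertz", p, times = c(3, 2, 1)),
               "increasing")
})
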