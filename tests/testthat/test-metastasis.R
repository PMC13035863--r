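# The metastasis model: seeding function, characteristics reduction,
# interventions, counting and size distributions.

test_that("seeding_rate follows beta(x, theta) = mu (1 - theta/K) x^chi", {
  p <- metastatic_params(a_PT = 0.1, a_m = 0.1, K = 5000, mu = 0.016,
                         chi = 0.279, vartheta = 0.1, X0 = 1)
  K_cells <- 5000 * 1e6
  # vanishes at capacity and for a vanished tumor
  expect_equal(seeding_rate(1e6, K_cells, p), 0)
  expect_equal(seeding_rate(0, 1e5, p), 0)
  # chi = 0: rate independent of size (0^0 := 0 excepted)
  p0 <- metastatic_params(0.1, 0.1, 5000, 0.02, 0, 0.1, 1)
  expect_equal(seeding_rate(10, K_cells / 2, p0), 0.02 * 0.5)
  expect_equal(seeding_rate(1e8, K_cells / 2, p0), 0.02 * 0.5)
  # hand-evaluated value
  expect_equal(seeding_rate(1e6, K_cells / 2, p),
               0.016 * 0.5 * (1e6)^0.279)
  expect_error(seeding_rate(-1, 0, p), "non-negative")
})

test_that("mu = 0 collapses the model to a single Gompertz primary", {
  p <- metastatic_params(a_PT = 0.08, a_m = 0.05, K = 3000, mu = 0,
                         chi = 0.3, vartheta = 0.05, X0 = 2)
  tr <- simulate_metastatic(p, 40)
  expect_true(all(tr$N == 0))
  expect_true(all(tr$B == 0))
  x0 <- 0.05 * 2 * 1e6
  expect_lt(max(abs(tr$x_PT / gompertz_closed_form(x0, 0.08, 3000 * 1e6,
                                                   tr$times) - 1)), 1e-6)
  # seeding_off achieves the same as mu = 0
  p2 <- metastatic_params(0.08, 0.05, 3000, 0.04, 0.3, 0.05, 2)
  tr2 <- simulate_metastatic(p2, 40,
                             intervention(seeding_off = TRUE))
  expect_equal(tr2$x_PT, tr$x_PT, tolerance = 1e-10)
})

test_that("burden stays below capacity and the accounting is consistent", {
  p <- small_met_params()
  tr <- simulate_metastatic(p, 35)
  K_cells <- p$K * 1e6
  expect_true(all(tr$theta < K_cells))
  expect_true(all(diff(tr$N) >= -1e-9))
  expect_true(all(tr$B >= 0))
  expect_true(all(diff(tr$G) > 0))
  expect_equal(tr$theta, tr$x_PT + tr$M, tolerance = 1e-12)
  # counts never exceed the seeded total
  expect_lte(count_above(tr, 35, 2)$raw, max(tr$N))
  expect_equal(count_above(tr, 35, 1)$raw, max(tr$N), tolerance = 1e-8)
})

test_that("metastasis sizes follow the characteristics", {
  p <- small_met_params()
  tr <- simulate_metastatic(p, 30)
  # born at t -> one cell; a_m = 0 -> stays one cell
  expect_equal(metastasis_size(tr, 20, 20), 1)
  p0 <- metastatic_params(0.1, 0, 2000, 0.05, 0.3, 0.1, 1)
  tr0 <- simulate_metastatic(p0, 30)
  expect_equal(metastasis_size(tr0, 5, 30), 1)
  # forced constant theta = K/e: G(t) = t, size = exp(a_m (t - s))
  fake <- structure(list(times = 0:50, G = as.numeric(0:50),
                         N = as.numeric(0:50),
                         params = list(a_m = 0.07)),
                    class = "metastatic_trajectory")
  expect_equal(metastasis_size(fake, 10, 40), exp(0.07 * 30))
  expect_error(metastasis_size(tr, 25, 10), "birth_time")
  expect_error(metastasis_size(tr, 5, 60), "span")
})

test_that("count_above inverts the size threshold correctly", {
  p <- small_met_params()
  tr <- simulate_metastatic(p, 30)
  # before any seeding the count is zero (threshold above one cell)
  expect_equal(count_above(tr, 1e-6 + tr$times[2], 3500)$raw, 0)
  expect_error(count_above(tr, 10, 0.5), "at least 1")
  # self-consistency: metastases counted above thr were born before s*,
  # and one born exactly at s* has exactly size thr
  thr <- 200
  cnt <- count_above(tr, 30, thr)$raw
  ip_n <- approx(cummax(tr$N), tr$times, xout = cnt)$y
  expect_equal(metastasis_size(tr, ip_n, 30), thr, tolerance = 1e-3)
})

test_that("cumulative size distributions are monotone and anchored at N", {
  p <- small_met_params()
  tr <- simulate_metastatic(p, 30)
  grid <- c(1, 10, 100, 1000, 1e4, 1e5)
  d <- cumulative_size_distribution(tr, 30, grid)
  expect_equal(d$cumulative_count[1], max(tr$N), tolerance = 1e-8)
  expect_true(all(diff(d$cumulative_count) <= 1e-9))
  expect_equal(d$size_mm3, grid / 1e6)
  expect_error(cumulative_size_distribution(tr, 30, numeric(0)), "empty")
})

test_that("surgery with no tumor left removes the disease entirely", {
  # mu = 0: nothing was ever seeded, so resecting the primary zeroes theta
  p <- metastatic_params(0.08, 0.05, 3000, 0, 0.3, 0.05, 2)
  tr <- simulate_metastatic(p, 40, intervention(20, "resect"))
  after <- tr$times > 20
  expect_true(all(tr$theta[after] == 0))
  expect_true(all(tr$B[after] == 0))
  expect_true(all(tr$N == 0))
})

test_that("resection accelerates metastatic growth; arrest preserves the burden", {
  p <- mouse9_params()
  tr_res <- simulate_metastatic(p, 59, intervention(35, "resect"))
  tr_arr <- simulate_metastatic(p, 59, intervention(35, "arrest"))
  i_pre <- max(which(tr_res$times < 35))
  i_post <- min(which(tr_res$times > 35))
  # resect: theta drops by the primary's mass, growth rate jumps up
  rate <- function(tr, i) p$a_m * log(p$K * 1e6 / tr$theta[i])
  expect_gt(rate(tr_res, i_post), rate(tr_res, i_pre))
  expect_lt(tr_res$theta[i_post], tr_res$theta[i_pre] / 2)
  # arrest: burden continuous across the event, primary mass frozen
  expect_lt(abs(tr_arr$theta[i_post] / tr_arr$theta[i_pre] - 1), 0.05)
  i_ev <- which(tr_arr$times == 35)
  n_arr <- length(tr_arr$times)
  expect_equal(tr_arr$x_PT[n_arr], tr_arr$x_PT[i_ev], tolerance = 1e-9)
  # both dominate the no-surgery trajectory in post-surgery G
  tr_non <- simulate_metastatic(p, 59)
  n <- length(tr_non$times)
  expect_gt(tr_res$G[n], tr_non$G[n])
  expect_gt(tr_arr$G[n], tr_non$G[n])
})

test_that("suppressing seeding lets the primary grow larger (bi-directional coupling)", {
  p <- small_met_params()
  tr_on <- simulate_metastatic(p, 35)
  tr_off <- simulate_metastatic(p, 35, intervention(seeding_off = TRUE))
  n <- length(tr_on$times)
  expect_gt(max(tr_on$N), 0)
  expect_gt(tr_off$x_PT[n], tr_on$x_PT[n])
})

test_that("unit conversions are exact inverses with the published anchors", {
  expect_equal(cells_to_volume(1e6), 1)
  expect_equal(volume_to_cells(cells_to_volume(12345)), 12345)
  expect_equal(cells_to_volume(0), 0)
  expect_equal(diameter_from_cells(3500),
               2 * (3 * 0.0035 / (4 * pi))^(1 / 3))
  expect_error(cells_to_volume(-1), "non-negative")
  # area <-> volume via the spherical section formula
  expect_equal(area_to_volume(pi), 4 * pi / 3)
  expect_equal(area_to_volume(0), 0)
  expect_equal(area_to_volume(1), 4 / 3 * pi * (1 / sqrt(pi))^3)
  expect_equal(volume_to_area(area_to_volume(1)), 1, tolerance = 1e-12)
  expect_error(area_to_volume(-2), "non-negative")
})
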