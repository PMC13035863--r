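# Synthetic data generators: determinism, noise model, sacrifice rule,
# Poisson nodule sampling, fixtures.

test_that("two-tumor generation is exact at sigma 0 and seeded otherwise", {
  cfg0 <- two_tumor_config(n_mice = 2, sigma = 0, seed = 5)
  d0 <- generate_two_tumor_dataset(cfg0)
  m1 <- d0$measurements[d0$measurements$mouse_id == "m01" &
                          d0$measurements$site == "T1", ]
  tr <- simulate_two_tumor("gompertz",
                           two_tumor_params(r1 = d0$truth$r[1],
                                            K = d0$truth$K[1], T1_0 = 1,
                                            phi = d0$truth$phi[1]),
                           c(0, m1$day))
  expect_equal(m1$volume_mm3, tr$T1[-1], tolerance = 1e-8)

  cfg <- two_tumor_config(n_mice = 3, sigma = 0.05, seed = 9)
  a <- generate_two_tumor_dataset(cfg)
  b <- generate_two_tumor_dataset(cfg)
  expect_identical(a, b)
  c2 <- generate_two_tumor_dataset(two_tumor_config(n_mice = 3, sigma = 0.05,
                                                    seed = 10))
  expect_false(identical(a$measurements, c2$measurements))
  # generation does not disturb the caller's RNG
  set.seed(77); x <- runif(1); set.seed(77)
  invisible(generate_two_tumor_dataset(cfg))
  expect_identical(runif(1), x)
})

test_that("the sacrifice rule truncates at the first ceiling crossing", {
  cfg <- two_tumor_config(n_mice = 4, sigma = 0.05, seed = 13,
                          K_median = 8000, K_sd = 0, r_median = 0.12,
                          r_sd = 0, schedule = 1:60, ceiling_mm3 = 1000)
  d <- generate_two_tumor_dataset(cfg)
  for (mid in unique(d$measurements$mouse_id)) {
    m <- d$measurements[d$measurements$mouse_id == mid, ]
    w <- split(m$volume_mm3, m$site)
    over <- which(pmax(w$T1, w$T2) > 1000)
    expect_length(setdiff(over, length(w$T1)), 0)  # only the last day crosses
  }
})

test_that("metastatic generation: no seeding means no nodules; counts are Poisson-consistent", {
  cfg0 <- metastatic_config(n_mice = 2, mu = 0, seed = 3)
  d0 <- generate_metastatic_dataset(cfg0)
  expect_equal(nrow(d0$nodules), 0)

  # expected nodule count tracks the deterministic N(t_end): average over
  # seeded replicates within 3 sampling standard errors
  cfg <- metastatic_config(n_mice = 1, sigma = 0, mu = 0.05,
                           a_m_median = 0.05, a_m_sd = 0,
                           chi_median = 0.3, chi_sd = 0, K_sd = 0,
                           t_end = 40, detection_limit_cells = 1)
  p <- metastatic_params(cfg$a_PT, cfg$a_m_median, cfg$K_median, cfg$mu,
                         cfg$chi_median, cfg$vartheta, cfg$X0)
  tr <- simulate_metastatic(p, 40)
  expected <- max(tr$N)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg_i <- cfg; cfg_i$seed <- 1000L + i
    nrow(generate_metastatic_dataset(cfg_i)$nodules)
  }, numeric(1))
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("aggressive cohorts develop more nodules than indolent ones", {
  # group contrasts in the spirit of the two experimental cohorts
  agg <- metastatic_config(n_mice = 5, a_PT = 0.104, mu = 0.208,
                           vartheta = 0.014, X0 = 0.025, a_m_median = 0.120,
                           chi_median = 0.531, K_median = 6.81e3, t_end = 28,
                           seed = 41)
  ind <- metastatic_config(n_mice = 5, a_PT = 0.032, mu = 0.016,
                           vartheta = 0.011, X0 = 3, a_m_median = 0.026,
                           chi_median = 0.279, K_median = 6.80e3, t_end = 28,
                           seed = 42)
  n_agg <- nrow(generate_metastatic_dataset(agg)$nodules)
  n_ind <- nrow(generate_metastatic_dataset(ind)$nodules)
  expect_gt(n_agg, n_ind)
})

test_that("nodule areas and volumes satisfy the sphere relation exactly", {
  d <- generate_metastatic_dataset(
    metastatic_config(n_mice = 2, mu = 0.05, a_m_median = 0.05, seed = 15,
                      detection_limit_cells = 500))
  expect_gt(nrow(d$nodules), 0)
  expect_equal(d$nodules$volume_mm3, area_to_volume(d$nodules$area_mm2),
               tolerance = 1e-12)
})

test_that("the fixture suite is reproducible, fits back, and flags its outlier", {
  dir_a <- tempfile("fx_a"); dir_b <- tempfile("fx_b")
  fa <- make_fixture_suite(seed = 424242L, dir = dir_a)
  fb <- make_fixture_suite(seed = 424242L, dir = dir_b)
  for (nm in names(fa$paths))
    expect_identical(readLines(fa$paths[[nm]]), readLines(fb$paths[[nm]]),
                     label = nm)
  # outlier mouse flagged by the ratio analysis
  ra <- ratio_analysis(read_measurements(fa$paths$dt))
  expect_false(ra$verdicts[[fa$manifest$dt_drift_mouse]])
  # the single-tumor fixture refits to its manifest parameters
  st <- read_measurements(fa$paths$st)
  f <- fit_two_tumor(st, model_variant("gompertz", "individual_equal"),
                     quick_opt(seed = 6))
  expect_rel_equal(f$parameters$r1, fa$manifest$st_truth$r, 0.10)
})
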