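# Synthetic cohorts and site simulation: design counts, determinism,
# missingness masks, Beta/M conversion and the implied moment structure.

test_that("cohort generation honors the configured design", {
  cfg <- cohort_config(22, 31, country_label = 0, age_t1_mean = 62.9,
                       age_sd = 7.2, gap_range = c(8, 11.82),
                       prop_female = 0.53, n_singleton_pairs = 4,
                       seed = 99)
  coh <- make_cohort(cfg)
  expect_equal(nrow(coh), 53)
  expect_equal(sum(coh$zygosity == "MZ"), 22)
  expect_equal(sum(coh$zygosity == "DZ"), 31)
  mask <- as.matrix(coh[, c("obs_tw1_t1", "obs_tw1_t2", "obs_tw2_t1",
                            "obs_tw2_t2")])
  expect_equal(sum(rowSums(mask) == 3L), 4)   # 4 single-occasion twins
  expect_equal(sum(rowSums(mask) == 4L), 49)
  gap <- coh$age_t2 - coh$age_t1
  expect_true(all(gap >= 8 & gap <= 11.82))
  # determinism
  expect_identical(coh, make_cohort(cfg))
  # empty cohort
  expect_equal(nrow(make_cohort(cohort_config(0, 0))), 0)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(-1, 5), "non-negative")
  expect_error(cohort_config(2, 2, prop_female = 1.2), "prop_female")
  expect_error(cohort_config(2, 2, gap_range = c(11, 8)), "gap_range")
  expect_error(cohort_config(2, 2, n_singleton_pairs = 5), "exceeds")
})

test_that("the default two-cohort design matches the study layout", {
  coh <- make_cohort(default_cohorts(seed = 1))
  expect_equal(nrow(coh), 96)
  expect_equal(sum(coh$zygosity == "MZ"), 40)
  expect_equal(sum(coh$zygosity == "DZ"), 56)
  expect_equal(sum(coh$country == 0), 53)
  expect_equal(sum(coh$country == 1), 43)
  expect_false(anyDuplicated(coh$pair_id) > 0)
})

test_that("Beta/M conversion is the log2 ratio with exact round trip", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(m_to_beta(beta_to_m(0.173)), 0.173)
  expect_equal(m_to_beta(-6.25), 2^-6.25 / (1 + 2^-6.25))
  expect_error(beta_to_m(1), "strictly inside")
  expect_error(beta_to_m(0), "strictly inside")
  expect_equal(beta_to_m(1, clip = TRUE), log2((1 - 1e-6) / 1e-6))
})

test_that("masked slots never appear and simulation is seed-deterministic", {
  cfg <- cohort_config(10, 10, n_singleton_pairs = 3, seed = 5)
  coh <- make_cohort(cfg)
  d1 <- simulate_site(ade_truth(), coh, seed = 21)
  d2 <- simulate_site(ade_truth(), coh, seed = 21)
  expect_identical(d1$y, d2$y)
  mask <- as.matrix(coh[, c("obs_tw1_t1", "obs_tw1_t2", "obs_tw2_t1",
                            "obs_tw2_t2")])
  expect_equal(is.na(d1$y), !mask, ignore_attr = TRUE)
  expect_error(simulate_site(ade_truth(), make_cohort(cohort_config(0, 0))),
               "empty cohort")
})

test_that("simulated data reproduce the implied covariance structure", {
  # E-only truth: cross-twin correlation ~ 0 for MZ
  e_only <- path_params("E", e = c(1, 0, 1))
  cfg <- cohort_config(2000, 0, seed = 8)
  d <- simulate_site(e_only, make_cohort(cfg), seed = 31)
  expect_lt(abs(cor(d$y[, 1], d$y[, 3])), 0.06)

  # strong additive truth: MZ correlation ~ 1 x A-share, DZ ~ 0.5 x A-share
  p <- path_params("ADE", a = c(1, 0, 1), e = c(0.2, 0, 0.2))
  share <- 1 / (1 + 0.04)
  dm <- simulate_site(p, make_cohort(cohort_config(2000, 0, seed = 9)),
                      seed = 32)
  dd <- simulate_site(p, make_cohort(cohort_config(0, 2000, seed = 10)),
                      seed = 33)
  expect_equal(cor(dm$y[, 1], dm$y[, 3]), share, tolerance = 0.05)
  expect_equal(cor(dd$y[, 1], dd$y[, 3]), 0.5 * share, tolerance = 0.1)

  # country-1 SD scaled by k1 at occasion 1
  ps <- ade_truth(k = c(0.5, 0.88))
  d0 <- simulate_site(ps, make_cohort(cohort_config(1500, 0,
                                                    country_label = 0,
                                                    seed = 12)), seed = 34)
  d1 <- simulate_site(ps, make_cohort(cohort_config(1500, 0,
                                                    country_label = 1,
                                                    seed = 13)), seed = 35)
  expect_equal(sd(d1$y[, 1]) / sd(d0$y[, 1]), 0.5, tolerance = 0.06)
})

test_that("methylome simulation threads seeds and emits a truth table", {
  coh <- make_cohort(cohort_config(5, 5, seed = 2))
  sim <- simulate_methylome(4, ade_truth(), coh, seed = 77)
  expect_length(sim$sites, 4)
  expect_equal(nrow(sim$truth), 4)
  # standardized truth shares sum to 1 at each occasion
  expect_equal(sim$truth$std_A_1 + sim$truth$std_CD_1 + sim$truth$std_E_1,
               rep(1, 4))
  expect_equal(sim$truth$std_A_2 + sim$truth$std_CD_2 + sim$truth$std_E_2,
               rep(1, 4))
  # fixed truth -> identical truth rows
  expect_equal(unique(sim$truth$a11), sim$truth$a11[1])
  sim2 <- simulate_methylome(4, ade_truth(), coh, seed = 77)
  expect_identical(sim$sites[[2]]$y, sim2$sites[[2]]$y)
  # single site
  expect_length(simulate_methylome(1, ade_truth(), coh, seed = 1)$sites, 1)
  # function-valued truth sampler
  sampler <- function(i) if (i %% 2) ade_truth() else
    path_params("E", e = c(1, 0, 1))
  simf <- simulate_methylome(4, sampler, coh, seed = 5)
  expect_equal(simf$truth$variant, c("ADE", "E", "ADE", "E"))
})
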