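# Per-site estimation, model selection, nested tests and probe filtering.

test_that("variant fits respect nesting and AIC bookkeeping", {
  d <- simulate_site(ade_truth(), small_cohort(), seed = 11)
  fits <- fit_site(d, seed = 3)
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  for (f in fits)
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_free, tolerance = 1e-9)
  # submodel likelihood never exceeds its full model
  expect_lte(fits$AE$loglik, fits$ACE$loglik + 1e-6)
  expect_lte(fits$AE$loglik, fits$ADE$loglik + 1e-6)
  expect_lte(fits$CE$loglik, fits$ACE$loglik + 1e-6)
  expect_lte(fits$E$loglik, fits$AE$loglik + 1e-6)
  expect_lte(fits$E$loglik, fits$CE$loglik + 1e-6)
  # free-parameter counts give the stated LRT dfs
  expect_equal(fits$ACE$n_free - fits$E$n_free, 6L)
  expect_equal(fits$ADE$n_free - fits$E$n_free, 6L)
  expect_equal(fits$AE$n_free - fits$E$n_free, 3L)
  # optimizer solution matches the dataset likelihood at those parameters
  expect_equal(fits$ADE$loglik, dataset_loglik(fits$ADE$params, d),
               tolerance = 1e-8)
})

test_that("likelihood-ratio machinery clips at zero and checks nesting", {
  d <- simulate_site(ade_truth(), small_cohort(), seed = 12)
  fits <- fit_site(d, variants = c("ADE", "AE", "E"), seed = 4)
  t1 <- lrt(fits$ADE, fits$E)
  expect_equal(t1$df, 6L)
  expect_gte(t1$chi2, 0)
  expect_true(t1$p >= 0 && t1$p <= 1)
  t2 <- lrt(fits$AE, fits$E)
  expect_equal(t2$df, 3L)
  # identical logliks -> chi2 0, p 1
  fake_full <- fits$ADE
  fake_nested <- fits$AE
  fake_nested$loglik <- fake_full$loglik
  expect_equal(lrt(fake_full, fake_nested)$chi2, 0)
  expect_equal(lrt(fake_full, fake_nested)$p, 1)
  # non-nested pair errors
  ace <- twinchol(d, "ACE", seed = 5)
  expect_error(lrt(fits$ADE, ace), "not nested|identical")
  # anova method agrees with lrt
  tab <- anova(fits$E, fits$ADE)
  expect_equal(tab$chi2[2], t1$chi2)
  expect_equal(tab$df[2], 6)
})

test_that("ADE is retained on AIC ties and convergence fallbacks apply", {
  p <- ade_truth()
  ace <- fake_fit(p, loglik = -100, n_free = 16)
  ade <- fake_fit(p, loglik = -100, n_free = 16)
  expect_equal(select_best(ace, ade), "ADE")          # tie -> ADE
  ace2 <- fake_fit(p, loglik = -99, n_free = 16)      # ACE better by 2
  expect_equal(select_best(ace2, ade), "ACE")
  ace3 <- fake_fit(p, converged = FALSE)
  expect_equal(select_best(ace3, ade), "ADE")
  expect_equal(select_best(ace3, fake_fit(p, converged = FALSE)),
               NA_character_)
})

test_that("the stability refit is a 3-df test with lower likelihood", {
  d <- simulate_site(ade_truth(), small_cohort(), seed = 13)
  f <- twinchol(d, "ADE", seed = 6)
  st <- stability_test(f, d, seed = 7)
  expect_equal(st$df, 3L)
  expect_lte(st$constrained$loglik, f$loglik + 1e-6)
  expect_equal(st$constrained$params$a[["a21"]], 0)
  expect_equal(st$constrained$params$cd[["cd21"]], 0)
  expect_equal(st$constrained$params$e[["e21"]], 0)
})

test_that("probe filter applies the mean and SD bounds strictly", {
  mk <- function(mean_t2, sd_t1) {
    # e11 sets the occasion-1 SD; intercepts set the implied means
    fake_fit(path_params("ADE", a = c(0, 0, 0), cd = c(0, 0, 0),
                         e = c(sd_t1, 0, 1),
                         beta = c(t1 = 0, t2 = mean_t2, age = 0, sex = 0,
                                  country = 0)),
             sex = c(0, 0))
  }
  # mean 6.30 at t2 under one model only -> flagged
  flag <- filter_site(mk(6.30, 1), mk(0, 1))
  expect_true(flag$mean_out_of_range)
  expect_false(flag$keep)
  # boundary mean exactly 6.25 is kept (strict inequality)
  expect_true(filter_site(mk(6.25, 1), mk(-6.25, 1))$keep)
  # SDs 1.49/1.50 not flagged; 1.51 flagged
  expect_false(filter_site(mk(0, 1.49), mk(0, 1.50))$sd_out_of_range)
  expect_true(filter_site(mk(0, 1.51), mk(0, 1))$sd_out_of_range)
  expect_true(filter_site(mk(0, 1), mk(0, 1))$keep)
  # sex enters the reference mean at its sample average
  shifted <- fake_fit(path_params("ADE", e = c(1, 0, 1),
                                  beta = c(t1 = 6.0, t2 = 0, age = 0,
                                           sex = 0.5, country = 0)),
                      sex = c(1, 1))
  expect_true(filter_site(shifted, mk(0, 1))$mean_out_of_range)
})

test_that("the raw-moment filter switch uses sample moments instead", {
  y <- cbind(rnorm(20, 7, 0.1), rnorm(20, 0, 0.1),
             rnorm(20, 7, 0.1), rnorm(20, 0, 0.1))
  d <- twin_data(y, matrix(70, 20, 2), rep(0:1, 10), rep(0L, 20),
                 rep(c("MZ", "DZ"), 10))
  f <- structure(list(params = path_params("ADE", e = c(1, 0, 1)),
                      data = d), class = "twinchol")
  raw <- filter_site(f, f, moments = "raw")
  expect_true(raw$mean_out_of_range)     # raw occasion-1 mean ~ 7
  expect_false(raw$sd_out_of_range)
  expect_true(filter_site(f, f, moments = "implied")$keep)
})

test_that("the methylome scan is lossless, deterministic and fault-tolerant", {
  coh <- make_cohort(cohort_config(8, 8, seed = 21))
  sim <- simulate_methylome(3, ade_truth(), coh, seed = 22)
  scan1 <- run_methylome(sim, seed = 5)
  expect_equal(length(unique(scan1$results$site_id)), 3)
  expect_equal(nrow(scan1$results), 15)
  expect_equal(nrow(scan1$failures), 0)
  scan2 <- run_methylome(sim, seed = 5)
  expect_identical(scan1$results, scan2$results)
  # a corrupt site is recorded as a failure, the rest proceed
  sites <- sim$sites
  sites[["broken"]] <- structure(list(y = matrix(0.5, 1, 4)),
                                 class = "twin_data")
  scan3 <- run_methylome(sites, seed = 5)
  expect_equal(nrow(scan3$failures), 1)
  expect_equal(scan3$failures$site_id, "broken")
  expect_equal(length(unique(scan3$results$site_id)), 3)
})

test_that("occasion-specific covariate slopes expand the mean model", {
  d <- simulate_site(ade_truth(), small_cohort(), seed = 14)
  f0 <- twinchol(d, "ADE", seed = 8)
  f1 <- twinchol(d, "ADE", occasion_specific = TRUE, seed = 8)
  expect_equal(f1$n_free - f0$n_free, 3L)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})
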