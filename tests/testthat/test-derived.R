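# Variance decomposition, cross-time correlations, classification rules
# and across-site summaries.

test_that("standardization squares and sums the Cholesky paths", {
  p <- path_params("ADE", a = c(1, 0, 0), cd = c(1, 0, 0),
                   e = c(sqrt(2), 0, 1))
  vc <- varcomp(p)
  expect_equal(unname(vc$std["t1", ]), c(0.25, 0.25, 0.50))
  expect_equal(unname(vc$h2[["t1"]]), 0.5)     # A + D under ADE
  # occasion 2 pools the second-row paths
  p2 <- path_params("ADE", a = c(1, 0.6, 0.8), e = c(1, 0, 1))
  vc2 <- varcomp(p2)
  expect_equal(unname(vc2$abs["t2", "A"]), 0.36 + 0.64)
  # E-only model is all E
  vcE <- varcomp(path_params("E", e = c(1, 0.5, 1)))
  expect_equal(unname(vcE$std[, "E"]), c(1, 1))
  expect_equal(unname(vcE$h2), c(0, 0))
  # ACE broad heritability excludes C
  vcACE <- varcomp(path_params("ACE", a = c(1, 0, 1), cd = c(1, 0, 1),
                               e = c(1, 0, 1)))
  expect_equal(unname(vcACE$h2[["t1"]]), 1 / 3)
})

test_that("cross-time correlations follow the path formula with flags", {
  # a22 = 0 with a21 > 0: single factor, perfect correlation
  p <- path_params("ADE", a = c(1, 0.5, 0), e = c(1, 0, 1))
  expect_equal(unname(cross_time_cor(p)$r[["A"]]), 1)
  expect_true(cross_time_cor(p)$clipped[["A"]])
  # a21 = 0: zero correlation
  p0 <- path_params("ADE", a = c(1, 0, 0.5), e = c(1, 0, 1))
  expect_equal(unname(cross_time_cor(p0)$r[["A"]]), 0)
  # zero variance at an occasion: undefined and flagged
  pz <- path_params("ADE", a = c(0, 0, 1), e = c(1, 0, 1))
  ct <- cross_time_cor(pz)
  expect_true(is.na(ct$r[["A"]]))
  expect_true(ct$undefined[["A"]])
  # z = atanh(r) round-trips where defined
  pr <- path_params("ADE", a = c(0.8, 0.3, 0.4), cd = c(0.5, -0.2, 0.3),
                    e = c(1, 0.1, 1))
  ct2 <- cross_time_cor(pr)
  expect_equal(tanh(ct2$z), ct2$r, tolerance = 1e-12)
})

test_that("path correlations agree with the correlation of simulated
           latent scores", {
  set.seed(91)
  z <- matrix(rnorm(2e5 * 2), ncol = 2)
  for (i in 1:20) {
    l11 <- runif(1, 0.3, 1.5); l21 <- runif(1, -1, 1)
    l22 <- runif(1, 0.1, 1.2)
    s1 <- l11 * z[, 1]
    s2 <- l21 * z[, 1] + l22 * z[, 2]
    p <- path_params("ADE", a = c(l11, l21, l22), e = c(1, 0, 1))
    expect_lt(abs(cross_time_cor(p)$r[["A"]] - cor(s1, s2)), 0.01)
  }
})

test_that("low-stability and E-dominance rules reproduce the definitions", {
  expect_true(classify_low_stability(0.02, 0.45, 0.80))
  expect_false(classify_low_stability(0.005, 0.45, 0.45))
  expect_false(classify_low_stability(0.50, 0.95, 0.95))
  expect_equal(classify_low_stability(c(0.02, 0.005), c(0.45, 0.45),
                                      c(0.80, 0.45)),
               c(TRUE, FALSE))

  # diagnostics: correlations computed pairwise-complete per zygosity
  coh <- make_cohort(cohort_config(30, 30, seed = 41))
  d <- simulate_site(path_params("E", e = c(1, 0, 1)), coh, seed = 42)
  diag_ <- e_dominance_diagnostics(d, 0.995, 0.999)
  expect_true(diag_$e_dominated)
  expect_false(e_dominance_diagnostics(d, 0.995, 0.98)$e_dominated)
  expect_equal(dim(diag_$cors), c(2L, 2L))

  # indicator thresholds on constructed correlation patterns
  d2 <- d
  d2$y[d2$zygosity == "MZ", 3:4] <- -d2$y[d2$zygosity == "MZ", 1:2]
  diag2 <- e_dominance_diagnostics(d2, 0.995, 0.999)
  expect_true(diag2$mz_negative)
  # MZ - DZ differences of about -0.05 do not trip the -0.1 threshold
  expect_false(isTRUE(diag2$diff_negative) &&
                 all(diag2$cors["MZ", ] - diag2$cors["DZ", ] > -0.1))
})

test_that("E-dominance separates E-only from heritable truth", {
  cfg <- cohort_config(120, 130, seed = 51)
  coh <- make_cohort(cfg)
  res <- sapply(1:6, function(i) {
    d <- simulate_site(path_params("E", e = c(1, 0.1, 1)), coh,
                       seed = 600 + i)
    fits <- fit_site(d, variants = c("ACE", "ADE"), seed = 700 + i)
    best <- fits[[select_best(fits$ACE, fits$ADE)]]
    vc <- varcomp(best)
    c(vc$std["t1", "E"], vc$std["t2", "E"])
  })
  # E-only truth: non-shared share dominates at both occasions
  expect_gt(mean(res[1, ]), 0.9)
  expect_gt(mean(res[2, ]), 0.9)
  # heritable truth never trips the 99% rule
  dh <- simulate_site(ade_truth(), coh, seed = 611)
  fh <- fit_site(dh, variants = c("ACE", "ADE"), seed = 711)
  vch <- varcomp(fh[[select_best(fh$ACE, fh$ADE)]])
  expect_false(e_dominance_diagnostics(dh, vch$std["t1", "E"],
                                       vch$std["t2", "E"])$e_dominated)
})

test_that("component summaries and the paired change test behave", {
  res <- data.frame(site_id = rep(c("a", "b"), each = 5),
                    variant = rep(c("ACE", "ADE", "AE", "CE", "E"), 2),
                    is_best = rep(c(FALSE, TRUE, FALSE, FALSE, FALSE), 2),
                    std_A_1 = 0.2, std_CD_1 = 0.3, std_E_1 = 0.5,
                    std_A_2 = 0.1, std_CD_2 = 0.3, std_E_2 = 0.6,
                    abs_A_1 = 0.2, abs_CD_1 = 0.3, abs_E_1 = 0.5,
                    abs_A_2 = 0.1, abs_CD_2 = 0.3, abs_E_2 = 0.6,
                    h2_1 = 0.5, h2_2 = 0.4)
  sm <- summarize_components(res)
  ade1 <- sm[sm$group == "ADE" & sm$component == "std_E" & sm$occasion == 1, ]
  expect_equal(ade1$mean, 0.5)
  expect_equal(ade1$sd, 0)
  expect_equal(unique(sm$n_sites[sm$group == "ADE_best"]), 2L)

  pc <- paired_change_test(rep(0.5, 10), rep(0.5, 10) - 0.058)
  expect_equal(pc$mean_diff, -0.058)
  expect_equal(pc$df, 9)
  expect_true(pc$ci95[1] <= pc$mean_diff && pc$mean_diff <= pc$ci95[2])
  ident <- paired_change_test(seq(0.1, 1, length.out = 5),
                              seq(0.1, 1, length.out = 5))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("SD-heritability correlation tracks constructed dependence", {
  # sites where larger total variance comes from larger A paths
  n <- 60
  set.seed(61)
  a <- runif(n, 0.1, 1)
  res <- data.frame(total_var_1 = a^2 + 0.5, total_var_2 = a^2 + 0.6,
                    h2_1 = a^2 / (a^2 + 0.5), h2_2 = a^2 / (a^2 + 0.6))
  r <- sd_h2_correlation(res)
  expect_gt(r[["t1"]], 0.9)
  expect_gt(r[["t2"]], 0.9)
  # constant SD -> undefined with a warning
  resc <- data.frame(total_var_1 = 1, total_var_2 = 1,
                     h2_1 = runif(5), h2_2 = runif(5))
  w <- capture_warnings(rc <- sd_h2_correlation(resc))
  expect_length(w, 2)           # undefined at both occasions
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(rc[["t1"]]))
})
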