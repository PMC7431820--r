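# Probability core: component covariances, structured means, pair
# covariance sharing structure, FIML likelihood.

test_that("component_cov is the Cholesky outer product", {
  expect_equal(component_cov(1, 0, 0), matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(component_cov(1, 1, 1), matrix(c(1, 1, 1, 2), 2, 2))
  set.seed(42)
  for (i in 1:200) {
    l <- rnorm(3)
    m <- component_cov(l[1], l[2], l[3])
    L <- matrix(c(l[1], l[2], 0, l[3]), 2, 2)
    expect_equal(m, L %*% t(L))
    expect_true(all(eigen(m, symmetric = TRUE)$values > -1e-12))
  }
})

test_that("expected_pair_mean applies centered-age, sex and country terms", {
  p <- path_params("ADE", beta = c(t1 = 0, t2 = 0, age = 1, sex = 0,
                                   country = 0))
  expect_equal(unname(expected_pair_mean(p, c(74, 84), 0, 0)),
               c(0, 10, 0, 10))
  p2 <- path_params("ADE", beta = c(t1 = 1, t2 = 0, age = 0.1, sex = 0.2,
                                    country = 0.5))
  expect_equal(unname(expected_pair_mean(p2, c(84, 94), 1, 0))[1],
               1 + 1 + 0.2)
  # twins share sex/country, so within-pair slot means differ only via age
  mu <- expected_pair_mean(p2, c(70, 80, 71, 81), 1, 1)
  expect_equal(unname(mu[3] - mu[1]), 0.1 * 1)
})

test_that("pair covariance carries the MZ/DZ sharing coefficients", {
  a_only <- path_params("ADE", a = c(1, 0, 0), e = c(0, 0, 0))
  expect_equal(expected_pair_cov(a_only, "MZ")[1, 3], 1)
  expect_equal(expected_pair_cov(a_only, "DZ")[1, 3], 0.5)
  d_only <- path_params("ADE", cd = c(1, 0, 0), e = c(0, 0, 0))
  expect_equal(expected_pair_cov(d_only, "MZ")[1, 3], 1)
  expect_equal(expected_pair_cov(d_only, "DZ")[1, 3], 0.25)
  c_only <- path_params("ACE", cd = c(1, 0, 0), e = c(0, 0, 0))
  expect_equal(expected_pair_cov(c_only, "DZ")[1, 3], 1)
  e_only <- path_params("E", e = c(1, 0.3, 0.8))
  S <- expected_pair_cov(e_only, "MZ")
  expect_equal(unname(S[1:2, 3:4]), matrix(0, 2, 2))
})

test_that("country-1 covariance is the k-scaled country-0 covariance", {
  p <- ade_truth()
  S0 <- expected_pair_cov(p, "DZ", 0)
  S1 <- expected_pair_cov(p, "DZ", 1)
  kv <- c(0.9, 0.88, 0.9, 0.88)
  expect_equal(S1, S0 * tcrossprod(kv), ignore_attr = TRUE)
})

test_that("pair covariance is symmetric PSD across random admissible paths", {
  set.seed(11)
  for (i in 1:200) {
    p <- path_params("ADE",
                     a = c(abs(rnorm(1)), rnorm(1), abs(rnorm(1))),
                     cd = c(abs(rnorm(1)), rnorm(1), abs(rnorm(1))),
                     e = c(abs(rnorm(1)), rnorm(1), abs(rnorm(1))),
                     k = c(runif(1, 0.3, 2), runif(1, 0.3, 2)))
    for (z in c("MZ", "DZ")) for (cc in 0:1) {
      S <- expected_pair_cov(p, z, cc)
      expect_equal(S, t(S))
      expect_true(min(eigen(S, symmetric = TRUE)$values) > -1e-10)
    }
    # MZ cross-twin covariance dominates DZ when path products >= 0
    Smz <- expected_pair_cov(p, "MZ")
    Sdz <- expected_pair_cov(p, "DZ")
    if (p$a[2] >= 0 && p$cd[2] >= 0)
      expect_true(all(Smz[1:2, 3:4] - Sdz[1:2, 3:4] >= -1e-12))
  }
})

# helpers bypassing path_params validation for the sign-flip checks
component_flip_cov <- function(q) {
  A <- component_cov(q$a[1], q$a[2], q$a[3])
  S <- component_cov(q$cd[1], q$cd[2], q$cd[3])
  E <- component_cov(q$e[1], q$e[2], q$e[3])
  w <- A + S + E; x <- 0.5 * A + 0.25 * S
  kv <- q$k[c(1, 2, 1, 2)]
  rbind(cbind(w, x), cbind(x, w)) * tcrossprod(kv)
}
component_flip_cov2 <- function(q) {
  A <- component_cov(q$a[1], q$a[2], q$a[3])
  S <- component_cov(q$cd[1], q$cd[2], q$cd[3])
  E <- component_cov(q$e[1], q$e[2], q$e[3])
  w <- A + S + E; x <- 1 * A + 1 * S
  rbind(cbind(w, x), cbind(x, w))
}

test_that("sign conventions leave the implied covariance unchanged", {
  p <- ade_truth()
  # second-column diagonal enters only squared
  q <- p; q$a["a22"] <- -q$a["a22"]
  expect_equal(expected_pair_cov(p, "DZ", 1),
               component_flip_cov(q), ignore_attr = TRUE)
  # joint flip of a whole Cholesky column
  r <- p; r$a[c("a11", "a21")] <- -r$a[c("a11", "a21")]
  expect_equal(expected_pair_cov(p, "MZ", 0), component_flip_cov2(r),
               ignore_attr = TRUE)
})

test_that("pair_loglik equals an independent dense log-density and is
           invariant to twin relabelling", {
  p <- ade_truth()
  set.seed(3)
  y <- c(1.2, 0.9, 1.5, 1.1)
  age <- c(70, 80, 70, 80)
  for (z in c("MZ", "DZ")) for (cc in 0:1) {
    mu <- expected_pair_mean(p, age, 1, cc)
    S <- expected_pair_cov(p, z, cc)
    expect_equal(pair_loglik(p, y, age, 1, cc, z),
                 dense_mvn_logdens(y, mu, S), tolerance = 1e-12)
  }
  # single observed slot reduces to the univariate normal density
  y1 <- c(1.2, NA, NA, NA)
  mu <- expected_pair_mean(p, age, 0, 0)
  S <- expected_pair_cov(p, "MZ", 0)
  expect_equal(pair_loglik(p, y1, age, 0, 0, "MZ"),
               dnorm(1.2, mu[1], sqrt(S[1, 1]), log = TRUE),
               tolerance = 1e-12)
  # swapping twin labels permutes slots (1,2,3,4) -> (3,4,1,2)
  y <- c(1.2, NA, 1.5, 1.1)
  expect_equal(pair_loglik(p, y, age, 1, 1, "DZ"),
               pair_loglik(p, y[c(3, 4, 1, 2)], age[c(3, 4, 1, 2)], 1, 1,
                           "DZ"),
               tolerance = 1e-12)
})

test_that("dataset likelihood sums independent pair contributions", {
  p <- ade_truth()
  coh <- small_cohort()
  d <- simulate_site(p, coh, seed = 5)
  ll <- dataset_loglik(p, d)
  llR <- sum(vapply(seq_len(nrow(d$y)), function(i)
    pair_loglik(p, d$y[i, ], d$age[i, ], d$sex[i], d$country[i],
                d$zygosity[i]), 0))
  expect_equal(ll, llR, tolerance = 1e-10)
  # duplicating a pair doubles its contribution; permutation is neutral
  idx <- sample(nrow(d$y))
  expect_equal(dataset_loglik(p, d[idx]), ll, tolerance = 1e-10)
  two <- d[c(1, 1)]
  expect_equal(dataset_loglik(p, two),
               2 * pair_loglik(p, d$y[1, ], d$age[1, ], d$sex[1],
                               d$country[1], d$zygosity[1]),
               tolerance = 1e-10)
})

test_that("standardized components are invariant to the country scalars", {
  p1 <- ade_truth(k = c(1, 1))
  p2 <- ade_truth(k = c(0.5, 0.44))
  expect_equal(varcomp(p1)$std, varcomp(p2)$std)
})
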