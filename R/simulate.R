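## Synthetic twin cohorts and per-site methylation with the statistical
## structure the analysis assumes, plus generative truth for recovery
## studies. The default two-cohort design emulates a Swedish and a Danish
## aging-twin sample measured ~10 years apart.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic per-site seed derived from a master seed (kept < 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 + index) %% 2147483629) + 1L
}

#' Configuration of one synthetic twin cohort
#'
#' @param n_mz_pairs,n_dz_pairs pair counts (same-sex pairs).
#' @param country_label 0 (reference cohort) or 1 (SD-scaled cohort).
#' @param age_t1_mean,age_sd mean and SD (years) of age at occasion 1.
#' @param gap_range length-2 range (years) of the inter-occasion gap,
#'   drawn uniformly.
#' @param prop_female fraction of female pairs in `[0, 1]`; both twins of
#'   a pair share the sex draw.
#' @param n_singleton_pairs number of pairs in which one twin is observed
#'   at only one occasion.
#' @param seed optional integer seed making [make_cohort()] deterministic.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_mz_pairs, n_dz_pairs, country_label = 0,
                          age_t1_mean = 70, age_sd = 5,
                          gap_range = c(8, 11.82), prop_female = 0.5,
                          n_singleton_pairs = 0, seed = NULL) {
  if (n_mz_pairs < 0 || n_dz_pairs < 0 || n_singleton_pairs < 0)
    stop("pair counts must be non-negative")
  if (prop_female < 0 || prop_female > 1)
    stop("prop_female must lie in [0, 1]")
  if (length(gap_range) != 2L || gap_range[1] > gap_range[2])
    stop("gap_range must be (min, max) with min <= max")
  if (n_singleton_pairs > n_mz_pairs + n_dz_pairs)
    stop("n_singleton_pairs exceeds the number of pairs")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 country_label = as.integer(country_label),
                 age_t1_mean = age_t1_mean, age_sd = age_sd,
                 age_gap_mean = mean(gap_range), gap_range = gap_range,
                 prop_female = prop_female,
                 n_singleton_pairs = as.integer(n_singleton_pairs),
                 seed = seed),
            class = "cohort_config")
}

#' Default two-cohort aging-twin design
#'
#' Two same-sex twin cohorts measured about a decade apart: a Swedish-type
#' cohort (22 MZ + 31 DZ pairs, 53% female, age ~62.9 at occasion 1,
#' SD 7.2, 4 pairs with a twin observed at a single occasion) and a
#' Danish-type cohort (18 MZ + 25 DZ pairs, 72% female, age ~76.2, SD 1.8,
#' complete observation). Inter-occasion gaps are drawn uniformly on
#' 8.00-11.82 years in both.
#'
#' @param seed optional master seed split deterministically between the
#'   two cohorts.
#' @return list of two [cohort_config()] objects.
#' @export
default_cohorts <- function(seed = NULL) {
  s1 <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  s2 <- if (is.null(seed)) NULL else derive_seed(seed, 2L)
  list(
    sweden = cohort_config(22, 31, country_label = 0, age_t1_mean = 62.9,
                           age_sd = 7.2, gap_range = c(8, 11.82),
                           prop_female = 0.53, n_singleton_pairs = 4,
                           seed = s1),
    denmark = cohort_config(18, 25, country_label = 1, age_t1_mean = 76.2,
                            age_sd = 1.8, gap_range = c(8, 11.82),
                            prop_female = 0.72, n_singleton_pairs = 0,
                            seed = s2)
  )
}

#' Generate pair skeletons for one or more cohorts
#'
#' Draws ids, zygosity, shared sex, ages at both occasions and the
#' observation mask for every pair. Occasion-2 age is occasion-1 age plus
#' a uniform gap within `gap_range`. Exactly `n_singleton_pairs` pairs get
#' one twin masked at one (random) occasion.
#'
#' @param config a [cohort_config()] or a list of them.
#' @return data.frame with one row per pair: `pair_id`, `zygosity`,
#'   `country`, `sex`, `age_t1`, `age_t2`, and logical observation-mask
#'   columns `obs_tw1_t1`, `obs_tw1_t2`, `obs_tw2_t1`, `obs_tw2_t2`.
#' @export
make_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    parts <- lapply(config, make_cohort)
    out <- do.call(rbind, parts)
    out$pair_id <- sprintf("p%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    return(out)
  }
  n <- config$n_mz_pairs + config$n_dz_pairs
  empty <- data.frame(pair_id = character(), zygosity = character(),
                      country = integer(), sex = integer(),
                      age_t1 = numeric(), age_t2 = numeric(),
                      obs_tw1_t1 = logical(), obs_tw1_t2 = logical(),
                      obs_tw2_t1 = logical(), obs_tw2_t2 = logical())
  if (n == 0L) return(empty)
  with_seed(config$seed, {
    zyg <- c(rep("MZ", config$n_mz_pairs), rep("DZ", config$n_dz_pairs))
    sex <- rbinom(n, 1L, config$prop_female)
    age1 <- rnorm(n, config$age_t1_mean, config$age_sd)
    gap <- runif(n, config$gap_range[1], config$gap_range[2])
    mask <- matrix(TRUE, n, 4L)
    if (config$n_singleton_pairs > 0L) {
      idx <- sample.int(n, config$n_singleton_pairs)
      twin <- sample(1:2, config$n_singleton_pairs, replace = TRUE)
      occ <- sample(1:2, config$n_singleton_pairs, replace = TRUE)
      mask[cbind(idx, (twin - 1L) * 2L + occ)] <- FALSE
    }
    data.frame(pair_id = sprintf("p%04d", seq_len(n)), zygosity = zyg,
               country = config$country_label, sex = sex,
               age_t1 = age1, age_t2 = age1 + gap,
               obs_tw1_t1 = mask[, 1], obs_tw1_t2 = mask[, 2],
               obs_tw2_t1 = mask[, 3], obs_tw2_t2 = mask[, 4])
  })
}

#' Generative truth for one site
#'
#' @param site_id site identifier.
#' @param params generating [path_params()].
#' @return A `site_truth` object.
#' @export
site_truth <- function(site_id, params) {
  stopifnot(inherits(params, "path_params"))
  structure(list(site_id = site_id, params = params,
                 variant = params$variant),
            class = "site_truth")
}

#' Build Cholesky paths from standardized components
#'
#' Convenience inverse of [varcomp()]: given standardized shares at the
#' two occasions, cross-time source correlations and total variances,
#' returns the implied lower-triangular paths (diagonals non-negative).
#'
#' @param std_t1,std_t2 length-3 vectors of standardized (A, C/D, E)
#'   shares; each must sum to 1.
#' @param cors length-3 cross-time correlations (rA, rC/D, rE).
#' @param total_var length-2 total phenotypic variances (country-0 scale).
#' @param variant model variant for the returned [path_params()].
#' @param k,beta passed through to [path_params()].
#' @return A [path_params()] object.
#' @export
paths_from_components <- function(std_t1, std_t2, cors = c(1, 1, 0),
                                  total_var = c(1, 1), variant = "ADE",
                                  k = c(1, 1),
                                  beta = c(t1 = 0, t2 = 0, age = 0,
                                           sex = 0, country = 0)) {
  stopifnot(length(std_t1) == 3L, length(std_t2) == 3L,
            abs(sum(std_t1) - 1) < 1e-8, abs(sum(std_t2) - 1) < 1e-8,
            all(std_t1 >= 0), all(std_t2 >= 0), all(abs(cors) <= 1))
  one <- function(s1, s2, r) {
    v1 <- s1 * total_var[1]; v2 <- s2 * total_var[2]
    l11 <- sqrt(v1)
    l21 <- if (v1 > 0) r * sqrt(v2) else 0
    l22 <- sqrt(max(v2 - l21^2, 0))
    c(l11, l21, l22)
  }
  path_params(variant, a = one(std_t1[1], std_t2[1], cors[1]),
              cd = one(std_t1[2], std_t2[2], cors[2]),
              e = one(std_t1[3], std_t2[3], cors[3]), k = k, beta = beta)
}

#' Simulate one site's M-values for a cohort
#'
#' Draws each pair's observed vector from the multivariate normal implied
#' by [expected_pair_mean()] and [expected_pair_cov()] under the pair's
#' zygosity and country; masked slots are `NA`.
#'
#' @param truth a [site_truth()] (or bare [path_params()]).
#' @param cohort pair skeleton data.frame from [make_cohort()].
#' @param seed optional integer seed.
#' @return A [twin_data()] object.
#' @export
simulate_site <- function(truth, cohort, seed = NULL) {
  params <- if (inherits(truth, "site_truth")) truth$params else truth
  stopifnot(inherits(params, "path_params"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  n <- nrow(cohort)
  age <- as.matrix(cohort[, c("age_t1", "age_t2")])
  with_seed(seed, {
    y <- matrix(NA_real_, n, 4L)
    chols <- list()
    for (i in seq_len(n)) {
      key <- paste0(cohort$zygosity[i], cohort$country[i])
      if (is.null(chols[[key]]))
        chols[[key]] <- chol(expected_pair_cov(params, cohort$zygosity[i],
                                               cohort$country[i]))
      mu <- expected_pair_mean(params, age[i, ], cohort$sex[i],
                               cohort$country[i])
      y[i, ] <- mu + drop(rnorm(4L) %*% chols[[key]])
    }
    mask <- as.matrix(cohort[, c("obs_tw1_t1", "obs_tw1_t2",
                                 "obs_tw2_t1", "obs_tw2_t2")])
    y[!mask] <- NA_real_
    twin_data(y, age, cohort$sex, cohort$country, cohort$zygosity,
              cohort$pair_id,
              site_id = if (inherits(truth, "site_truth")) truth$site_id)
  })
}

#' Simulate a synthetic methylome with generative truth
#'
#' Per-site independent simulation with per-site seeds derived
#' reproducibly from the master seed.
#'
#' @param n_sites number of sites (>= 1).
#' @param truth a [site_truth()]/[path_params()] recycled to all sites, a
#'   list of them (length `n_sites`), or a function `f(site_index)`
#'   returning one.
#' @param cohort pair skeleton from [make_cohort()].
#' @param seed master integer seed.
#' @return list with `sites` (named list of [twin_data()]), `cohort` (the
#'   skeleton), and `truth` (data.frame of generating paths and
#'   standardized components per site).
#' @export
simulate_methylome <- function(n_sites, truth, cohort, seed = 1L) {
  stopifnot(n_sites >= 1L)
  get_truth <- function(i) {
    tt <- if (is.function(truth)) truth(i)
          else if (inherits(truth, c("site_truth", "path_params"))) truth
          else truth[[i]]
    p <- if (inherits(tt, "site_truth")) tt$params else tt
    site_truth(sprintf("cg%07d", i), p)
  }
  sites <- vector("list", n_sites)
  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    tt <- get_truth(i)
    sites[[i]] <- simulate_site(tt, cohort, seed = derive_seed(seed, i))
    vc <- varcomp(tt$params)
    rows[[i]] <- data.frame(site_id = tt$site_id, variant = tt$variant,
                            t(unlist(tt$params[c("a", "cd", "e", "k")])),
                            std_A_1 = vc$std[1, 1], std_CD_1 = vc$std[1, 2],
                            std_E_1 = vc$std[1, 3], std_A_2 = vc$std[2, 1],
                            std_CD_2 = vc$std[2, 2], std_E_2 = vc$std[2, 3])
  }
  names(sites) <- vapply(rows, `[[`, "", "site_id")
  list(sites = sites, cohort = cohort,
       truth = do.call(rbind, rows))
}

#' Convert Beta-values to M-values and back
#'
#' `M = log2(beta / (1 - beta))`; the inverse is the logistic
#' `beta = 2^M / (1 + 2^M)`. Beta-values of exactly 0 or 1 are a domain
#' error unless `clip = TRUE`, which first clips to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param beta methylated fraction(s) in (0, 1).
#' @param m M-value(s).
#' @param clip clip boundary Beta-values instead of erroring.
#' @return numeric vector.
#' @export
beta_to_m <- function(beta, clip = FALSE) {
  if (clip) beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly inside (0, 1); set clip = TRUE ",
         "to clip boundary values")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)
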