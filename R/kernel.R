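## Probability core: structured means, 4x4 pair covariance and FIML
## log-likelihood for the bivariate Cholesky twin model.
##
## Slot order throughout: (twin1.t1, twin1.t2, twin2.t1, twin2.t2).
## Variants: ACE, ADE (full), AE, CE, E (nested). The second familial
## source is C (shared environment, cross-twin coefficient 1 in both
## zygosities) or D (dominance, coefficient 1 in MZ and 0.25 in DZ);
## additive genetic A crosses with 1 in MZ and 0.5 in DZ; E never crosses.

VARIANTS <- c("ACE", "ADE", "AE", "CE", "E")

# age at which the time-varying age covariate is centered (years)
AGE_CENTER <- 74

#' Path parameters of a bivariate Cholesky twin model
#'
#' Container for one model variant's paths, country SD scalars and mean
#' coefficients. Each source (A, second source C or D, E) has a lower
#' triangular 2x2 Cholesky factor `(l11, l21, l22)` over the two
#' occasions; its within-person covariance contribution is `L %*% t(L)`.
#'
#' @param variant one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param a,cd,e numeric length-3 vectors `(l11, l21, l22)` for the
#'   additive, second (C or D by variant), and non-shared source. Paths of
#'   sources absent from the variant must be zero.
#' @param k numeric length-2, SD scalars `(k1, k2)` applied to country 1
#'   at occasions 1 and 2; country 0 is the reference (fixed at 1).
#' @param beta mean coefficients: either length 5
#'   `(t1, t2, age, sex, country)` with slopes shared across occasions, or
#'   length 8 `(t1, t2, age1, age2, sex1, sex2, country1, country2)` for
#'   occasion-specific slopes. Age enters centered at 74 years.
#'
#' @return An object of class `path_params`.
#' @examples
#' p <- path_params("ADE", a = c(.4, .3, .2), cd = c(.3, .2, .2),
#'                  e = c(.8, .1, .8))
#' expected_pair_cov(p, "DZ", country = 0)
#' @export
path_params <- function(variant = c("ACE", "ADE", "AE", "CE", "E"),
                        a = c(0, 0, 0), cd = c(0, 0, 0), e = c(1, 0, 1),
                        k = c(1, 1),
                        beta = c(t1 = 0, t2 = 0, age = 0, sex = 0,
                                 country = 0)) {
  variant <- match.arg(variant)
  stopifnot(length(a) == 3L, length(cd) == 3L, length(e) == 3L,
            length(k) == 2L, length(beta) %in% c(5L, 8L))
  if (variant %in% c("AE", "E") && any(cd != 0))
    stop("variant ", variant, " fixes all C/D paths at 0")
  if (variant %in% c("CE", "E") && any(a != 0))
    stop("variant ", variant, " fixes all A paths at 0")
  if (any(k <= 0)) stop("country SD scalars k must be positive")
  if (any(c(a[c(1, 3)], cd[c(1, 3)], e[c(1, 3)]) < 0))
    stop("diagonal Cholesky paths must be non-negative (sign convention)")
  second <- switch(variant, ACE = "C", ADE = "D", AE = NA_character_,
                   CE = "C", E = NA_character_)
  names(a) <- c("a11", "a21", "a22")
  names(cd) <- c("cd11", "cd21", "cd22")
  names(e) <- c("e11", "e21", "e22")
  names(k) <- c("k1", "k2")
  names(beta) <- if (length(beta) == 5L)
    c("t1", "t2", "age", "sex", "country")
  else
    c("t1", "t2", "age1", "age2", "sex1", "sex2", "country1", "country2")
  structure(list(variant = variant, second_source = second,
                 a = a, cd = cd, e = e, k = k, beta = beta),
            class = "path_params")
}

#' @export
print.path_params <- function(x, digits = 4, ...) {
  cat(sprintf("Cholesky twin-model paths (%s variant)\n", x$variant))
  m <- rbind(A = x$a, `C/D` = x$cd, E = x$e)
  colnames(m) <- c("l11", "l21", "l22")
  print(round(m, digits))
  cat("k (country-1 SD scalars):", round(x$k, digits), "\n")
  cat("mean coefficients:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' Within-person covariance contribution of one source
#'
#' For a lower-triangular Cholesky factor `L = [[l11, 0], [l21, l22]]`
#' over the two occasions, returns `L %*% t(L)`, i.e. the 2x2 covariance
#' this source contributes within a person:
#' `[[l11^2, l11*l21], [l11*l21, l21^2 + l22^2]]`.
#'
#' @param l11,l21,l22 Cholesky paths; `l11`, `l22` are the diagonal.
#' @return 2x2 symmetric positive semidefinite matrix.
#' @export
component_cov <- function(l11, l21, l22) {
  matrix(c(l11^2, l11 * l21,
           l11 * l21, l21^2 + l22^2), 2L, 2L)
}

# cross-twin weight of each source by zygosity
cross_coef <- function(source, zygosity) {
  switch(source,
         A = if (zygosity == "MZ") 1 else 0.5,
         C = 1,
         D = if (zygosity == "MZ") 1 else 0.25,
         E = 0)
}

#' Model-implied mean vector for one pair
#'
#' Slot mean = occasion intercept + beta_age * (age - 74) + beta_sex * sex
#' + beta_country * country, with slopes optionally occasion-specific.
#'
#' @param params a [path_params] object.
#' @param age ages at the four slots (length 4) or the two occasions
#'   (length 2, shared by both twins).
#' @param sex,country pair-level covariates (0/1).
#' @return numeric length-4 mean vector in slot order.
#' @export
expected_pair_mean <- function(params, age, sex, country) {
  if (length(age) == 2L) age <- age[c(1L, 2L, 1L, 2L)]
  stopifnot(length(age) == 4L)
  occ <- c(1L, 2L, 1L, 2L)
  b <- params$beta
  if (length(b) == 5L) {
    b[occ] + b["age"] * (age - AGE_CENTER) + b["sex"] * sex +
      b["country"] * country
  } else {
    b[occ] + b[c("age1", "age2")][occ] * (age - AGE_CENTER) +
      b[c("sex1", "sex2")][occ] * sex +
      b[c("country1", "country2")][occ] * country
  }
}

#' Model-implied 4x4 pair covariance
#'
#' Within-twin 2x2 blocks are A + (C or D) + E, each from
#' [component_cov()]; cross-twin blocks weight A by 1 (MZ) or 0.5 (DZ),
#' D by 1 (MZ) or 0.25 (DZ), C by 1 in both, and E by 0. For country 1
#' the matrix is pre- and post-multiplied by `diag(k1, k2, k1, k2)`.
#'
#' @param params a [path_params] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param country 0 (reference scale) or 1 (k-scaled).
#' @return 4x4 symmetric positive semidefinite covariance matrix in slot
#'   order.
#' @export
expected_pair_cov <- function(params, zygosity, country = 0) {
  stopifnot(zygosity %in% c("MZ", "DZ"), country %in% 0:1)
  A <- component_cov(params$a[1], params$a[2], params$a[3])
  S <- component_cov(params$cd[1], params$cd[2], params$cd[3])
  E <- component_cov(params$e[1], params$e[2], params$e[3])
  within <- A + S + E
  wS <- if (is.na(params$second_source)) 0 else
    cross_coef(params$second_source, zygosity)
  cross <- cross_coef("A", zygosity) * A + wS * S
  sigma <- rbind(cbind(within, cross), cbind(cross, within))
  if (country == 1L) {
    kv <- params$k[c(1L, 2L, 1L, 2L)]
    sigma <- sigma * tcrossprod(kv)
  }
  dimnames(sigma) <- list(c("tw1.t1", "tw1.t2", "tw2.t1", "tw2.t2"),
                          c("tw1.t1", "tw1.t2", "tw2.t1", "tw2.t2"))
  sigma
}

#' Log-likelihood contribution of a single twin pair
#'
#' Gaussian log-density of the pair's observed subvector under the
#' model-implied mean and covariance restricted to the observed slots
#' (full-information marginalization).
#'
#' @param params a [path_params] object.
#' @param y length-4 observation vector with `NA` for unobserved slots.
#' @param age,sex,country,zygosity pair covariates as in
#'   [expected_pair_mean()] and [expected_pair_cov()].
#' @return scalar log-likelihood; `-Inf` with a warning if the observed
#'   submatrix is not positive definite.
#' @export
pair_loglik <- function(params, y, age, sex, country, zygosity) {
  obs <- which(!is.na(y))
  if (length(obs) == 0L) stop("pair has no observed slots")
  mu <- expected_pair_mean(params, age, sex, country)
  sigma <- expected_pair_cov(params, zygosity, country)
  S <- sigma[obs, obs, drop = FALSE]
  r <- y[obs] - mu[obs]
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular observed-submatrix for this pair")
    return(-Inf)
  }
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Build the (mu, sigma-cube, group-index) representation consumed by the
# compiled likelihood. Groups: (MZ,0) (DZ,0) (MZ,1) (DZ,1) -> 0..3.
fiml_parts <- function(params, data) {
  agec <- data$age - AGE_CENTER
  occ <- c(1L, 2L, 1L, 2L)
  b <- params$beta
  n <- nrow(data$y)
  mu <- matrix(0, n, 4L)
  if (length(b) == 5L) {
    for (j in 1:4)
      mu[, j] <- b[occ[j]] + b["age"] * agec[, j] + b["sex"] * data$sex +
        b["country"] * data$country
  } else {
    bage <- b[c("age1", "age2")]; bsex <- b[c("sex1", "sex2")]
    bcty <- b[c("country1", "country2")]
    for (j in 1:4)
      mu[, j] <- b[occ[j]] + bage[occ[j]] * agec[, j] +
        bsex[occ[j]] * data$sex + bcty[occ[j]] * data$country
  }
  sigma <- array(0, c(4L, 4L, 4L))
  sigma[, , 1L] <- expected_pair_cov(params, "MZ", 0L)
  sigma[, , 2L] <- expected_pair_cov(params, "DZ", 0L)
  sigma[, , 3L] <- expected_pair_cov(params, "MZ", 1L)
  sigma[, , 4L] <- expected_pair_cov(params, "DZ", 1L)
  grp <- ifelse(data$zygosity == "MZ", 0L, 1L) + 2L * data$country
  list(mu = mu, sigma = sigma, grp = grp)
}

#' Full-information log-likelihood of a twin dataset
#'
#' Sum of independent per-pair contributions ([pair_loglik()]) over all
#' pairs of one site, evaluated through a compiled kernel.
#'
#' @param params a [path_params] object.
#' @param data a [twin_data] object.
#' @return scalar log-likelihood (`-Inf` if any observed submatrix is
#'   singular).
#' @export
dataset_loglik <- function(params, data) {
  stopifnot(inherits(data, "twin_data"))
  if (nrow(data$y) == 0L) stop("empty dataset")
  p <- fiml_parts(params, data)
  fiml_loglik_cpp(data$y, p$mu, p$sigma, p$grp)
}

# per-pair version (NA-safe diagnostics)
dataset_loglik_pairs <- function(params, data) {
  p <- fiml_parts(params, data)
  setNames(fiml_loglik_pairs_cpp(data$y, p$mu, p$sigma, p$grp), data$pair_id)
}
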