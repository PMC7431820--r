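## Maximum-likelihood fitting of one model variant at one site.
##
## Free parameters are the variant's Cholesky paths (diagonals bounded at
## zero), the mean coefficients, and the country-1 SD scalars when both
## countries are present. Optimization is quasi-Newton (L-BFGS-B) with
## numerical gradients from a moment-based start plus random restarts.

nesting_table <- list(ACE = c("AE", "CE", "E"), ADE = c("AE", "E"),
                      AE = "E", CE = "E", E = character())

# free-parameter layout for a variant / dataset combination
par_info <- function(variant, two_countries, occasion_specific,
                     constrain_cross, has_sex = TRUE, has_country = TRUE) {
  src <- switch(variant, ACE = , ADE = c("a", "cd", "e"),
                AE = c("a", "e"), CE = c("cd", "e"), E = "e")
  path_names <- unlist(lapply(src, function(s) paste0(s, c("11", "21", "22"))))
  if (constrain_cross) path_names <- path_names[!grepl("21$", path_names)]
  lower <- ifelse(grepl("(11|22)$", path_names), 0, -Inf)
  beta_names <- if (occasion_specific)
    c("b_t1", "b_t2", "b_age1", "b_age2", "b_sex1", "b_sex2",
      "b_country1", "b_country2")
  else c("b_t1", "b_t2", "b_age", "b_sex", "b_country")
  if (!has_sex) beta_names <- beta_names[!grepl("sex", beta_names)]
  if (!has_country) beta_names <- beta_names[!grepl("country", beta_names)]
  nm <- c(path_names, beta_names)
  lo <- c(lower, rep(-Inf, length(beta_names)))
  if (two_countries) {
    nm <- c(nm, "k1", "k2")
    lo <- c(lo, 1e-4, 1e-4)
  }
  list(names = nm, lower = lo, upper = rep(Inf, length(nm)),
       variant = variant, occasion_specific = occasion_specific,
       constrain_cross = constrain_cross, two_countries = two_countries,
       has_sex = has_sex, has_country = has_country)
}

# free vector -> path_params
unpack_params <- function(theta, info) {
  v <- setNames(theta, info$names)
  g <- function(n) if (n %in% info$names) unname(v[n]) else 0
  src_vec <- function(s) c(g(paste0(s, "11")), g(paste0(s, "21")),
                           g(paste0(s, "22")))
  beta <- if (info$occasion_specific)
    c(t1 = g("b_t1"), t2 = g("b_t2"), age1 = g("b_age1"),
      age2 = g("b_age2"), sex1 = g("b_sex1"), sex2 = g("b_sex2"),
      country1 = g("b_country1"), country2 = g("b_country2"))
  else
    c(t1 = g("b_t1"), t2 = g("b_t2"), age = g("b_age"), sex = g("b_sex"),
      country = g("b_country"))
  k <- if (info$two_countries) c(unname(v["k1"]), unname(v["k2"])) else c(1, 1)
  path_params(info$variant, a = src_vec("a"), cd = src_vec("cd"),
              e = src_vec("e"), k = k, beta = beta)
}

# path_params -> free vector under a layout (used for warm starts)
pack_params <- function(params, info) {
  val <- c(a11 = params$a[[1]], a21 = params$a[[2]], a22 = params$a[[3]],
           cd11 = params$cd[[1]], cd21 = params$cd[[2]],
           cd22 = params$cd[[3]],
           e11 = params$e[[1]], e21 = params$e[[2]], e22 = params$e[[3]],
           k1 = params$k[[1]], k2 = params$k[[2]])
  b <- params$beta
  if (length(b) == 5L) {
    val <- c(val, b_t1 = b[["t1"]], b_t2 = b[["t2"]], b_age = b[["age"]],
             b_sex = b[["sex"]], b_country = b[["country"]])
    if (info$occasion_specific)
      val <- c(val, b_age1 = b[["age"]], b_age2 = b[["age"]],
               b_sex1 = b[["sex"]], b_sex2 = b[["sex"]],
               b_country1 = b[["country"]], b_country2 = b[["country"]])
  } else {
    val <- c(val, b_t1 = b[["t1"]], b_t2 = b[["t2"]],
             b_age1 = b[["age1"]], b_age2 = b[["age2"]],
             b_sex1 = b[["sex1"]], b_sex2 = b[["sex2"]],
             b_country1 = b[["country1"]], b_country2 = b[["country2"]],
             b_age = mean(b[c("age1", "age2")]),
             b_sex = mean(b[c("sex1", "sex2")]),
             b_country = mean(b[c("country1", "country2")]))
  }
  out <- val[info$names]
  out[is.na(out)] <- 0
  pmax(unname(out), info$lower)
}

# zero out the sources a target (sub)variant drops; used to warm-start
# nested fits from a fuller fit
reduce_params <- function(params, to_variant) {
  a <- if (to_variant %in% c("CE", "E")) c(0, 0, 0) else params$a
  cd <- if (to_variant %in% c("AE", "E")) c(0, 0, 0) else params$cd
  path_params(to_variant, a = a, cd = cd, e = params$e, k = params$k,
              beta = params$beta)
}

# moment-based starting values: OLS means, residual variances split per
# variant from empirical MZ/DZ cross-twin covariances
moment_start <- function(data, info) {
  occ <- c(1L, 2L, 1L, 2L)
  obs <- !is.na(data$y)
  long <- data.frame(
    value = data$y[obs],
    occ = factor(occ[col(data$y)][obs], levels = 1:2),
    agec = (data$age - AGE_CENTER)[obs],
    sex = data$sex[row(data$y)][obs],
    country = data$country[row(data$y)][obs])
  form <- value ~ 0 + occ + agec
  if (info$has_sex) form <- update(form, . ~ . + sex)
  if (info$has_country) form <- update(form, . ~ . + country)
  fit <- lm(form, data = long)
  cf <- coef(fit)
  beta <- c(b_t1 = unname(cf["occ1"]), b_t2 = unname(cf["occ2"]),
            b_age = unname(cf["agec"]) %|na|% 0,
            b_sex = unname(cf["sex"]) %|na|% 0,
            b_country = unname(cf["country"]) %|na|% 0)
  res <- matrix(NA_real_, nrow(data$y), 4L)
  res[obs] <- resid(fit)

  k <- c(1, 1)
  if (info$two_countries) {
    for (t in 1:2) {
      s0 <- sd(res[data$country == 0L, c(t, t + 2L)], na.rm = TRUE)
      s1 <- sd(res[data$country == 1L, c(t, t + 2L)], na.rm = TRUE)
      if (is.finite(s0) && is.finite(s1) && s0 > 0 && s1 > 0)
        k[t] <- min(max(s1 / s0, 0.3), 3)
      res[data$country == 1L, c(t, t + 2L)] <-
        res[data$country == 1L, c(t, t + 2L)] / k[t]
    }
  }

  V <- pmax(c(var(c(res[, c(1, 3)]), na.rm = TRUE),
              var(c(res[, c(2, 4)]), na.rm = TRUE)), 1e-4)
  # within-person cross-occasion correlation
  wp <- rbind(res[, 1:2], res[, 3:4])
  wp <- wp[complete.cases(wp), , drop = FALSE]
  r12 <- if (nrow(wp) >= 3L && sd(wp[, 1]) > 0 && sd(wp[, 2]) > 0)
    min(max(cor(wp[, 1], wp[, 2]), -0.9), 0.9) else 0
  ctc <- function(zyg, t) {  # cross-twin covariance
    m <- res[data$zygosity == zyg, c(t, t + 2L), drop = FALSE]
    m <- m[complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 3L) cov(m[, 1], m[, 2]) else 0
  }
  shares <- function(t) {
    mz <- ctc("MZ", t); dz <- ctc("DZ", t); Vt <- V[t]
    cl <- function(x) min(max(x, 0.02 * Vt), 0.9 * Vt)
    out <- switch(info$variant,
      ACE = c(A = cl(2 * (mz - dz)), S = cl(2 * dz - mz)),
      ADE = c(A = cl(4 * dz - mz), S = cl(2 * mz - 4 * dz)),
      AE = c(A = cl(mz), S = 0),
      CE = c(A = 0, S = cl((mz + dz) / 2)),
      E = c(A = 0, S = 0))
    tot <- sum(out)
    if (tot > 0.9 * Vt) out <- out * 0.9 * Vt / tot
    c(out, E = Vt - sum(out))
  }
  s1 <- shares(1); s2 <- shares(2)
  paths <- function(src, key) {
    v1 <- s1[[key]]; v2 <- s2[[key]]
    l11 <- sqrt(v1)
    l21 <- if (info$constrain_cross || v1 <= 0) 0 else r12 * sqrt(v2)
    l22 <- sqrt(max(v2 - l21^2, 0.02 * V[2]))
    setNames(c(l11, l21, l22), paste0(src, c("11", "21", "22")))
  }
  theta <- c(paths("a", "A"), paths("cd", "S"), paths("e", "E"), beta,
             k1 = k[1], k2 = k[2])
  out <- theta[info$names]
  out[is.na(out)] <- 0
  pmax(unname(out), info$lower)
}

# compiled objective: negative log-likelihood and analytic gradient over
# the free-parameter vector, with a one-slot cache so optim's separate
# fn/gr calls at the same point cost a single evaluation
make_objective <- function(data, info) {
  n <- nrow(data$y)
  agec <- data$age - AGE_CENTER
  occ1 <- matrix(rep(c(1, 0, 1, 0), each = n), n, 4L)
  occ2 <- 1 - occ1
  sexm <- matrix(data$sex, n, 4L)
  ctym <- matrix(data$country, n, 4L)
  slices <- list(b_t1 = occ1, b_t2 = occ2, b_age = agec, b_sex = sexm,
                 b_country = ctym, b_age1 = agec * occ1,
                 b_age2 = agec * occ2, b_sex1 = sexm * occ1,
                 b_sex2 = sexm * occ2, b_country1 = ctym * occ1,
                 b_country2 = ctym * occ2)
  beta_names <- info$names[grepl("^b_", info$names)]
  D <- array(0, c(n, 4L, length(beta_names)))
  for (j in seq_along(beta_names)) D[, , j] <- slices[[beta_names[j]]]
  grp <- ifelse(data$zygosity == "MZ", 0L, 1L) + 2L * data$country
  path_full <- c("a11", "a21", "a22", "cd11", "cd21", "cd22",
                 "e11", "e21", "e22")
  free_paths <- intersect(info$names, path_full)
  path_pos <- match(free_paths, path_full)
  path_idx <- match(free_paths, info$names)
  beta_idx <- match(beta_names, info$names)
  k_present <- "k1" %in% info$names
  k_idx <- match(c("k1", "k2"), info$names)
  hasS <- info$variant %in% c("ACE", "ADE", "CE")
  wSdz <- if (info$variant == "ADE") 0.25 else 1
  cache <- new.env(parent = emptyenv())
  evalc <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    paths <- numeric(9L)
    paths[path_pos] <- theta[path_idx]
    kk <- if (k_present) theta[k_idx] else c(1, 1)
    res <- twin_negll_grad_cpp(paths, kk, theta[beta_idx], data$y, D, grp,
                               wSdz, hasS, k_present)
    gfree <- numeric(length(theta))
    gfree[path_idx] <- res$grad[path_pos]
    gfree[beta_idx] <- res$grad[11L + seq_along(beta_names)]
    if (k_present) gfree[k_idx] <- res$grad[10:11]
    cache$theta <- theta
    cache$res <- list(value = res$value, grad = gfree)
    cache$res
  }
  list(fn = function(th) evalc(th)$value,
       gr = function(th) evalc(th)$grad)
}

perturb_start <- function(theta, info, scale = 1) {
  out <- theta
  pathish <- grepl("^(a|cd|e)", info$names)
  diagp <- pathish & grepl("(11|22)$", info$names)
  offp <- pathish & grepl("21$", info$names)
  amp <- max(mean(abs(theta[diagp])), 0.05)
  out[diagp] <- theta[diagp] * exp(rnorm(sum(diagp), 0, 0.4 * scale))
  out[offp] <- theta[offp] + rnorm(sum(offp), 0, 0.3 * amp * scale)
  bb <- grepl("^b_", info$names)
  out[bb] <- theta[bb] + rnorm(sum(bb), 0, 0.1 * amp * scale)
  kk <- grepl("^k", info$names)
  out[kk] <- theta[kk] * exp(rnorm(sum(kk), 0, 0.2 * scale))
  pmax(out, info$lower)
}

#' Fit a bivariate Cholesky twin model to one site
#'
#' Full-information maximum likelihood over twin pairs for one model
#' variant. Diagonal paths are constrained non-negative; the country-1 SD
#' scalars `k1`, `k2` are estimated only when both countries are present.
#' The optimizer runs from a moment-based start (OLS means; variance
#' split from empirical MZ/DZ cross-twin covariances) plus random
#' restarts, and keeps the best converged solution.
#'
#' @param data a [twin_data()] object (at least 2 pairs).
#' @param variant model variant: `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param occasion_specific if `TRUE`, age/sex/country slopes are
#'   occasion-specific instead of shared.
#' @param constrain_cross if `TRUE`, all cross-occasion paths (`a21`,
#'   `cd21`, `e21`) are fixed at 0 (the stability null model).
#' @param start optional [path_params()] used as an additional start.
#' @param extra_starts optional list of [path_params()] warm starts.
#' @param n_random_starts random restarts beyond the moment start
#'   (default 3).
#' @param seed optional seed for the restarts.
#' @param control passed to [stats::optim()] (`maxit`, `factr`, ...).
#' @return An object of class `twinchol` with components `params`,
#'   `coefficients`, `loglik`, `n_free`, `aic`, `converged`,
#'   `n_pairs_used`.
#' @seealso [varcomp()], [cross_time_cor()], [anova.twinchol()]
#' @export
twinchol <- function(data, variant = c("ACE", "ADE", "AE", "CE", "E"),
                     occasion_specific = FALSE, constrain_cross = FALSE,
                     start = NULL, extra_starts = NULL,
                     n_random_starts = 3L, seed = NULL, control = list()) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "twin_data"))
  if (nrow(data$y) < 2L) stop("need at least 2 pairs to fit")
  info <- par_info(variant,
                   two_countries = length(unique(data$country)) > 1L,
                   occasion_specific = occasion_specific,
                   constrain_cross = constrain_cross,
                   has_sex = length(unique(data$sex)) > 1L,
                   has_country = length(unique(data$country)) > 1L)
  obj <- make_objective(data, info)
  negll <- obj$fn
  base_start <- moment_start(data, info)
  starts <- list(base_start)
  for (p in c(list(start), extra_starts)) {
    if (is.null(p)) next
    starts[[length(starts) + 1L]] <- pack_params(p, info)
  }
  if (n_random_starts > 0L)
    starts <- c(starts, with_seed(seed, lapply(seq_len(n_random_starts),
                  function(i) perturb_start(base_start, info))))
  ctrl <- utils::modifyList(list(maxit = 400L, factr = 1e7, pgtol = 1e-8),
                            control)
  best <- NULL
  for (s in starts) {
    if (!is.finite(negll(s))) {  # inflate E variance until feasible
      for (j in which(grepl("^e(11|22)$", info$names))) s[j] <- max(s[j], 0.5)
      if (!is.finite(negll(s))) next
    }
    ctrl$parscale <- pmax(abs(s), 0.1)
    opt <- tryCatch(
      optim(s, negll, obj$gr, method = "L-BFGS-B", lower = info$lower,
            upper = info$upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) ||
        (opt$convergence == 0 && best$convergence != 0) ||
        (opt$value < best$value &&
         !(opt$convergence != 0 && best$convergence == 0)))
      best <- opt
  }
  if (is.null(best))
    stop("no start produced a finite likelihood for variant ", variant)
  theta <- setNames(best$par, info$names)
  params <- unpack_params(theta, info)
  ll <- -best$value
  n_free <- length(theta)
  structure(list(variant = variant, params = params, coefficients = theta,
                 loglik = ll, n_free = n_free, aic = -2 * ll + 2 * n_free,
                 converged = best$convergence == 0,
                 n_pairs_used = nrow(data$y), n_obs = sum(!is.na(data$y)),
                 occasion_specific = occasion_specific,
                 constrain_cross = constrain_cross,
                 two_countries = info$two_countries, data = data,
                 optim = best[c("convergence", "message", "counts")],
                 call = match.call()),
            class = "twinchol")
}

#' @export
print.twinchol <- function(x, digits = 4, ...) {
  cat(sprintf("Bivariate Cholesky twin model (%s%s), %d pairs\n",
              x$variant, if (x$constrain_cross) ", cross paths = 0" else "",
              x$n_pairs_used))
  cat(sprintf("  logLik %.4f on %d free parameters; AIC %.4f%s\n",
              x$loglik, x$n_free, x$aic,
              if (x$converged) "" else "  [NOT converged]"))
  vc <- varcomp(x)
  cat("  standardized components:\n")
  print(round(vc$std, digits))
  invisible(x)
}

#' @export
coef.twinchol <- function(object, ...) object$coefficients

#' @export
logLik.twinchol <- function(object, ...)
  structure(object$loglik, df = object$n_free, nobs = object$n_pairs_used,
            class = "logLik")

#' @export
fitted.twinchol <- function(object, ...)
  fiml_parts(object$params, object$data)$mu

#' @export
residuals.twinchol <- function(object, ...)
  object$data$y - fitted(object)

#' Likelihood-ratio test between nested twin-model fits
#'
#' `chi2 = 2 * (logLik_full - logLik_nested)` (clipped at 0), with the
#' difference in free-parameter counts as degrees of freedom and an
#' upper-tail chi-square p-value. The naive chi-square reference with the
#' stated df is used throughout (no boundary-mixture correction).
#'
#' @param full,nested converged [twinchol()] fits, `nested` nested in
#'   `full` (submodel variant and/or cross paths fixed at 0).
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, nested) {
  stopifnot(inherits(full, "twinchol"), inherits(nested, "twinchol"))
  variant_ok <- nested$variant %in% nesting_table[[full$variant]] ||
    nested$variant == full$variant
  cross_ok <- !full$constrain_cross || nested$constrain_cross
  if (nested$variant == full$variant &&
      nested$constrain_cross == full$constrain_cross)
    stop("models are identical, not nested")
  if (!variant_ok || !cross_ok ||
      nested$occasion_specific != full$occasion_specific)
    stop("'nested' is not nested within 'full'")
  df <- full$n_free - nested$n_free
  if (df <= 0L) stop("'nested' has no fewer parameters than 'full'")
  chi2 <- 2 * (full$loglik - nested$loglik)
  if (chi2 < -1e-6)
    warning("nested fit exceeds full fit by more than tolerance ",
            "(optimization failure); statistic clipped at 0")
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' @rdname lrt
#' @param object,... for the `anova` method: two `twinchol` fits, fuller
#'   model first or second (ordered automatically by parameter count).
#' @export
anova.twinchol <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1]], "twinchol"))
    stop("anova.twinchol compares exactly two fits")
  m <- list(object, others[[1]])
  ord <- order(vapply(m, `[[`, 0L, "n_free"))
  nested <- m[[ord[1]]]; full <- m[[ord[2]]]
  tst <- lrt(full, nested)
  tab <- data.frame(
    variant = c(nested$variant, full$variant),
    n_free = c(nested$n_free, full$n_free),
    logLik = c(nested$loglik, full$loglik),
    AIC = c(nested$aic, full$aic),
    chi2 = c(NA, tst$chi2), df = c(NA, tst$df), p = c(NA, tst$p))
  class(tab) <- c("anova", "data.frame")
  attr(tab, "heading") <- "Likelihood-ratio test of nested twin models\n"
  tab
}

#' @export
summary.twinchol <- function(object, ...) {
  structure(list(fit = object, varcomp = varcomp(object),
                 cors = cross_time_cor(object)),
            class = "summary.twinchol")
}

#' @export
print.summary.twinchol <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  broad heritability:", round(x$varcomp$h2, digits), "\n")
  cat("  cross-time correlations (A, C/D, E):",
      round(x$cors$r, digits), "\n")
  cat("  country-1 SD scalars k:", round(x$fit$params$k, digits), "\n")
  invisible(x)
}

#' @export
simulate.twinchol <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  skel <- data.frame(pair_id = d$pair_id, zygosity = d$zygosity,
                     country = d$country, sex = d$sex,
                     age_t1 = d$age[, 1], age_t2 = d$age[, 2],
                     obs_tw1_t1 = !is.na(d$y[, 1]),
                     obs_tw1_t2 = !is.na(d$y[, 2]),
                     obs_tw2_t1 = !is.na(d$y[, 3]),
                     obs_tw2_t2 = !is.na(d$y[, 4]))
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_site(object$params, skel)))
}

#' @export
plot.twinchol <- function(x, ...) {
  vc <- varcomp(x)
  m <- t(vc$std)
  rownames(m) <- c("A", x$params$second_source %||% "C/D", "E")
  graphics::barplot(m, beside = FALSE, col = c("#1b7837", "#af8dc3",
                                               "#d9d9d9"),
                    ylab = "share of variance",
                    legend.text = rownames(m),
                    main = sprintf("%s variance decomposition", x$variant),
                    ...)
  invisible(x)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
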