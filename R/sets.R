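## Set-level meta-analysis: random-intercept mixed models over the two
## per-occasion estimates of each site, Wald chi-square tests for
## category effects, the intraclass ratio rho, and maximum-likelihood
## skew-normal regression of Fisher-Z cross-time correlations.

#' Random-intercept mixed model over per-site, per-occasion estimates
#'
#' Fits `value ~ category (+ occasion) + (1 | site)` by maximum
#' likelihood (not REML, so Wald tests on fixed effects are coherent
#' across fits), via \pkg{lme4}. Reports the between-site intercept
#' variance, the residual (within-site) variance, their ratio
#' `rho = var_between / (var_between + var_within)`, and a Wald
#' chi-square jointly testing the category coefficients
#' (df = number of categories - 1).
#'
#' @param value numeric response (a biometrical estimate, one row per
#'   site x occasion).
#' @param category factor (or coercible) of category codes per row; a
#'   single-level category yields variance components but no Wald test.
#' @param site site identifier per row.
#' @param occasion optional occasion indicator added as a fixed covariate.
#' @return list of class `lmm_result`: `fixed_effects` (estimate, SE),
#'   `var_between`, `var_within`, `rho`, `wald_chi2`, `wald_df`, `p`,
#'   and the underlying `fit`.
#' @export
fit_random_intercept_lmm <- function(value, category, site,
                                     occasion = NULL) {
  ok <- is.finite(value)
  df <- data.frame(value = value[ok],
                   category = factor(category)[ok],
                   site = factor(site)[ok])
  if (!is.null(occasion)) df$occasion <- factor(occasion)[ok]
  if (nlevels(droplevels(df$site)) < 2L) stop("need at least 2 sites")
  df$category <- droplevels(df$category)
  has_cat <- nlevels(df$category) > 1L
  form <- if (has_cat && !is.null(occasion))
    value ~ category + occasion + (1 | site)
  else if (has_cat) value ~ category + (1 | site)
  else if (!is.null(occasion)) value ~ occasion + (1 | site)
  else value ~ 1 + (1 | site)
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_between <- vc$vcov[vc$grp == "site"]
  var_within <- vc$vcov[vc$grp == "Residual"]
  rho <- var_between / (var_between + var_within)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  fixed <- data.frame(term = names(fe), estimate = unname(fe),
                      se = unname(se))
  wald <- list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
  if (has_cat) {
    idx <- grep("^category", names(fe))
    b <- fe[idx]
    V <- as.matrix(vcov(fit))[idx, idx, drop = FALSE]
    chi2 <- drop(t(b) %*% solve(V, b))
    wald <- list(chi2 = chi2, df = length(idx),
                 p = pchisq(chi2, length(idx), lower.tail = FALSE))
  }
  structure(list(fixed_effects = fixed, var_between = var_between,
                 var_within = var_within, rho = rho,
                 wald_chi2 = wald$chi2, wald_df = wald$df, p = wald$p,
                 fit = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, digits = 4, ...) {
  cat("Random-intercept model (ML)\n")
  print(cbind(round(x$fixed_effects[, -1, drop = FALSE], digits),
              term = x$fixed_effects$term)[, c(3, 1, 2)], row.names = FALSE)
  cat(sprintf("  var between sites %.5g, within %.5g, rho = %.3f\n",
              x$var_between, x$var_within, x$rho))
  if (!is.na(x$wald_chi2))
    cat(sprintf("  Wald chi2(%d) = %.2f, p = %.3g\n", x$wald_df,
                x$wald_chi2, x$p))
  invisible(x)
}

# long (site, occasion, value) layout of one component column pair
component_long <- function(results, component, variant = "best") {
  if (inherits(results, "twin_scan")) results <- results$results
  sub <- if (identical(variant, "best"))
    results[results$is_best, , drop = FALSE]
  else results[results$variant == variant, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for variant selection '", variant, "'")
  c1 <- paste0(component, "_1"); c2 <- paste0(component, "_2")
  if (!all(c(c1, c2) %in% names(sub)))
    stop("unknown component '", component, "'")
  data.frame(site_id = rep(sub$site_id, 2L),
             occasion = rep(1:2, each = nrow(sub)),
             value = c(sub[[c1]], sub[[c2]]))
}

#' Compare a CpG set against background sites
#'
#' For each requested component, stacks the two per-occasion estimates of
#' every site, codes set membership, and fits the random-intercept model
#' of [fit_random_intercept_lmm()] with membership (and occasion) as
#' fixed effects. The membership coefficient estimates the set-vs-
#' background difference in the component.
#'
#' @param results a `twin_scan` or results data.frame.
#' @param set_sites character vector of member site ids; ids absent from
#'   the results are reported and dropped.
#' @param components component column stems to compare (default broad
#'   heritability plus the standardized and absolute components).
#' @param variant `"best"` (default), `"ADE"` or `"ACE"` rows.
#' @return data.frame with one row per component: membership estimate,
#'   SE, Wald chi2/df/p, rho, and group means.
#' @export
compare_sets <- function(results, set_sites,
                         components = c("h2", "std_A", "std_CD", "std_E",
                                        "abs_A", "abs_CD", "abs_E"),
                         variant = "best") {
  if (inherits(results, "twin_scan")) results <- results$results
  universe <- unique(results$site_id)
  m <- match_site_set(set_sites, universe)
  if (length(m$present) == 0L) stop("set has no overlap with the results")
  if (length(m$present) == length(universe))
    stop("set equals the analysis universe; no background to compare")
  rows <- lapply(components, function(cc) {
    long <- component_long(results, cc, variant)
    member <- factor(ifelse(long$site_id %in% m$present, "set",
                            "background"),
                     levels = c("background", "set"))
    lmm <- fit_random_intercept_lmm(long$value, member, long$site_id,
                                    occasion = long$occasion)
    est <- lmm$fixed_effects
    b <- est$estimate[grep("^category", est$term)]
    se <- est$se[grep("^category", est$term)]
    data.frame(component = cc, n_set = length(m$present),
               estimate = b, se = se, wald_chi2 = lmm$wald_chi2,
               wald_df = lmm$wald_df, p = lmm$p, rho = lmm$rho,
               mean_background = mean(long$value[member == "background"],
                                      na.rm = TRUE),
               mean_set = mean(long$value[member == "set"], na.rm = TRUE))
  })
  do.call(rbind, rows)
}

## ---- skew-normal regression ------------------------------------------

# maximum skewness magnitude of the skew-normal family, minus guard
SN_GAMMA_MAX <- 0.995

# centered parametrization (mean mu, sd sigma, skewness gamma1) ->
# direct parametrization (xi, omega, alpha)
sn_cp_to_dp <- function(mu, sigma, gamma1) {
  t <- sign(gamma1) * (2 * abs(gamma1) / (4 - pi))^(1 / 3)
  muz <- t / sqrt(1 + t^2)
  delta <- muz * sqrt(pi / 2)
  delta <- pmin(pmax(delta, -0.9999999), 0.9999999)
  alpha <- delta / sqrt(1 - delta^2)
  omega <- sigma / sqrt(1 - muz^2)
  xi <- mu - omega * muz
  list(xi = xi, omega = omega, alpha = alpha, muz = muz)
}

sn_logdens <- function(y, xi, omega, alpha) {
  z <- (y - xi) / omega
  log(2) - log(omega) + dnorm(z, log = TRUE) + pnorm(alpha * z, log.p = TRUE)
}

#' Skew-normal regression of Fisher-Z cross-time correlations
#'
#' Maximum-likelihood skew-normal regression of Z-transformed cross-time
#' correlations on a group indicator, as used to compare low-stability
#' sites against background. Internally the centered parametrization
#' (mean-scale coefficients, SD, skewness) is optimized for stability and
#' mapped to the direct parametrization (location, scale, shape) for
#' reporting. The fitted group mean is the distribution mean (not the
#' location, which differs when shape is nonzero); group means are
#' inverse-transformed to correlation units by `tanh`.
#'
#' @param z finite Fisher-Z values (non-finite values are dropped).
#' @param group factor (or coercible) with >= 1 level; each group needs
#'   at least `min_per_group` observations.
#' @param shape `NULL` (free, default) or a fixed shape value; `0` gives
#'   a normal-error regression.
#' @param min_per_group minimum group size (default 10).
#' @return object of class `skew_fit`: centered coefficients `cp`
#'   (mean-scale group coefficients, sigma, gamma1), direct parameters
#'   `dp` (xi coefficients, omega, alpha), `loglik`, `converged`,
#'   `fallback_normal`, `group_mean_z`, `group_r`, and `test` (LRT of the
#'   group effect against an intercept-only skew-normal model).
#' @export
skew_regress_z <- function(z, group, shape = NULL, min_per_group = 10L) {
  ok <- is.finite(z)
  z <- z[ok]
  group <- droplevels(factor(group)[ok])
  if (any(table(group) < min_per_group))
    stop("each group needs at least ", min_per_group, " finite z values")
  if (sd(z) == 0) stop("all z values identical; scale degenerate")
  X <- if (nlevels(group) > 1L) model.matrix(~group)
       else matrix(1, length(z), 1L, dimnames = list(NULL, "(Intercept)"))
  fit <- sn_ml(z, X, shape = shape)
  ## group-effect test: LRT vs intercept-only model with same shape setup
  test <- list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
  if (nlevels(group) > 1L) {
    fit0 <- sn_ml(z, X[, 1, drop = FALSE], shape = shape)
    chi2 <- max(2 * (fit$loglik - fit0$loglik), 0)
    df <- ncol(X) - 1L
    test <- list(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE))
  }
  Xg <- unique(X)
  mu_g <- drop(Xg %*% fit$beta)
  names(mu_g) <- levels(group)
  structure(list(cp = list(beta = fit$beta, sigma = fit$sigma,
                           gamma1 = fit$gamma1),
                 dp = fit$dp, loglik = fit$loglik,
                 converged = fit$converged,
                 fallback_normal = fit$fallback_normal,
                 group_mean_z = mu_g, group_r = tanh(mu_g),
                 test = test, n = length(z)),
            class = "skew_fit")
}

# core skew-normal ML on a design matrix (centered parametrization)
sn_ml <- function(y, X, shape = NULL) {
  p <- ncol(X)
  ols <- lm.fit(X, y)
  b0 <- ols$coefficients
  s0 <- sqrt(mean(ols$residuals^2))
  r <- ols$residuals / s0
  g0 <- min(max(mean(r^3), -0.9 * SN_GAMMA_MAX), 0.9 * SN_GAMMA_MAX)
  fixed_shape <- !is.null(shape)
  if (fixed_shape && shape == 0) {
    ll <- sum(dnorm(y, X %*% b0, s0, log = TRUE))
    return(list(beta = setNames(b0, colnames(X)), sigma = s0, gamma1 = 0,
                dp = list(xi = b0, omega = s0, alpha = 0), loglik = ll,
                converged = TRUE, fallback_normal = FALSE))
  }
  negll <- function(th) {
    beta <- th[1:p]
    sigma <- exp(th[p + 1L])
    gamma1 <- if (fixed_shape) sn_alpha_to_gamma1(shape) else
      SN_GAMMA_MAX * tanh(th[p + 2L])
    dp <- sn_cp_to_dp(0, sigma, gamma1)
    mu <- drop(X %*% beta)
    v <- -sum(sn_logdens(y, mu + dp$xi, dp$omega, dp$alpha))
    if (!is.finite(v)) 1e10 else v
  }
  th0 <- c(b0, log(s0), if (!fixed_shape) atanh(g0 / SN_GAMMA_MAX))
  opt <- optim(th0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  ok <- opt$convergence == 0 && is.finite(opt$value)
  if (!ok) {  # fall back to normal-error regression, flagged
    ll <- sum(dnorm(y, X %*% b0, s0, log = TRUE))
    return(list(beta = setNames(b0, colnames(X)), sigma = s0, gamma1 = 0,
                dp = list(xi = b0, omega = s0, alpha = 0), loglik = ll,
                converged = FALSE, fallback_normal = TRUE))
  }
  beta <- setNames(opt$par[1:p], colnames(X))
  sigma <- exp(opt$par[p + 1L])
  gamma1 <- if (fixed_shape) sn_alpha_to_gamma1(shape) else
    SN_GAMMA_MAX * tanh(opt$par[p + 2L])
  dp <- sn_cp_to_dp(0, sigma, gamma1)
  list(beta = beta, sigma = sigma, gamma1 = gamma1,
       dp = list(xi_coef = c(beta[1] + dp$xi, beta[-1]), omega = dp$omega,
                 alpha = dp$alpha),
       loglik = -opt$value, converged = TRUE, fallback_normal = FALSE)
}

# skewness implied by a direct-parametrization shape alpha
sn_alpha_to_gamma1 <- function(alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  muz <- delta * sqrt(2 / pi)
  (4 - pi) / 2 * muz^3 / (1 - muz^2)^1.5
}

#' @export
print.skew_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Skew-normal regression of Fisher-Z values (n = %d)%s\n",
              x$n, if (x$fallback_normal) "  [normal fallback]" else ""))
  cat(sprintf("  sigma %.4f, skewness %.4f (shape alpha %.3f), logLik %.4f\n",
              x$cp$sigma, x$cp$gamma1, x$dp$alpha, x$loglik))
  cat("  group mean z:", round(x$group_mean_z, digits), "\n")
  cat("  group r (tanh):", round(x$group_r, digits), "\n")
  if (!is.na(x$test$chi2))
    cat(sprintf("  group effect: chi2(%d) = %.2f, p = %.3g\n",
                x$test$df, x$test$chi2, x$test$p))
  invisible(x)
}
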