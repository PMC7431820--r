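## Per-site model battery: all variants, AIC selection between the full
## ACE and ADE models, nested LRTs, the cross-path stability test,
## post-fit probe filtering on implied moments, and the methylome-wide
## driver.

default_thresholds <- function() {
  list(significance_strict = 1e-7, significance_nominal = 1e-2,
       stability_p = 0.01, e_dominance = 0.99,
       filter_mean = 6.25, filter_sd = 1.5)
}

#' Fit all model variants at one site
#'
#' Fits the requested variants in the order ACE, ADE, AE, CE, E, passing
#' reduced versions of fuller solutions on as warm starts so nested fits
#' respect the likelihood ordering.
#'
#' @param data a [twin_data()] object.
#' @param variants subset of `c("ACE","ADE","AE","CE","E")`.
#' @param seed seed for random restarts (split across variants).
#' @param ... passed to [twinchol()].
#' @return named list of [twinchol()] fits.
#' @export
fit_site <- function(data, variants = VARIANTS, seed = NULL, ...) {
  variants <- intersect(VARIANTS, variants)
  fits <- list()
  warm <- function(to) {
    src <- intersect(names(fits), switch(to, AE = c("ACE", "ADE"),
                                         CE = "ACE",
                                         E = c("AE", "CE", "ACE", "ADE"),
                                         character()))
    lapply(fits[src], function(f) reduce_params(f$params, to))
  }
  for (i in seq_along(variants)) {
    v <- variants[i]
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    fits[[v]] <- twinchol(data, v, extra_starts = warm(v), seed = s, ...)
  }
  fits
}

#' Select between the full ACE and ADE fits
#'
#' The ADE model is retained as best-fitting when its AIC is as good or
#' better than the ACE model's (ties retain ADE); otherwise ACE. A
#' non-converged fit loses to a converged one; if neither converged the
#' site is flagged (`NA`).
#'
#' @param ace,ade [twinchol()] fits of the two full variants.
#' @return `"ADE"`, `"ACE"`, or `NA_character_`.
#' @export
select_best <- function(ace, ade) {
  if (!ace$converged && !ade$converged) return(NA_character_)
  if (!ace$converged) return("ADE")
  if (!ade$converged) return("ACE")
  if (ade$aic <= ace$aic) "ADE" else "ACE"
}

#' Cross-path stability test
#'
#' Refits the given variant with all cross-occasion paths fixed at zero
#' (`a21 = c21/d21 = e21 = 0`) and performs the 3-df likelihood-ratio
#' test. A significant result indicates cross-time association (stability)
#' through genetic and/or environmental mechanisms.
#'
#' @param fit a converged full-variant [twinchol()] fit.
#' @param data the site's [twin_data()].
#' @param seed,... passed to the constrained refit.
#' @return list with `chi2`, `df`, `p` (all `NA` if the constrained refit
#'   fails to converge) and the constrained fit as `constrained`.
#' @export
stability_test <- function(fit, data, seed = NULL, ...) {
  con <- twinchol(data, fit$variant, constrain_cross = TRUE,
                  extra_starts = list(reduce_params_cross(fit$params)),
                  occasion_specific = fit$occasion_specific,
                  seed = seed, ...)
  if (!con$converged)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                constrained = con))
  if (con$loglik > fit$loglik + 1e-6) {
    # restore nesting: the constrained solution is a feasible point of the
    # full model, so refitting from it can only improve the full fit
    refit <- twinchol(data, fit$variant,
                      extra_starts = list(con$params, fit$params),
                      occasion_specific = fit$occasion_specific,
                      seed = seed, ...)
    if (refit$converged && refit$loglik > fit$loglik) fit <- refit
  }
  c(lrt(fit, con), list(constrained = con))
}

# zero the cross paths of a path_params (stability null warm start)
reduce_params_cross <- function(params) {
  path_params(params$variant, a = c(params$a[1], 0, params$a[3]),
              cd = c(params$cd[1], 0, params$cd[3]),
              e = c(params$e[1], 0, params$e[3]),
              k = params$k, beta = params$beta)
}

# model-implied reference moments: means at age 74, sex at its sample
# mean, country 0; SDs on the country-0 scale
implied_moments <- function(fit, sex_bar) {
  mu <- expected_pair_mean(fit$params, age = c(AGE_CENTER, AGE_CENTER),
                           sex = sex_bar, country = 0)[1:2]
  vc <- varcomp(fit)
  list(mean = unname(mu), sd = sqrt(unname(vc$total)))
}

#' Post-fit probe filter on implied moments
#'
#' Flags sites whose model-implied M-value mean falls outside
#' `[-6.25, 6.25]` or whose implied SD exceeds 1.5 at either occasion
#' under either full model (ACE or ADE). Means are evaluated at age 74,
#' sample-mean sex and country 0; SDs on the country-0 scale.
#'
#' @param ace,ade full-variant [twinchol()] fits.
#' @param mean_bound,sd_bound filter thresholds (strict inequalities).
#' @param moments `"implied"` (default) evaluates model-implied moments;
#'   `"raw"` uses the per-occasion sample mean and SD of the observed
#'   M-values instead.
#' @return list with `mean_out_of_range`, `sd_out_of_range`, `keep`.
#' @export
filter_site <- function(ace, ade, mean_bound = 6.25, sd_bound = 1.5,
                        moments = c("implied", "raw")) {
  moments <- match.arg(moments)
  if (moments == "raw") {
    y <- ace$data$y
    vt <- list(c(y[, 1], y[, 3]), c(y[, 2], y[, 4]))
    means <- vapply(vt, mean, 0, na.rm = TRUE)
    sds <- vapply(vt, sd, 0, na.rm = TRUE)
  } else {
    sex_bar <- mean(ace$data$sex)
    mom <- lapply(list(ace, ade), implied_moments, sex_bar = sex_bar)
    means <- unlist(lapply(mom, `[[`, "mean"))
    sds <- unlist(lapply(mom, `[[`, "sd"))
  }
  mean_flag <- any(abs(means) > mean_bound)
  sd_flag <- any(sds > sd_bound)
  list(mean_out_of_range = mean_flag, sd_out_of_range = sd_flag,
       keep = !(mean_flag || sd_flag))
}

# one results row per fitted variant for a site
site_rows <- function(site_id, fits, best, tests, filt, diag_, class_) {
  rows <- lapply(names(fits), function(v) {
    f <- fits[[v]]
    vc <- varcomp(f)
    ct <- cross_time_cor(f)
    p <- f$params
    data.frame(
      site_id = site_id, variant = v, is_best = identical(v, best),
      converged = f$converged, loglik = f$loglik, n_free = f$n_free,
      aic = f$aic, n_pairs = f$n_pairs_used,
      a11 = p$a[[1]], a21 = p$a[[2]], a22 = p$a[[3]],
      cd11 = p$cd[[1]], cd21 = p$cd[[2]], cd22 = p$cd[[3]],
      e11 = p$e[[1]], e21 = p$e[[2]], e22 = p$e[[3]],
      k1 = p$k[[1]], k2 = p$k[[2]],
      b_t1 = p$beta[[1]], b_t2 = p$beta[[2]],
      std_A_1 = vc$std["t1", "A"], std_CD_1 = vc$std["t1", "CD"],
      std_E_1 = vc$std["t1", "E"], std_A_2 = vc$std["t2", "A"],
      std_CD_2 = vc$std["t2", "CD"], std_E_2 = vc$std["t2", "E"],
      abs_A_1 = vc$abs["t1", "A"], abs_CD_1 = vc$abs["t1", "CD"],
      abs_E_1 = vc$abs["t1", "E"], abs_A_2 = vc$abs["t2", "A"],
      abs_CD_2 = vc$abs["t2", "CD"], abs_E_2 = vc$abs["t2", "E"],
      total_var_1 = vc$total[["t1"]], total_var_2 = vc$total[["t2"]],
      h2_1 = vc$h2[["t1"]], h2_2 = vc$h2[["t2"]],
      rA = ct$r[["A"]], rCD = ct$r[["CD"]], rE = ct$r[["E"]],
      zA = ct$z[["A"]], zCD = ct$z[["CD"]], zE = ct$z[["E"]],
      best_variant = best %|na|% NA_character_,
      chi2_full_vs_E = tests$full$chi2, df_full_vs_E = tests$full$df,
      p_full_vs_E = tests$full$p,
      chi2_AE_vs_E = tests$ae$chi2, df_AE_vs_E = tests$ae$df,
      p_AE_vs_E = tests$ae$p,
      chi2_stability = tests$stability$chi2,
      df_stability = tests$stability$df, p_stability = tests$stability$p,
      mean_out_of_range = filt$mean_out_of_range,
      sd_out_of_range = filt$sd_out_of_range, keep = filt$keep,
      low_stability = class_$low_stability,
      e_dominated = class_$e_dominated,
      significant_1e7 = class_$significant_1e7,
      significant_1e2 = class_$significant_1e2,
      mz_cor_t1 = diag_$cors["MZ", "t1"], mz_cor_t2 = diag_$cors["MZ", "t2"],
      dz_cor_t1 = diag_$cors["DZ", "t1"], dz_cor_t2 = diag_$cors["DZ", "t2"])
  })
  do.call(rbind, rows)
}

#' Apply the site classification rules to a results table
#'
#' Recomputes the low-stability, E-dominance and significance flags from
#' the stored test p-values and best-variant components, so that a
#' written results table classifies identically to the in-memory run.
#'
#' @param results results data.frame (rows for all variants).
#' @param thresholds list as from the package defaults: significance
#'   `1e-7` / `1e-2`, stability p `0.01`, E-dominance `0.99`.
#' @return data.frame with one row per site: the four flags.
#' @export
classify_sites <- function(results, thresholds = default_thresholds()) {
  if (inherits(results, "twin_scan")) results <- results$results
  best <- results[results$is_best, , drop = FALSE]
  data.frame(
    site_id = best$site_id,
    low_stability = classify_low_stability(best$p_stability, best$std_E_1,
                                           best$std_E_2,
                                           thresholds$stability_p),
    e_dominated = best$std_E_1 > thresholds$e_dominance &
      best$std_E_2 > thresholds$e_dominance,
    significant_1e7 = best$p_full_vs_E < thresholds$significance_strict,
    significant_1e2 = best$p_full_vs_E < thresholds$significance_nominal,
    row.names = NULL)
}

#' Fit the model battery across a methylome
#'
#' Maps [fit_site()] over sites, applies model selection, the full-vs-E
#' and AE-vs-E likelihood-ratio tests, the cross-path stability test,
#' implied-moment probe filtering and site classification. Per-site
#' failures are recorded and the run continues. Deterministic given the
#' master seed.
#'
#' @param sites named list of [twin_data()] objects (or the output of
#'   [simulate_methylome()]).
#' @param variants variants to fit; must include `"ACE"`, `"ADE"` and
#'   `"E"` for selection and testing, `"AE"` for the AE-vs-E test.
#' @param seed master seed (split per site).
#' @param threads sites are independent; with `threads > 1` they are
#'   fitted with [parallel::mclapply()].
#' @param thresholds classification thresholds, see [classify_sites()].
#' @param ... passed to [twinchol()].
#' @return An object of class `twin_scan`: list with `results` (one row
#'   per site x variant), `failures`, `settings`.
#' @export
run_methylome <- function(sites, variants = VARIANTS, seed = 1L,
                          threads = 1L,
                          thresholds = default_thresholds(), ...) {
  if (is.list(sites) && !is.null(sites$sites)) sites <- sites$sites
  stopifnot(length(sites) >= 1L, all(vapply(sites, inherits, TRUE,
                                            "twin_data")))
  if (is.null(names(sites)))
    names(sites) <- vapply(seq_along(sites), function(i)
      sites[[i]]$site_id %|na|% sprintf("site%05d", i), "")
  one <- function(i) {
    sid <- names(sites)[i]
    tryCatch({
      data <- sites[[i]]
      fits <- fit_site(data, variants, seed = derive_seed(seed, i), ...)
      best <- select_best(fits$ACE, fits$ADE)
      bf <- if (is.na(best)) NULL else fits[[best]]
      tests <- list(
        full = if (!is.null(bf) && fits$E$converged) lrt(bf, fits$E)
               else list(chi2 = NA_real_, df = NA_integer_, p = NA_real_),
        ae = if (!is.null(fits$AE) && fits$AE$converged &&
                 fits$E$converged) lrt(fits$AE, fits$E)
             else list(chi2 = NA_real_, df = NA_integer_, p = NA_real_),
        stability = if (!is.null(bf))
          stability_test(bf, data, seed = derive_seed(seed, i + 500000L),
                         ...)
        else list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
      filt <- filter_site(fits$ACE, fits$ADE,
                          mean_bound = thresholds$filter_mean,
                          sd_bound = thresholds$filter_sd)
      vcb <- if (!is.null(bf)) varcomp(bf) else NULL
      diag_ <- e_dominance_diagnostics(
        data,
        std_E_1 = if (is.null(vcb)) NA_real_ else vcb$std["t1", "E"],
        std_E_2 = if (is.null(vcb)) NA_real_ else vcb$std["t2", "E"],
        threshold = thresholds$e_dominance)
      class_ <- list(
        low_stability = !is.null(vcb) && !is.na(tests$stability$p) &&
          classify_low_stability(tests$stability$p, vcb$std["t1", "E"],
                                 vcb$std["t2", "E"],
                                 thresholds$stability_p),
        e_dominated = isTRUE(diag_$e_dominated),
        significant_1e7 = !is.na(tests$full$p) &&
          tests$full$p < thresholds$significance_strict,
        significant_1e2 = !is.na(tests$full$p) &&
          tests$full$p < thresholds$significance_nominal)
      site_rows(sid, fits, best, tests, filt, diag_, class_)
    }, error = function(e) structure(conditionMessage(e),
                                     class = "site_failure"))
  }
  res <- if (threads > 1L)
    parallel::mclapply(seq_along(sites), one, mc.cores = threads)
  else lapply(seq_along(sites), one)
  failed <- vapply(res, inherits, TRUE, "site_failure")
  failures <- data.frame(site_id = names(sites)[failed],
                         error = vapply(res[failed], as.character, ""))
  results <- do.call(rbind, res[!failed])
  rownames(results) <- NULL
  structure(list(results = results, failures = failures,
                 settings = list(variants = variants, seed = seed,
                                 threads = threads,
                                 thresholds = thresholds,
                                 filter_reference = paste(
                                   "mean at age 74, sample-mean sex,",
                                   "country 0; SD on country-0 scale"))),
            class = "twin_scan")
}

#' @export
print.twin_scan <- function(x, ...) {
  n_sites <- length(unique(x$results$site_id))
  cat(sprintf("Methylome twin-model scan: %d sites, %d result rows, %d failures\n",
              n_sites, nrow(x$results), nrow(x$failures)))
  best <- x$results[x$results$is_best, , drop = FALSE]
  if (nrow(best)) {
    cat(sprintf("  best-fitting: ADE %d (%.0f%%), ACE %d (%.0f%%)\n",
                sum(best$variant == "ADE"),
                100 * mean(best$variant == "ADE"),
                sum(best$variant == "ACE"),
                100 * mean(best$variant == "ACE")))
    cat(sprintf("  mean broad h2: %.3f (t1), %.3f (t2); kept by filter: %d\n",
                mean(best$h2_1, na.rm = TRUE), mean(best$h2_2, na.rm = TRUE),
                sum(best$keep)))
  }
  invisible(x)
}

#' @export
summary.twin_scan <- function(object, ...) {
  out <- list(scan = object, components = summarize_components(object),
              classification = classify_sites(object))
  class(out) <- "summary.twin_scan"
  out
}

#' @export
print.summary.twin_scan <- function(x, ...) {
  print(x$scan)
  cl <- x$classification
  cat(sprintf("  significant (p<1e-7): %d; (p<1e-2): %d; low-stability: %d; E-dominated: %d\n",
              sum(cl$significant_1e7, na.rm = TRUE),
              sum(cl$significant_1e2, na.rm = TRUE),
              sum(cl$low_stability, na.rm = TRUE),
              sum(cl$e_dominated, na.rm = TRUE)))
  comp <- x$components
  ade <- comp[comp$group == "ADE" & comp$component %in%
                c("std_A", "std_CD", "std_E"), ]
  if (nrow(ade)) {
    cat("  ADE standardized component means:\n")
    print(ade[, c("component", "occasion", "mean", "sd")], row.names = FALSE)
  }
  invisible(x)
}
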