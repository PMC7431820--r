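## Quantities derived from fitted paths: variance components, broad
## heritability, cross-time etiologic correlations, site classification
## and across-site summaries.

#' Variance components of a fitted or generating model
#'
#' Absolute (M-value^2, country-0 scale) and standardized A, C/D and E
#' components at each occasion, plus broad-sense heritability (A + D
#' under ADE, A under ACE/AE, 0 where no genetic source is present).
#' Occasion 1 uses the squared first-column paths; occasion 2 sums the
#' squared second-row paths of each source.
#'
#' @param x a [path_params()] or fitted [twinchol()] object.
#' @param ... unused.
#' @return A `varcomp` object: matrices `abs` and `std` (occasions x
#'   components), `total` and `h2` (length 2), and the variant.
#' @export
varcomp <- function(x, ...) UseMethod("varcomp")

#' @export
varcomp.path_params <- function(x, ...) {
  one <- function(l) c(l[1]^2, l[2]^2 + l[3]^2)  # occ1, occ2
  a <- one(x$a); s <- one(x$cd); e <- one(x$e)
  abs <- cbind(A = a, CD = s, E = e)
  rownames(abs) <- c("t1", "t2")
  total <- rowSums(abs)
  if (any(total <= 0)) {
    std <- abs * NA_real_
    warning("zero total variance at an occasion; standardized components ",
            "undefined")
  } else std <- abs / total
  h2 <- switch(x$variant,
               ADE = std[, "A"] + std[, "CD"],
               ACE = std[, "A"], AE = std[, "A"],
               CE = c(t1 = 0, t2 = 0), E = c(t1 = 0, t2 = 0))
  structure(list(abs = abs, std = std, total = total, h2 = h2,
                 variant = x$variant, second_source = x$second_source),
            class = "varcomp")
}

#' @export
varcomp.twinchol <- function(x, ...) varcomp(x$params, ...)

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("Variance components (%s)\n", x$variant))
  tab <- cbind(x$std, total = x$total, h2 = x$h2)
  colnames(tab)[1:3] <- paste0("std_", c("A", x$second_source %||% "CD", "E"))
  print(round(tab, digits))
  cat("absolute (country-0 scale):\n")
  print(round(x$abs, digits))
  invisible(x)
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Cross-time etiologic correlations
#'
#' Correlation of each source's latent scores across the two occasions,
#' computed from the Cholesky paths as
#' \code{l11*l21 / sqrt(l11^2 * (l21^2 + l22^2))}, together with Fisher-Z
#' transforms `z = atanh(r)`. `|r|` is capped at `1 - 1e-6` before the
#' transform; capped values are flagged. A source with zero variance at
#' either occasion has an undefined correlation (`NA`, flagged).
#'
#' @param x a [path_params()] or [twinchol()] object.
#' @param ... unused.
#' @return list with `r`, `z` (named length-3: A, CD, E), and logical
#'   flags `undefined`, `clipped`.
#' @export
cross_time_cor <- function(x, ...) UseMethod("cross_time_cor")

#' @export
cross_time_cor.path_params <- function(x, ...) {
  one <- function(l) {
    denom2 <- l[[1]]^2 * (l[[2]]^2 + l[[3]]^2)
    if (denom2 <= 0) return(NA_real_)
    (l[[1]] * l[[2]]) / sqrt(denom2)
  }
  r <- c(A = one(x$a), CD = one(x$cd), E = one(x$e))
  undefined <- is.na(r)
  cap <- 1 - 1e-6
  clipped <- !undefined & abs(r) > cap
  rc <- pmin(pmax(r, -cap), cap)
  z <- atanh(rc)
  z[undefined] <- NA_real_
  list(r = r, z = z, undefined = undefined, clipped = clipped)
}

#' @export
cross_time_cor.twinchol <- function(x, ...) cross_time_cor(x$params, ...)

#' Low-stability classification
#'
#' A site shows low stability with meaningful familial contributions when
#' its cross-path stability test is non-significant (`p > 0.01`, 3 df)
#' while non-shared factors account for less than half the variance at
#' one or both occasions, judged on the best-fitting variant.
#'
#' @param p_stability stability-test p-value(s).
#' @param std_E_1,std_E_2 standardized E at occasions 1 and 2.
#' @param p_threshold stability p threshold (default 0.01).
#' @return logical vector.
#' @export
classify_low_stability <- function(p_stability, std_E_1, std_E_2,
                                   p_threshold = 0.01) {
  (p_stability > p_threshold) & (std_E_1 < 0.5 | std_E_2 < 0.5)
}

#' E-dominance flag and twin-correlation diagnostics
#'
#' Flags sites where non-shared factors explain more than 99% of the
#' variance at both occasions, and reports the empirical cross-twin
#' Pearson correlations (pairwise-complete) with the three diagnostic
#' indicators expected to accompany such sites: MZ correlations negative
#' (< 0) at both occasions, DZ correlations below -0.05 at both, or the
#' MZ - DZ difference below -0.1 at both.
#'
#' @param data a [twin_data()] object.
#' @param std_E_1,std_E_2 standardized E of the best-fitting variant.
#' @param threshold E-dominance threshold (default 0.99).
#' @return list with `e_dominated`, the correlation matrix `cors`
#'   (zygosity x occasion), and logical `mz_negative`, `dz_negative`,
#'   `diff_negative` (NA when fewer than 2 complete pairs per group).
#' @export
e_dominance_diagnostics <- function(data, std_E_1, std_E_2,
                                    threshold = 0.99) {
  flag <- std_E_1 > threshold && std_E_2 > threshold
  cors <- twin_correlations(data)
  mzn <- if (anyNA(cors["MZ", ])) NA else all(cors["MZ", ] < 0)
  dzn <- if (anyNA(cors["DZ", ])) NA else all(cors["DZ", ] < -0.05)
  dfn <- if (anyNA(cors)) NA else all(cors["MZ", ] - cors["DZ", ] < -0.1)
  list(e_dominated = flag, cors = cors, mz_negative = mzn,
       dz_negative = dzn, diff_negative = dfn)
}

#' Across-site component summaries
#'
#' Means and SDs of standardized and absolute components per occasion,
#' for the four reporting groups: all sites under the ADE fit, ADE-best
#' sites, all sites under the ACE fit, ACE-best sites.
#'
#' @param results results table from [run_methylome()] (or the
#'   `$results` data.frame).
#' @return data.frame with one row per group x component x occasion.
#' @export
summarize_components <- function(results) {
  if (inherits(results, "twin_scan")) results <- results$results
  comp_cols <- c("std_A", "std_CD", "std_E", "abs_A", "abs_CD", "abs_E", "h2")
  groups <- list(ADE = quote(variant == "ADE"),
                 ADE_best = quote(variant == "ADE" & is_best),
                 ACE = quote(variant == "ACE"),
                 ACE_best = quote(variant == "ACE" & is_best))
  rows <- list()
  for (g in names(groups)) {
    sub <- results[eval(groups[[g]], results), , drop = FALSE]
    for (cc in comp_cols) for (t in 1:2) {
      v <- sub[[paste0(cc, "_", t)]]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = cc, occasion = t, n_sites = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Paired within-site change test
#'
#' Classical paired t-test of a per-site estimate across the two
#' occasions (e.g. broad heritability at occasion 2 minus occasion 1).
#'
#' @param x_t1,x_t2 per-site estimates at occasions 1 and 2.
#' @return list with `mean_diff` (t2 - t1), `t`, `df`, `ci95`, `p`.
#' @export
paired_change_test <- function(x_t1, x_t2) {
  ok <- is.finite(x_t1) & is.finite(x_t2)
  if (sum(ok) < 2L) stop("need at least 2 sites with estimates at both occasions")
  d <- x_t2[ok] - x_t1[ok]
  if (sd(d) == 0) {  # degenerate: all within-site differences equal
    m <- mean(d)
    return(list(mean_diff = m, t = if (m == 0) 0 else sign(m) * Inf,
                df = length(d) - 1L, ci95 = c(m, m),
                p = if (m == 0) 1 else 0))
  }
  tt <- t.test(x_t2[ok], x_t1[ok], paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), ci95 = unname(tt$conf.int),
       p = tt$p.value)
}

#' Correlation between implied site SD and heritable share
#'
#' Pearson correlation, per occasion, between the model-implied M-value
#' SD (country-0 scale) and the standardized heritable share across
#' sites.
#'
#' @param results results table (rows of one variant subset, e.g.
#'   best-fitting ADE rows).
#' @param h2_col column holding the heritable share (default broad `h2`).
#' @return named length-2 vector (`t1`, `t2`); `NA` with a warning when a
#'   vector is constant.
#' @export
sd_h2_correlation <- function(results, h2_col = "h2") {
  if (inherits(results, "twin_scan")) results <- results$results
  if (nrow(results) < 3L) stop("need at least 3 sites")
  out <- c(t1 = NA_real_, t2 = NA_real_)
  for (t in 1:2) {
    s <- sqrt(results[[paste0("total_var_", t)]])
    h <- results[[paste0(h2_col, "_", t)]]
    ok <- is.finite(s) & is.finite(h)
    if (sum(ok) >= 3L && sd(s[ok]) > 0 && sd(h[ok]) > 0)
      out[t] <- cor(s[ok], h[ok])
    else warning("constant or insufficient values at occasion ", t,
                 "; correlation undefined")
  }
  out
}
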