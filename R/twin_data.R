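#' Assemble per-site twin-pair observations
#'
#' Builds the analysis container for one CpG site: the observation matrix
#' over the four pair slots (twin 1 occasion 1, twin 1 occasion 2, twin 2
#' occasion 1, twin 2 occasion 2) together with pair covariates. `NA` in
#' `y` marks an unobserved slot; the likelihood marginalizes over it.
#'
#' @param y numeric matrix, pairs x 4, M-values; `NA` = unobserved.
#'   Columns in slot order (tw1.t1, tw1.t2, tw2.t1, tw2.t2).
#' @param age numeric matrix, pairs x 4, age in years at the occasion each
#'   slot was measured, or a pairs x 2 matrix of per-occasion ages shared
#'   by both twins.
#' @param sex integer vector (0 = male, 1 = female), one per pair; twins
#'   in a pair are same-sex.
#' @param country integer vector (0 = reference country, 1 = scaled
#'   country), one per pair.
#' @param zygosity character vector, `"MZ"` or `"DZ"`, one per pair.
#' @param pair_id character vector of pair identifiers.
#' @param site_id optional site identifier carried along for reporting.
#'
#' @return An object of class `twin_data`.
#' @export
twin_data <- function(y, age, sex, country, zygosity, pair_id = NULL,
                      site_id = NULL) {
  y <- as.matrix(y)
  if (ncol(y) != 4L) stop("'y' must have 4 columns (pair slots)")
  n <- nrow(y)
  age <- as.matrix(age)
  if (ncol(age) == 2L) age <- age[, c(1L, 2L, 1L, 2L), drop = FALSE]
  if (ncol(age) != 4L) stop("'age' must have 2 or 4 columns")
  if (nrow(age) != n) stop("'age' rows must match 'y'")
  sex <- as.integer(sex)
  country <- as.integer(country)
  zygosity <- as.character(zygosity)
  if (length(sex) != n || length(country) != n || length(zygosity) != n)
    stop("covariate lengths must match the number of pairs")
  if (!all(zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  if (!all(sex %in% 0:1)) stop("sex must be coded 0/1")
  if (!all(country %in% 0:1)) stop("country must be coded 0/1")
  obs <- !is.na(y)
  if (any(rowSums(obs) == 0L))
    stop("every pair must have at least one observed slot; offending pairs: ",
         paste(which(rowSums(obs) == 0L), collapse = ", "))
  if (is.null(pair_id)) pair_id <- sprintf("pair%04d", seq_len(n))
  colnames(y) <- colnames(age) <- c("tw1.t1", "tw1.t2", "tw2.t1", "tw2.t2")
  structure(list(y = y, age = age, sex = sex, country = country,
                 zygosity = zygosity, pair_id = as.character(pair_id),
                 site_id = site_id),
            class = "twin_data")
}

#' @export
print.twin_data <- function(x, ...) {
  n_obs <- sum(!is.na(x$y))
  cat("Twin-pair data", if (!is.null(x$site_id)) paste0("for site ", x$site_id),
      "\n", sep = " ")
  cat(sprintf("  %d pairs (%d MZ, %d DZ), %d observed values\n",
              nrow(x$y), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"),
              n_obs))
  cat(sprintf("  countries: %s; complete pairs: %d\n",
              paste(sort(unique(x$country)), collapse = ", "),
              sum(rowSums(!is.na(x$y)) == 4L)))
  invisible(x)
}

#' @export
`[.twin_data` <- function(x, i) {
  twin_data(x$y[i, , drop = FALSE], x$age[i, , drop = FALSE],
            x$sex[i], x$country[i], x$zygosity[i], x$pair_id[i], x$site_id)
}

# number of pairs
n_pairs <- function(data) nrow(data$y)

# Empirical cross-twin Pearson correlations per occasion and zygosity,
# pairwise-complete. Returns a 2x2 matrix [zyg x occasion] (NA where fewer
# than `min_pairs` complete pairs).
twin_correlations <- function(data, min_pairs = 2L) {
  out <- matrix(NA_real_, 2L, 2L, dimnames = list(c("MZ", "DZ"), c("t1", "t2")))
  for (z in c("MZ", "DZ")) {
    zi <- data$zygosity == z
    for (t in 1:2) {
      c1 <- data$y[zi, t]
      c2 <- data$y[zi, t + 2L]
      ok <- !is.na(c1) & !is.na(c2)
      if (sum(ok) >= min_pairs && sd(c1[ok]) > 0 && sd(c2[ok]) > 0)
        out[z, t] <- cor(c1[ok], c2[ok])
    }
  }
  out
}
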