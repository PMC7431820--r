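## Tabular readers/writers: long methylation TSV, pairs table, CpG
## annotation (plain or Illumina-manifest column naming), site-set lists,
## and the round-trippable results table. All files are UTF-8 TSV with a
## header and '.' decimal separator.

ISLAND_LEVELS <- c("Island", "North Shore", "South Shore", "North Shelf",
                   "South Shelf", "Open Seas")

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv <- function(df, path, digits17 = TRUE) {
  if (digits17) {
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- NA
      out
    })
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long methylation table
#'
#' Expects columns `site_id`, `pair_id`, `twin_index` (1 or 2),
#' `occasion` (1 or 2), `m_value`. Malformed rows and duplicate
#' (site, pair, twin, occasion) keys are rejected with their line
#' numbers (header = line 1).
#'
#' @param path TSV file path.
#' @return validated long data.frame.
#' @export
read_methylation <- function(path) {
  df <- read_tsv(path)
  need <- c("site_id", "pair_id", "twin_index", "occasion", "m_value")
  if (!all(need %in% names(df)))
    stop("methylation file must have columns: ", paste(need, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L
  bad <- !(df$twin_index %in% 1:2) | !(df$occasion %in% 1:2) |
    !is.finite(suppressWarnings(as.numeric(df$m_value)))
  if (any(bad))
    stop("malformed methylation rows at line(s): ",
         paste(utils::head(line[bad], 20), collapse = ", "))
  key <- paste(df$site_id, df$pair_id, df$twin_index, df$occasion)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (site, pair, twin, occasion) rows at line(s): ",
         paste(utils::head(line[dup], 20), collapse = ", "))
  df$m_value <- as.numeric(df$m_value)
  df$twin_index <- as.integer(df$twin_index)
  df$occasion <- as.integer(df$occasion)
  df
}

#' Read a pairs/demographics table
#'
#' Expects columns `pair_id`, `zygosity` (MZ/DZ), `country` (0/1), `sex`
#' (0/1), `age_t1`, `age_t2`; observation-mask columns (`obs_tw1_t1`,
#' ...) are optional — actual missingness is taken from the methylation
#' table on assembly.
#'
#' @param path TSV file path.
#' @return validated pairs data.frame.
#' @export
read_pairs <- function(path) {
  df <- read_tsv(path)
  need <- c("pair_id", "zygosity", "country", "sex", "age_t1", "age_t2")
  if (!all(need %in% names(df)))
    stop("pairs file must have columns: ", paste(need, collapse = ", "))
  if (!all(df$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be MZ or DZ")
  if (anyDuplicated(df$pair_id)) stop("duplicate pair_id in pairs file")
  df
}

#' Assemble per-site twin data from long methylation + pairs tables
#'
#' Joins are validated: every methylation `pair_id` must appear in the
#' pairs table (offenders are listed). No observed value is silently
#' dropped; pairs with no observed slot at a site are omitted from that
#' site's records.
#'
#' @param meth long methylation data.frame ([read_methylation()]).
#' @param pairs pairs data.frame ([read_pairs()]).
#' @return named list of [twin_data()] objects, one per site.
#' @export
assemble_twin_data <- function(meth, pairs) {
  missing_pairs <- setdiff(unique(meth$pair_id), pairs$pair_id)
  if (length(missing_pairs))
    stop("methylation pair_id(s) absent from pairs table: ",
         paste(utils::head(missing_pairs, 20), collapse = ", "))
  pairs <- pairs[order(pairs$pair_id), , drop = FALSE]
  slot <- (meth$twin_index - 1L) * 2L + meth$occasion
  out <- lapply(split(seq_len(nrow(meth)), meth$site_id), function(idx) {
    sub <- meth[idx, , drop = FALSE]
    pidx <- match(sub$pair_id, pairs$pair_id)
    upair <- sort(unique(pidx))
    y <- matrix(NA_real_, length(upair), 4L)
    y[cbind(match(pidx, upair), slot[idx])] <- sub$m_value
    pp <- pairs[upair, , drop = FALSE]
    twin_data(y, as.matrix(pp[, c("age_t1", "age_t2")]), pp$sex,
              pp$country, pp$zygosity, pp$pair_id,
              site_id = sub$site_id[1])
  })
  out[order(names(out))]
}

#' Write simulated or assembled data back to TSV
#'
#' @param sites named list of [twin_data()] (or a [simulate_methylome()]
#'   result).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_methylation <- function(sites, path) {
  if (is.list(sites) && !is.null(sites$sites)) sites <- sites$sites
  rows <- lapply(names(sites), function(sid) {
    d <- sites[[sid]]
    obs <- which(!is.na(d$y), arr.ind = TRUE)
    data.frame(site_id = sid, pair_id = d$pair_id[obs[, 1]],
               twin_index = ifelse(obs[, 2] > 2L, 2L, 1L),
               occasion = ifelse(obs[, 2] %% 2L == 1L, 1L, 2L),
               m_value = d$y[obs])
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_methylation
#' @param cohort pair-skeleton data.frame ([make_cohort()]).
#' @export
write_pairs <- function(cohort, path) write_tsv(cohort, path)

#' Read a CpG annotation table
#'
#' Two layouts: `format = "plain"` expects `site_id` and
#' `island_relation` (plus optional logical/0-1 set-membership columns);
#' `format = "illumina"` expects manifest naming (`IlmnID`,
#' `Relation_to_UCSC_CpG_Island` with values like `N_Shore`). A blank
#' island field maps to `"Open Seas"`.
#'
#' @param path TSV file path.
#' @param format `"plain"` or `"illumina"`.
#' @return data.frame with `site_id`, `island_relation` and any
#'   membership columns.
#' @export
read_annotation <- function(path, format = c("plain", "illumina")) {
  format <- match.arg(format)
  df <- read_tsv(path)
  if (format == "illumina") {
    if (!all(c("IlmnID", "Relation_to_UCSC_CpG_Island") %in% names(df)))
      stop("illumina annotation needs IlmnID and Relation_to_UCSC_CpG_Island")
    map <- c(Island = "Island", N_Shore = "North Shore",
             S_Shore = "South Shore", N_Shelf = "North Shelf",
             S_Shelf = "South Shelf")
    rel <- map[df$Relation_to_UCSC_CpG_Island]
    df <- data.frame(site_id = df$IlmnID,
                     island_relation = unname(rel),
                     df[, setdiff(names(df),
                                  c("IlmnID", "Relation_to_UCSC_CpG_Island")),
                        drop = FALSE])
  }
  if (!all(c("site_id", "island_relation") %in% names(df)))
    stop("annotation must have site_id and island_relation")
  blank <- is.na(df$island_relation) | df$island_relation == ""
  df$island_relation[blank] <- "Open Seas"
  bad <- !df$island_relation %in% ISLAND_LEVELS
  if (any(bad))
    stop("unknown island_relation value(s): ",
         paste(unique(df$island_relation[bad]), collapse = ", "))
  df
}

#' Read a site-set list and match it against a universe
#'
#' `read_site_set` reads one site id per line (no header needed; a
#' `site_id` header line is tolerated). `match_site_set` intersects a set
#' with the analysed universe, reporting — not failing on — absent ids.
#'
#' @param path text file of site ids.
#' @return character vector of ids.
#' @export
read_site_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  setdiff(unique(ids), "site_id")
}

#' @rdname read_site_set
#' @param set character vector of site ids.
#' @param universe site ids present in the analysis.
#' @export
match_site_set <- function(set, universe) {
  present <- intersect(set, universe)
  absent <- setdiff(set, universe)
  if (length(absent))
    message(length(present), " of ", length(set),
            " set sites present in data; ", length(absent), " absent")
  list(present = present, absent = absent)
}

#' Write / read a scan results table
#'
#' One row per site x fitted variant with likelihoods, AIC, paths,
#' components, tests and flags. Numeric fields are written with 17
#' significant digits so a read-back reproduces the in-memory values.
#'
#' @param scan a `twin_scan` object or its `results` data.frame.
#' @param path TSV file path.
#' @return `write_results`: the path, invisibly. `read_results`: the
#'   results data.frame.
#' @export
write_results <- function(scan, path) {
  df <- if (inherits(scan, "twin_scan")) scan$results else scan
  write_tsv(df, path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0L) return(df)
  logi <- c("is_best", "converged", "mean_out_of_range", "sd_out_of_range",
            "keep", "low_stability", "e_dominated", "significant_1e7",
            "significant_1e2")
  for (cc in intersect(logi, names(df))) df[[cc]] <- as.logical(df[[cc]])
  df
}

#' @rdname write_methylation
#' @param truth truth data.frame from [simulate_methylome()].
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)
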