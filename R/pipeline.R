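## One-call orchestration: simulate -> fit -> classify -> summarize ->
## set comparisons -> overlap, with TSV artifacts and a reproducibility
## manifest. Configurable from a YAML file or an equivalent list.

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a synthetic methylome over the configured twin
#' cohorts; (2) fit the per-site model battery; (3) classify sites;
#' (4) summarize components; (5) optional CpG-set comparison; (6)
#' optional hypergeometric overlap test. Each stage writes a TSV under
#' `out_dir`; a manifest records the seed, package version, configuration
#' and output checksums. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config path to a YAML file or a list with elements:
#'   `out_dir` (required), `seed`, `n_sites`, `truth` (list:
#'   `std_t1`, `std_t2`, `cors`, `variant`, optional `k`, `beta`),
#'   `cohorts` (`"default"` or a list of [cohort_config()] argument
#'   lists), `variants`, `thresholds`, `threads`, optional `set_file`
#'   (site-id list for a set comparison) and `overlap` (list with
#'   counts `k`, `K`, `n`, `N`).
#' @return list with the scan, summaries and output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    seed = 1L, n_sites = 20L, cohorts = "default",
    variants = VARIANTS, threads = 1L,
    truth = list(std_t1 = c(0.111, 0.127, 0.762),
                 std_t2 = c(0.091, 0.089, 0.820),
                 cors = c(0.9, 0.9, 0.2), variant = "ADE",
                 k = c(0.90, 0.88)),
    thresholds = default_thresholds()), config)
  if (is.null(cfg$out_dir)) stop("config must provide out_dir")
  if (!is.null(cfg$set_file) && !file.exists(cfg$set_file))
    stop("set_file not found: ", cfg$set_file)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)

  ## stage 1: simulate
  cohorts <- if (identical(cfg$cohorts, "default"))
    default_cohorts(seed = derive_seed(cfg$seed, 900001L))
  else lapply(seq_along(cfg$cohorts), function(i)
    do.call(cohort_config,
            utils::modifyList(cfg$cohorts[[i]],
                              list(seed = derive_seed(cfg$seed,
                                                      900001L + i)))))
  skel <- make_cohort(cohorts)
  tr <- cfg$truth
  truth_params <- paths_from_components(
    unlist(tr$std_t1), unlist(tr$std_t2), unlist(tr$cors %||% c(1, 1, 0)),
    total_var = unlist(tr$total_var %||% c(1, 1)),
    variant = tr$variant %||% "ADE", k = unlist(tr$k %||% c(1, 1)))
  sim <- simulate_methylome(cfg$n_sites, truth_params, skel,
                            seed = cfg$seed)
  write_methylation(sim, pth("methylation.tsv"))
  write_pairs(sim$cohort, pth("pairs.tsv"))
  write_truth(sim$truth, pth("truth.tsv"))

  ## stage 2: fit
  scan <- run_methylome(sim, variants = cfg$variants, seed = cfg$seed,
                        threads = cfg$threads,
                        thresholds = cfg$thresholds)
  write_results(scan, pth("results.tsv"))

  ## stage 3: classify
  cls <- classify_sites(scan, cfg$thresholds)
  write_tsv(cls, pth("classifications.tsv"))

  ## stage 4: summarize
  comp <- summarize_components(scan)
  write_tsv(comp, pth("summary.tsv"))

  ## stage 5: set comparison (optional)
  setcmp <- NULL
  if (!is.null(cfg$set_file)) {
    set_ids <- read_site_set(cfg$set_file)
    setcmp <- compare_sets(scan, set_ids)
    write_tsv(setcmp, pth("setcompare.tsv"))
  }

  ## stage 6: overlap (optional)
  ovl <- NULL
  if (!is.null(cfg$overlap)) {
    o <- cfg$overlap
    ovl <- hypergeom_overlap(o$k, o$K, o$n, o$N)
    write_tsv(data.frame(k = ovl$k, K = ovl$K, n = ovl$n, N = ovl$N,
                         p_upper = ovl$p_upper,
                         fold_enrichment = ovl$fold_enrichment,
                         overlap_fraction = ovl$overlap_fraction),
              pth("overlap.tsv"))
  }

  ## manifest
  outputs <- list.files(cfg$out_dir, pattern = "\\.tsv$")
  outputs <- setdiff(outputs, "manifest.yaml")
  manifest <- list(
    package = "twinmeth",
    version = as.character(utils::packageVersion("twinmeth")),
    seed = cfg$seed, n_sites = cfg$n_sites,
    variants = cfg$variants,
    thresholds = cfg$thresholds,
    outputs = as.list(tools::md5sum(file.path(cfg$out_dir,
                                              sort(outputs)))))
  names(manifest$outputs) <- sort(outputs)
  yaml::write_yaml(manifest, pth("manifest.yaml"))

  invisible(list(scan = scan, classification = cls, components = comp,
                 set_comparison = setcmp, overlap = ovl,
                 out_dir = cfg$out_dir,
                 manifest = pth("manifest.yaml")))
}
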