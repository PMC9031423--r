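#' One complete synthetic fidelity run
#'
#' Generates a paired fresh/air-dried dataset under the default study
#' design (19 plots at 4 sites, 300 OTUs at depth 5000), runs the full
#' pipeline (rarefied to 4000 reads, technical replicates at depth 2000)
#' and condenses the result into the study-level metrics: NDEP summaries
#' split by within- vs between-site pairs, the NDEP-distance Spearman
#' correlations, the EP-decline test, variation-partitioning fractions and
#' the recovery of the planted drying responders.
#'
#' @param seed integer seed driving both the generator and the pipeline.
#' @param generator optional [synthetic_config()] override (its seed is
#'   replaced by `seed`).
#' @param config optional [pipeline_config()] override (its seed is
#'   replaced by `seed`).
#' @return list: `metrics` (named numeric vector), `result` (the full
#'   [run_pipeline()] output), `dataset`.
#' @export
fidelity_run <- function(seed, generator = NULL, config = NULL) {
  gen <- generator %||% synthetic_config()
  gen$seed <- seed
  cfg <- config %||% pipeline_config(rarefy_depth = 4000,
                                     replicate_depth = 2000)
  cfg$seed <- seed
  ds <- generate_dataset(gen)
  res <- run_pipeline(ds$table, ds$frame, cfg)
  p <- res$pairs
  site_of <- ds$truth$site_of_plot
  same_site <- site_of[p$plot_a] == site_of[p$plot_b]
  da <- res$diff_abundance
  up <- da$otu_id[da$significant & da$direction == "up_in_air_dried"]
  down <- da$otu_id[da$significant & da$direction == "down_in_air_dried"]
  planted <- c(ds$truth$responders, ds$truth$sensitive)
  false_hits <- setdiff(da$otu_id[da$significant], planted)
  metrics <- c(
    n_pairs = nrow(p),
    mean_ndep = mean(p$ndep),
    median_ndep = stats::median(p$ndep),
    mean_ndep_within_site = mean(p$ndep[same_site]),
    mean_ndep_between_site = mean(p$ndep[!same_site]),
    median_ep_fresh = stats::median(p$ep_fresh),
    median_ep_air_dried = stats::median(p$ep_air_dried),
    ep_decline_fraction = mean(p$ep_fresh > p$ep_air_dried),
    ep_test_effect_r = res$ep_test$effect_size_r,
    ep_test_p = res$ep_test$p_value,
    spearman_spatial_rho = res$spearman_spatial$rho,
    spearman_env_rho = res$spearman_env$rho,
    varpart_pure_spatial = res$varpart$frac_a,
    varpart_shared = res$varpart$frac_b,
    varpart_pure_env = res$varpart$frac_c,
    sensitivity_responders = mean(ds$truth$responders %in% up),
    sensitivity_sensitive = mean(ds$truth$sensitive %in% down),
    false_discoveries = length(false_hits),
    n_tested_otus = attr(da, "n_tests"))
  list(metrics = metrics, result = res, dataset = ds)
}

#' Multi-seed synthetic fidelity study
#'
#' Repeats [fidelity_run()] over `n_seeds` independent seeds derived from
#' `base_seed` and stacks the per-seed metrics.
#'
#' @param n_seeds number of independent runs (default 50).
#' @param base_seed master seed.
#' @param generator,config passed to [fidelity_run()].
#' @param quiet suppress the per-run progress message.
#' @return data.frame of metrics, one row per seed, with a `seed` column.
#' @export
fidelity_study <- function(n_seeds = 50, base_seed = 1L, generator = NULL,
                           config = NULL, quiet = TRUE) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- derive_seed(base_seed, paste0("study|", i))
    if (!quiet) message("fidelity run ", i, "/", n_seeds, " (seed ", s, ")")
    m <- fidelity_run(s, generator = generator, config = config)$metrics
    c(seed = s, m)
  })
  as.data.frame(do.call(rbind, rows))
}
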