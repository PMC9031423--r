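#' Pipeline configuration
#'
#' Bundles the tunable parameters of [run_pipeline()]. Thresholds mirror
#' the motivating study's choices (6 technical replicates, 7 scale classes,
#' 90% prevalence, Bonferroni at alpha) but none is hard-coded.
#'
#' @param rarefy_depth depth all samples are rarefied to before analysis;
#'   `NULL` uses the minimum sample total.
#' @param replicate_depth depth of the technical-replicate subsamples drawn
#'   inside [pairwise_ep()]; `NULL` uses half the rarefaction depth.
#' @param n_replicates technical replicates per plot.
#' @param n_permutations PERMANOVA permutations when exact enumeration is
#'   unavailable.
#' @param k_classes Jenks classes per scale type.
#' @param variables environmental variables used for the environmental
#'   difference and the predictor matrix.
#' @param min_prevalence prevalence threshold for differential abundance.
#' @param alpha significance level.
#' @param varpart_env `"scalar"` (composite environmental difference) or
#'   `"columns"` (per-variable difference matrix) as the second
#'   explanatory set of the variation partitioning.
#' @param criterion model-selection criterion for [best_subset()].
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(rarefy_depth = NULL, replicate_depth = NULL,
                            n_replicates = 6, n_permutations = 999,
                            k_classes = 7, variables = env_variables(),
                            min_prevalence = 0.9, alpha = 0.05,
                            varpart_env = c("scalar", "columns"),
                            criterion = c("bic", "adjr2", "cp"),
                            seed = 1L) {
  varpart_env <- match.arg(varpart_env)
  criterion <- match.arg(criterion)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full fidelity pipeline
#'
#' Executes, in order: rarefaction; pairwise EP by PERMANOVA for the fresh
#' and the air-dried series; pair assembly and NDEP; the paired signed-rank
#' comparison of the EP series; Spearman correlations of NDEP against
#' spatial distance and environmental difference; Jenks scale summaries for
#' both; two-set variation partitioning; best-subset regression of NDEP on
#' the per-variable environmental differences with relative effects; and
#' paired differential abundance. All randomness flows from `config$seed`
#' through named sub-streams, so a rerun with the same inputs is
#' byte-identical. A stage failure aborts with the stage name; results of
#' completed stages are still written when `outdir` is set.
#'
#' @param table community_table with both treatments.
#' @param frame paired sample metadata.
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, result tables are written
#'   as TSV plus a JSON run manifest.
#' @param quiet suppress progress messages.
#' @return list: `pairs`, `ep_test`, `spearman_spatial`, `spearman_env`,
#'   `scale_spatial`, `scale_env`, `varpart`, `model`, `diff_abundance`,
#'   `rarefied_depth`, `replicate_depth`, `manifest`.
#' @export
run_pipeline <- function(table, frame, config = pipeline_config(),
                         outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  frame <- validate_sample_frame(frame)
  res <- list()
  stage <- "rarefy"
  fail <- function(e) {
    if (!is.null(outdir)) write_pipeline_outputs(res, outdir, config)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  run <- function(name, expr) {
    stage <<- name
    say("stage: %s", name)
    tryCatch(expr, error = fail)
  }

  depth <- config$rarefy_depth %||% min(rowSums(table$counts))
  tab_r <- run("rarefy",
               rarefy(table, depth = depth,
                      seed = derive_seed(config$seed, "rarefy"),
                      drop_shallow = TRUE))
  frame <- frame[frame$sample_id %in% rownames(tab_r$counts), , drop = FALSE]
  rep_depth <- config$replicate_depth %||% floor(depth / 2)
  res$rarefied_depth <- depth
  res$replicate_depth <- rep_depth

  ep_f <- run("pairwise_ep_fresh",
              pairwise_ep(tab_r, frame, "fresh",
                          n_replicates = config$n_replicates,
                          depth = rep_depth, seed = config$seed,
                          n_permutations = config$n_permutations))
  ep_d <- run("pairwise_ep_air_dried",
              pairwise_ep(tab_r, frame, "air_dried",
                          n_replicates = config$n_replicates,
                          depth = rep_depth, seed = config$seed,
                          n_permutations = config$n_permutations))

  res$pairs <- run("assemble_pairs", {
    sp_dm <- geodesic_matrix(frame)
    env_dm <- environmental_distance(frame, config$variables)
    assemble_pairs(ep_f, ep_d, sp_dm, env_dm)
  })
  pairs <- res$pairs

  res$ep_test <- run("paired_ep_test",
                     paired_ep_test(pairs$ep_fresh, pairs$ep_air_dried))
  res$spearman_spatial <- run("spearman_spatial",
                              spearman(pairs$spatial_km, pairs$ndep))
  res$spearman_env <- run("spearman_env",
                          spearman(pairs$env_diff, pairs$ndep))
  res$scale_spatial <- run("scale_spatial",
                           scale_summary(pairs, "spatial", config$k_classes))
  res$scale_env <- run("scale_environmental",
                       scale_summary(pairs, "environmental",
                                     config$k_classes))

  res$varpart <- run("varpart", {
    x2 <- if (config$varpart_env == "scalar") {
      matrix(pairs$env_diff, dimnames = list(NULL, "env_diff"))
    } else {
      predictor_differences(frame, pairs, config$variables)
    }
    varpart2(pairs$ndep,
             matrix(pairs$spatial_km, dimnames = list(NULL, "spatial_km")),
             x2)
  })

  res$model <- run("best_subset", {
    Xd <- predictor_differences(frame, pairs, config$variables)
    best_subset(pairs$ndep, Xd, criterion = config$criterion)
  })

  res$diff_abundance <- run("diff_abundance",
                            differential_abundance(
                              tab_r, frame,
                              min_prevalence = config$min_prevalence,
                              alpha = config$alpha))

  res$manifest <- list(
    package = "soilNDEP",
    version = as.character(utils::packageVersion("soilNDEP")),
    seed = config$seed,
    config_hash = derive_seed(0L, paste(deparse(unclass(config)),
                                        collapse = "")),
    n_plots = length(unique(frame$plot_id)),
    n_pairs = nrow(pairs),
    rarefied_depth = depth,
    replicate_depth = rep_depth)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir, config)
  res
}

#' Write pipeline outputs as TSV + JSON manifest
#' @keywords internal
write_pipeline_outputs <- function(res, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$pairs)) wt(res$pairs, "pair_results.tsv")
  if (!is.null(res$scale_spatial)) wt(res$scale_spatial, "scale_spatial.tsv")
  if (!is.null(res$scale_env)) wt(res$scale_env, "scale_environmental.tsv")
  if (!is.null(res$model) && nrow(res$model$coefficients)) {
    wt(res$model$coefficients, "model_selection.tsv")
  }
  if (!is.null(res$diff_abundance) && NROW(res$diff_abundance)) {
    wt(res$diff_abundance, "diff_abundance.tsv")
  }
  if (!is.null(res$varpart)) {
    vp <- res$varpart
    wt(data.frame(fraction = c("pure_spatial", "shared", "pure_env",
                               "residual", "r2adj_spatial", "r2adj_env",
                               "r2adj_both"),
                  value = c(vp$frac_a, vp$frac_b, vp$frac_c,
                            vp$frac_residual, vp$r2adj_x1, vp$r2adj_x2,
                            vp$r2adj_both)),
       "varpart.tsv")
  }
  summary <- list(manifest = res$manifest)
  if (!is.null(res$ep_test)) {
    summary$ep_test <- res$ep_test[c("statistic", "p_value",
                                     "effect_size_r", "n_pairs", "method",
                                     "median_a", "median_b")]
  }
  if (!is.null(res$spearman_spatial)) {
    summary$spearman_spatial <- res$spearman_spatial
    summary$spearman_env <- res$spearman_env
  }
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
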