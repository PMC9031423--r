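#' Synthetic study configuration
#'
#' Defaults emulate the motivating field design: 4 agricultural sites with
#' 5, 5, 6 and 3 plots (19 plots, 38 paired samples), inter-site distances
#' of roughly 500-2500 km, within-site plot scatter up to ~25 km, and an
#' environmental gradient (pH, nutrients, texture, water content, climate)
#' that tracks latitude, so space and environment are confounded as they
#' are in real transects.
#'
#' Fresh communities are log-normal: per-OTU log intensity = OTU baseline +
#' site effect + environmental loading + plot-level noise, mapped through a
#' softmax to multinomial probabilities and sampled at `depth` reads.
#' Air-drying applies a taxon-specific log-fold-change — a "responder" set
#' with positive LFC (a Firmicutes-like bloom) and a "sensitive" set with
#' negative LFC (a Proteobacteria-like decline) — plus plot-level log-normal
#' noise, to the same latent intensities.
#'
#' @param n_sites number of sites.
#' @param plots_per_site integer vector of plots per site.
#' @param n_otus number of OTUs.
#' @param depth reads per sample.
#' @param site_effect_scale SD of per-site, per-OTU log-abundance effects.
#' @param env_gradient_strength SD of per-OTU loadings on the two
#'   environmental axes (temperature, pH).
#' @param plot_effect_scale SD of plot-level log-abundance noise.
#' @param n_responders,n_sensitive sizes of the perturbed OTU sets (chosen
#'   among high-baseline OTUs so they survive prevalence filtering).
#' @param responder_lfc,sensitive_lfc mean log-fold-changes applied on
#'   drying.
#' @param lfc_spread SD of the per-OTU spread around the set mean LFC
#'   (shared across plots: the response is taxon-specific but directionally
#'   consistent everywhere).
#' @param perturbed_attenuation factor shrinking the site, environmental
#'   and plot effects of the perturbed OTUs. Drought responders and
#'   casualties are modelled as cosmopolitan generalists (spore-forming
#'   Firmicutes-like, ubiquitous Proteobacteria-like): their baseline share
#'   is similar at every plot, so the drying response is a shared
#'   perturbation rather than an amplifier of pre-existing site contrasts.
#' @param drying_effect optional full per-OTU LFC vector overriding the two
#'   sets.
#' @param drying_noise_sd SD of plot-by-OTU log noise added on drying (the
#'   idiosyncratic, plot-local part of the response).
#' @param seed master seed; all randomness flows from it through named
#'   sub-streams.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 4,
                             plots_per_site = c(5, 5, 6, 3),
                             n_otus = 300,
                             depth = 5000,
                             site_effect_scale = 1.2,
                             env_gradient_strength = 0.8,
                             plot_effect_scale = 0.4,
                             n_responders = 8,
                             n_sensitive = 12,
                             responder_lfc = 1.5,
                             sensitive_lfc = -1.0,
                             lfc_spread = 0.3,
                             perturbed_attenuation = 0.2,
                             drying_effect = NULL,
                             drying_noise_sd = 0.05,
                             seed = 1L) {
  stopifnot(length(plots_per_site) == n_sites, all(plots_per_site >= 1),
            n_otus > n_responders + n_sensitive, depth > 0,
            site_effect_scale > 0, env_gradient_strength >= 0,
            plot_effect_scale >= 0, drying_noise_sd >= 0, lfc_spread >= 0,
            perturbed_attenuation >= 0, perturbed_attenuation <= 1)
  if (!is.null(drying_effect)) stopifnot(length(drying_effect) == n_otus)
  structure(as.list(environment()), class = "synthetic_config")
}

# Default site centres (lon, lat): northeast black soil, north China plain,
# and two subtropical paddy regions; pairwise separations span ~0.5-2.5
# thousand km. Extra sites beyond four are interpolated along the transect.
site_centres <- function(n_sites) {
  base <- matrix(c(126.63, 47.43,
                   116.57, 36.83,
                   111.45, 28.92,
                   116.93, 28.21), ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("longitude", "latitude")))
  if (n_sites <= 4) return(base[seq_len(n_sites), , drop = FALSE])
  extra <- cbind(longitude = stats::runif(n_sites - 4, 108, 126),
                 latitude = stats::runif(n_sites - 4, 25, 48))
  rbind(base, extra)
}

#' Generate a paired fresh/air-dried synthetic dataset
#'
#' @param config a [synthetic_config()].
#' @return list: `table` (community_table, 2 x n_plots samples, with
#'   taxonomy), `frame` (sample metadata), `truth` (ground truth: per-plot
#'   fresh and air-dried probability vectors, applied LFC vector, responder
#'   and sensitive OTU ids, site assignments, environmental matrix).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n_plots <- sum(cf$plots_per_site)
  site_of_plot <- rep(seq_len(cf$n_sites), cf$plots_per_site)
  site_ids <- sprintf("S%d", seq_len(cf$n_sites))
  plot_ids <- sprintf("%sP%02d", site_ids[site_of_plot],
                      unlist(lapply(cf$plots_per_site, seq_len)))

  # --- placement: site centres plus within-site scatter (~<= 25 km) ---
  set.seed(derive_seed(cf$seed, "placement"))
  centres <- site_centres(cf$n_sites)
  lat <- centres[site_of_plot, "latitude"] + stats::runif(n_plots, -0.11, 0.11)
  lon <- centres[site_of_plot, "longitude"] + stats::runif(n_plots, -0.14, 0.14)

  # --- environment: latitude-driven gradients + site and plot noise ---
  set.seed(derive_seed(cf$seed, "environment"))
  site_noise <- function(sd) rep(stats::rnorm(cf$n_sites, 0, sd), cf$plots_per_site)
  pj <- function(sd) stats::rnorm(n_plots, 0, sd)
  AAT <- 30 - 0.62 * lat + pj(0.2)
  AP <- 3400 - 60 * lat + site_noise(60) + pj(25)
  pH <- 1.8 + 0.115 * lat + site_noise(0.45) + pj(0.15)
  SOC <- 5 + 0.45 * lat + site_noise(2.5) + pj(1.2)
  TN <- pmax(0.3, SOC / 11 + pj(0.08))
  TP <- pmax(0.2, 0.62 + site_noise(0.1) + pj(0.05))
  TK <- pmax(2, 5 + 0.25 * lat + site_noise(1.5) + pj(0.6))
  sand <- pmin(75, pmax(10, 40 + site_noise(9) + pj(2.5)))
  clay <- pmin(55, pmax(8, 25 + site_noise(7) + pj(2)))
  silt <- pmax(5, 100 - sand - clay)
  WC <- pmax(5, 12 + AP / 150 + site_noise(1.5) + pj(0.8))
  env <- cbind(pH = pH, SOC = SOC, TN = TN, TP = TP, TK = TK, sand = sand,
               silt = silt, clay = clay, WC = WC, AAT = AAT, AP = AP)
  rownames(env) <- plot_ids

  # --- fresh composition ---
  set.seed(derive_seed(cf$seed, "composition"))
  base <- stats::rnorm(cf$n_otus, 0, 1.5)
  site_eff <- matrix(stats::rnorm(cf$n_sites * cf$n_otus, 0,
                                  cf$site_effect_scale),
                     cf$n_sites, cf$n_otus)
  load_t <- stats::rnorm(cf$n_otus, 0, cf$env_gradient_strength / sqrt(2))
  load_p <- stats::rnorm(cf$n_otus, 0, cf$env_gradient_strength / sqrt(2))
  z <- function(v) (v - mean(v)) / stats::sd(v)
  plot_eff <- matrix(stats::rnorm(n_plots * cf$n_otus, 0,
                                  cf$plot_effect_scale),
                     n_plots, cf$n_otus)

  # perturbed sets: abundant but not the very top of the rank curve, so the
  # dried bloom stays a moderate share of the community; attenuated site /
  # env / plot effects make them cosmopolitan (see synthetic_config)
  otu_ids <- sprintf("OTU_%04d", seq_len(cf$n_otus))
  ord <- order(base, decreasing = TRUE)
  n_pert <- cf$n_responders + cf$n_sensitive
  start <- max(1L, min(10L, cf$n_otus - n_pert + 1L))
  idx_resp <- ord[start:(start + cf$n_responders - 1L)]
  idx_sens <- ord[(start + cf$n_responders):(start + n_pert - 1L)]
  responders <- otu_ids[idx_resp]
  sensitive <- otu_ids[idx_sens]
  idx_pert <- c(idx_resp, idx_sens)
  a <- cf$perturbed_attenuation
  site_eff[, idx_pert] <- a * site_eff[, idx_pert]
  load_t[idx_pert] <- a * load_t[idx_pert]
  load_p[idx_pert] <- a * load_p[idx_pert]
  plot_eff[, idx_pert] <- a * plot_eff[, idx_pert]

  lambda <- matrix(base, n_plots, cf$n_otus, byrow = TRUE) +
    site_eff[site_of_plot, , drop = FALSE] +
    outer(z(AAT), load_t) + outer(z(pH), load_p) + plot_eff
  softmax_rows <- function(m) {
    e <- exp(m - apply(m, 1, max))
    e / rowSums(e)
  }
  p_fresh <- softmax_rows(lambda)

  # --- drying perturbation ---
  set.seed(derive_seed(cf$seed, "drying"))
  lfc <- cf$drying_effect
  if (is.null(lfc)) {
    lfc <- numeric(cf$n_otus)
    lfc[idx_resp] <- cf$responder_lfc +
      stats::rnorm(cf$n_responders, 0, cf$lfc_spread)
    lfc[idx_sens] <- cf$sensitive_lfc +
      stats::rnorm(cf$n_sensitive, 0, cf$lfc_spread)
  }
  dry_noise <- if (cf$drying_noise_sd > 0) {
    matrix(stats::rnorm(n_plots * cf$n_otus, 0, cf$drying_noise_sd),
           n_plots, cf$n_otus)
  } else {
    matrix(0, n_plots, cf$n_otus)
  }
  p_dry <- softmax_rows(lambda +
                          matrix(lfc, n_plots, cf$n_otus, byrow = TRUE) +
                          dry_noise)

  # --- sequencing: multinomial reads per sample ---
  set.seed(derive_seed(cf$seed, "sampling"))
  counts <- matrix(0L, 2 * n_plots, cf$n_otus,
                   dimnames = list(c(paste0(plot_ids, "_F"),
                                     paste0(plot_ids, "_D")), otu_ids))
  for (i in seq_len(n_plots)) {
    counts[i, ] <- stats::rmultinom(1, cf$depth, p_fresh[i, ])[, 1]
    counts[n_plots + i, ] <- stats::rmultinom(1, cf$depth, p_dry[i, ])[, 1]
  }
  # every sample must stay non-empty; depth >= 1 guarantees it

  # --- taxonomy: responders Firmicutes-like, sensitive Proteobacteria/
  #     Acidobacteria-like, background from typical soil phylum weights ---
  set.seed(derive_seed(cf$seed, "taxonomy"))
  pool <- c(Proteobacteria = 0.22, Chloroflexi = 0.15, Actinobacteria = 0.14,
            Acidobacteria = 0.12, Planctomycetes = 0.09, Firmicutes = 0.08,
            Bacteroidetes = 0.06, Gemmatimonadetes = 0.05,
            Crenarchaeota = 0.05, Nitrospirae = 0.04)
  phyla <- sample(names(pool), cf$n_otus, replace = TRUE, prob = pool)
  phyla[match(responders, otu_ids)] <- "Firmicutes"
  phyla[match(sensitive, otu_ids)] <-
    rep_len(c("Proteobacteria", "Acidobacteria"), cf$n_sensitive)
  taxonomy <- stats::setNames(paste0("Bacteria; ", phyla), otu_ids)

  frame <- data.frame(
    sample_id = rownames(counts),
    plot_id = rep(plot_ids, 2),
    site_id = rep(site_ids[site_of_plot], 2),
    treatment = rep(c("fresh", "air_dried"), each = n_plots),
    latitude = rep(lat, 2), longitude = rep(lon, 2),
    rbind(env, env), row.names = NULL, check.names = FALSE)

  rownames(p_fresh) <- rownames(p_dry) <- plot_ids
  colnames(p_fresh) <- colnames(p_dry) <- otu_ids
  list(table = community_table(counts, taxonomy = taxonomy),
       frame = validate_sample_frame(frame),
       truth = list(p_fresh = p_fresh, p_air_dried = p_dry,
                    lfc = stats::setNames(lfc, otu_ids),
                    responders = responders, sensitive = sensitive,
                    site_of_plot = stats::setNames(site_ids[site_of_plot],
                                                   plot_ids),
                    env = env, config = cf))
}

#' Deterministic miniature fixtures for tests and examples
#'
#' @return named list of small generated datasets: `null` (no drying
#'   perturbation at all), `strong_drying` (large LFCs, no drying noise)
#'   and `mini` (default-like perturbation), each 4 plots x 60 OTUs.
#' @export
fixture_suite <- function() {
  small <- function(...) {
    synthetic_config(n_sites = 2, plots_per_site = c(2, 2), n_otus = 60,
                     depth = 1500, n_responders = 4, n_sensitive = 6, ...)
  }
  list(
    null = generate_dataset(small(drying_effect = rep(0, 60),
                                  drying_noise_sd = 0, seed = 101L)),
    strong_drying = generate_dataset(small(responder_lfc = 4,
                                           sensitive_lfc = -3,
                                           drying_noise_sd = 0, seed = 102L)),
    mini = generate_dataset(small(seed = 103L)))
}
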