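#' Normalised difference explanation proportion (NDEP)
#'
#' `NDEP = (EP_fresh - EP_air_dried) / EP_fresh`. NDEP is at most 1 and may
#' be negative when the air-dried EP exceeds the fresh EP.
#'
#' @param ep_fresh,ep_air_dried EP values (vectors recycle).
#' @return NDEP values.
#' @export
compute_ndep <- function(ep_fresh, ep_air_dried) {
  if (any(ep_fresh <= 0)) {
    stop("NDEP undefined: ep_fresh must be > 0")
  }
  (ep_fresh - ep_air_dried) / ep_fresh
}

#' Paired comparison of fresh and air-dried EP series
#'
#' Wilcoxon signed-rank test on the matched EP differences (fresh minus
#' air-dried), two-sided. Zero differences are excluded by default
#' (Wilcoxon's rule; Pratt's method keeps them in the ranking). The effect
#' size is `r = |Z| / sqrt(n)` where Z is the normal-approximation statistic
#' (with tie correction and continuity correction) and n the number of
#' non-zero pairs. The p-value uses the exact signed-rank null for
#' `n <= exact_limit` without ties, the normal approximation otherwise.
#'
#' @param eps_fresh,eps_air_dried matched EP vectors.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit maximum n for the exact null distribution.
#' @return list of class `paired_ep_test`: statistic (V, sum of positive
#'   ranks), p_value, effect_size_r, z, n_pairs (non-zero pairs), method,
#'   median/IQR of both series, and the vector of differences.
#' @export
paired_ep_test <- function(eps_fresh, eps_air_dried,
                           zero_method = c("wilcox", "pratt"),
                           exact_limit = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(eps_fresh) == length(eps_air_dried))
  if (length(eps_fresh) < 5) stop("need at least 5 pairs")
  d <- eps_fresh - eps_air_dried
  if (all(d == 0)) stop("degenerate test: all paired differences are zero")

  if (zero_method == "wilcox") {
    dnz <- d[d != 0]
  } else {
    dnz <- d  # zeros ranked, then dropped from the statistic (Pratt)
  }
  n <- sum(d != 0)
  r <- rank(abs(dnz))
  if (zero_method == "pratt") {
    keep <- dnz != 0
    r <- r[keep]
    dnz <- dnz[keep]
  }
  v <- sum(r[dnz > 0])

  # normal approximation Z (used for the effect size, and for p when exact
  # enumeration is unavailable)
  if (zero_method == "pratt") {
    rall <- rank(abs(d))
    mu <- sum(rall[d != 0]) / 2
    sigma2 <- sum(rall[d != 0]^2) / 4
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  }
  z_raw <- (v - mu) / sqrt(sigma2)
  cc <- sign(v - mu) * 0.5
  z <- if (sigma2 > 0) (v - mu - cc) / sqrt(sigma2) else 0

  has_ties <- anyDuplicated(abs(dnz)) > 0
  if (zero_method == "wilcox" && n <= 15) {
    # direct enumeration of all 2^n sign patterns (valid with tied ranks)
    p <- signed_rank_enum_p(r, v, mu)
    method <- "exact"
  } else if (zero_method == "wilcox" && !has_ties && n <= exact_limit) {
    p <- signed_rank_exact_p(v, n)
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }

  structure(list(statistic = v, p_value = p,
                 effect_size_r = abs(z_raw) / sqrt(n), z = z,
                 n_pairs = n, method = method,
                 median_a = stats::median(eps_fresh),
                 median_b = stats::median(eps_air_dried),
                 iqr_a = stats::IQR(eps_fresh),
                 iqr_b = stats::IQR(eps_air_dried),
                 differences = d),
            class = "paired_ep_test")
}

#' @export
print.paired_ep_test <- function(x, ...) {
  cat(sprintf(
    "Paired signed-rank: V = %g, p = %.3g (%s), effect size r = %.3f, n = %d\n",
    x$statistic, x$p_value, x$method, x$effect_size_r, x$n_pairs))
  cat(sprintf("  medians (IQR): %.4f (%.4f) vs %.4f (%.4f)\n",
              x$median_a, x$iqr_a, x$median_b, x$iqr_b))
  invisible(x)
}

#' Exact two-sided signed-rank p-value by full sign enumeration
#'
#' Distribution of the positive-rank sum over all 2^n sign assignments of
#' the (possibly tied, average) ranks; two-sided via symmetry around mu.
#' @keywords internal
signed_rank_enum_p <- function(r, v, mu) {
  n <- length(r)
  v_all <- as.vector(as.matrix(expand.grid(rep(list(c(0, 1)), n))) %*% r)
  mean(abs(v_all - mu) >= abs(v - mu) - 1e-12)
}

#' Exact two-sided signed-rank p-value (no ties)
#'
#' Uses the exact distribution of the sum of positive ranks via
#' \code{stats::psignrank}.
#' @keywords internal
signed_rank_exact_p <- function(v, n) {
  lower <- stats::psignrank(v, n)
  upper <- 1 - stats::psignrank(v - 1, n)
  min(1, 2 * min(lower, upper))
}

#' Assemble per-pair results
#'
#' Joins the fresh and air-dried EP tables with the spatial and
#' environmental plot-distance matrices on the unordered plot-pair key and
#' computes NDEP per pair.
#'
#' @param fresh_eps,air_dried_eps data.frames from [pairwise_ep()].
#' @param spatial_dm,env_dm plot-level `dist_matrix` objects.
#' @return data.frame: plot_a, plot_b, ep_fresh, ep_air_dried, ndep,
#'   spatial_km, env_diff; one row per pair, ordered by (plot_a, plot_b).
#' @export
assemble_pairs <- function(fresh_eps, air_dried_eps, spatial_dm, env_dm) {
  kf <- pair_key(fresh_eps$plot_a, fresh_eps$plot_b)
  ka <- pair_key(air_dried_eps$plot_a, air_dried_eps$plot_b)
  sp <- dist_long(spatial_dm)
  ev <- dist_long(env_dm)
  ks <- pair_key(sp$label_a, sp$label_b)
  ke <- pair_key(ev$label_a, ev$label_b)
  all_keys <- list(fresh = kf, air_dried = ka, spatial = ks, env = ke)
  universe <- Reduce(union, all_keys)
  for (nm in names(all_keys)) {
    miss <- setdiff(universe, all_keys[[nm]])
    if (length(miss)) {
      stop("pairs missing from ", nm, " input: ",
           paste(utils::head(miss, 10), collapse = ", "))
    }
  }
  if (anyDuplicated(kf) || anyDuplicated(ka)) stop("duplicated pairs in EP input")
  o <- order(kf)
  out <- data.frame(
    plot_a = pmin(fresh_eps$plot_a[o], fresh_eps$plot_b[o]),
    plot_b = pmax(fresh_eps$plot_a[o], fresh_eps$plot_b[o]),
    ep_fresh = fresh_eps$ep[o],
    ep_air_dried = air_dried_eps$ep[match(kf[o], ka)],
    spatial_km = sp$value[match(kf[o], ks)],
    env_diff = ev$value[match(kf[o], ke)])
  out$ndep <- compute_ndep(out$ep_fresh, out$ep_air_dried)
  out[, c("plot_a", "plot_b", "ep_fresh", "ep_air_dried", "ndep",
          "spatial_km", "env_diff")]
}
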