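test_that("NDEP formula and its antisymmetry identity", {
  expect_equal(compute_ndep(0.9, 0.9), 0)
  expect_equal(compute_ndep(0.8, 0), 1)
  # the two series' medians give a small positive fidelity loss
  expect_equal(compute_ndep(0.956, 0.944), 0.0125523, tolerance = 1e-6)
  expect_error(compute_ndep(0, 0.5), "undefined")

  # compute_ndep(a, b) * a == -compute_ndep(b, a) * b
  set.seed(2)
  a <- runif(50, 0.1, 1)
  b <- runif(50, 0.1, 1)
  expect_equal(compute_ndep(a, b) * a, -compute_ndep(b, a) * b,
               tolerance = 1e-12)
})

test_that("paired EP test matches exact signed-rank enumeration", {
  # all-positive differences, n = 10: two-sided p = 2 / 2^10
  f <- seq(0.5, 0.95, length.out = 10)
  d <- c(0.011, 0.023, 0.017, 0.031, 0.008, 0.027, 0.019, 0.041, 0.013,
         0.037)
  res <- paired_ep_test(f, f - d)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / 1024)
  expect_equal(res$statistic, 55)

  # mixed signs vs brute-force enumeration of all 2^n patterns
  for (dd in list(c(1, 2, 3, -1, 4, 5) / 100,
                  c(3, -2, 7, 1, -5, 4, 6, -1) / 100,
                  c(5, 4, -3, 2, 1, -6, 7, 8, -9, 10, 11, -12) / 1000)) {
    fr <- seq(0.6, 0.9, length.out = length(dd))
    got <- paired_ep_test(fr, fr - dd)
    expect_equal(got$p_value, brute_signed_rank_p(dd), tolerance = 1e-12,
                 info = paste(dd, collapse = ","))
    # and against the base implementation (whose exact path needs
    # untied absolute differences)
    if (!anyDuplicated(abs(dd))) {
      ref <- stats::wilcox.test(fr, fr - dd, paired = TRUE)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
    expect_lte(got$effect_size_r, 1)
  }

  # identical series are degenerate
  expect_error(paired_ep_test(f, f), "degenerate")
  # zero differences are excluded from n under the default rule
  fz <- c(f, 0.7)
  res_z <- paired_ep_test(fz, fz - c(d, 0))
  expect_equal(res_z$n_pairs, 10L)
})

test_that("effect size r tracks the normal-approximation Z", {
  set.seed(14)
  f <- runif(40, 0.5, 1)
  d <- rnorm(40, 0.02, 0.03)
  res <- paired_ep_test(f, f - d)
  n <- res$n_pairs
  expect_equal(res$effect_size_r,
               abs(res$statistic - n * (n + 1) / 4) /
                 sqrt(n * (n + 1) * (2 * n + 1) / 24) / sqrt(n),
               tolerance = 1e-9)
})

test_that("pair assembly joins on unordered keys and is order-invariant", {
  tp <- toy_paired_table(n_plots = 5)
  epf <- pairwise_ep(tp$table, tp$frame, "fresh", depth = 500, seed = 3)
  epd <- pairwise_ep(tp$table, tp$frame, "air_dried", depth = 500, seed = 3)
  sp <- geodesic_matrix(tp$frame)
  # a synthetic environmental matrix over the same plots
  fr <- tp$frame
  fr$pH <- rep(seq(4, 8, length.out = 5), 2)
  fr$SOC <- rep(c(12, 9, 22, 30, 17), 2)
  ev <- environmental_distance(fr, c("pH", "SOC"))

  pairs <- assemble_pairs(epf, epd, sp, ev)
  expect_equal(nrow(pairs), choose(5, 2))
  expect_equal(pairs$ndep,
               (pairs$ep_fresh - pairs$ep_air_dried) / pairs$ep_fresh)

  # shuffled EP row order gives the identical assembled table
  set.seed(8)
  pairs2 <- assemble_pairs(epf[sample(nrow(epf)), ],
                           epd[sample(nrow(epd)), ], sp, ev)
  expect_identical(pairs, pairs2)

  # swapped a/b columns still join (unordered key)
  eps <- epf
  eps[1, c("plot_a", "plot_b")] <- eps[1, c("plot_b", "plot_a")]
  expect_identical(assemble_pairs(eps, epd, sp, ev), pairs)

  # unmatched pairs are reported
  expect_error(assemble_pairs(epf[-1, ], epd, sp, ev), "missing")
})

test_that("mean NDEP grows with drying perturbation strength", {
  # monotonicity of the fidelity loss in the planted effect size
  mean_ndep <- vapply(c(0, 1, 2), function(strength) {
    out <- numeric(2)
    for (s in 1:2) {
      ds <- generate_dataset(synthetic_config(
        n_sites = 2, plots_per_site = c(3, 3), n_otus = 120, depth = 2500,
        n_responders = 4, n_sensitive = 6,
        responder_lfc = strength, sensitive_lfc = -strength / 1.5,
        drying_noise_sd = 0.02, seed = 300 + s))
      epf <- pairwise_ep(ds$table, ds$frame, "fresh", depth = 1200,
                         seed = s)
      epd <- pairwise_ep(ds$table, ds$frame, "air_dried", depth = 1200,
                         seed = s)
      out[s] <- mean(compute_ndep(epf$ep, epd$ep))
    }
    mean(out)
  }, numeric(1))
  expect_lt(abs(mean_ndep[1]), 0.02)     # null perturbation: NDEP ~ 0
  expect_gt(mean_ndep[3], mean_ndep[1])  # strong drying raises NDEP
})
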