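test_that("PERMANOVA hand cases: perfect separation and equal distances", {
  # 2 groups of 2, within d = 0, between d = 1: SS_total = 1, SS_within = 0
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  fit <- permanova(dist_matrix(d), c("g1", "g1", "g2", "g2"))
  expect_equal(fit$r_squared, 1)
  expect_true(fit$degenerate)
  expect_equal(fit$ss[["total"]], 1)

  # all distances equal: R^2 = df_between / (n - 1), pseudo-F = 1
  for (sizes in list(c(3, 3), c(4, 2), c(2, 2, 2))) {
    n <- sum(sizes)
    a <- length(sizes)
    de <- matrix(0.7, n, n, dimnames = list(paste0("s", 1:n),
                                            paste0("s", 1:n)))
    diag(de) <- 0
    g <- rep(paste0("g", seq_along(sizes)), sizes)
    fe <- permanova(dist_matrix(de), g, n_permutations = 19, seed = 1)
    expect_equal(fe$r_squared, (a - 1) / (n - 1), tolerance = 1e-12)
    expect_equal(fe$pseudo_f, 1, tolerance = 1e-12)
  }
})

test_that("PERMANOVA is invariant to consistent relabeling and decomposes SS", {
  set.seed(5)
  m <- matrix(rpois(8 * 30, 6), 8, 30,
              dimnames = list(paste0("s", 1:8), paste0("o", 1:30)))
  d <- bray_curtis(m)
  g <- stats::setNames(rep(c("x", "y"), each = 4), rownames(m))
  f1 <- permanova(d, g)
  # permute matrix rows jointly with (named) labels
  p <- sample(8)
  d2 <- dist_matrix(unclass(d)[p, p])
  f2 <- permanova(d2, g[rownames(d2)])
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$pseudo_f, f2$pseudo_f, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value)

  expect_equal(f1$ss[["within"]] + f1$ss[["between"]], f1$ss[["total"]],
               tolerance = 1e-9)

  expect_error(permanova(d, rep("x", 8)), "2 groups")
  expect_error(permanova(d, c("x", rep("y", 7))), "singleton")
})

test_that("PERMANOVA agrees with exhaustive-permutation oracle (n <= 8)", {
  set.seed(9)
  for (sizes in list(c(3, 3), c(4, 4), c(5, 3))) {
    n <- sum(sizes)
    m <- matrix(rpois(n * 25, 7), n, 25,
                dimnames = list(paste0("s", 1:n), paste0("o", 1:25)))
    m[1:sizes[1], 1:5] <- m[1:sizes[1], 1:5] + 4  # real group signal
    d <- bray_curtis(m)
    g <- rep(c("A", "B"), sizes)
    mine <- permanova(d, g)
    oracle <- brute_permanova(d, g)
    expect_equal(mine$r_squared, oracle$r_squared, tolerance = 1e-10)
    expect_equal(mine$pseudo_f, oracle$pseudo_f, tolerance = 1e-10)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-10)
  }
})

test_that("PERMANOVA R2 and F agree with vegan::adonis2", {
  set.seed(21)
  m <- matrix(rpois(12 * 50, 9), 12, 50,
              dimnames = list(paste0("s", 1:12), paste0("o", 1:50)))
  m[1:6, 1:8] <- m[1:6, 1:8] + 3
  g <- rep(c("A", "B"), each = 6)
  mine <- permanova(bray_curtis(m), g)
  ref <- vegan::adonis2(m ~ g, method = "bray", permutations = 99)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  # 500 null datasets: 12 exchangeable multinomial draws split 6/6; the
  # exact 462-split p should reject at close to nominal alpha = 0.05
  probs <- {
    set.seed(1)
    w <- exp(rnorm(80, 0, 1))
    w / sum(w)
  }
  g <- rep(c("A", "B"), each = 6)
  rej <- vapply(1:500, function(i) {
    set.seed(1000 + i)
    m <- t(vapply(1:12, function(j) rmultinom(1, 400, probs)[, 1],
                  numeric(80)))
    rownames(m) <- paste0("s", 1:12)
    permanova(bray_curtis(m), g)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("pairwise EP covers all plot pairs and detects disjoint support", {
  tp <- toy_paired_table(n_plots = 3)
  ep <- pairwise_ep(tp$table, tp$frame, "fresh", depth = 600, seed = 4)
  expect_equal(nrow(ep), 3L)  # C(3, 2)
  expect_true(all(ep$ep >= 0 & ep$ep <= 1))

  # identical call is deterministic and order-independent
  ep2 <- pairwise_ep(tp$table, tp$frame, "fresh", depth = 600, seed = 4)
  expect_identical(ep, ep2)

  # plots with disjoint OTU support: EP ~ 1
  counts <- rbind(A_F = c(rep(50L, 10), rep(0L, 10)),
                  B_F = c(rep(0L, 10), rep(50L, 10)),
                  A_D = c(rep(50L, 10), rep(0L, 10)),
                  B_D = c(rep(0L, 10), rep(50L, 10)))
  colnames(counts) <- paste0("o", 1:20)
  fr <- data.frame(sample_id = rownames(counts),
                   plot_id = rep(c("A", "B"), 2),
                   site_id = "s",
                   treatment = rep(c("fresh", "air_dried"), each = 2),
                   latitude = c(10, 11, 10, 11), longitude = 0)
  epd <- pairwise_ep(community_table(counts), fr, "fresh", depth = 250,
                     seed = 1)
  expect_gt(epd$ep, 0.95)

  # missing treatment sample for a plot
  expect_error(pairwise_ep(tp$table, tp$frame[-1, ], "fresh", depth = 600),
               "paired|missing|plot")
})
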