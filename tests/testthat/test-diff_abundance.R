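test_that("a consistently boosted OTU survives Bonferroni across 19 pairs", {
  set.seed(20)
  n_plots <- 19
  n_otus <- 40
  base <- exp(rnorm(n_otus, 0, 1))
  probs <- base / sum(base)
  boost <- probs
  boost[1] <- boost[1] * 3          # planted responder
  boost <- boost / sum(boost)
  depth <- 3000
  counts <- matrix(0L, 2 * n_plots, n_otus,
                   dimnames = list(c(sprintf("P%02d_F", 1:n_plots),
                                     sprintf("P%02d_D", 1:n_plots)),
                                   sprintf("o%02d", 1:n_otus)))
  for (i in 1:n_plots) {
    counts[i, ] <- rmultinom(1, depth, probs)[, 1]
    counts[n_plots + i, ] <- rmultinom(1, depth, boost)[, 1]
  }
  frame <- data.frame(sample_id = rownames(counts),
                      plot_id = rep(sprintf("P%02d", 1:n_plots), 2),
                      site_id = "s",
                      treatment = rep(c("fresh", "air_dried"),
                                      each = n_plots),
                      latitude = 30, longitude = 110)
  res <- differential_abundance(community_table(counts), frame,
                                min_prevalence = 0.9)
  row <- res[res$otu_id == "o01", ]
  expect_true(row$significant)
  expect_equal(row$direction, "up_in_air_dried")
  # 19 uniform-sign pairs: exact p = 2 * 2^-19, still significant when
  # multiplied by ~192 tests
  expect_lt(row$raw_p * 192, 0.05)
  # Bonferroni is monotone and never below raw p
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-15))
  expect_true(all(diff(res$adjusted_p[order(res$raw_p)]) >= -1e-15))
})

test_that("untestable OTUs are excluded from the Bonferroni family", {
  counts <- matrix(20L, 8, 4,
                   dimnames = list(c(sprintf("P%d_F", 1:4),
                                     sprintf("P%d_D", 1:4)),
                                   paste0("o", 1:4)))
  # o2 differs between treatments; o1, o3, o4 are identical everywhere
  counts[5:8, 2] <- 40L
  counts[5:8, 3] <- 10L  # keeps row sums varied; o3 also shifts
  frame <- data.frame(sample_id = rownames(counts),
                      plot_id = rep(paste0("P", 1:4), 2),
                      site_id = "s",
                      treatment = rep(c("fresh", "air_dried"), each = 4),
                      latitude = 0, longitude = 0)
  res <- differential_abundance(community_table(counts), frame,
                                min_prevalence = 0.5)
  # o1 and o4 have equal relative abundance in every pair -> untestable
  expect_setequal(attr(res, "untestable"), character(0))
  # equal counts but different row sums still give differing proportions;
  # force true untestability with equal row sums instead
  counts2 <- counts
  counts2[5:8, ] <- counts[1:4, ]
  counts2[5:8, 2] <- counts[1:4, 2]  # identical tables
  expect_warning(
    res2 <- differential_abundance(community_table(counts2), frame,
                                   min_prevalence = 0.5),
    "no testable")
  expect_equal(attr(res2, "n_tests"), 0L)
  expect_setequal(attr(res2, "untestable"), paste0("o", 1:4))

  # with a single testable OTU, adjusted p equals raw p
  counts3 <- counts2
  counts3[5:8, 1] <- c(30L, 28L, 33L, 25L)
  counts3[5:8, 2] <- counts3[5:8, 2] - (counts3[5:8, 1] - 20L)  # keep sums
  res3 <- differential_abundance(community_table(counts3), frame,
                                 min_prevalence = 0.5)
  testable <- res3[res3$otu_id %in% c("o1", "o2"), ]
  expect_equal(attr(res3, "n_tests"), 2L)
})

test_that("relative abundances and tested share are coherent", {
  tp <- toy_paired_table(n_plots = 6, n_otus = 30, depth = 900)
  res <- differential_abundance(tp$table, tp$frame, min_prevalence = 0.5)
  share <- attr(res, "tested_share_pct")
  expect_true(all(share > 0 & share <= 100))
  # per-sample relative abundances of ALL OTUs sum to one by construction
  ra <- tp$table$counts / rowSums(tp$table$counts)
  expect_equal(unname(rowSums(ra)), rep(1, 12), tolerance = 1e-12)
})

test_that("planted drying responders are recovered with correct direction", {
  ds <- generate_dataset(synthetic_config(seed = 41L))
  tab <- rarefy(ds$table, 4000, seed = 5)
  res <- differential_abundance(tab, ds$frame)
  hits <- res[res$significant, ]
  up <- hits$otu_id[hits$direction == "up_in_air_dried"]
  down <- hits$otu_id[hits$direction == "down_in_air_dried"]
  expect_gte(mean(ds$truth$responders %in% up), 0.9)
  expect_gte(mean(ds$truth$sensitive %in% down), 0.9)
})
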