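test_that("TSV round trip preserves counts and catches malformed input", {
  counts <- matrix(c(5L, 0L, 1L, 3L), 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("o1", "o2")))
  tab <- community_table(counts)
  expect_equal(unname(rowSums(tab$counts)), c(5, 4))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(tab, path)
  back <- read_community_table(path)
  expect_identical(back$counts, tab$counts)

  # duplicated sample id
  writeLines(c("sample_id\to1\to2", "s1\t5\t0", "s1\t1\t3"), path)
  expect_error(read_community_table(path), "duplicate")
  # empty file
  writeLines(character(), path)
  expect_error(read_community_table(path), "parse error")
  # fractional / negative counts
  expect_error(community_table(matrix(c(1.5, 1, 1, 1), 2,
                                      dimnames = list(c("a", "b"),
                                                      c("x", "y")))),
               "integral")
  expect_error(community_table(matrix(c(-1, 1, 1, 1), 2,
                                      dimnames = list(c("a", "b"),
                                                      c("x", "y")))),
               "non-negative")
})

test_that("BIOM-JSON tables read through biomformat, dense and sparse", {
  counts <- matrix(c(5L, 0L, 1L, 3L), 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("o1", "o2")))
  for (type in c("dense", "sparse")) {
    dat <- if (type == "dense") {
      list(list(5, 1), list(0, 3))  # OTUs x samples
    } else {
      list(list(0, 0, 5), list(0, 1, 1), list(1, 1, 3))
    }
    biom <- list(
      id = "t", format = "1.0.0", format_url = "http://biom-format.org",
      type = "OTU table", generated_by = "test", date = "2026-01-01",
      matrix_type = type, matrix_element_type = "int", shape = c(2, 2),
      rows = list(list(id = "o1", metadata = NULL),
                  list(id = "o2", metadata = NULL)),
      columns = list(list(id = "s1", metadata = NULL),
                     list(id = "s2", metadata = NULL)),
      data = dat)
    path <- withr::local_tempfile(fileext = ".biom")
    jsonlite::write_json(biom, path, auto_unbox = TRUE)
    tab <- read_community_table(path, format = "biom")
    expect_equal(tab$counts[c("s1", "s2"), c("o1", "o2")],
                 matrix(c(5, 0, 1, 3), 2, byrow = TRUE,
                        dimnames = list(c("s1", "s2"), c("o1", "o2"))),
                 info = type)
  }
})

test_that("rarefaction is hypergeometric, depth-exact and conservative", {
  counts <- matrix(c(10L, 0L, 6L, 6L), 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("x", "y")))
  tab <- community_table(counts)

  # depth equal to total leaves the sample unchanged
  r <- rarefy(tab, depth = 10, drop_shallow = TRUE, seed = 1)
  expect_identical(r$counts["a", ], c(x = 10, y = 0))

  # single-taxon sample keeps its support
  set.seed(1)
  expect_equal(unname(rarefy_counts(c(10, 0), 5)), c(5, 0))

  # hypergeometric expectation: [6, 6] at depth 6 averages 3 per taxon
  draws <- vapply(1:10000, function(i) {
    set.seed(i)
    rarefy_counts(c(6, 6), 6)[1]
  }, numeric(1))
  expect_lt(abs(mean(draws) - 3), 0.05)

  # properties on a random table: row sums hit depth, no taxa introduced
  set.seed(7)
  m <- matrix(rpois(200, 8), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("o", 1:20)))
  m[1, ] <- m[1, ] + 1  # guard non-zero rows
  big <- community_table(m)
  for (sd in c(1, 99)) {
    rr <- rarefy(big, depth = min(rowSums(m)), seed = sd)
    expect_true(all(rowSums(rr$counts) == min(rowSums(m))))
    expect_true(all(rr$counts <= big$counts))
  }

  # shallow samples: error by default, dropped with warning on request
  expect_error(rarefy(tab, depth = 11), "below depth")
  expect_warning(r2 <- rarefy(tab, depth = 11, drop_shallow = TRUE),
                 "dropping")
  expect_equal(rownames(r2$counts), "b")
  expect_error(rarefy(tab, depth = 20), "every sample")
})

test_that("prevalence filter uses strict 'more than' and is idempotent", {
  n <- 38
  m <- matrix(1L, n, 3,
              dimnames = list(paste0("s", 1:n), c("keep", "edge", "drop")))
  m[1:3, "edge"] <- 0L   # present in 35 of 38 -> 35 > 34.2, retained
  m[1:4, "drop"] <- 0L   # present in 34 of 38 -> removed
  tab <- community_table(m)
  f <- prevalence_filter(tab, 0.9)
  expect_setequal(colnames(f$counts), c("keep", "edge"))
  expect_equal(attr(f, "n_retained"), 2L)

  # idempotence
  f2 <- prevalence_filter(f, 0.9)
  expect_identical(f2$counts, f$counts)

  # min_fraction = 1 with strict ">" removes even ubiquitous OTUs
  expect_warning(f3 <- prevalence_filter(tab, 1, comparison = "gt"),
                 "no OTUs")
  expect_equal(ncol(f3$counts), 0L)
  f4 <- prevalence_filter(tab, 1, comparison = "ge")
  expect_true("keep" %in% colnames(f4$counts))
})

test_that("phylum summary ranks by mean relative abundance", {
  m <- matrix(c(60L, 40L, 30L, 20L), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  tax <- c(o1 = "Bacteria; Proteobacteria", o2 = "Bacteria; Firmicutes")
  tab <- community_table(m, taxonomy = tax)
  ps <- phylum_summary(tab, top_k = 1)
  expect_equal(ps$summary$phylum, "Proteobacteria")
  expect_equal(ps$summary$min_pct, 60)
  expect_equal(ps$summary$max_pct, 60)
  expect_equal(unname(ps$coverage), c(60, 60))

  # single phylum holds everything
  tab1 <- community_table(m, taxonomy = c(o1 = "Bacteria; Firmicutes",
                                          o2 = "Bacteria; Firmicutes"))
  ps1 <- phylum_summary(tab1, top_k = 3)
  expect_equal(nrow(ps1$summary), 1L)
  expect_equal(ps1$summary$min_pct, 100)
  expect_equal(unname(ps1$coverage), c(100, 100))

  expect_error(phylum_summary(community_table(m)), "taxonomy")
})

test_that("sample frame validation enforces the paired design", {
  tp <- toy_paired_table()
  expect_silent(validate_sample_frame(tp$frame))
  broken <- tp$frame[-1, ]
  expect_error(validate_sample_frame(broken), "paired design")
  bad <- tp$frame
  bad$latitude[1] <- 95
  expect_error(validate_sample_frame(bad), "latitude")
})
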