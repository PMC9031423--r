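#' Spearman rank correlation
#'
#' Average-rank tie handling; p-value from \code{stats::cor.test} (exact
#' permutation null for small n without ties, t/AS89 approximation
#' otherwise).
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return list: rho, p_value, n.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Jenks natural-breaks classification
#'
#' Exact Fisher-Jenks optimisation: the sorted values are cut into `k`
#' contiguous classes minimising the total within-class sum of squared
#' deviations from class means. Computed by dynamic programming over the
#' distinct values (weighted by multiplicity), so tied values always stay
#' in one class.
#'
#' @param values numeric vector.
#' @param k number of classes (>= 2, at most the number of distinct values).
#' @return list: `assignment` (class index 1..k per input value, 1 = lowest),
#'   `breaks` (per-class maximum value), `ssd` (optimal total within-class
#'   SSD).
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(k >= 2)
  u <- sort(unique(values))
  m <- length(u)
  if (m < k) stop("k = ", k, " exceeds the ", m, " distinct values")
  w <- as.numeric(table(factor(values, levels = u)))
  # prefix sums for O(1) weighted SSD of any run u[i..j]
  cw <- cumsum(w)
  cwx <- cumsum(w * u)
  cwx2 <- cumsum(w * u^2)
  ssd_run <- function(i, j) {
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    S <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    S2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    S2 - S^2 / W
  }
  # dp[c, j]: minimal SSD of splitting u[1..j] into c classes
  dp <- matrix(Inf, k, m)
  cut_at <- matrix(NA_integer_, k, m)
  for (j in 1:m) dp[1, j] <- ssd_run(1, j)
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:m) {
        for (i in c:j) {
          cand <- dp[c - 1, i - 1] + ssd_run(i, j)
          if (cand < dp[c, j]) {
            dp[c, j] <- cand
            cut_at[c, j] <- i
          }
        }
      }
    }
  }
  # backtrack class boundaries
  bounds <- integer(k + 1)
  bounds[k + 1] <- m
  j <- m
  for (c in k:2) {
    i <- cut_at[c, j]
    bounds[c] <- i - 1L
    j <- i - 1L
  }
  bounds[1] <- 0L
  class_of_value <- rep(seq_len(k), diff(bounds))
  assignment <- class_of_value[match(values, u)]
  breaks <- u[bounds[-1]]
  list(assignment = assignment, breaks = breaks, ssd = dp[k, m])
}

#' Per-class NDEP summaries across scale classes
#'
#' Classifies the chosen pairwise distance (spatial or environmental) into
#' `k` Jenks classes and summarises NDEP within each class.
#'
#' @param pairs data.frame from [assemble_pairs()].
#' @param which `"spatial"` or `"environmental"`.
#' @param k number of classes (default 7).
#' @return data.frame of class rows: class (1..k, smallest scale first),
#'   upper_value (class maximum distance), median_ndep, mean_ndep, n.
#'   Attribute `assignment` carries the per-pair class index.
#' @export
scale_summary <- function(pairs, which = c("spatial", "environmental"),
                          k = 7) {
  which <- match.arg(which)
  if (!nrow(pairs)) stop("no pairs")
  x <- if (which == "spatial") pairs$spatial_km else pairs$env_diff
  jb <- jenks_breaks(x, k)
  cls <- jb$assignment
  out <- data.frame(
    class = seq_len(k),
    upper_value = jb$breaks,
    median_ndep = vapply(seq_len(k),
                         function(c) stats::median(pairs$ndep[cls == c]),
                         numeric(1)),
    mean_ndep = vapply(seq_len(k),
                       function(c) mean(pairs$ndep[cls == c]), numeric(1)),
    n = as.integer(tabulate(cls, nbins = k)))
  attr(out, "assignment") <- cls
  attr(out, "which") <- which
  out
}
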