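# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# all permutations of 1..n as a matrix (n! rows); n <= 8
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# PERMANOVA by direct formula plus exhaustive label-permutation null
brute_permanova <- function(d, grouping) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- length(unique(grouping))
  ss <- function(g) {
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + d[i, j]^2
    tot <- tot / n
    w <- 0
    for (lab in unique(g)) {
      idx <- which(g == lab)
      for (i in idx) for (j in idx) if (i < j) w <- w + d[i, j]^2 / length(idx)
    }
    c(total = tot, within = w, between = tot - w)
  }
  s <- ss(grouping)
  f_of <- function(g) {
    sg <- ss(g)
    (sg[["between"]] / (a - 1)) / (sg[["within"]] / (n - a))
  }
  f_obs <- f_of(grouping)
  perms <- all_permutations(n)
  f_all <- apply(perms, 1, function(p) f_of(grouping[p]))
  list(r_squared = unname(s[["between"]] / s[["total"]]),
       pseudo_f = unname(f_obs),
       p_value = mean(f_all >= f_obs - 1e-12))
}

# optimal contiguous k-partition of sorted distinct values, exhaustive
brute_jenks <- function(values, k) {
  u <- sort(unique(values))
  m <- length(u)
  ssd_of <- function(v, w) sum(w * (v - sum(w * v) / sum(w))^2)
  w <- as.numeric(table(factor(values, levels = u)))
  best <- NULL
  for (cuts in utils::combn(seq_len(m - 1), k - 1, simplify = FALSE)) {
    b <- c(0, cuts, m)
    ssd <- sum(vapply(seq_len(k), function(c) {
      i <- (b[c] + 1):b[c + 1]
      ssd_of(u[i], w[i])
    }, numeric(1)))
    if (is.null(best) || ssd < best$ssd - 1e-12) {
      best <- list(ssd = ssd, bounds = b)
    }
  }
  cls <- rep(seq_len(k), diff(best$bounds))
  list(ssd = best$ssd, assignment = cls[match(values, u)],
       breaks = u[best$bounds[-1]])
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# a tiny paired community table with known structure: n_plots plots, both
# treatments, counts drawn from per-plot probability vectors
toy_paired_table <- function(n_plots = 4, n_otus = 40, depth = 1200,
                             seed = 42) {
  set.seed(seed)
  plots <- sprintf("P%02d", seq_len(n_plots))
  probs <- t(vapply(seq_len(n_plots), function(i) {
    w <- exp(rnorm(n_otus, 0, 1))
    w / sum(w)
  }, numeric(n_otus)))
  counts <- rbind(
    t(vapply(seq_len(n_plots),
             function(i) rmultinom(1, depth, probs[i, ])[, 1],
             numeric(n_otus))),
    t(vapply(seq_len(n_plots),
             function(i) rmultinom(1, depth, probs[i, ])[, 1],
             numeric(n_otus))))
  rownames(counts) <- c(paste0(plots, "_F"), paste0(plots, "_D"))
  colnames(counts) <- sprintf("OTU_%03d", seq_len(n_otus))
  frame <- data.frame(
    sample_id = rownames(counts),
    plot_id = rep(plots, 2),
    site_id = rep(c("SA", "SB"), length.out = n_plots)[rep(1:n_plots, 2)],
    treatment = rep(c("fresh", "air_dried"), each = n_plots),
    latitude = rep(seq(30, 31, length.out = n_plots), 2),
    longitude = rep(seq(110, 111, length.out = n_plots), 2))
  list(table = community_table(counts), frame = frame, probs = probs)
}
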