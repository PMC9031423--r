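.split_cache <- new.env(parent = emptyenv())

#' Indicator matrix of all distinct two-group splits
#'
#' Columns are 0/1 membership vectors of the smaller group over all
#' distinct splits of `n` samples into groups of `n1` and `n - n1`; with
#' equal group sizes sample 1 is fixed in group 1 to drop the symmetric
#' duplicates. Cached per (n, n1), since the pairwise-EP design reuses one
#' layout hundreds of times.
#' @keywords internal
split_indicators <- function(n, n1, equal) {
  key <- sprintf("%d|%d|%d", n, n1, equal)
  if (!is.null(.split_cache[[key]])) return(.split_cache[[key]])
  combos <- if (equal) utils::combn(2:n, n1 - 1L) else utils::combn(n, n1)
  k <- ncol(combos)
  Z <- matrix(0, n, k)
  if (equal) Z[1, ] <- 1
  Z[cbind(as.vector(combos), rep(seq_len(k), each = nrow(combos)))] <- 1
  .split_cache[[key]] <- Z
  Z
}

#' Sums of squares for a distance matrix grouping
#' @keywords internal
permanova_ss <- function(d2, grouping) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the sum of squared dissimilarities between and within groups,
#' forms the pseudo-F ratio, and obtains a p-value by permuting group labels.
#' `R^2 = SS_between / SS_total` is the explanation proportion (EP) of the
#' grouping factor.
#'
#' For two groups, when the number of distinct splits `choose(n, n1)`
#' (halved for equal group sizes) does not exceed `exact_limit`, the exact
#' null distribution is enumerated and
#' `p = #\{F_perm >= F_obs\} / n_splits` (the identity split is included, so
#' p >= 1/n_splits). Otherwise `n_permutations` random label permutations
#' are drawn and the add-one estimator `p = (1 + #\{F* >= F\}) / (1 + N)` is
#' used.
#'
#' @param dm `dist_matrix` (or square symmetric matrix with dimnames).
#' @param grouping named character/factor vector of group labels; names must
#'   match the matrix labels (unnamed vectors are taken in matrix order).
#' @param n_permutations number of random permutations when exact
#'   enumeration is not used.
#' @param seed integer seed for the permutation draw.
#' @param exact_limit maximum number of distinct two-group splits to
#'   enumerate exactly; set to 0 to force sampling.
#' @return list of class `permanova_result`: `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`, `df_between`, `df_within`, `ss` (total /
#'   within / between), `degenerate` (TRUE when SS_within = 0 and F is
#'   undefined), `method` ("exact" or "sampled").
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = NULL,
                      exact_limit = 10000) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (!is.null(names(grouping))) {
    if (!all(rownames(d) %in% names(grouping))) {
      stop("grouping does not cover all distance-matrix labels")
    }
    grouping <- grouping[rownames(d)]
  }
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match matrix size")
  sizes <- table(grouping)
  a <- length(sizes)
  if (a < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  d2 <- d^2
  ss <- permanova_ss(d2, grouping)
  df_between <- a - 1L
  df_within <- n - a
  degenerate <- ss[["within"]] <= .Machine$double.eps * ss[["total"]]
  f_obs <- if (degenerate) Inf else
    (ss[["between"]] / df_between) / (ss[["within"]] / df_within)
  r2 <- ss[["between"]] / ss[["total"]]

  # F is a monotone transform of SS_within (SS_total is permutation
  # invariant), so permuted F >= observed F iff permuted SS_within <=
  # observed SS_within; comparisons are done on SS_within for stability.
  w_obs <- ss[["within"]]
  eps <- 1e-12 * max(ss[["total"]], 1)

  exact <- FALSE
  if (a == 2 && exact_limit > 0) {
    n1 <- min(sizes)
    n_splits <- choose(n, n1)
    if (sizes[1] == sizes[2]) n_splits <- n_splits / 2
    if (n_splits <= exact_limit) exact <- TRUE
  }

  if (exact) {
    n1 <- as.integer(min(sizes))
    n2 <- n - n1
    Z <- split_indicators(n, n1, equal = sizes[[1]] == sizes[[2]])
    tot2 <- sum(d2)                       # sum over ordered pairs
    M <- crossprod(Z, d2)                 # splits x n
    s1 <- rowSums(M * t(Z))               # ordered-pair sum within group 1
    rest <- tot2 - 2 * as.vector(M %*% rep(1, n)) + s1
    w_all <- s1 / (2 * n1) + rest / (2 * n2)
    p <- mean(w_all <= w_obs + eps)
    n_perm_used <- ncol(Z)
    method <- "exact"
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      gp <- grouping[sample.int(n)]
      wp <- permanova_ss(d2, gp)[["within"]]
      if (wp <= w_obs + eps) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_permutations)
    n_perm_used <- n_permutations
    method <- "sampled"
  }

  structure(list(r_squared = unname(r2), pseudo_f = unname(f_obs),
                 p_value = p, n_permutations = n_perm_used,
                 df_between = df_between, df_within = df_within,
                 ss = ss, degenerate = degenerate, method = method),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.4f, pseudo-F = %s (df %d, %d), p = %.4g [%s, %d perms]%s\n",
    x$r_squared,
    if (x$degenerate) "undefined (SS_within = 0)" else sprintf("%.3f", x$pseudo_f),
    x$df_between, x$df_within, x$p_value, x$method, x$n_permutations,
    if (x$degenerate) " *degenerate*" else ""))
  invisible(x)
}

#' Pairwise explanation proportions (EP) for one treatment
#'
#' For every unordered pair of plots, technical replicates are produced by
#' independently rarefying each plot's count vector `n_replicates` times to
#' `depth`, giving a two-group design with `n_replicates` members per group.
#' A PERMANOVA on Bray-Curtis dissimilarities with plot identity (the
#' sampling location) as the factor yields the pair's EP (= R^2). 19 plots
#' give the full set of 171 pairs.
#'
#' Replicate RNG streams are derived from `(seed, treatment, pair,
#' replicate)`, so results do not depend on pair evaluation order.
#'
#' @param table community_table holding the samples of this treatment (and
#'   possibly others; rows are selected through `frame`).
#' @param frame sample metadata frame.
#' @param treatment `"fresh"` or `"air_dried"`.
#' @param n_replicates technical replicates per plot (default 6).
#' @param depth rarefaction depth for the replicates; must be at most the
#'   shallowest selected sample total.
#' @param seed master seed.
#' @param n_permutations permutations when exact enumeration is unavailable.
#' @param exact_limit see [permanova()].
#' @param resample `"rarefy"` (without replacement, default) or
#'   `"bootstrap"` (multinomial with replacement).
#' @return data.frame: plot_a, plot_b, treatment, ep, p_value,
#'   n_permutations, ordered by (plot_a, plot_b).
#' @export
pairwise_ep <- function(table, frame, treatment = c("fresh", "air_dried"),
                        n_replicates = 6, depth = NULL, seed = 1L,
                        n_permutations = 999, exact_limit = 10000,
                        resample = c("rarefy", "bootstrap")) {
  treatment <- match.arg(treatment)
  resample <- match.arg(resample)
  stopifnot(n_replicates >= 2)
  sub <- frame[frame$treatment == treatment, , drop = FALSE]
  if (anyDuplicated(sub$plot_id)) stop("multiple samples per plot for ",
                                       treatment)
  unpaired <- setdiff(unique(frame$plot_id), sub$plot_id)
  if (length(unpaired)) {
    stop("no ", treatment, " sample for plot(s): ",
         paste(unpaired, collapse = ", "))
  }
  missing <- setdiff(sub$sample_id, rownames(table$counts))
  if (length(missing)) stop("samples missing from table: ",
                            paste(missing, collapse = ", "))
  plots <- sort(sub$plot_id)
  sample_of <- stats::setNames(sub$sample_id, sub$plot_id)
  counts <- table$counts[sample_of[plots], , drop = FALSE]
  rownames(counts) <- plots
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- floor(min(totals) / 2)
  if (resample == "rarefy" && depth > min(totals)) {
    stop("depth ", depth, " exceeds shallowest sample (",
         min(totals), ") for plot ", plots[which.min(totals)])
  }
  if (length(plots) < 2) stop("need at least 2 plots")

  draw <- function(x, s) {
    set.seed(s)
    if (resample == "rarefy") rarefy_counts(x, depth)
    else stats::rmultinom(1, depth, x / sum(x))[, 1]
  }

  pairs <- utils::combn(plots, 2)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    mat <- matrix(0, 2 * n_replicates, ncol(counts))
    for (r in seq_len(n_replicates)) {
      mat[r, ] <- draw(counts[a, ],
                       derive_seed(seed, sprintf("%s|%s|%s|%d", treatment, a, b, r)))
      mat[n_replicates + r, ] <-
        draw(counts[b, ],
             derive_seed(seed, sprintf("%s|%s|%s|%d", treatment, b, a, r)))
    }
    rownames(mat) <- paste0(rep(c(a, b), each = n_replicates), "_r",
                            rep(seq_len(n_replicates), 2))
    dm <- bray_curtis(mat)
    fit <- permanova(dm, rep(c(a, b), each = n_replicates),
                     n_permutations = n_permutations,
                     seed = derive_seed(seed, sprintf("perm|%s|%s|%s", treatment, a, b)),
                     exact_limit = exact_limit)
    res[[k]] <- data.frame(plot_a = a, plot_b = b, treatment = treatment,
                           ep = fit$r_squared, p_value = fit$p_value,
                           n_permutations = fit$n_permutations)
  }
  out <- do.call(rbind, res)
  out[order(out$plot_a, out$plot_b), , drop = FALSE]
}
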