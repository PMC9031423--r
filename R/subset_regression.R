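#' Pairwise environmental-difference design matrix
#'
#' For every plot pair, the absolute difference of the min-max-normalised
#' plot values of each variable (predictors are standardised at the plot
#' level before differencing; `normalize = FALSE` differences first and
#' min-max-scales the differences instead).
#'
#' @param frame sample (or plot) metadata frame.
#' @param pairs data.frame with plot_a / plot_b columns; rows of the result
#'   align with it.
#' @param variables variable names (default [env_variables()]).
#' @param normalize normalise-then-difference (default TRUE).
#' @return numeric matrix, one row per pair, one column per variable.
#' @export
predictor_differences <- function(frame, pairs,
                                  variables = env_variables(),
                                  normalize = TRUE) {
  f <- plot_frame(frame)
  missing <- setdiff(variables, colnames(f))
  if (length(missing)) stop("missing variable(s): ",
                            paste(missing, collapse = ", "))
  m <- as.matrix(f[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  if (normalize) m <- minmax_scale(m)
  bad <- setdiff(c(pairs$plot_a, pairs$plot_b), rownames(m))
  if (length(bad)) stop("unknown plot(s): ", paste(unique(bad), collapse = ", "))
  d <- abs(m[pairs$plot_a, , drop = FALSE] - m[pairs$plot_b, , drop = FALSE])
  if (!normalize) d <- minmax_scale(d)
  rownames(d) <- pair_key(pairs$plot_a, pairs$plot_b)
  d
}

#' Model-selection criterion value for one OLS fit
#' @keywords internal
subset_criterion <- function(fit, y, criterion, sigma2_full) {
  n <- length(y)
  p <- length(fit$coefficients) - 1  # predictors, excluding intercept
  rss <- sum(fit$residuals^2)
  switch(criterion,
         bic = n * log(rss / n) + (p + 2) * log(n),
         adjr2 = -(1 - (rss / sum((y - mean(y))^2)) * (n - 1) / (n - p - 1)),
         cp = rss / sigma2_full - n + 2 * (p + 1))
}

#' Exhaustive best-subset OLS selection
#'
#' Enumerates every subset of the predictors (including the intercept-only
#' model), fits OLS with intercept, and returns the subset optimal under
#' the chosen criterion, with coefficient table and relative effects.
#'
#' @param y response vector.
#' @param X design matrix (named columns; p <= 20).
#' @param criterion `"bic"` (default), `"adjr2"` or `"cp"` (Mallows).
#' @return list of class `subset_model`: `selected` (character vector,
#'   empty if the intercept-only model wins), `coefficients` (data.frame
#'   variable, estimate, std_error, t_value, p_value, relative_effect_pct),
#'   `criterion_name`, `criterion_value`, and `by_criterion` (winning
#'   subset under each of the three criteria).
#' @export
best_subset <- function(y, X, criterion = c("bic", "adjr2", "cp")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  n <- length(y)
  stopifnot(p <= 20, n > p + 1)
  full <- stats::lm.fit(cbind(1, X), y)
  sigma2_full <- sum(full$residuals^2) / (n - p - 1)

  subsets <- lapply(0:(2^p - 1), function(mask) which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0))
  crits <- matrix(NA_real_, length(subsets), 3,
                  dimnames = list(NULL, c("bic", "adjr2", "cp")))
  for (i in seq_along(subsets)) {
    idx <- subsets[[i]]
    fit <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    if (fit$rank < length(idx) + 1) next  # rank-deficient candidate: skip
    for (cr in colnames(crits)) {
      crits[i, cr] <- subset_criterion(fit, y, cr, sigma2_full)
    }
  }
  if (all(is.na(crits[, criterion]))) stop("no full-rank candidate model")
  by_criterion <- lapply(stats::setNames(colnames(crits), colnames(crits)),
                         function(cr) colnames(X)[subsets[[which.min(crits[, cr])]]])
  best_idx <- subsets[[which.min(crits[, criterion])]]
  selected <- colnames(X)[best_idx]

  if (length(best_idx)) {
    df <- data.frame(y = y, X[, best_idx, drop = FALSE], check.names = FALSE)
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    rows <- rownames(sm) != "(Intercept)"
    est <- sm[rows, 1]
    if (any(est == 0) && all(est == 0)) stop("all estimates zero")
    coefs <- data.frame(
      variable = sub("^`|`$", "", rownames(sm)[rows]),
      estimate = est,
      std_error = sm[rows, 2],
      t_value = sm[rows, 3],
      p_value = sm[rows, 4],
      relative_effect_pct = relative_effects(stats::setNames(est, rownames(sm)[rows])),
      row.names = NULL)
  } else {
    coefs <- data.frame(variable = character(), estimate = numeric(),
                        std_error = numeric(), t_value = numeric(),
                        p_value = numeric(), relative_effect_pct = numeric())
  }
  structure(list(selected = selected, coefficients = coefs,
                 criterion_name = criterion,
                 criterion_value = min(crits[, criterion], na.rm = TRUE),
                 by_criterion = by_criterion),
            class = "subset_model")
}

#' @export
print.subset_model <- function(x, ...) {
  cat(sprintf("Best subset by %s: %s\n", x$criterion_name,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(intercept only)"))
  if (nrow(x$coefficients)) {
    tab <- x$coefficients
    tab$signif <- p_stars(tab$p_value)
    print(tab, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#' @keywords internal
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Relative effects of model estimates
#'
#' Each predictor's share of the total absolute standardised estimate:
#' `100 * |estimate_v| / sum_w |estimate_w|`. Shares sum to 100.
#'
#' @param estimates named numeric vector of (standardised) estimates.
#' @return named numeric vector of percentages.
#' @export
relative_effects <- function(estimates) {
  if (!length(estimates)) stop("empty estimates")
  total <- sum(abs(estimates))
  if (total == 0) stop("all estimates are zero")
  100 * abs(estimates) / total
}
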