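#' Adjusted R-squared of an OLS fit
#' @keywords internal
adj_r2 <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("too few observations (n = ", n, ") for ", p,
                       " predictors")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  p_eff <- fit$rank - 1L  # aliased columns carry no degrees of freedom
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(r2 = r2, adj = 1 - (1 - r2) * (n - 1) / (n - p_eff - 1))
}

#' Two-set variation partitioning on a univariate response
#'
#' Partitions the variation of a response (here NDEP) explained by two
#' explanatory sets into the pure fraction of set 1 (`frac_a`), the shared
#' fraction (`frac_b`), the pure fraction of set 2 (`frac_c`) and the
#' residual, using adjusted R-squared of the three OLS fits (on x1, on x2,
#' and on both). Fractions can be negative and are reported unclipped; a
#' display layer may floor them at zero.
#'
#' Identities: `frac_a + frac_b = r2adj_x1`, `frac_b + frac_c = r2adj_x2`,
#' `frac_a + frac_b + frac_c = r2adj_both`, and the four fractions sum to 1.
#'
#' @param response numeric vector.
#' @param x1,x2 explanatory matrices (vectors accepted) with matching rows.
#' @param adjusted use adjusted R-squared (default TRUE); FALSE uses raw
#'   R-squared.
#' @return list of class `varpart_result` with the fractions and the
#'   component (adjusted) R-squared values.
#' @export
varpart2 <- function(response, x1, x2, adjusted = TRUE) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  stopifnot(length(response) == nrow(x1), nrow(x1) == nrow(x2))
  pick <- function(f) if (adjusted) f$adj else f$r2
  r1 <- pick(adj_r2(response, x1))
  r2_ <- pick(adj_r2(response, x2))
  rb <- pick(adj_r2(response, cbind(x1, x2)))
  frac_a <- rb - r2_
  frac_c <- rb - r1
  frac_b <- r1 + r2_ - rb
  structure(list(frac_a = frac_a, frac_b = frac_b, frac_c = frac_c,
                 frac_residual = 1 - rb,
                 r2adj_x1 = r1, r2adj_x2 = r2_, r2adj_both = rb,
                 adjusted = adjusted),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf(
    "Variation partitioning (%s R2):\n  pure x1 = %.4f, shared = %.4f, pure x2 = %.4f, residual = %.4f\n",
    if (x$adjusted) "adjusted" else "raw",
    x$frac_a, x$frac_b, x$frac_c, x$frac_residual))
  cat(sprintf("  R2[x1] = %.4f, R2[x2] = %.4f, R2[x1+x2] = %.4f\n",
              x$r2adj_x1, x$r2adj_x2, x$r2adj_both))
  if (any(c(x$frac_a, x$frac_b, x$frac_c) < 0)) {
    cat("  note: negative fraction(s) reported unclipped\n")
  }
  invisible(x)
}
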