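#' Paired fresh vs air-dried differential abundance
#'
#' Converts counts to per-sample relative abundances, keeps OTUs present in
#' more than `min_prevalence` of the samples, and tests each surviving OTU
#' with a Wilcoxon signed-rank test on plot-matched (fresh, air-dried)
#' relative abundances. P-values are Bonferroni-corrected over the number
#' of testable OTUs (those with at least one non-zero paired difference);
#' OTUs with identical relative abundance in every pair are flagged
#' untestable and excluded from that count.
#'
#' @param table community_table covering both treatments (typically the
#'   rarefied table, so proportions are computed at constant depth).
#' @param frame paired sample metadata frame.
#' @param min_prevalence prevalence threshold (default 0.9; strict `>`).
#' @param alpha significance level for flags (default 0.05).
#' @return data.frame, one row per tested OTU sorted by adjusted p:
#'   otu_id, mean_ra_fresh, mean_ra_air_dried, delta, raw_p, adjusted_p,
#'   significant, direction, phylum. Attributes: `n_tests`,
#'   `untestable` (OTU ids), `tested_share_pct` (per-sample summed relative
#'   abundance of the tested OTUs, %).
#' @export
differential_abundance <- function(table, frame, min_prevalence = 0.9,
                                   alpha = 0.05) {
  validate_sample_frame(frame, require_paired = TRUE)
  missing <- setdiff(frame$sample_id, rownames(table$counts))
  if (length(missing)) stop("samples missing from table: ",
                            paste(missing, collapse = ", "))
  filtered <- prevalence_filter(
    table, min_fraction = min_prevalence)
  if (ncol(filtered$counts) == 0) {
    warning("no OTUs to test after prevalence filtering")
    return(data.frame())
  }
  ra <- filtered$counts / rowSums(table$counts[rownames(filtered$counts), ,
                                               drop = FALSE])
  plots <- sort(unique(frame$plot_id))
  id_of <- function(tr) {
    s <- frame[frame$treatment == tr, ]
    stats::setNames(s$sample_id, s$plot_id)[plots]
  }
  ra_f <- ra[id_of("fresh"), , drop = FALSE]
  ra_d <- ra[id_of("air_dried"), , drop = FALSE]

  diffs <- ra_d - ra_f
  testable <- colSums(diffs != 0) > 0
  untestable <- colnames(diffs)[!testable]
  n_tests <- sum(testable)
  if (n_tests == 0) {
    warning("no testable OTUs: all paired differences are zero")
    out <- data.frame(otu_id = character(), mean_ra_fresh = numeric(),
                      mean_ra_air_dried = numeric(), delta = numeric(),
                      raw_p = numeric(), adjusted_p = numeric(),
                      significant = logical(), direction = character(),
                      phylum = character())
    attr(out, "n_tests") <- 0L
    attr(out, "untestable") <- untestable
    attr(out, "tested_share_pct") <- 100 * attr(filtered, "retained_share")
    return(out)
  }

  raw_p <- vapply(which(testable), function(j) {
    suppressWarnings(stats::wilcox.test(ra_f[, j], ra_d[, j],
                                        paired = TRUE)$p.value)
  }, numeric(1))
  adj_p <- stats::p.adjust(raw_p, method = "bonferroni", n = n_tests)

  phyla <- if (!is.null(table$taxonomy)) {
    vapply(colnames(diffs)[testable], function(o) {
      lin <- table$taxonomy[[o]]
      if (is.null(lin) || is.na(lin)) NA_character_ else lineage_phylum(lin)
    }, character(1))
  } else NA_character_

  out <- data.frame(
    otu_id = colnames(diffs)[testable],
    mean_ra_fresh = colMeans(ra_f[, testable, drop = FALSE]),
    mean_ra_air_dried = colMeans(ra_d[, testable, drop = FALSE]),
    raw_p = raw_p, adjusted_p = adj_p, phylum = phyla, row.names = NULL)
  out$delta <- out$mean_ra_air_dried - out$mean_ra_fresh
  out$direction <- ifelse(out$delta >= 0, "up_in_air_dried",
                          "down_in_air_dried")
  out$significant <- out$adjusted_p < alpha
  out <- out[order(out$adjusted_p, out$raw_p), ,
             drop = FALSE]
  out <- out[, c("otu_id", "mean_ra_fresh", "mean_ra_air_dried", "delta",
                 "raw_p", "adjusted_p", "significant", "direction", "phylum")]
  attr(out, "n_tests") <- n_tests
  attr(out, "untestable") <- untestable
  attr(out, "tested_share_pct") <- 100 * attr(filtered, "retained_share")
  out
}
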