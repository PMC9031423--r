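#' Reported NDEP model coefficients
#'
#' The selected-model coefficient table reported by the motivating field
#' study of air-dried farmland soil archives (min-max-standardised
#' environmental-difference predictors of NDEP): estimates and standard
#' errors for AAT, sand, clay and pH, with a category tag separating
#' climate from soil physical/chemical properties. Shipped so that the
#' derived quantities — t statistics, relative effects, and category
#' shares — can be recomputed from the primary values.
#'
#' @return data.frame: variable, estimate, std_error, category.
#' @export
reported_model_coefficients <- function() {
  utils::read.delim(system.file("extdata",
                                "reported_ndep_model_coefficients.tsv",
                                package = "soilNDEP", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Derived statistics of a reported coefficient table
#'
#' From estimates and standard errors alone: t statistics
#' (estimate / std. error), relative effects (each estimate's share of the
#' summed absolute estimates, in %), and the summed relative effect per
#' category (e.g. the share of soil properties vs climate, and of physical
#' vs chemical soil properties).
#'
#' @param coefs data.frame like [reported_model_coefficients()].
#' @return list: `table` (with t_value and relative_effect_pct columns
#'   added), `category_share_pct` (named vector).
#' @export
coefficient_statistics <- function(coefs = reported_model_coefficients()) {
  stopifnot(all(c("variable", "estimate", "std_error") %in% colnames(coefs)))
  tab <- coefs
  tab$t_value <- tab$estimate / tab$std_error
  tab$relative_effect_pct <-
    relative_effects(stats::setNames(tab$estimate, tab$variable))
  shares <- if ("category" %in% colnames(tab)) {
    tapply(tab$relative_effect_pct, tab$category, sum)
  } else {
    NULL
  }
  list(table = tab, category_share_pct = shares)
}
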