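check_pvalues <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1) stop("empty p-value family")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  p
}

#' Bonferroni adjustment within a family of tests
#'
#' Each p-value is multiplied by the family size and capped at 1. Within this
#' package the natural family is the five genetic-model tests run on one
#' population category.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, aligned with `p`.
#' @export
bonferroni <- function(p) {
  p <- check_pvalues(p)
  stats::p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with raw p-values sorted ascending,
#' `adj_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1 and mapped back
#' to the input order. Adjusted values are never below the raw values and
#' never above the Bonferroni adjustment.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, aligned with `p`.
#' @export
bh_fdr <- function(p) {
  p <- check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Group pipeline results into multiplicity families
#'
#' One family per population category, each holding the five genetic-model
#' p-values (family size m = 5). Categories missing any model are an error;
#' multiplicity adjustment is only meaningful over the complete family.
#'
#' @param results A result table from [run_analysis()].
#' @return Named list of families; each family is a list with `category`,
#'   `labels` (model names), `p_raw` and `m`.
#' @export
build_families <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("empty result set: no families to build")
  }
  out <- lapply(split(results, results$category), function(part) {
    missing <- setdiff(GENETIC_MODELS, part$model)
    if (length(missing) > 0) {
      stop(sprintf(
        "category '%s' is missing model(s): %s",
        part$category[1], paste(missing, collapse = ", ")
      ))
    }
    part <- part[match(GENETIC_MODELS, part$model), ]
    list(
      category = part$category[1], labels = part$model,
      p_raw = part$p, m = length(part$model)
    )
  })
  out[unique(results$category)]
}
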