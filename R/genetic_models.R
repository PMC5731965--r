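GENETIC_MODELS <- c("allele", "dominant", "recessive", "hom", "het")

#' The five genetic-model contrasts
#'
#' For a biallelic G>A variant the association can be parameterised as five
#' 2x2 contrasts of "exposed" versus "unexposed" genotype carriers:
#'
#' * `allele` — A alleles vs G alleles (each subject contributes two alleles);
#' * `dominant` — GA+AA carriers vs GG;
#' * `recessive` — AA vs GA+GG;
#' * `hom` — AA vs GG (co-dominant homozygote contrast; GA subjects excluded);
#' * `het` — GA vs GG (co-dominant heterozygote contrast; AA subjects excluded).
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() GENETIC_MODELS

new_two_by_two <- function(a, b, c, d, corrected = FALSE, correction = 0) {
  structure(
    list(a = a, b = b, c = c, d = d, corrected = corrected, correction = correction),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf(
    "<two_by_two> cases %g/%g, controls %g/%g%s\n",
    x$a, x$b, x$c, x$d,
    if (x$corrected) sprintf(" (continuity-corrected +%g)", x$correction) else ""
  ))
  invisible(x)
}

#' Derive the 2x2 table for a genetic-model contrast
#'
#' Maps genotype counts in each arm to the exposed/unexposed cells `a`
#' (exposed cases), `b` (unexposed cases), `c` (exposed controls), `d`
#' (unexposed controls). The allele model uses allele counts (2 per subject);
#' all genotype models use subject counts. The `hom` and `het` contrasts drop
#' the excluded genotype entirely. No continuity correction is applied here;
#' see [apply_continuity_correction()].
#'
#' @param cases,controls [genotype_counts()] (or numeric triples gg, ga, aa).
#' @param model One of [genetic_models()].
#' @return A `two_by_two` object.
#' @examples
#' derive_two_by_two(c(304, 141, 5), c(736, 292, 22), "allele")
#' @export
derive_two_by_two <- function(cases, controls, model) {
  model <- match.arg(model, GENETIC_MODELS)
  cs <- as.numeric(cases)
  ct <- as.numeric(controls)
  if (sum(cs) <= 0) stop("case arm has zero subjects")
  if (sum(ct) <= 0) stop("control arm has zero subjects")
  cells <- switch(model,
    allele = c(
      cs[2] + 2 * cs[3], 2 * cs[1] + cs[2],
      ct[2] + 2 * ct[3], 2 * ct[1] + ct[2]
    ),
    dominant = c(cs[2] + cs[3], cs[1], ct[2] + ct[3], ct[1]),
    recessive = c(cs[3], cs[1] + cs[2], ct[3], ct[1] + ct[2]),
    hom = c(cs[3], cs[1], ct[3], ct[1]),
    het = c(cs[2], cs[1], ct[2], ct[1])
  )
  if (cells[1] + cells[2] <= 0 || cells[3] + cells[4] <= 0) {
    stop(sprintf(
      "empty contrast: model '%s' leaves an arm with no subjects", model
    ))
  }
  new_two_by_two(cells[1], cells[2], cells[3], cells[4])
}

#' Continuity correction for sparse 2x2 tables
#'
#' If any cell is zero, 0.5 is added to all four cells and the table flagged
#' as corrected; otherwise the table is returned unchanged. Corrected tables
#' feed the per-study (inverse-variance) effect computation; Mantel-Haenszel
#' sums use the uncorrected counts, which the estimator tolerates.
#'
#' @param t A `two_by_two`.
#' @return A `two_by_two`, corrected if needed.
#' @export
apply_continuity_correction <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (any(c(t$a, t$b, t$c, t$d) == 0)) {
    new_two_by_two(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5,
      corrected = TRUE, correction = 0.5
    )
  } else {
    t
  }
}

#' 2x2 tables for every study in a collection
#'
#' @param x A `study_collection`.
#' @param model One of [genetic_models()].
#' @return A named list of `two_by_two` tables, one per study.
#' @export
model_tables <- function(x, model) {
  tabs <- lapply(seq_len(nrow(x)), function(i) {
    derive_two_by_two(case_counts(x, i), control_counts(x, i), model)
  })
  names(tabs) <- x$study_id
  tabs
}
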