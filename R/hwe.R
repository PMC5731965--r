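new_hwe_result <- function(chi2, p, exact_p = NA_real_, monomorphic = FALSE,
                           alpha = 0.05) {
  decisive <- if (!is.na(exact_p)) exact_p else p
  structure(
    list(
      chi2 = chi2, df = 1L, p = p, exact_p = exact_p,
      monomorphic = monomorphic, in_hwe = decisive >= alpha
    ),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf(
    "<hwe_result> chi2 = %.3f (df 1), p = %.4g%s -> %s\n",
    x$chi2, x$p,
    if (!is.na(x$exact_p)) sprintf(", exact p = %.4g", x$exact_p) else "",
    if (x$in_hwe) "in HWE" else "out of HWE"
  ))
  invisible(x)
}

#' Chi-square goodness-of-fit test for Hardy-Weinberg equilibrium
#'
#' With allele frequency `q = (ga + 2*aa) / (2n)` estimated from the sample,
#' expected genotype counts are `n(1-q)^2`, `2nq(1-q)`, `nq^2` and the test
#' statistic is the usual Pearson chi-square over the three genotype classes
#' with 1 degree of freedom (3 classes, 1 estimated frequency, no Yates
#' correction). A monomorphic sample (q of 0 or 1) is reported as chi2 = 0,
#' p = 1 with the `monomorphic` flag set.
#'
#' @param g [genotype_counts()] (or numeric triple gg, ga, aa).
#' @param alpha Significance level used for the `in_hwe` flag (default 0.05).
#' @return An `hwe_result` with `chi2`, `df`, `p` and `in_hwe`.
#' @examples
#' hwe_chi2(c(99, 60, 2))   # out of HWE (p ~ 0.03)
#' hwe_chi2(c(194, 100, 14)) # in HWE (p ~ 0.81)
#' @export
hwe_chi2 <- function(g, alpha = 0.05) {
  g <- as.numeric(g)
  n <- sum(g)
  if (n <= 0) stop("empty sample: genotype counts sum to zero")
  q <- (g[2] + 2 * g[3]) / (2 * n)
  if (q == 0 || q == 1) {
    return(new_hwe_result(chi2 = 0, p = 1, monomorphic = TRUE, alpha = alpha))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((g - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  new_hwe_result(chi2 = chi2, p = p, alpha = alpha)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditions on the observed allele counts: given `n` subjects and `nA`
#' copies of the minor allele, the heterozygote count `nAB` (same parity as
#' `nA`) has probability
#' `P(nAB) = 2^nAB * n! * nA! * nB! / (nAA! nAB! nBB! (2n)!)`.
#' The exact p-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed table.
#'
#' @inheritParams hwe_chi2
#' @return An `hwe_result` carrying both the chi-square fields and `exact_p`;
#'   `in_hwe` is decided by `exact_p`.
#' @export
hwe_exact <- function(g, alpha = 0.05) {
  g <- as.numeric(g)
  n <- sum(g)
  if (n <= 0) stop("empty sample: genotype counts sum to zero")
  base <- hwe_chi2(g, alpha = alpha)
  if (base$monomorphic) {
    return(new_hwe_result(
      chi2 = 0, p = 1, exact_p = 1,
      monomorphic = TRUE, alpha = alpha
    ))
  }
  nA <- g[2] + 2 * g[3]
  nB <- g[2] + 2 * g[1]
  if (nA > nB) { # relabel so A is the minor allele; the test is symmetric
    tmp <- nA; nA <- nB; nB <- tmp
  }
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    h * log(2) + lgamma(n + 1) + lgamma(nA + 1) + lgamma(nB + 1) -
      lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hets == g[2]]
  exact_p <- min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
  new_hwe_result(chi2 = base$chi2, p = base$p, exact_p = exact_p, alpha = alpha)
}

#' Hardy-Weinberg test for every study in a collection
#'
#' @param x A `study_collection`.
#' @param arm `"control"` (the conventional arm to test) or `"case"`.
#' @param test `"chi2"` (default) or `"exact"`.
#' @param alpha Significance level for the `in_hwe` flag.
#' @return Data frame with one row per study: `study_id`, `chi2`, `p`,
#'   `exact_p` (NA unless `test = "exact"`) and `in_hwe`.
#' @export
hwe_table <- function(x, arm = c("control", "case"), test = c("chi2", "exact"),
                      alpha = 0.05) {
  arm <- match.arg(arm)
  test <- match.arg(test)
  get <- if (arm == "control") control_counts else case_counts
  fun <- if (test == "chi2") hwe_chi2 else hwe_exact
  rows <- lapply(seq_len(nrow(x)), function(i) {
    h <- fun(get(x, i), alpha = alpha)
    data.frame(
      study_id = x$study_id[i], chi2 = h$chi2, p = h$p,
      exact_p = h$exact_p, in_hwe = h$in_hwe
    )
  })
  do.call(rbind, rows)
}
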