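new_effect_estimate <- function(log_or, se, conf_level = 0.95) {
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      log_or = log_or, se = se, or = exp(log_or),
      ci_low = exp(log_or - crit * se), ci_high = exp(log_or + crit * se)
    ),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "<effect_estimate> OR = %.3f [%.3f; %.3f], log OR = %.4f (se %.4f)\n",
    x$or, x$ci_low, x$ci_high, x$log_or, x$se
  ))
  invisible(x)
}

#' Per-study odds ratio and standard error
#'
#' Woolf log odds ratio `y = ln(ad / bc)` with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and Wald confidence limits on the OR scale.
#' All four cells must be positive; sparse tables should first go through
#' [apply_continuity_correction()].
#'
#' @param t A `two_by_two`.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return An `effect_estimate` with `log_or`, `se`, `or`, `ci_low`, `ci_high`.
#' @export
study_effect <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    stop("zero cell in 2x2 table; run apply_continuity_correction() first")
  }
  new_effect_estimate(
    log_or = log(t$a * t$d / (t$b * t$c)),
    se = sqrt(sum(1 / cells)),
    conf_level = conf_level
  )
}

#' Per-study effects for a list of 2x2 tables
#'
#' Applies [apply_continuity_correction()] then [study_effect()] to each
#' table.
#'
#' @param tables List of `two_by_two` tables.
#' @param conf_level Confidence level (default 0.95).
#' @return List of `effect_estimate`s, names preserved.
#' @export
study_effects <- function(tables, conf_level = 0.95) {
  lapply(tables, function(t) {
    study_effect(apply_continuity_correction(t), conf_level = conf_level)
  })
}

effect_vectors <- function(effects) {
  if (length(effects) == 0) stop("empty effect list")
  y <- vapply(effects, function(e) e$log_or, numeric(1))
  se <- vapply(effects, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("all standard errors must be positive")
  list(y = y, se = se)
}

new_pooled_result <- function(method, k, log_or, se, het, conf_level = 0.95) {
  zt <- z_test(log_or, se)
  structure(
    list(
      method = method, k = k,
      pooled = new_effect_estimate(log_or, se, conf_level = conf_level),
      z = zt$z, p = zt$p, het = het
    ),
    class = "pooled_result"
  )
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "<pooled_result> %s, k = %d: OR = %.3f [%.3f; %.3f], z = %.3f, p = %.4g\n",
    x$method, x$k, x$pooled$or, x$pooled$ci_low, x$pooled$ci_high, x$z, x$p
  ))
  cat(sprintf(
    "  heterogeneity: Q = %.3f (df %d, p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
    x$het$q, x$het$df, x$het$p_q, x$het$i2, x$het$tau2
  ))
  invisible(x)
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Q is computed with inverse-variance weights `w = 1/se^2` around the
#' inverse-variance fixed-effect pooled log OR (the conventional pairing even
#' when the reported fixed-effect estimator is Mantel-Haenszel), with
#' `I2 = max(0, (Q - df)/Q) * 100` and the moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`. A single study
#' gives Q = 0, I2 = 0, tau2 = 0.
#'
#' @param effects List of `effect_estimate`s.
#' @param pooled_y Optional pooled log OR around which to compute Q; defaults
#'   to the inverse-variance fixed-effect estimate.
#' @return A `heterogeneity` object with `q`, `df`, `p_q`, `i2`, `tau2`.
#' @export
heterogeneity <- function(effects, pooled_y = NULL) {
  ev <- effect_vectors(effects)
  k <- length(ev$y)
  w <- 1 / ev$se^2
  if (is.null(pooled_y)) pooled_y <- sum(w * ev$y) / sum(w)
  if (k == 1) {
    return(structure(
      list(q = 0, df = 0L, p_q = 1, i2 = 0, tau2 = 0),
      class = "heterogeneity"
    ))
  }
  q <- sum(w * (ev$y - pooled_y)^2)
  df <- k - 1L
  p_q <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - df) / denom) else 0
  structure(
    list(q = q, df = df, p_q = p_q, i2 = i2, tau2 = tau2),
    class = "heterogeneity"
  )
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` on uncorrected counts,
#' with the variance of the log pooled OR from the Robins-Breslow-Greenland
#' estimator. Heterogeneity is computed from per-study inverse-variance
#' effects (continuity-corrected where needed) around the inverse-variance
#' pooled estimate.
#'
#' @param tables List of `two_by_two` tables (uncorrected counts).
#' @param conf_level Confidence level (default 0.95).
#' @return A `pooled_result` with `method = "MH_FIXED"`.
#' @examples
#' studies <- rs671_gastric()
#' pool_mh(model_tables(studies, "allele"))
#' @export
pool_mh <- function(tables, conf_level = 0.95) {
  if (length(tables) == 0) stop("no tables to pool")
  a <- vapply(tables, function(t) t$a, numeric(1))
  b <- vapply(tables, function(t) t$b, numeric(1))
  c_ <- vapply(tables, function(t) t$c, numeric(1))
  d <- vapply(tables, function(t) t$d, numeric(1))
  n <- a + b + c_ + d
  if (any(n <= 0)) stop("table with zero total")
  R_i <- a * d / n
  S_i <- b * c_ / n
  R <- sum(R_i)
  S <- sum(S_i)
  if (R == 0 || S == 0) stop("degenerate pooled OR: all a*d or all b*c are zero")
  P_i <- (a + d) / n
  Q_i <- (b + c_) / n
  var_log <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  het <- heterogeneity(study_effects(tables, conf_level = conf_level))
  new_pooled_result(
    method = "MH_FIXED", k = length(tables),
    log_or = log(R / S), se = sqrt(var_log),
    het = het, conf_level = conf_level
  )
}

#' Inverse-variance fixed-effect pooling
#'
#' Weights `w = 1/se^2`; pooled log OR `sum(w*y)/sum(w)` with standard error
#' `1/sqrt(sum(w))`. Used for Cochran's Q and as a cross-check of the
#' Mantel-Haenszel estimate.
#'
#' @param effects List of `effect_estimate`s.
#' @param conf_level Confidence level (default 0.95).
#' @return A `pooled_result` with `method = "IV_FIXED"`.
#' @export
pool_iv <- function(effects, conf_level = 0.95) {
  ev <- effect_vectors(effects)
  w <- 1 / ev$se^2
  y <- sum(w * ev$y) / sum(w)
  het <- heterogeneity(effects, pooled_y = y)
  new_pooled_result(
    method = "IV_FIXED", k = length(effects),
    log_or = y, se = 1 / sqrt(sum(w)),
    het = het, conf_level = conf_level
  )
}

#' DerSimonian-Laird random-effects pooling
#'
#' Between-study variance tau-squared from [heterogeneity()]; weights
#' `w* = 1/(se^2 + tau2)`. When tau2 = 0 the result reduces exactly to the
#' inverse-variance fixed-effect estimate.
#'
#' @param effects List of `effect_estimate`s.
#' @param conf_level Confidence level (default 0.95).
#' @return A `pooled_result` with `method = "DL_RANDOM"`.
#' @export
pool_dl <- function(effects, conf_level = 0.95) {
  ev <- effect_vectors(effects)
  het <- heterogeneity(effects)
  w <- 1 / (ev$se^2 + het$tau2)
  new_pooled_result(
    method = "DL_RANDOM", k = length(effects),
    log_or = sum(w * ev$y) / sum(w), se = 1 / sqrt(sum(w)),
    het = het, conf_level = conf_level
  )
}

#' I-squared rule for choosing the pooling method
#'
#' Random effects (DerSimonian-Laird) when I-squared exceeds the threshold,
#' fixed effect (Mantel-Haenszel) otherwise; an I-squared exactly at the
#' threshold goes to the fixed-effect model.
#'
#' @param het A `heterogeneity` object (or an I-squared percentage).
#' @param i2_threshold Percentage threshold (default 50).
#' @return `"DL_RANDOM"` or `"MH_FIXED"`.
#' @export
select_method <- function(het, i2_threshold = 50) {
  i2 <- if (inherits(het, "heterogeneity")) het$i2 else as.numeric(het)
  if (i2 > i2_threshold) "DL_RANDOM" else "MH_FIXED"
}

#' Pool a set of 2x2 tables with automatic method selection
#'
#' Full pooling pass for one set of tables: per-study effects,
#' heterogeneity, I-squared method selection ([select_method()]), then
#' Mantel-Haenszel or DerSimonian-Laird pooling. The workhorse behind the
#' pipeline, leave-one-out and the collapsed-stratum analysis.
#'
#' @param tables List of `two_by_two` tables.
#' @param i2_threshold I-squared percentage above which random effects are
#'   used (default 50).
#' @param conf_level Confidence level (default 0.95).
#' @return A `pooled_result`.
#' @export
pool_auto <- function(tables, i2_threshold = 50, conf_level = 0.95) {
  effects <- study_effects(tables, conf_level = conf_level)
  het <- heterogeneity(effects)
  if (select_method(het, i2_threshold) == "DL_RANDOM") {
    pool_dl(effects, conf_level = conf_level)
  } else {
    pool_mh(tables, conf_level = conf_level)
  }
}

#' Z-test of a pooled log odds ratio
#'
#' @param log_or Pooled log OR (or an `effect_estimate`).
#' @param se Its standard error (ignored when an `effect_estimate` is given).
#' @return List with `z = log_or/se` and two-sided normal `p`.
#' @export
z_test <- function(log_or, se = NULL) {
  if (inherits(log_or, "effect_estimate")) {
    se <- log_or$se
    log_or <- log_or$log_or
  }
  if (is.null(se) || se <= 0) stop("se must be positive")
  z <- log_or / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Post-hoc power of a pooled estimate (Hedges-Pigott)
#'
#' For a hypothesised true log OR and the standard error of the pooled
#' estimate, the noncentrality is `lambda = true_log_or / se` and the power
#' of the two-sided level-alpha Z-test is
#' `1 - pnorm(z_crit - lambda) + pnorm(-z_crit - lambda)`.
#'
#' @param true_log_or Hypothesised true effect on the log OR scale.
#' @param se Standard error of the pooled log OR.
#' @param alpha Test level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_hedges_pigott <- function(true_log_or, se, alpha = 0.05) {
  if (se <= 0) stop("se must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  lambda <- true_log_or / se
  z_crit <- stats::qnorm(1 - alpha / 2)
  1 - stats::pnorm(z_crit - lambda) + stats::pnorm(-z_crit - lambda)
}
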