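#' Egger regression test for small-study effects
#'
#' Ordinary least-squares regression of the standard normal deviate
#' `y_i/se_i` on precision `1/se_i`; a nonzero intercept indicates funnel
#' asymmetry. The intercept is tested with a two-sided t-test on k-2 degrees
#' of freedom. This is algebraically identical to the weighted regression of
#' `y` on `se` with weights `1/se^2`. A fit with constant standard normal
#' deviates has zero residual variance and is returned with the `degenerate`
#' flag set instead of a p-value.
#'
#' @param effects List of `effect_estimate`s, k >= 3.
#' @return List with `egger_intercept`, `egger_se`, `egger_t`, `egger_p`,
#'   `df` and `degenerate`.
#' @export
egger_test <- function(effects) {
  ev <- effect_vectors(effects)
  k <- length(ev$y)
  if (k < 3) stop("Egger's test needs at least 3 studies")
  snd <- ev$y / ev$se
  prec <- 1 / ev$se
  fit <- stats::lm(snd ~ prec)
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-12 * max(1, sum(snd^2))) {
    return(list(
      egger_intercept = unname(stats::coef(fit)[1]), egger_se = 0,
      egger_t = NA_real_, egger_p = NA_real_, df = k - 2L, degenerate = TRUE
    ))
  }
  cf <- summary(fit)$coefficients
  list(
    egger_intercept = cf[1, 1], egger_se = cf[1, 2],
    egger_t = cf[1, 3], egger_p = cf[1, 4], df = k - 2L, degenerate = FALSE
  )
}

#' Begg and Mazumdar rank-correlation test for publication bias
#'
#' Standardises each effect against the inverse-variance fixed-effect pooled
#' value, `v_i = (y_i - y_pool) / sqrt(se_i^2 - se_pool^2)`, and computes
#' Kendall's tau between `v_i` and the variances `se_i^2` by explicit pair
#' counting with tie correction. The normal statistic is
#' `z = (concordant - discordant) / sqrt(k(k-1)(2k+5)/18)` with no continuity
#' correction. Studies whose variance does not exceed the pooled variance
#' have the difference clamped at a small positive floor (flagged).
#'
#' @param effects List of `effect_estimate`s, k >= 3.
#' @return List with `begg_tau`, `begg_z`, `begg_p` and `clamped`.
#' @export
begg_test <- function(effects) {
  ev <- effect_vectors(effects)
  k <- length(ev$y)
  if (k < 3) stop("Begg's test needs at least 3 studies")
  w <- 1 / ev$se^2
  y_pool <- sum(w * ev$y) / sum(w)
  var_pool <- 1 / sum(w)
  vdiff <- ev$se^2 - var_pool
  clamped <- any(vdiff <= 0)
  vdiff <- pmax(vdiff, 1e-12)
  v <- (ev$y - y_pool) / sqrt(vdiff)
  s2 <- ev$se^2
  concordant <- 0
  discordant <- 0
  tie_v <- 0
  tie_s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dv <- sign(v[j] - v[i])
      ds <- sign(s2[j] - s2[i])
      if (dv == 0) tie_v <- tie_v + 1
      if (ds == 0) tie_s <- tie_s + 1
      if (dv * ds > 0) concordant <- concordant + 1
      if (dv * ds < 0) discordant <- discordant + 1
    }
  }
  n_pairs <- k * (k - 1) / 2
  denom <- sqrt((n_pairs - tie_v) * (n_pairs - tie_s))
  tau <- if (denom > 0) (concordant - discordant) / denom else 0
  z <- (concordant - discordant) / sqrt(k * (k - 1) * (2 * k + 5) / 18)
  list(
    begg_tau = tau, begg_z = z, begg_p = 2 * stats::pnorm(-abs(z)),
    clamped = clamped
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the collection k times, omitting each study in turn; the pooling
#' method is re-selected by the I-squared rule on each reduced set.
#'
#' @param x A `study_collection` with at least 2 studies.
#' @param model One of [genetic_models()].
#' @param i2_threshold I-squared percentage above which random effects are
#'   used (default 50).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per omitted study: `omitted_study_id`,
#'   `k`, `method`, `or`, `ci_low`, `ci_high`, `z`, `p`, `i2`.
#' @export
leave_one_out <- function(x, model, i2_threshold = 50, conf_level = 0.95) {
  if (nrow(x) < 2) stop("leave-one-out needs at least 2 studies")
  tables <- model_tables(x, model)
  rows <- lapply(seq_along(tables), function(i) {
    res <- pool_auto(tables[-i],
      i2_threshold = i2_threshold,
      conf_level = conf_level
    )
    data.frame(
      omitted_study_id = x$study_id[i], k = res$k, method = res$method,
      or = res$pooled$or, ci_low = res$pooled$ci_low,
      ci_high = res$pooled$ci_high, z = res$z, p = res$p, i2 = res$het$i2
    )
  })
  do.call(rbind, rows)
}

#' Funnel-plot data
#'
#' Study points (log OR against standard error, sorted by standard error)
#' plus pseudo confidence limits `y_pool +/- z * se` evaluated on a grid of
#' standard errors from 0 to the largest observed, for rendering a funnel
#' plot in any plotting system.
#'
#' @param effects List of `effect_estimate`s.
#' @param conf_level Confidence level for the pseudo limits (default 0.95).
#' @param grid_n Number of grid points (default 50).
#' @return List of two data frames: `studies` (`log_or`, `se`) and `limits`
#'   (`se`, `lower`, `upper` on the log OR scale).
#' @export
funnel_data <- function(effects, conf_level = 0.95, grid_n = 50) {
  ev <- effect_vectors(effects)
  w <- 1 / ev$se^2
  y_pool <- sum(w * ev$y) / sum(w)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  ord <- order(ev$se)
  se_grid <- seq(0, max(ev$se), length.out = grid_n)
  list(
    studies = data.frame(log_or = ev$y[ord], se = ev$se[ord]),
    limits = data.frame(
      se = se_grid,
      lower = y_pool - crit * se_grid,
      upper = y_pool + crit * se_grid
    )
  )
}
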