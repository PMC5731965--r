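test_that("per-study effect follows the Woolf closed form", {
  # Hidaka allele-model cells
  t <- derive_two_by_two(c(287, 149, 21), c(292, 150, 15), "allele")
  e <- study_effect(t)
  expect_equal(e$or, 191 * 734 / (723 * 180), tolerance = 1e-12)
  expect_equal(e$or, 1.0773, tolerance = 1e-4)
  expect_equal(e$se, sqrt(1 / 191 + 1 / 723 + 1 / 180 + 1 / 734), tolerance = 1e-12)
  expect_equal(e$se, 0.1164, tolerance = 1e-3)

  # symmetric table: OR exactly 1
  sym <- derive_two_by_two(c(194, 106, 8), c(194, 100, 14), "dominant")
  expect_equal(study_effect(sym)$log_or, 0)

  e10 <- study_effect(structure(
    list(a = 10, b = 10, c = 10, d = 10, corrected = FALSE, correction = 0),
    class = "two_by_two"
  ))
  expect_equal(e10$or, 1)
  expect_equal(e10$se, sqrt(0.4))

  zero <- derive_two_by_two(c(10, 5, 0), c(10, 10, 4), "recessive")
  expect_error(study_effect(zero), "apply_continuity_correction")
  expect_silent(study_effect(apply_continuity_correction(zero)))
})

test_that("Mantel-Haenszel pooling matches published subgroup odds ratios", {
  x <- rs671_gastric()
  japan <- x[x$country == "Japan", ]
  res <- pool_mh(model_tables(japan, "allele"))
  expect_equal(round(res$pooled$or, 3), 1.138)
  expect_equal(round(res$p, 3), 0.034)

  korea <- x[x$country == "Korea", ]
  expect_equal(round(pool_mh(model_tables(korea, "recessive"))$pooled$or, 3), 0.563)
})

test_that("single-study MH pooling is the study's own odds ratio", {
  x <- rs671_gastric()
  t1 <- model_tables(x, "dominant")[1]
  res <- pool_mh(t1)
  expect_equal(res$k, 1)
  expect_equal(res$pooled$or, study_effect(t1[[1]])$or, tolerance = 1e-12)
  expect_equal(res$het$q, 0)
})

test_that("MH pooling agrees with the reference implementation", {
  x <- rs671_gastric()
  for (model in c("allele", "dominant", "hom")) {
    tabs <- model_tables(x, model)
    a <- vapply(tabs, `[[`, 0, "a"); b <- vapply(tabs, `[[`, 0, "b")
    cc <- vapply(tabs, `[[`, 0, "c"); d <- vapply(tabs, `[[`, 0, "d")
    ref <- metafor::rma.mh(ai = a, bi = b, ci = cc, di = d, correct = FALSE)
    res <- pool_mh(tabs)
    expect_equal(res$pooled$log_or, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(res$p, ref$pval, tolerance = 1e-8)
    expect_equal(res$het$i2, ref$I2, tolerance = 1e-3)
    expect_equal(res$het$p_q, ref$QEp, tolerance = 1e-3)
  }
})

test_that("inverse-variance pooling has its closed forms", {
  e <- make_effects(c(0.1, 0.1), c(0.2, 0.2))
  res <- pool_iv(e)
  expect_equal(res$pooled$log_or, 0.1)
  expect_equal(res$pooled$se, 0.2 / sqrt(2))

  e <- make_effects(c(-0.3, 0.1, 0.5), c(0.25, 0.25, 0.25))
  expect_equal(pool_iv(e)$pooled$log_or, 0.1) # equal weights: plain mean

  expect_error(pool_iv(list()), "empty")
})

test_that("MH and IV fixed-effect estimates agree on large balanced tables", {
  x <- rs671_gastric()
  japan <- x[x$country == "Japan", ]
  tabs <- model_tables(japan, "allele")
  or_mh <- pool_mh(tabs)$pooled$or
  or_iv <- pool_iv(study_effects(tabs))$pooled$or
  expect_lt(abs(or_mh - or_iv), 0.01)
  # and across all overall rows, within 1%
  for (model in genetic_models()) {
    tabs <- model_tables(x, model)
    expect_lt(
      abs(pool_mh(tabs)$pooled$or / pool_iv(study_effects(tabs))$pooled$or - 1),
      0.01
    )
  }
})

test_that("heterogeneity statistics behave at their boundary cases", {
  e <- make_effects(c(0.2, 0.2, 0.2), c(0.1, 0.15, 0.2))
  h <- heterogeneity(e)
  expect_equal(h$q, 0)
  expect_equal(h$i2, 0)
  expect_equal(h$tau2, 0)

  h1 <- heterogeneity(make_effects(0.3, 0.1))
  expect_equal(h1$q, 0)
  expect_equal(h1$df, 0L)

  japan <- rs671_gastric()[rs671_gastric()$country == "Japan", ]
  expect_equal(heterogeneity(study_effects(model_tables(japan, "allele")))$i2, 0)
})

test_that("DerSimonian-Laird pooling has its closed form and bounds", {
  # two-point closed form: y = 0, 1 with se = 0.1 each
  e <- make_effects(c(0, 1), c(0.1, 0.1))
  h <- heterogeneity(e)
  expect_equal(h$q, 50)
  expect_equal(h$tau2, 0.49) # (50 - 1) / (200 - 20000/200)
  res <- pool_dl(e)
  expect_equal(res$pooled$log_or, 0.5)
  expect_equal(res$pooled$se, 0.5) # 1/sqrt(2 * 1/(0.01 + 0.49))
  expect_gt(res$pooled$se, pool_iv(e)$pooled$se)

  # tau2 = 0: DL reduces to IV exactly
  e0 <- make_effects(c(0.2, 0.2, 0.2), c(0.1, 0.15, 0.2))
  expect_equal(pool_dl(e0)$pooled$log_or, pool_iv(e0)$pooled$log_or)
  expect_equal(pool_dl(e0)$pooled$se, pool_iv(e0)$pooled$se)

  # single study: DL is the study itself
  e1 <- make_effects(0.3, 0.12)
  expect_equal(pool_dl(e1)$pooled$log_or, 0.3)
  expect_equal(pool_dl(e1)$pooled$se, 0.12)
})

test_that("DL pooling agrees with the reference implementation", {
  x <- rs671_gastric()
  tabs <- model_tables(x, "recessive")
  ev <- lapply(study_effects(tabs), function(e) c(e$log_or, e$se))
  y <- vapply(ev, `[`, 0, 1)
  se <- vapply(ev, `[`, 0, 2)
  ref <- metafor::rma(yi = y, sei = se, method = "DL")
  res <- pool_dl(study_effects(tabs))
  expect_equal(res$pooled$log_or, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(res$het$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("DL interval is never narrower than the fixed-effect interval", {
  set.seed(42)
  for (r in 1:20) {
    k <- sample(3:15, 1)
    e <- make_effects(rnorm(k, 0, 0.4), runif(k, 0.05, 0.5))
    dl <- pool_dl(e)$pooled
    iv <- pool_iv(e)$pooled
    expect_gte(dl$se, iv$se - 1e-12)
  }
})

test_that("the I2 rule selects fixed below and at the threshold, random above", {
  expect_equal(select_method(10.9), "MH_FIXED")
  expect_equal(select_method(93.9), "DL_RANDOM")
  expect_equal(select_method(50.0), "MH_FIXED")
  h <- heterogeneity(make_effects(c(0, 1), c(0.1, 0.1)))
  expect_equal(select_method(h), "DL_RANDOM")
})

test_that("Z-test and Hedges-Pigott power follow the normal closed forms", {
  expect_equal(z_test(0, 0.2), list(z = 0, p = 1))
  zt <- z_test(1.96 * 0.25, 0.25)
  expect_equal(zt$p, 0.05, tolerance = 1e-3)

  expect_equal(power_hedges_pigott(0, 1), 0.05, tolerance = 1e-6)
  expect_equal(power_hedges_pigott(2.80 * 0.1, 0.1), 0.7995, tolerance = 1e-3)
  expect_gt(power_hedges_pigott(50, 1), 1 - 1e-10)
  expect_error(power_hedges_pigott(0.1, -1), "positive")
})

test_that("DL recovers a known allele-model effect without heterogeneity", {
  # 200 simulated meta-analyses, k = 20, 2000/arm, multiplicative genotype
  # ORs 1.2 / 1.44 so the per-allele OR is 1.2
  errs <- vapply(1:200, function(r) {
    sim <- simulate_collection(sim_params(
      k = 20, n_cases = 2000, n_controls = 2000, maf = 0.25,
      or_het = 1.2, or_hom = 1.44, tau2 = 0, seed = 5000 + r
    ))
    eff <- study_effects(model_tables(sim$collection, "allele"))
    abs(pool_dl(eff)$pooled$log_or - log(1.2))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})
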