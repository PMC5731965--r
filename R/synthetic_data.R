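# Run expr under a local RNG stream: the global .Random.seed is left exactly
# as it was, so simulation calls do not perturb user code.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parameters for the synthetic study generator
#'
#' Defines a population of case-control studies with the structure the
#' meta-analysis assumes: control genotypes at (or perturbed from)
#' Hardy-Weinberg proportions for a given minor-allele frequency, case
#' genotypes tilted by genotype odds ratios, optional between-study
#' heterogeneity of the log odds ratios, and optional small-study selection
#' bias.
#'
#' @param k Number of studies (>= 1).
#' @param n_cases,n_controls Per-study arm sizes; scalars are recycled to
#'   length `k`.
#' @param maf Control minor-allele (A) frequency in (0, 0.5].
#' @param or_het,or_hom Genotype odds ratios of GA and AA relative to GG
#'   (default 1, the null).
#' @param tau2 Between-study variance of the log OR (default 0); realised as
#'   one shared normal shift per study added to both genotype log ORs, so the
#'   allele-model log OR inherits variance of about `tau2` under
#'   multiplicative effects.
#' @param hwe_disequilibrium Inbreeding-style coefficient F applied to the
#'   control genotype distribution (0 = exact HWE); genotype probabilities
#'   become `(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)`.
#' @param bias_strength Selection-on-significance coefficient (0 = none).
#'   Each simulated study is retained with probability
#'   `exp(-bias_strength * pnorm(-z))`, `z` the study's allele-model Wald
#'   statistic, thinning small null studies the way publication bias does.
#' @param seed Integer seed; every draw flows from it.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(k, n_cases, n_controls, maf, or_het = 1, or_hom = 1,
                       tau2 = 0, hwe_disequilibrium = 0, bias_strength = 0,
                       seed = 1L) {
  if (k < 1) stop("k must be at least 1")
  n_cases <- rep_len(as.integer(n_cases), k)
  n_controls <- rep_len(as.integer(n_controls), k)
  if (any(n_cases < 1) || any(n_controls < 1)) stop("arm sizes must be >= 1")
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (or_het <= 0 || or_hom <= 0) stop("genotype odds ratios must be positive")
  if (tau2 < 0) stop("tau2 must be non-negative")
  if (bias_strength < 0) stop("bias_strength must be non-negative")
  p <- 1 - maf
  q <- maf
  probs <- c(p^2, 2 * p * q, q^2) +
    hwe_disequilibrium * c(p * q, -2 * p * q, p * q)
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("hwe_disequilibrium pushes a genotype probability outside (0, 1)")
  }
  structure(
    list(
      k = as.integer(k), n_cases = n_cases, n_controls = n_controls,
      maf = maf, or_het = or_het, or_hom = or_hom, tau2 = tau2,
      hwe_disequilibrium = hwe_disequilibrium,
      bias_strength = bias_strength, seed = as.integer(seed),
      control_probs = probs
    ),
    class = "sim_params"
  )
}

draw_study <- function(params, u) {
  pc <- params$control_probs
  tilt <- pc * c(1, params$or_het * exp(u), params$or_hom * exp(u))
  pa <- tilt / sum(tilt)
  list(control_probs = pc, case_probs = pa)
}

#' Simulate a collection of case-control studies
#'
#' Per study: a shared heterogeneity shift `u ~ Normal(0, tau2)` is added to
#' both genotype log odds ratios, case genotype probabilities are the control
#' probabilities tilted by the shifted genotype ORs and renormalised, and
#' genotype counts are drawn from three-class multinomials. With
#' `bias_strength > 0`, studies are thinned by selection on the observed
#' allele-model Wald statistic (see [sim_params()]) and redrawn until `k`
#' studies are retained.
#'
#' @param params A [sim_params()] object.
#' @param label Collection label (default "simulated").
#' @return List of class `"simulated_collection"`: `collection` (a
#'   `study_collection`) and `truth` (the generating parameters plus the
#'   per-study realised shifts `u`).
#' @examples
#' sim <- simulate_collection(sim_params(
#'   k = 5, n_cases = 500, n_controls = 500,
#'   maf = 0.25, or_het = 1.2, or_hom = 1.44, seed = 7
#' ))
#' pool_mh(model_tables(sim$collection, "allele"))
#' @export
simulate_collection <- function(params, label = "simulated") {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    kept <- 0L
    attempts <- 0L
    max_attempts <- 1000L * params$k + 1000L
    rows <- vector("list", params$k)
    u_kept <- numeric(params$k)
    while (kept < params$k) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("bias_strength rejects nearly every study; cannot fill collection")
      }
      i <- kept + 1L
      u <- if (params$tau2 > 0) stats::rnorm(1, 0, sqrt(params$tau2)) else 0
      pr <- draw_study(params, u)
      ctrl <- as.vector(stats::rmultinom(1, params$n_controls[i], pr$control_probs))
      case <- as.vector(stats::rmultinom(1, params$n_cases[i], pr$case_probs))
      if (params$bias_strength > 0) {
        t <- apply_continuity_correction(
          derive_two_by_two(case, ctrl, "allele")
        )
        eff <- study_effect(t)
        keep_prob <- exp(
          -params$bias_strength * stats::pnorm(-eff$log_or / eff$se)
        )
        if (stats::runif(1) > keep_prob) next
      }
      kept <- i
      u_kept[i] <- u
      rows[[i]] <- data.frame(
        study_id = sprintf("sim%03d", i), first_author = "Synthetic",
        year = 2000L + i, country = "Simland", control_source = "PB",
        case_gg = case[1], case_ga = case[2], case_aa = case[3],
        control_gg = ctrl[1], control_ga = ctrl[2], control_aa = ctrl[3],
        nos_score = NA_integer_
      )
    }
    collection <- new_study_collection(do.call(rbind, rows), label = label)
    validate_studies(collection, file = label)
    structure(
      list(
        collection = collection,
        truth = c(params[setdiff(names(params), "control_probs")], list(u = u_kept))
      ),
      class = "simulated_collection"
    )
  })
}

#' Simulate collapsed (dominant-model) stratum records
#'
#' Simulates a collection with [simulate_collection()] and collapses each
#' study's genotype counts to GA+AA versus GG in both arms — exactly the
#' dominant-model 2x2 derivation — labelling every record with
#' `stratum_label`.
#'
#' @param params A [sim_params()] object.
#' @param stratum_label Label attached to every record (e.g. "Drinker").
#' @return A `collapsed_studies` data frame with `k` rows.
#' @export
simulate_collapsed <- function(params, stratum_label) {
  sim <- simulate_collection(params)
  x <- sim$collection
  structure(
    data.frame(
      study_id = x$study_id, stratum_label = stratum_label,
      case_exposed = x$case_ga + x$case_aa, case_ref = x$case_gg,
      control_exposed = x$control_ga + x$control_aa, control_ref = x$control_gg
    ),
    class = c("collapsed_studies", "data.frame")
  )
}

#' Write a simulated collection to the studies CSV schema
#'
#' @param sim A `simulated_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulated_csv <- function(sim, path) {
  write_studies_csv(sim$collection, path)
}
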