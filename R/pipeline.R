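RESULT_COLUMNS <- c(
  "category", "model", "k", "method", "or", "ci_low", "ci_high",
  "p", "p_bonferroni", "p_fdr", "q", "het_p", "i2", "tau2",
  "begg_p", "egger_p"
)

result_row <- function(category, model, res, begg_p = NA_real_,
                       egger_p = NA_real_) {
  data.frame(
    category = category, model = model, k = res$k, method = res$method,
    or = res$pooled$or, ci_low = res$pooled$ci_low,
    ci_high = res$pooled$ci_high, p = res$p,
    p_bonferroni = NA_real_, p_fdr = NA_real_,
    q = res$het$q, het_p = res$het$p_q, i2 = res$het$i2, tau2 = res$het$tau2,
    begg_p = begg_p, egger_p = egger_p
  )
}

#' Run the full genetic-model meta-analysis
#'
#' For every category (Overall plus, optionally, each level of the grouping
#' columns) and every requested genetic model: derives the 2x2 tables,
#' computes per-study effects (continuity-corrected where needed) and
#' heterogeneity, selects fixed (Mantel-Haenszel) or random
#' (DerSimonian-Laird) pooling by the I-squared rule, pools, and tests the
#' pooled OR with a Z-test. Begg and Egger publication-bias tests are
#' attached for categories with at least `bias_min_k` studies. When all five
#' genetic models are run, Bonferroni and Benjamini-Hochberg adjustments are
#' applied within each category (family size 5); partial model sets leave the
#' adjusted columns NA.
#'
#' @param x A `study_collection`.
#' @param models Subset of [genetic_models()] (default: all five).
#' @param group_by Character vector of grouping columns, e.g.
#'   `c("country", "control_source")`; `NULL` for the overall analysis only.
#' @param i2_threshold I-squared percentage above which random effects are
#'   used (default 50).
#' @param conf_level Confidence level (default 0.95).
#' @param bias_min_k Minimum studies for Begg/Egger tests (default 3).
#' @return Data frame of class `"meta_result_table"`, one row per
#'   (category, model).
#' @examples
#' studies <- rs671_gastric()
#' run_analysis(studies, group_by = "country")
#' @export
run_analysis <- function(x, models = genetic_models(), group_by = NULL,
                         i2_threshold = 50, conf_level = 0.95,
                         bias_min_k = 3) {
  if (nrow(x) == 0) stop("empty study collection")
  models <- vapply(models, function(m) match.arg(m, GENETIC_MODELS), "")
  parts <- list(Overall = x)
  for (col in group_by) {
    if (!col %in% names(x)) {
      stop(sprintf("grouping column '%s' not present in the collection", col))
    }
    if (any(is.na(x[[col]]) | !nzchar(x[[col]]))) {
      stop(sprintf("grouping column '%s' has missing values", col))
    }
    for (lev in unique(x[[col]])) {
      sub <- x[x[[col]] == lev, , drop = FALSE]
      if (nrow(sub) == 0) {
        warning(sprintf("subgroup '%s' has no studies; omitted", lev))
        next
      }
      parts[[lev]] <- sub
    }
  }
  rows <- list()
  for (cat_name in names(parts)) {
    part <- parts[[cat_name]]
    for (model in models) {
      tables <- model_tables(part, model)
      res <- pool_auto(tables,
        i2_threshold = i2_threshold,
        conf_level = conf_level
      )
      begg_p <- NA_real_
      egger_p <- NA_real_
      if (length(tables) >= bias_min_k) {
        effects <- study_effects(tables, conf_level = conf_level)
        begg_p <- begg_test(effects)$begg_p
        egger_p <- egger_test(effects)$egger_p
      }
      rows[[length(rows) + 1]] <- result_row(cat_name, model, res,
        begg_p = begg_p, egger_p = egger_p
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(RESULT_COLUMNS))),
      RESULT_COLUMNS
    )
  }
  if (setequal(models, GENETIC_MODELS) && nrow(out) > 0) {
    for (fam in build_families(out)) {
      idx <- out$category == fam$category
      ord <- match(out$model[idx], fam$labels)
      out$p_bonferroni[idx] <- bonferroni(fam$p_raw)[ord]
      out$p_fdr[idx] <- bh_fdr(fam$p_raw)[ord]
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("meta_result_table", "data.frame"))
}

#' Meta-analysis of collapsed (dominant-model) strata
#'
#' Each record already carries the GA+AA versus GG collapse, so the 2x2
#' tables are formed directly from the collapsed counts. Records are grouped
#' by `stratum_label`; each stratum is pooled like a category in
#' [run_analysis()] (I-squared rule, Z-test, Begg/Egger where enough
#' studies). Multiplicity columns stay NA: the dominant contrast is the only
#' model available for these data.
#'
#' @param records A `collapsed_studies` data frame (see
#'   [read_collapsed_csv()]).
#' @inheritParams run_analysis
#' @return A `meta_result_table` with one row per stratum,
#'   `model = "dominant"`.
#' @export
run_collapsed_analysis <- function(records, i2_threshold = 50,
                                   conf_level = 0.95, bias_min_k = 3) {
  if (nrow(records) == 0) stop("no collapsed records")
  rows <- lapply(split(records, records$stratum_label), function(part) {
    tables <- lapply(seq_len(nrow(part)), function(i) {
      new_two_by_two(
        part$case_exposed[i], part$case_ref[i],
        part$control_exposed[i], part$control_ref[i]
      )
    })
    res <- pool_auto(tables,
      i2_threshold = i2_threshold,
      conf_level = conf_level
    )
    begg_p <- NA_real_
    egger_p <- NA_real_
    if (length(tables) >= bias_min_k) {
      effects <- study_effects(tables, conf_level = conf_level)
      begg_p <- begg_test(effects)$begg_p
      egger_p <- egger_test(effects)$egger_p
    }
    result_row(part$stratum_label[1], "dominant", res,
      begg_p = begg_p, egger_p = egger_p
    )
  })
  out <- do.call(rbind, rows[unique(records$stratum_label)])
  rownames(out) <- NULL
  structure(out, class = c("meta_result_table", "data.frame"))
}

#' Summary of study characteristics
#'
#' Totals and breakdowns a characteristics table would report: study count,
#' case and control totals, studies per country and control source, and the
#' Hardy-Weinberg status of each control arm (computed, not read from
#' metadata).
#'
#' @param x A `study_collection`.
#' @param alpha Level for the HWE flag (default 0.05).
#' @return List with `n_studies`, `total_cases`, `total_controls`,
#'   `by_country`, `by_control_source` (named integer vectors) and `hwe`
#'   (data frame from [hwe_table()]).
#' @export
characteristics_summary <- function(x, alpha = 0.05) {
  if (nrow(x) == 0) {
    return(list(
      n_studies = 0L, total_cases = 0L, total_controls = 0L,
      by_country = integer(0), by_control_source = integer(0),
      hwe = NULL
    ))
  }
  list(
    n_studies = nrow(x),
    total_cases = sum(x$case_gg + x$case_ga + x$case_aa),
    total_controls = sum(x$control_gg + x$control_ga + x$control_aa),
    by_country = table(x$country),
    by_control_source = table(x$control_source),
    hwe = hwe_table(x, arm = "control", alpha = alpha)
  )
}

#' Round a result table to reporting precision
#'
#' ORs and confidence limits to 3 decimals, p-values to 3 decimals,
#' I-squared to 1 decimal; NA rendered as "NA".
#'
#' @param results A `meta_result_table`.
#' @return A character data frame ready for TSV export.
#' @export
format_result_table <- function(results) {
  fmt <- function(v, digits) {
    ifelse(is.na(v), "NA", formatC(round(v, digits), format = "f", digits = digits))
  }
  data.frame(
    category = results$category, model = results$model,
    k = as.character(results$k), method = results$method,
    or = fmt(results$or, 3),
    ci_low = fmt(results$ci_low, 3), ci_high = fmt(results$ci_high, 3),
    p = fmt(results$p, 3),
    p_bonferroni = fmt(results$p_bonferroni, 3),
    p_fdr = fmt(results$p_fdr, 3),
    het_p = fmt(results$het_p, 3), i2 = fmt(results$i2, 1),
    begg_p = fmt(results$begg_p, 3), egger_p = fmt(results$egger_p, 3),
    stringsAsFactors = FALSE
  )
}

#' Write a result table to TSV or JSON
#'
#' TSV output is the rounded report (see [format_result_table()]) and is
#' byte-identical across runs on identical input; JSON carries the full
#' unrounded columns.
#'
#' @param results A `meta_result_table`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(format_result_table(results), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    jsonlite::write_json(as.data.frame(results), path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}
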