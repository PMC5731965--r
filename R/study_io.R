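# Columns every studies CSV must carry; nos_score is optional metadata.
STUDY_COLUMNS <- c(
  "study_id", "first_author", "year", "country", "control_source",
  "case_gg", "case_ga", "case_aa",
  "control_gg", "control_ga", "control_aa"
)

COUNT_COLUMNS <- c(
  "case_gg", "case_ga", "case_aa",
  "control_gg", "control_ga", "control_aa"
)

COLLAPSED_COLUMNS <- c(
  "study_id", "stratum_label",
  "case_exposed", "case_ref", "control_exposed", "control_ref"
)

#' Genotype counts for one study arm
#'
#' Validated counts of G/G homozygotes, G/A heterozygotes and A/A homozygotes
#' in a single arm (cases or controls) of a case-control study of a biallelic
#' G>A variant.
#'
#' @param gg,ga,aa Non-negative integer counts of the three genotype classes.
#' @return A named integer vector of class `"genotype_counts"` with elements
#'   `gg`, `ga`, `aa`.
#' @examples
#' g <- genotype_counts(194, 100, 14)
#' sum(g)            # subjects
#' allele_counts(g)  # G and A allele counts
#' @export
genotype_counts <- function(gg, ga, aa) {
  g <- c(gg = gg, ga = ga, aa = aa)
  if (length(g) != 3L || anyNA(g) || !is.numeric(g)) {
    stop("genotype counts must be three non-missing numbers (gg, ga, aa)")
  }
  if (any(g < 0)) {
    bad <- names(g)[g < 0][1L]
    stop(sprintf("genotype count '%s' is negative (%s)", bad, g[[bad]]))
  }
  if (any(g != round(g))) {
    bad <- names(g)[g != round(g)][1L]
    stop(sprintf("genotype count '%s' is not an integer (%s)", bad, g[[bad]]))
  }
  structure(as.integer(round(g)), names = names(g), class = "genotype_counts")
}

#' Allele counts implied by genotype counts
#'
#' @param g A [genotype_counts()] vector (or any numeric triple gg, ga, aa).
#' @return Named integer vector with the G allele count `g = 2*gg + ga` and
#'   the A allele count `a = ga + 2*aa`.
#' @export
allele_counts <- function(g) {
  g <- as.numeric(g)
  c(g = 2 * g[1] + g[2], a = g[2] + 2 * g[3])
}

new_study_collection <- function(df, label) {
  structure(df, label = label, class = c("study_collection", "data.frame"))
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf(
    "<study_collection> '%s': %d studies, %d cases / %d controls\n",
    attr(x, "label"), nrow(x),
    sum(x$case_gg + x$case_ga + x$case_aa),
    sum(x$control_gg + x$control_ga + x$control_aa)
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}

validate_studies <- function(df, file = "<data>") {
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing required column(s): %s",
      file, paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(df$study_id)) {
    dup <- df$study_id[duplicated(df$study_id)][1L]
    stop(sprintf("%s: duplicate study_id '%s'", file, dup))
  }
  for (i in seq_len(nrow(df))) {
    for (col in COUNT_COLUMNS) {
      v <- df[[col]][i]
      if (is.na(v) || !is.numeric(v)) {
        stop(sprintf("%s: row %d, field '%s': missing or non-numeric count", file, i, col))
      }
      if (v != round(v)) {
        stop(sprintf("%s: row %d, field '%s': count %s is not an integer", file, i, col, v))
      }
      if (v < 0) {
        stop(sprintf("%s: row %d, field '%s': negative count %s", file, i, col, v))
      }
    }
    if (df$case_gg[i] + df$case_ga[i] + df$case_aa[i] <= 0) {
      stop(sprintf("%s: row %d: case arm has zero subjects", file, i))
    }
    if (df$control_gg[i] + df$control_ga[i] + df$control_aa[i] <= 0) {
      stop(sprintf("%s: row %d: control arm has zero subjects", file, i))
    }
    for (col in c("study_id", "country", "control_source")) {
      if (is.na(df[[col]][i]) || !nzchar(df[[col]][i])) {
        stop(sprintf("%s: row %d, field '%s': must be non-empty", file, i, col))
      }
    }
  }
  invisible(df)
}

#' Read a collection of case-control studies from CSV
#'
#' The file must have one header row with columns `study_id`, `first_author`,
#' `year`, `country`, `control_source` (HB or PB), the six genotype-count
#' columns `case_gg`, `case_ga`, `case_aa`, `control_gg`, `control_ga`,
#' `control_aa`, and optionally `nos_score`. Rows are validated: counts must
#' be non-negative integers, both arms non-empty, and `study_id` unique.
#'
#' @param path Path to a CSV file.
#' @param label Collection label; defaults to the file name.
#' @return A `study_collection` (a validated data frame with a `label`
#'   attribute), one row per study in file order.
#' @seealso [write_studies_csv()], [rs671_gastric()]
#' @export
read_studies_csv <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    validate_studies(df, file = path)
  } else {
    missing_cols <- setdiff(STUDY_COLUMNS, names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf(
        "%s: missing required column(s): %s",
        path, paste(missing_cols, collapse = ", ")
      ))
    }
  }
  if (!"nos_score" %in% names(df)) df[["nos_score"]] <- rep(NA_integer_, nrow(df))
  new_study_collection(df[, c(STUDY_COLUMNS, "nos_score")], label = label)
}

#' Write a study collection to CSV
#'
#' Inverse of [read_studies_csv()]: a write followed by a read reproduces
#' every field exactly.
#'
#' @param x A `study_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled studies: ALDH2 rs671 G>A and gastric cancer in East Asia
#'
#' Twelve case-control studies (published 2009-2017; eight from China, two
#' from Japan, two from Korea; six hospital-based and six population-based
#' control series) of the ALDH2 rs671 G>A (Glu504Lys) polymorphism and
#' gastric cancer risk, with per-arm genotype counts, totalling 6,420 cases
#' and 8,832 controls as counted from the genotype columns. The source
#' characteristics table lists the Matsuo case series as 697 subjects while
#' its genotype counts sum to 696; the genotype counts are taken as ground
#' truth here. The Yuan control arm departs from Hardy-Weinberg equilibrium
#' (chi-square p ~ 0.03) and is retained, as it was in all pooled analyses.
#'
#' @return A `study_collection` with 12 rows.
#' @examples
#' studies <- rs671_gastric()
#' characteristics_summary(studies)
#' @export
rs671_gastric <- function() {
  path <- system.file("extdata", "rs671_gastric_studies.csv",
    package = "assocmeta", mustWork = TRUE
  )
  read_studies_csv(path, label = "rs671_gastric")
}

#' Read collapsed (dominant-model) stratum records from CSV
#'
#' Carrier format for stratified analyses where only the pooled
#' GA+AA ("exposed") versus GG ("reference") counts are available per study,
#' as is common when primary reports break genotypes down by sex, smoking or
#' drinking status. Columns: `study_id`, `stratum_label`, `case_exposed`,
#' `case_ref`, `control_exposed`, `control_ref`.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `"collapsed_studies"`, one row per record,
#'   `stratum_label` preserved verbatim.
#' @seealso [run_collapsed_analysis()], [simulate_collapsed()]
#' @export
read_collapsed_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COLLAPSED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  cnt <- c("case_exposed", "case_ref", "control_exposed", "control_ref")
  for (i in seq_len(nrow(df))) {
    for (col in cnt) {
      v <- df[[col]][i]
      if (is.na(v) || !is.numeric(v) || v != round(v) || v < 0) {
        stop(sprintf(
          "%s: row %d, field '%s': counts must be non-negative integers",
          path, i, col
        ))
      }
    }
    if (df$case_exposed[i] + df$case_ref[i] <= 0) {
      stop(sprintf("%s: row %d: case arm has zero subjects", path, i))
    }
    if (df$control_exposed[i] + df$control_ref[i] <= 0) {
      stop(sprintf("%s: row %d: control arm has zero subjects", path, i))
    }
  }
  structure(df[, COLLAPSED_COLUMNS], class = c("collapsed_studies", "data.frame"))
}

#' Write collapsed stratum records to CSV
#'
#' @param x A data frame with the collapsed-record columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Arm accessors used throughout the pipeline.
case_counts <- function(x, i) {
  genotype_counts(x$case_gg[i], x$case_ga[i], x$case_aa[i])
}

control_counts <- function(x, i) {
  genotype_counts(x$control_gg[i], x$control_ga[i], x$control_aa[i])
}
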