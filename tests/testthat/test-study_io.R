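test_that("genotype counts validate and derive allele counts", {
  g <- genotype_counts(194, 100, 14)
  expect_equal(sum(g), 308)
  expect_equal(allele_counts(g), c(g = 488, a = 128))
  expect_error(genotype_counts(1, -2, 3), "'ga'")
  expect_error(genotype_counts(1, 2.5, 3), "not an integer")
})

test_that("bundled collection matches the published genotype table", {
  x <- rs671_gastric()
  expect_s3_class(x, "study_collection")
  expect_equal(nrow(x), 12)
  expect_equal(sum(x$case_gg + x$case_ga + x$case_aa), 6420)
  expect_equal(sum(x$control_gg + x$control_ga + x$control_aa), 8832)

  zhang <- x[x$first_author == "Zhang", ]
  expect_equal(
    unlist(zhang[, c("case_gg", "case_ga", "case_aa")], use.names = FALSE),
    c(1995, 643, 48)
  )
  expect_equal(
    unlist(zhang[, c("control_gg", "control_ga", "control_aa")], use.names = FALSE),
    c(2663, 941, 71)
  )
  matsuo <- x[x$first_author == "Matsuo", ]
  expect_equal(matsuo$case_gg + matsuo$case_ga + matsuo$case_aa, 696)

  expect_equal(as.vector(table(x$country)[c("China", "Japan", "Korea")]), c(8, 2, 2))
  expect_equal(as.vector(table(x$control_source)[c("HB", "PB")]), c(6, 6))
})

test_that("bundled allele counts reproduce the published allele columns", {
  x <- rs671_gastric()
  # spot-checks against printed G/A cells
  yang <- x[x$first_author == "Yang", ]
  expect_equal(
    allele_counts(c(yang$case_gg, yang$case_ga, yang$case_aa)),
    c(g = 749, a = 151)
  )
  matsuo <- x[x$first_author == "Matsuo", ]
  expect_equal(
    allele_counts(c(matsuo$case_gg, matsuo$case_ga, matsuo$case_aa)),
    c(g = 943, a = 449)
  )
  hidaka <- x[x$first_author == "Hidaka", ]
  expect_equal(
    allele_counts(c(hidaka$control_gg, hidaka$control_ga, hidaka$control_aa)),
    c(g = 734, a = 180)
  )
  # identity across all arms: allele totals are twice the subject totals
  for (i in seq_len(nrow(x))) {
    cs <- c(x$case_gg[i], x$case_ga[i], x$case_aa[i])
    expect_equal(sum(allele_counts(cs)), 2 * sum(cs))
  }
})

test_that("studies CSV round-trips exactly", {
  x <- rs671_gastric()
  path <- withr::local_tempfile(fileext = ".csv")
  write_studies_csv(x, path)
  y <- read_studies_csv(path, label = attr(x, "label"))
  expect_equal(as.data.frame(y), as.data.frame(x))
  expect_equal(attr(y, "label"), attr(x, "label"))
})

test_that("studies CSV validation names the offending row and field", {
  x <- as.data.frame(rs671_gastric())
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- x
  bad$case_aa[3] <- -1
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_studies_csv(path), "row 3.*case_aa.*negative")

  bad <- x
  bad$study_id[2] <- bad$study_id[1]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_studies_csv(path), "duplicate study_id")

  write.csv(x[, setdiff(names(x), "control_ga")], path, row.names = FALSE)
  expect_error(read_studies_csv(path), "missing required column.*control_ga")

  bad <- x
  bad$case_gg[1] <- 10.5
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_studies_csv(path), "row 1.*case_gg.*not an integer")
})

test_that("header-only studies CSV yields an empty collection with its label", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c(
    "study_id,first_author,year,country,control_source",
    "case_gg,case_ga,case_aa,control_gg,control_ga,control_aa"
  ), collapse = ","), path)
  x <- read_studies_csv(path, label = "empty-set")
  expect_equal(nrow(x), 0)
  expect_equal(attr(x, "label"), "empty-set")
})

test_that("collapsed CSV reads, validates and round-trips", {
  rec <- data.frame(
    study_id = sprintf("s%d", 1:7), stratum_label = "Drinker",
    case_exposed = 11:17, case_ref = 21:27,
    control_exposed = 31:37, control_ref = 41:47
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_collapsed_csv(rec, path)
  got <- read_collapsed_csv(path)
  expect_equal(nrow(got), 7)
  expect_true(all(got$stratum_label == "Drinker"))
  expect_equal(as.data.frame(got), rec)

  writeLines("study_id,stratum_label,case_exposed,case_ref,control_exposed,control_ref", path)
  expect_equal(nrow(read_collapsed_csv(path)), 0)

  bad <- rec
  bad$case_exposed[1] <- 0
  bad$case_ref[1] <- 0
  write_collapsed_csv(bad, path)
  expect_error(read_collapsed_csv(path), "row 1.*case arm")
})
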