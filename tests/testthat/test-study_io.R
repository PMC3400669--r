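test_that("reconstruct_counts reproduces exact and rounded rows", {
  # exact products need no repair
  expect_equal(gt_counts <- reconstruct_counts(100, c(0.25, 0.50, 0.25)),
               genotype_counts(25, 50, 25))
  # frozen from the enumeration oracle (enum_min_maxdev); simple rounding
  # already balances both rows
  bao_case <- reconstruct_counts(160, c(0.400, 0.444, 0.156))
  expect_equal(unname(gt_vec(bao_case)), c(64, 71, 25))
  bhowmick_ctrl <- reconstruct_counts(76, c(0.158, 0.487, 0.355))
  expect_equal(unname(gt_vec(bhowmick_ctrl)), c(12, 37, 27))
})

test_that("reconstruct_counts validates its inputs", {
  expect_error(reconstruct_counts(100, c(0.5, 0.3, 0.1), label = "bad row"),
               "0.900.*bad row", class = "snpmeta_validation_error")
  expect_error(reconstruct_counts(-5, c(0.2, 0.3, 0.5)),
               class = "snpmeta_validation_error")
  expect_error(reconstruct_counts(0, c(0.2, 0.3, 0.5)),
               class = "snpmeta_validation_error")
  expect_error(reconstruct_counts(10, c(0.2, 0.3)),
               class = "snpmeta_validation_error")
})

test_that("reconstruction sums to n and attains the enumeration optimum", {
  set.seed(1201)
  for (i in 1:40) {
    n <- sample(5:120, 1)
    f <- as.vector(stats::rmultinom(1, 1000, c(1, 1, 1) / 3)) / 1000
    got <- reconstruct_counts(n, f)
    expect_identical(got$total, as.integer(n))
    achieved <- max(abs(unname(gt_vec(got)) - n * f))
    expect_lte(achieved, enum_min_maxdev(n, f) + 1e-9)
  }
})

test_that("reconstructed fixture arms reproduce the printed proportions", {
  fx <- egf_glioma_studies()
  tf <- table1_freqs()
  for (i in seq_len(nrow(tf))) {
    s <- fx$studies[[i]]
    expect_identical(s$label, tf$study[i])
    for (arm in c("cases", "controls")) {
      n <- s[[arm]]$total
      printed <- unlist(tf[i, paste0(if (arm == "cases") "case_f" else "ctrl_f",
                                     c("GG", "GA", "AA"))])
      expect_lt(max(abs(gt_vec(s[[arm]]) / n - printed)), 0.0005 + 0.5 / n)
    }
  }
})

test_that("bundled fixture has the published totals and strata", {
  fx <- egf_glioma_studies()
  expect_length(fx, 7)
  n_case <- vapply(fx$studies, function(s) s$cases$total, integer(1))
  n_ctrl <- vapply(fx$studies, function(s) s$controls$total, integer(1))
  expect_identical(sum(n_case), 1613L)
  expect_identical(sum(n_ctrl), 2267L)
  eth <- vapply(fx$studies, function(s) s$ethnicity, character(1))
  src <- vapply(fx$studies, function(s) s$control_source, character(1))
  expect_identical(sum(eth == "Asian"), 3L)
  expect_identical(sum(eth == "Caucasian"), 4L)
  expect_identical(sum(src == "Hospital"), 5L)
  expect_identical(sum(src == "Population"), 2L)
  wang <- fx$studies[[which(vapply(fx$studies, function(s) s$label, character(1)) == "Wang 2010")]]
  expect_equal(unname(gt_vec(wang$controls)), c(366, 276, 51))
  # frequency-mode reconstruction and the shipped count table agree cell by cell
  expect_identical(as.data.frame(egf_glioma_studies("frequencies")),
                   as.data.frame(fx))
})

test_that("count-mode rows pass through without reconstruction", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,year,ethnicity,source,n_case,n_control,case_GG,case_GA,case_AA,ctrl_GG,ctrl_GA,ctrl_AA",
               "Solo 2011,2011,asian,hospital,160,320,64,71,25,141,151,28"),
             path)
  col <- read_study_table(path)
  expect_length(col, 1)
  expect_equal(unname(gt_vec(col$studies[[1]]$cases)), c(64, 71, 25))
  expect_identical(col$studies[[1]]$ethnicity, "Asian")   # case-insensitive strata
  expect_identical(col$studies[[1]]$control_source, "Hospital")
})

test_that("parser rejects malformed tables with named causes", {
  write_rows <- function(lines) {
    path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(lines, path)
    path
  }
  header_f <- "study,year,ethnicity,source,n_case,n_control,case_fGG,case_fGA,case_fAA,ctrl_fGG,ctrl_fGA,ctrl_fAA"
  # missing required column
  expect_error(read_study_table(write_rows(c(
    "study,year,ethnicity,n_case,n_control", "x,2000,Asian,10,10"))),
    "source", class = "snpmeta_parse_error")
  # proportions summing to 0.90
  expect_error(read_study_table(write_rows(c(header_f,
    "x,2000,Asian,Hospital,100,100,0.5,0.3,0.1,0.3,0.4,0.3"))),
    "0.900", class = "snpmeta_validation_error")
  # duplicate study labels
  expect_error(read_study_table(write_rows(c(header_f,
    "x,2000,Asian,Hospital,100,100,0.3,0.4,0.3,0.3,0.4,0.3",
    "x,2001,Asian,Hospital,100,100,0.3,0.4,0.3,0.3,0.4,0.3"))),
    "duplicate", class = "snpmeta_validation_error")
  # counts and proportions mixed within one arm
  expect_error(read_study_table(write_rows(c(
    "study,year,ethnicity,source,n_case,n_control,case_GG,case_GA,case_AA,case_fGG,case_fGA,case_fAA,ctrl_GG,ctrl_GA,ctrl_AA",
    "x,2000,Asian,Hospital,100,100,30,40,30,0.3,0.4,0.3,30,40,30"))),
    "both counts and proportions", class = "snpmeta_validation_error")
  # counts disagreeing with the declared sample size
  expect_error(read_study_table(write_rows(c(
    "study,year,ethnicity,source,n_case,n_control,case_GG,case_GA,case_AA,ctrl_GG,ctrl_GA,ctrl_AA",
    "x,2000,Asian,Hospital,99,100,30,40,30,30,40,30"))),
    "declared sample size", class = "snpmeta_validation_error")
  # unknown stratum value is an error, not a third level
  expect_error(read_study_table(write_rows(c(header_f,
    "x,2000,Martian,Hospital,100,100,0.3,0.4,0.3,0.3,0.4,0.3"))),
    "Martian", class = "snpmeta_validation_error")
})

test_that("write/read round-trips counts, strata and order for both delimiters", {
  fx <- egf_glioma_studies()
  for (delim in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_study_table(fx, path, delim = delim)
    back <- read_study_table(path)   # delimiter auto-detected
    expect_identical(as.data.frame(back), as.data.frame(fx))
  }
})
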