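test_that("an all-unmapped file fails automatically under the example config", {
  fx <- generate_clean(fixture_spec(seed = 301, n_reads = 100,
                                    frac_unmapped = 1, file_id = "f1"))
  kv <- qa_mapping_ratio(fx$sam)
  expect_equal(kv$value[kv$key == "FILE_f1_MAPPING_RATIO"], 0)
  v <- apply_thresholds(kv, validate_sam(fx$sam)$findings,
                        example_threshold_config(), "f1")
  expect_equal(v$status, "FAIL")
  expect_true("FILE_f1_MAPPING_RATIO" %in% v$reasons$trigger)
  expect_equal(v$reasons$observed[v$reasons$trigger == "FILE_f1_MAPPING_RATIO"], 0)
})

test_that("clean files pass with empty reasons", {
  fx <- generate_clean(fixture_spec(seed = 302, n_reads = 100, file_id = "f1"))
  kv <- dplyr::bind_rows(qa_mapping_ratio(fx$sam), qa_mapping_quality(fx$sam))
  v <- apply_thresholds(kv, validate_sam(fx$sam)$findings,
                        example_threshold_config(), "f1")
  expect_equal(v$status, "PASS")
  expect_equal(nrow(v$reasons), 0L)
})

test_that("WARN bounds record the observed value and the bound", {
  kv <- tibble::tibble(key = "GROUP_f1_rgA_MAPQ_MEAN", value = 12)
  v <- apply_thresholds(kv, empty_findings_tbl(), example_threshold_config(), "f1")
  expect_equal(v$status, "WARN")
  expect_equal(v$reasons$observed, 12)
  expect_equal(v$reasons$bound, 20)
  expect_equal(v$reasons$action, "WARN")
})

test_that("technical findings in the fail set force rejection", {
  fx <- generate_clean(fixture_spec(seed = 303, n_reads = 100, file_id = "f1"))
  planted <- plant_errors(fx$sam, tibble::tibble(
    rule_id = "functional.cigar_on_unmapped", count = 1L), seed = 2)
  kv <- qa_mapping_ratio(planted$sam)
  v <- apply_thresholds(kv, validate_sam(planted$sam)$findings,
                        example_threshold_config(), "f1")
  expect_equal(v$status, "FAIL")
  expect_true("functional.cigar_on_unmapped" %in% v$reasons$trigger)
})

test_that("NA metrics never trigger numeric bounds, only an na_metric warning", {
  cfg <- threshold_config(tibble::tibble(pattern = "CORR_*", bound_type = "min",
                                         bound = 0.5, action = "FAIL"))
  kv <- tibble::tibble(key = "CORR_f1_a_b_COVERAGE", value = NA_real_)
  v <- apply_thresholds(kv, empty_findings_tbl(), cfg, "f1")
  expect_equal(v$status, "WARN")
  expect_match(v$reasons$trigger, "^na_metric:")
})

test_that("missing required tests fail the file", {
  cfg <- threshold_config(
    tibble::tibble(pattern = "FILE_*_MAPPING_RATIO", bound_type = "min",
                   bound = 0.5, action = "FAIL"),
    required_tests = "FILE_*_MAPPING_RATIO"
  )
  v <- apply_thresholds(tibble::tibble(key = character(), value = double()),
                        empty_findings_tbl(), cfg, "f1")
  expect_equal(v$status, "FAIL")
  expect_match(v$reasons$trigger, "^missing_required:")
})

test_that("relaxing any bound never flips a verdict toward FAIL", {
  withr::with_seed(304, {
    for (i in 1:25) {
      kv <- tibble::tibble(
        key = c("FILE_f1_MAPPING_RATIO", "FILE_f1_MAPQ_MEAN",
                "FILE_f1_ANOMALOUS_FRACTION"),
        value = c(stats::runif(1), stats::runif(1, 0, 60), stats::runif(1, 0, 0.2))
      )
      bounds <- tibble::tibble(
        pattern = c("FILE_*_MAPPING_RATIO", "FILE_*_MAPQ_MEAN",
                    "FILE_*_ANOMALOUS_FRACTION"),
        bound_type = c("min", "min", "max"),
        bound = c(stats::runif(1), stats::runif(1, 0, 60), stats::runif(1, 0, 0.2)),
        action = sample(c("FAIL", "WARN"), 3, replace = TRUE)
      )
      strict <- apply_thresholds(kv, empty_findings_tbl(),
                                 threshold_config(bounds), "f1")
      relaxed_bounds <- bounds
      j <- sample(3, 1)
      delta <- stats::runif(1, 0, 10)
      relaxed_bounds$bound[j] <- relaxed_bounds$bound[j] +
        ifelse(relaxed_bounds$bound_type[j] == "min", -delta, delta)
      relaxed <- apply_thresholds(kv, empty_findings_tbl(),
                                  threshold_config(relaxed_bounds), "f1")
      rank <- c(PASS = 1, WARN = 2, FAIL = 3)
      expect_lte(rank[[relaxed$status]], rank[[strict$status]])
    }
  })
})

test_that("batch verdicts summarise statuses and set the exit code", {
  specs <- c(
    lapply(1:8, function(i) fixture_spec(seed = 400 + i, n_reads = 60,
                                         file_id = sprintf("ok%02d", i))),
    lapply(1:2, function(i) fixture_spec(seed = 420 + i, n_reads = 60,
                                         frac_unmapped = 1,
                                         file_id = sprintf("bad%02d", i)))
  )
  results <- lapply(specs, function(sp) {
    fx <- generate_clean(sp)
    list(file_id = sp$file_id,
         kv = dplyr::bind_rows(qa_mapping_ratio(fx$sam),
                               qa_mapping_quality(fx$sam)),
         findings = validate_sam(fx$sam)$findings)
  })
  batch <- batch_verdicts(results, example_threshold_config())
  expect_equal(batch$summary$n[batch$summary$status == "PASS"], 8L)
  expect_equal(batch$summary$n[batch$summary$status == "FAIL"], 2L)
  expect_equal(batch$exit_code, 1L)

  empty <- batch_verdicts(list(), example_threshold_config())
  expect_equal(sum(empty$summary$n), 0L)
  expect_equal(empty$exit_code, 0L)

  allpass <- batch_verdicts(results[1:3], example_threshold_config())
  expect_equal(allpass$exit_code, 0L)
})

test_that("threshold configs round-trip through the TSV format", {
  cfg <- example_threshold_config()
  path <- withr::local_tempfile(fileext = ".cfg")
  write_threshold_config(cfg, path)
  back <- read_threshold_config(path)
  expect_equal(back$rules, cfg$rules)
  expect_equal(back$technical_fail_rules, cfg$technical_fail_rules)
  expect_length(back$required_tests, 0L)

  shipped <- read_threshold_config(
    system.file("extdata", "example_thresholds.cfg", package = "samqc"))
  expect_equal(shipped$rules, cfg$rules)
})

test_that("verdicts are a pure function of their inputs", {
  kv <- tibble::tibble(key = "FILE_f1_MAPPING_RATIO", value = 0.3)
  v1 <- apply_thresholds(kv, empty_findings_tbl(), example_threshold_config(), "f1")
  v2 <- apply_thresholds(kv, empty_findings_tbl(), example_threshold_config(), "f1")
  expect_identical(tidy(v1), tidy(v2))
  expect_equal(v1$status, "FAIL")
})
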