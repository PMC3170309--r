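test_that("coverage apportions bases across bins and normalises by bin size", {
  one <- test_sam(test_record(pos = 1, cigar = "100M"))
  kv <- qa_coverage(one, bin_size = 1000)
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_0_COVERAGE"], 0.1)

  straddle <- test_sam(test_record(pos = 951, cigar = "100M"))
  kv <- qa_coverage(straddle, bin_size = 1000)
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_0_COVERAGE"], 50 / 1000)
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_1_COVERAGE"], 50 / 1000)

  unmapped <- test_sam(test_record(flag = 4L, rname = NA_character_,
                                   pos = NA_real_, mapq = 0,
                                   cigar = NA_character_))
  expect_equal(nrow(qa_coverage(unmapped)), 0L)
})

test_that("coverage matches the per-base depth-array oracle", {
  fx <- generate_clean(fixture_spec(seed = 61, n_reads = 400, file_id = "s1",
                                    depth_profile = c(1, 5, 2, 8)))
  kv <- qa_coverage(fx$sam)
  bins <- kv[startsWith(kv$key, "BIN_"), ]
  expect_equal(bins, oracle_coverage(fx$sam), tolerance = 0)
})

test_that("deletions count as covering by default but can be excluded", {
  sam <- test_sam(test_record(pos = 1, cigar = "40M20D40M"))
  kv <- qa_coverage(sam)
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_0_COVERAGE"], 0.1)
  kv2 <- qa_coverage(sam, coverage_ops = c("M", "=", "X"))
  expect_equal(kv2$value[kv2$key == "BIN_s1_chr1_0_COVERAGE"], 0.08)
})

test_that("coverage conservation holds exactly", {
  withr::with_seed(71, {
    for (i in 1:10) {
      fx <- generate_clean(fixture_spec(seed = sample.int(1e6, 1),
                                        n_reads = sample(50:200, 1)))
      kv <- qa_coverage(fx$sam, bin_size = 1000)
      bins <- kv[startsWith(kv$key, "BIN_"), ]
      mapped <- !is_flag_set(fx$sam$records$flag, "unmapped")
      # each bin value is an exact integer base count / bin size; recover
      # the integers before summing so the comparison is exact
      bases <- round(bins$value * 1000)
      expect_true(all(bins$value == bases / 1000))
      expect_identical(sum(bases),
                       as.numeric(sum(reference_span(
                         fx$sam$records$cigar[mapped]))))
    }
  })
})

test_that("read frequency counts reads in their start bin only", {
  sam <- test_sam(dplyr::bind_rows(
    test_record(qname = "a", pos = 1),
    test_record(qname = "b", pos = 500),
    test_record(qname = "c", pos = 999)
  ))
  kv <- qa_read_frequency(sam, bin_size = 1000)
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_0_READCOUNT"], 3)
  # the read starting at 999 extends into bin 1 but is not counted there
  expect_false("BIN_s1_chr1_1_READCOUNT" %in% kv$key)
})

test_that("read frequency values sum to the mapped read count", {
  fx <- generate_clean(fixture_spec(seed = 81, n_reads = 300,
                                    frac_unmapped = 0.2))
  kv <- qa_read_frequency(fx$sam)
  mapped <- sum(!is_flag_set(fx$sam$records$flag, "unmapped"))
  expect_equal(sum(kv$value), mapped)
})

test_that("mapping quality reports means, histograms and group scopes", {
  sam <- test_sam(dplyr::bind_rows(
    test_record(qname = "a", mapq = 10),
    test_record(qname = "b", mapq = 20),
    test_record(qname = "c", mapq = 30)
  ))
  kv <- qa_mapping_quality(sam)
  expect_equal(kv$value[kv$key == "FILE_s1_MAPQ_MEAN"], 20)
  expect_equal(kv$value[kv$key == "FILE_s1_MAPQ10_COUNT"], 1)

  none <- test_sam(test_record(flag = 4L, mapq = 0))
  expect_equal(nrow(qa_mapping_quality(none)), 0L)

  grouped <- test_sam(dplyr::bind_rows(
    test_record(qname = "a", mapq = 12, tags = "RG:Z:rg1"),
    test_record(qname = "b", mapq = 55, tags = "RG:Z:rg2")
  ))
  kv <- qa_mapping_quality(grouped)
  expect_equal(kv$value[kv$key == "GROUP_s1_rg1_MAPQ_MEAN"], 12)
  expect_equal(kv$value[kv$key == "GROUP_s1_rg2_MAPQ_MEAN"], 55)
})

test_that("group mean mapq of a union is the count-weighted mean of the parts", {
  fx <- generate_clean(fixture_spec(seed = 91, n_reads = 200))
  r <- fx$sam$records
  a <- test_sam(r[1:120, ], header = fx$sam$header, file_id = "sample")
  b <- test_sam(r[121:200, ], header = fx$sam$header, file_id = "sample")
  whole <- qa_mapping_quality(fx$sam)
  ma <- qa_mapping_quality(a)
  mb <- qa_mapping_quality(b)
  key <- "FILE_sample_MAPQ_MEAN"
  expect_equal(whole$value[whole$key == key],
               (ma$value[ma$key == key] * 120 + mb$value[mb$key == key] * 80) / 200)
})

test_that("mapping ratio covers the mapped, all-unmapped and empty cases", {
  mixed <- test_sam(dplyr::bind_rows(
    purrr::map_dfr(1:9, ~ test_record(qname = paste0("m", .x))),
    test_record(qname = "u", flag = 4L, rname = NA_character_,
                pos = NA_real_, mapq = 0, cigar = NA_character_)
  ))
  kv <- qa_mapping_ratio(mixed)
  expect_equal(kv$value[kv$key == "FILE_s1_MAPPING_RATIO"], 0.9)

  allun <- test_sam(purrr::map_dfr(1:5, ~ test_record(
    qname = paste0("u", .x), flag = 4L, rname = NA_character_,
    pos = NA_real_, mapq = 0, cigar = NA_character_)))
  expect_equal(qa_mapping_ratio(allun)$value, 0)

  empty <- test_sam(test_record()[0, ])
  expect_equal(nrow(qa_mapping_ratio(empty)), 0L)
})

test_that("read statistics aggregate lengths and per-group counts", {
  sam <- test_sam(dplyr::bind_rows(
    test_record(qname = "a", seq = strrep("A", 36), qual = strrep("I", 36),
                cigar = "36M"),
    test_record(qname = "b", seq = strrep("A", 36), qual = strrep("I", 36),
                cigar = "36M"),
    test_record(qname = "c", seq = strrep("A", 100), qual = strrep("I", 100))
  ))
  kv <- qa_read_statistics(sam)
  expect_equal(kv$value[kv$key == "FILE_s1_LENGTH_MIN"], 36)
  expect_equal(kv$value[kv$key == "FILE_s1_LENGTH_MAX"], 100)
  expect_equal(kv$value[kv$key == "FILE_s1_LENGTH_MEAN"], 172 / 3)

  counts <- test_sam(dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ test_record(qname = paste0("a", .x), tags = "RG:Z:rg1")),
    purrr::map_dfr(1:3, ~ test_record(qname = paste0("b", .x), tags = "RG:Z:rg2"))
  ))
  kv <- qa_read_statistics(counts)
  expect_equal(kv$value[kv$key == "GROUP_s1_rg1_READCOUNT"], 5)
  expect_equal(kv$value[kv$key == "GROUP_s1_rg2_READCOUNT"], 3)

  clipped <- test_sam(test_record(seq = NA_character_, qual = NA_character_,
                                  cigar = "50M10S"))
  kv <- qa_read_statistics(clipped)
  expect_equal(kv$value[kv$key == "FILE_s1_LENGTH_MEAN"], 60)
})

test_that("read_stats mirrors the job output in tabular form", {
  fx <- generate_clean(fixture_spec(seed = 101, n_reads = 150))
  st <- read_stats(fx$sam)
  expect_equal(st$total_reads, 150L)
  expect_equal(st$mapped_reads, 150L)
  expect_equal(sum(st$mapq_histogram$n), st$mapped_reads)
  expect_equal(st$length_mean, 100)
})

test_that("anomalous chromosome counts respect the configurable pattern set", {
  h <- test_header(c(chr1 = 100000L, "chr1_gl000191_random" = 100000L))
  sam <- test_sam(dplyr::bind_rows(
    purrr::map_dfr(1:12, ~ test_record(qname = paste0("r", .x),
                                       rname = "chr1_gl000191_random")),
    purrr::map_dfr(1:4, ~ test_record(qname = paste0("c", .x)))
  ), header = h)
  kv <- qa_chromosome_check(sam)
  expect_equal(
    kv$value[kv$key == "CHROM_s1_chr1-gl000191-random_ANOMALOUS_READCOUNT"], 12)
  expect_equal(kv$value[kv$key == "FILE_s1_ANOMALOUS_FRACTION"], 12 / 16)

  clean <- test_sam(purrr::map_dfr(1:4, ~ test_record(qname = paste0("c", .x))))
  expect_equal(nrow(qa_chromosome_check(clean)), 0L)

  expect_equal(nrow(qa_chromosome_check(sam, anomalous_patterns = character(0))),
               0L)
})

test_that("discordant pairs are counted per bin and per platform unit", {
  h <- test_header(c(chr1 = 100000L, chr2 = 100000L))
  concordant <- test_record(qname = "ok", flag = 99L, rnext = "=",
                            pnext = 300, tlen = 400)
  inter <- test_record(qname = "ic", flag = 99L, rnext = "chr2",
                       pnext = 300, tlen = 0, pos = 3500)
  wide <- test_record(qname = "wd", flag = 99L, rnext = "=",
                      pnext = 9000, tlen = 8000, pos = 3500)
  improper <- test_record(qname = "ip", flag = 1L, rnext = "=",
                          pnext = 300, tlen = 400, pos = 3500)
  sam <- test_sam(dplyr::bind_rows(concordant, inter, wide, improper),
                  header = h)
  kv <- qa_structural_variation(sam, insert_lo = 0, insert_hi = 1000)
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_3_SV_COUNT"], 3)
  expect_false("BIN_s1_chr1_0_SV_COUNT" %in% kv$key)
  expect_equal(kv$value[kv$key == "PU_s1_pu-rg1_SV_FRACTION"], 3 / 4)
})

test_that("planted discordant reads are recovered in their bin", {
  base <- purrr::map_dfr(1:30, ~ test_record(
    qname = paste0("c", .x), flag = 99L, rnext = "=", pnext = 300, tlen = 400))
  planted <- purrr::map_dfr(1:20, ~ test_record(
    qname = paste0("d", .x), flag = 99L, rnext = "chr2", pnext = 1,
    tlen = 0, pos = 3000 + .x))
  h <- test_header(c(chr1 = 100000L, chr2 = 100000L))
  kv <- qa_structural_variation(test_sam(dplyr::bind_rows(base, planted),
                                         header = h))
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_3_SV_COUNT"], 20)
})

test_that("legacy 4-token BIN keys omit the chromosome token", {
  sam <- test_sam(test_record(pos = 1, cigar = "100M"))
  kv <- qa_coverage(sam, legacy_keys = TRUE)
  expect_true("BIN_s1_0_COVERAGE" %in% kv$key)
})

test_that("records on unknown references are skipped with a warning", {
  sam <- test_sam(dplyr::bind_rows(test_record(),
                                   test_record(qname = "x", rname = "chrZZ")))
  expect_warning(kv <- qa_coverage(sam), class = "samqc_unknown_reference")
  expect_equal(kv$value[kv$key == "BIN_s1_chr1_0_COVERAGE"], 0.1)
})
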