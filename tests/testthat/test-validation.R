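test_that("header checks report missing or inconsistent dictionary entries", {
  h <- test_header()
  expect_equal(nrow(check_header(h)), 0L)

  no_rg <- sam_header(sequences = h$sequences)
  f <- check_header(no_rg)
  expect_true("header.no_read_groups" %in% f$rule_id)
  expect_equal(f$severity[f$rule_id == "header.no_read_groups"], "WARNING")

  dup <- sam_header(
    sequences = tibble::tibble(name = c("chr1", "chr1"), length = c(10L, 10L)),
    read_groups = h$read_groups
  )
  expect_true("header.duplicate_sequence" %in% check_header(dup)$rule_id)

  bad_len <- sam_header(
    sequences = tibble::tibble(name = "chr1", length = 0L),
    read_groups = h$read_groups
  )
  expect_true("header.nonpositive_length" %in% check_header(bad_len)$rule_id)
})

test_that("syntax checks catch field-level violations and pass clean records", {
  h <- test_header()
  expect_equal(nrow(check_syntax(test_record(), h)), 0L)

  unknown <- test_record(rname = "chrX")
  expect_equal(check_syntax(unknown, h)$rule_id, "syntax.unknown_reference")

  zero <- test_record(seq = NA_character_, qual = NA_character_,
                      cigar = NA_character_)
  expect_true("syntax.zero_length_read" %in% check_syntax(zero, h)$rule_id)

  mism <- test_record(qual = strrep("I", 99))
  expect_equal(check_syntax(mism, h)$rule_id, "syntax.seq_qual_mismatch")

  badq <- test_record(qname = "has space")
  expect_equal(check_syntax(badq, h)$rule_id, "syntax.invalid_qname")

  bigflag <- test_record(flag = 70000L)
  expect_true("syntax.flag_range" %in% check_syntax(bigflag, h)$rule_id)

  farpos <- test_record(pnext = 3e9)
  expect_true("syntax.pos_range" %in% check_syntax(farpos, h)$rule_id)

  badcig <- test_record(cigar = "10M5")
  expect_true("syntax.invalid_cigar" %in% check_syntax(badcig, h)$rule_id)
})

test_that("functional checks emit the exact per-record contract messages", {
  h <- test_header()
  f1 <- check_functional(test_record(flag = 4L, mapq = 0, cigar = "10M"), h)
  expect_equal(f1$message, "CIGAR should have zero elements for unmapped read")

  f2 <- check_functional(test_record(flag = 4L, mapq = 37,
                                     cigar = NA_character_), h)
  expect_equal(f2$message, "MAPQ should be 0 for unmapped read")

  f3 <- check_functional(test_record(tags = "RG:Z:grpX"), h)
  expect_equal(f3$message, "RG ID on SAMRecord not found in header")
})

test_that("functional cross-field rules fire on the canonical counter-examples", {
  h <- test_header(c(chr1 = 100L))
  beyond <- test_record(pos = 95, cigar = "10M", seq = strrep("A", 10),
                        qual = strrep("I", 10))
  expect_equal(check_functional(beyond, h)$rule_id,
               "functional.maps_beyond_reference")
  # pos + span - 1 == length is legal
  at_edge <- test_record(pos = 91, cigar = "10M", seq = strrep("A", 10),
                         qual = strrep("I", 10))
  expect_equal(nrow(check_functional(at_edge, h)), 0L)

  indel <- test_record(cigar = "5M2I3D5M", seq = strrep("A", 12),
                       qual = strrep("I", 12))
  expect_equal(check_functional(indel, test_header())$rule_id,
               "functional.adjacent_indel")

  orphan <- test_record(flag = 2L)
  expect_equal(check_functional(orphan, test_header())$rule_id,
               "functional.proper_pair_without_pairing")

  badnm <- test_record(tags = "RG:Z:rg1\tNM:i:-1")
  expect_equal(check_functional(badnm, test_header())$rule_id,
               "functional.invalid_nm")
  oknm <- test_record(tags = "RG:Z:rg1\tNM:i:7")
  expect_equal(nrow(check_functional(oknm, test_header())), 0L)
})

test_that("unmapped records are exempt from position and reference checks", {
  h <- test_header(c(chr1 = 100L))
  r <- test_record(flag = 4L, mapq = 0, cigar = NA_character_, pos = 9000)
  f <- check_functional(r, h)
  expect_false("functional.maps_beyond_reference" %in% f$rule_id)
})

test_that("validate_sam recovers planted violations with matching locators", {
  for (k in c(0L, 1L, 50L)) {
    fx <- generate_clean(fixture_spec(seed = 31 + k, n_reads = 200))
    planted <- plant_errors(
      fx$sam,
      tibble::tibble(rule_id = "functional.cigar_on_unmapped", count = k),
      seed = 99
    )
    v <- validate_sam(planted$sam)
    hits <- v$findings[v$findings$rule_id == "functional.cigar_on_unmapped", ]
    expect_equal(nrow(hits), k)
    expect_setequal(hits$record_index, planted$manifest$record_index)
  }
})

test_that("a fully valid synthetic file yields zero findings", {
  fx <- generate_clean(fixture_spec(seed = 41, n_reads = 300))
  expect_equal(nrow(validate_sam(fx$sam)$findings), 0L)
})

test_that("pairing census distinguishes fully and partially unpaired files", {
  all_unpaired <- test_sam(purrr::map_dfr(1:4, ~ test_record(flag = 0L)))
  v <- validate_sam(all_unpaired)
  expect_true("file.all_unpaired" %in% v$findings$rule_id)

  mixed <- test_sam(dplyr::bind_rows(test_record(flag = 99L),
                                     test_record(flag = 0L)))
  expect_true("file.contains_unpaired" %in% validate_sam(mixed)$findings$rule_id)

  paired <- test_sam(purrr::map_dfr(1:4, ~ test_record(flag = 99L)))
  expect_false(any(grepl("unpaired", validate_sam(paired)$findings$rule_id)))
})

test_that("validation output is deterministic and serialises to TSV and KV", {
  fx <- generate_clean(fixture_spec(seed = 51, n_reads = 100, file_id = "s1"))
  planted <- plant_errors(fx$sam, tibble::tibble(
    rule_id = c("functional.adjacent_indel", "syntax.invalid_qname"),
    count = c(3L, 2L)), seed = 7)
  v1 <- validate_sam(planted$sam)
  v2 <- validate_sam(planted$sam)
  expect_identical(v1$findings, v2$findings)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_findings_tsv(v1$findings, path)
  expect_equal(length(readLines(path)), nrow(v1$findings) + 1L)

  kv <- findings_kv(v1)
  expect_setequal(kv$key, c("ERROR_s1_functional.adjacent-indel",
                            "ERROR_s1_syntax.invalid-qname"))
  expect_setequal(kv$value, c(3, 2))
})
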