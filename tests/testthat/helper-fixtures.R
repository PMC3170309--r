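# Shared builders for in-code fixtures. Everything is generated; nothing is
# read from disk except files the tests themselves write to tempdirs.

test_header <- function(chroms = c(chr1 = 100000L),
                        read_groups = c("rg1", "rg2")) {
  sam_header(
    sequences = tibble::tibble(name = names(chroms),
                               length = unname(chroms)),
    read_groups = tibble::tibble(id = read_groups, sample = "s1",
                                 platform = "ILLUMINA",
                                 platform_unit = paste0("pu_", read_groups))
  )
}

# One mapped record with overridable fields.
test_record <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 1,
                        mapq = 60, cigar = "100M", rnext = NA_character_,
                        pnext = NA_real_, tlen = 0, seq = strrep("A", 100),
                        qual = strrep("I", 100), tags = "RG:Z:rg1") {
  tibble::tibble(qname = qname, flag = as.integer(flag), rname = rname,
                 pos = as.numeric(pos), mapq = as.numeric(mapq),
                 cigar = cigar, rnext = rnext, pnext = as.numeric(pnext),
                 tlen = as.numeric(tlen), seq = seq, qual = qual, tags = tags)
}

test_sam <- function(records, header = test_header(), file_id = "s1") {
  sam_file(header, records, file_id)
}

# Brute-force per-base depth oracle: integer depth array over each
# reference, summed per bin and divided by bin size. Independent of the
# job implementation (walks CIGARs base by base via the consumption table).
oracle_coverage <- function(sam, bin_size = 1000) {
  consumes_ref <- with(cigar_op_table(), stats::setNames(consumes_reference, op))
  depth <- lapply(stats::setNames(sam$header$sequences$length,
                                  sam$header$sequences$name),
                  function(len) integer(len))
  r <- sam$records
  for (i in seq_len(nrow(r))) {
    if (is_flag_set(r$flag[i], "unmapped") || is.na(r$rname[i]) ||
        is.na(r$pos[i]) || !r$rname[i] %in% names(depth)) next
    cursor <- r$pos[i]
    ops <- cigar_ops(r$cigar[i])
    for (k in seq_len(nrow(ops))) {
      if (consumes_ref[[ops$op[k]]]) {
        span <- seq.int(cursor, cursor + ops$length[k] - 1L)
        depth[[r$rname[i]]][span] <- depth[[r$rname[i]]][span] + 1L
        cursor <- cursor + ops$length[k]
      }
    }
  }
  out <- purrr::map_dfr(names(depth), function(chrom) {
    d <- depth[[chrom]]
    if (!any(d > 0)) return(NULL)
    bin <- (seq_along(d) - 1L) %/% bin_size
    tot <- tapply(d, bin, sum)
    tibble::tibble(
      key = kv_key("BIN", sam$file_id, chrom, as.integer(names(tot)),
                   metric = "COVERAGE"),
      value = as.numeric(tot) / bin_size
    )
  })
  out <- out[out$value > 0, , drop = FALSE]
  dplyr::arrange(out, key)
}

empty_findings_tbl <- function() samqc:::empty_findings()

# Textbook two-pass Pearson: means first, then moments.
two_pass_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
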