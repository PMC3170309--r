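# Shared parameter defaults for the feature jobs.
.feature_defaults <- function(sam, params) {
  defaults <- list(
    sample = sam$file_id,
    bin_size = 1000,
    mb_bin_size = 1e6,
    insert_lo = 0,
    insert_hi = 1000,
    coverage_ops = c("M", "D", "N", "=", "X"),
    anomalous_patterns = c("random", "^chrUn", "hap", "alt$"),
    include_secondary = TRUE,
    include_duplicates = TRUE,
    legacy_keys = FALSE,
    genome_length = sum(as.numeric(sam$header$sequences$length))
  )
  utils::modifyList(defaults, params)
}

# Mapped records eligible for feature extraction. Records whose rname is
# absent from the dictionary are skipped with a warning (the syntax
# validator reports them as findings).
.eligible_mapped <- function(records, header, params) {
  keep <- !is_flag_set(records$flag, "unmapped") & !is.na(records$rname) &
    !is.na(records$pos)
  unknown <- keep & !(records$rname %in% header$sequences$name)
  if (any(unknown)) {
    rlang::warn(paste0("skipping ", sum(unknown),
                       " mapped record(s) with unknown reference name"),
                class = "samqc_unknown_reference")
    keep <- keep & !unknown
  }
  if (!isTRUE(params$include_secondary)) {
    keep <- keep & !is_flag_set(records$flag, "secondary")
  }
  if (!isTRUE(params$include_duplicates)) {
    keep <- keep & !is_flag_set(records$flag, "duplicate")
  }
  records[keep, , drop = FALSE]
}

# BIN key builder honouring the legacy 4-token form (no chromosome token,
# valid only for single-reference files).
.bin_key <- function(sample, chrom, bin, metric, params) {
  if (isTRUE(params$legacy_keys)) {
    kv_key("BIN", sample, bin, metric = metric)
  } else {
    kv_key("BIN", sample, chrom, bin, metric = metric)
  }
}

#' Per-kilobase coverage job
#'
#' For every (chromosome, bin) touched by at least one mapped read, emits
#' `BIN_<sample>_<chrom>_<binIndex>_COVERAGE` with value the number of
#' aligned reference-consuming bases falling in the bin (reads apportioned
#' base-by-base across bin boundaries) divided by the bin size. Bins are
#' 0-based and cover 1-based positions `[bin*size+1, (bin+1)*size]`; the
#' 1-based-to-bin conversion happens only here and in [read_frequency_job()].
#' Integer base counts are accumulated before the single final division, so
#' coverage conservation (sum of bin value x bin size == sum of reference
#' spans) is exact.
#'
#' Also emits `FILE_<sample>_MEAN_BIN_COVERAGE` (mean over touched bins) and
#' `FILE_<sample>_GENOME_COVERAGE` (total aligned bases / total reference
#' length) — the two readings of "average coverage" per file.
#'
#' @return A [qa_job()].
#' @export
coverage_job <- function() {
  qa_job(
    name = "OutputCoverage",
    map = function(records, header, params) {
      r <- .eligible_mapped(records, header, params)
      bs <- params$bin_size
      full_ops <- setequal(params$coverage_ops, c("M", "D", "N", "=", "X"))
      if (!nrow(r)) {
        return(tibble::tibble(key = character(), bases = double()))
      }
      if (full_ops) {
        span <- reference_span(r$cigar)
        ivs <- tibble::tibble(chrom = r$rname, start = r$pos,
                              end = r$pos + span - 1)[span > 0, , drop = FALSE]
      } else {
        ivs <- purrr::map_dfr(seq_len(nrow(r)), function(i) {
          iv <- cigar_ref_intervals(r$cigar[i], r$pos[i], params$coverage_ops)
          iv$chrom <- r$rname[i]
          iv
        })
      }
      if (!nrow(ivs)) {
        return(tibble::tibble(key = character(), bases = double()))
      }
      first_bin <- (ivs$start - 1) %/% bs
      last_bin <- (ivs$end - 1) %/% bs
      nb <- as.integer(last_bin - first_bin + 1)
      idx <- rep.int(seq_len(nrow(ivs)), nb)
      bin <- first_bin[idx] + sequence(nb) - 1
      lo <- pmax(ivs$start[idx], bin * bs + 1)
      hi <- pmin(ivs$end[idx], (bin + 1) * bs)
      tibble::tibble(
        key = .bin_key(params$sample, ivs$chrom[idx], bin, "COVERAGE", params),
        bases = hi - lo + 1
      )
    },
    combine = c(bases = "sum"),
    reduce = function(combined, params) {
      bins <- tibble::tibble(
        key = combined$key,
        value = combined$bases / params$bin_size
      )
      extra <- tibble::tibble(key = character(), value = double())
      if (nrow(bins)) {
        extra <- tibble::tibble(
          key = c(kv_key("FILE", params$sample, "MEAN", "BIN", metric = "COVERAGE"),
                  kv_key("FILE", params$sample, "GENOME", metric = "COVERAGE")),
          value = c(mean(bins$value),
                    sum(combined$bases) / params$genome_length)
        )
      }
      dplyr::bind_rows(bins, extra)
    }
  )
}

#' Per-kilobase read-frequency job
#'
#' Counts mapped reads whose leftmost position lies in each bin (a read
#' straddling a boundary counts once, in its start bin) and emits
#' `BIN_<sample>_<chrom>_<binIndex>_READCOUNT`.
#'
#' @return A [qa_job()].
#' @export
read_frequency_job <- function() {
  qa_job(
    name = "ReadFrequency",
    map = function(records, header, params) {
      r <- .eligible_mapped(records, header, params)
      if (!nrow(r)) return(tibble::tibble(key = character(), n = double()))
      bin <- (r$pos - 1) %/% params$bin_size
      tibble::tibble(
        key = .bin_key(params$sample, r$rname, bin, "READCOUNT", params),
        n = 1
      )
    },
    combine = c(n = "sum"),
    reduce = function(combined, params) {
      tibble::tibble(key = combined$key, value = combined$n)
    }
  )
}

#' Mapping-quality job
#'
#' Emits the mean MAPQ over mapped reads per file
#' (`FILE_<sample>_MAPQ_MEAN`) and per read group
#' (`GROUP_<sample>_<rg>_MAPQ_MEAN`; records without an RG tag pool into
#' `__no_rg__`), plus the full per-file MAPQ histogram
#' (`FILE_<sample>_MAPQ<q>_COUNT`). Unmapped reads are excluded throughout.
#'
#' @return A [qa_job()].
#' @export
mapping_quality_job <- function() {
  qa_job(
    name = "MappingQualityTest",
    map = function(records, header, params) {
      keep <- !is_flag_set(records$flag, "unmapped")
      r <- records[keep, , drop = FALSE]
      if (!nrow(r)) {
        return(tibble::tibble(key = character(), s = double(), n = double()))
      }
      rg <- tag_value(r, "RG")
      rg[is.na(rg)] <- "__no_rg__"
      dplyr::bind_rows(
        tibble::tibble(
          key = kv_key("FILE", params$sample, "MAPQ", metric = "MEAN"),
          s = sum(r$mapq), n = nrow(r)
        ),
        tibble::tibble(key = kv_key("GROUP", params$sample, rg, "MAPQ",
                                    metric = "MEAN"),
                       s = r$mapq, n = 1) |>
          dplyr::group_by(.data$key) |>
          dplyr::summarise(s = sum(.data$s), n = sum(.data$n), .groups = "drop"),
        tibble::tibble(
          key = kv_key("FILE", params$sample, paste0("MAPQ", r$mapq),
                       metric = "COUNT"),
          s = 0, n = 1
        )
      )
    },
    combine = c(s = "sum", n = "sum"),
    reduce = function(combined, params) {
      is_mean <- endsWith(combined$key, "_MEAN")
      tibble::tibble(
        key = combined$key,
        value = ifelse(is_mean, combined$s / combined$n, combined$n)
      )
    }
  )
}

#' Mapping-ratio job
#'
#' Emits `FILE_<sample>_MAPPING_RATIO` = mapped reads / total reads; 0 when
#' reads exist but none map (the automatic-rejection signal for files that
#' contain only unmapped reads); no key at all for an empty file.
#'
#' @return A [qa_job()].
#' @export
mapping_ratio_job <- function() {
  qa_job(
    name = "MappingRatioTest",
    map = function(records, header, params) {
      if (!nrow(records)) {
        return(tibble::tibble(key = character(), mapped = double(),
                              total = double()))
      }
      tibble::tibble(
        key = kv_key("FILE", params$sample, "MAPPING", metric = "RATIO"),
        mapped = sum(!is_flag_set(records$flag, "unmapped")),
        total = nrow(records)
      )
    },
    combine = c(mapped = "sum", total = "sum"),
    reduce = function(combined, params) {
      tibble::tibble(key = combined$key, value = combined$mapped / combined$total)
    }
  )
}

#' Read-statistics job
#'
#' Per file and per read group: read count and read-length minimum, mean and
#' maximum (`FILE_<sample>_READCOUNT`, `FILE_<sample>_LENGTH_MIN`, ...;
#' `GROUP_<sample>_<rg>_READCOUNT`, ...). Read length is the SEQ length, or
#' the query-consuming CIGAR length when SEQ is unset.
#'
#' @return A [qa_job()].
#' @export
read_statistics_job <- function() {
  qa_job(
    name = "ReadStatistics",
    map = function(records, header, params) {
      if (!nrow(records)) {
        return(tibble::tibble(key = character(), n = double(),
                              len_sum = double(), len_min = double(),
                              len_max = double()))
      }
      len <- ifelse(!is.na(records$seq), nchar(records$seq),
                    suppressWarnings(query_span(records$cigar)))
      len[is.na(len)] <- 0
      rg <- tag_value(records, "RG")
      rg[is.na(rg)] <- "__no_rg__"
      scope <- c(rep(paste0("FILE_", kv_sanitize(params$sample)), length(len)),
                 paste0("GROUP_", kv_sanitize(params$sample), "_", kv_sanitize(rg)))
      tibble::tibble(key = scope, n = 1,
                     len_sum = c(len, len), len_min = c(len, len),
                     len_max = c(len, len)) |>
        dplyr::group_by(.data$key) |>
        dplyr::summarise(n = sum(.data$n), len_sum = sum(.data$len_sum),
                         len_min = min(.data$len_min),
                         len_max = max(.data$len_max), .groups = "drop")
    },
    combine = c(n = "sum", len_sum = "sum", len_min = "min", len_max = "max"),
    reduce = function(combined, params) {
      purrr::map_dfr(seq_len(nrow(combined)), function(i) {
        row <- combined[i, ]
        tibble::tibble(
          key = paste0(row$key, "_",
                       c("READCOUNT", "LENGTH_MIN", "LENGTH_MEAN", "LENGTH_MAX")),
          value = c(row$n, row$len_min, row$len_sum / row$n, row$len_max)
        )
      })
    }
  )
}

#' Anomalous-chromosome job
#'
#' Counts reads mapped to reference sequences whose names match the
#' anomalous-name pattern set (default: contains `random`, `chrUn`-prefixed
#' unplaced contigs, `hap`/`alt`-suffixed haplotype sequences), emitting
#' `CHROM_<sample>_<name>_ANOMALOUS_READCOUNT`, plus the overall fraction of
#' mapped reads on anomalous sequences (`FILE_<sample>_ANOMALOUS_FRACTION`).
#' An empty pattern set yields no output.
#'
#' @return A [qa_job()].
#' @export
chromosome_check_job <- function() {
  qa_job(
    name = "ChromosomeCheck",
    map = function(records, header, params) {
      pats <- params$anomalous_patterns
      empty <- tibble::tibble(key = character(), n = double())
      if (!length(pats)) return(empty)
      r <- .eligible_mapped(records, header, params)
      if (!nrow(r)) return(empty)
      anom <- Reduce(`|`, lapply(pats, function(p) grepl(p, r$rname)))
      out <- tibble::tibble(key = "\tmapped_total", n = nrow(r))
      if (any(anom)) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          key = kv_key("CHROM", params$sample, r$rname[anom], "ANOMALOUS",
                       metric = "READCOUNT"),
          n = 1
        ))
      }
      out
    },
    combine = c(n = "sum"),
    reduce = function(combined, params) {
      helper <- combined$key == "\tmapped_total"
      mapped_total <- sum(combined$n[helper])
      chrom <- tibble::tibble(key = combined$key[!helper],
                              value = combined$n[!helper])
      if (!mapped_total || !nrow(chrom)) return(chrom)
      dplyr::bind_rows(chrom, tibble::tibble(
        key = kv_key("FILE", params$sample, "ANOMALOUS", metric = "FRACTION"),
        value = sum(chrom$value) / mapped_total
      ))
    }
  )
}

#' Structural-variation score job
#'
#' Counts discordant mapped reads per bin — paired reads whose proper-pair
#' flag is clear, whose mate maps to a different chromosome, or whose
#' |TLEN| lies outside the configured insert bounds — emitting
#' `BIN_<sample>_<chrom>_<binIndex>_SV_COUNT`. Additionally emits the
#' discordant fraction per platform unit
#' (`PU_<sample>_<platform_unit>_SV_FRACTION`), the projected
#' structural-variation signal across sequencing batches.
#'
#' @return A [qa_job()].
#' @export
structural_variation_job <- function() {
  qa_job(
    name = "StructuralVariation",
    map = function(records, header, params) {
      r <- .eligible_mapped(records, header, params)
      r <- r[is_flag_set(r$flag, "paired"), , drop = FALSE]
      if (!nrow(r)) {
        return(tibble::tibble(key = character(), n = double(), disc = double()))
      }
      inter_chrom <- !is.na(r$rnext) & r$rnext != "=" & r$rnext != r$rname
      bad_insert <- abs(r$tlen) < params$insert_lo | abs(r$tlen) > params$insert_hi
      disc <- !is_flag_set(r$flag, "proper_pair") | inter_chrom | bad_insert
      bin <- (r$pos - 1) %/% params$bin_size
      out <- tibble::tibble(key = character(), n = double(), disc = double())
      if (any(disc)) {
        out <- tibble::tibble(
          key = paste0(.bin_key(params$sample, r$rname[disc], bin[disc], "SV",
                                params), "_COUNT"),
          n = 1, disc = 0
        )
      }
      rg <- tag_value(r, "RG")
      pu <- header$read_groups$platform_unit[match(rg, header$read_groups$id)]
      known <- !is.na(pu)
      if (any(known)) {
        pu_rows <- tibble::tibble(
          key = kv_key("PU", params$sample, pu[known], "SV", metric = "FRACTION"),
          n = 1, disc = as.double(disc[known])
        )
        out <- dplyr::bind_rows(out, pu_rows)
      }
      out
    },
    combine = c(n = "sum", disc = "sum"),
    reduce = function(combined, params) {
      is_pu <- startsWith(combined$key, "PU_")
      tibble::tibble(
        key = combined$key,
        value = ifelse(is_pu, combined$disc / combined$n, combined$n)
      )
    }
  )
}

# Registry of the shipped feature jobs, keyed by CLI test name.
feature_job_registry <- function() {
  list(
    coverage = coverage_job(),
    readfreq = read_frequency_job(),
    mapq = mapping_quality_job(),
    ratio = mapping_ratio_job(),
    readstats = read_statistics_job(),
    chromcheck = chromosome_check_job(),
    sv = structural_variation_job()
  )
}

#' Run one feature job over a file
#'
#' Convenience wrapper: fills parameter defaults and executes the job
#' through the partition engine.
#'
#' @param sam A [sam_file()] object.
#' @param job A [qa_job()] or the name of a shipped job (`"coverage"`,
#'   `"readfreq"`, `"mapq"`, `"ratio"`, `"readstats"`, `"chromcheck"`,
#'   `"sv"`).
#' @param ... Parameter overrides (`bin_size`, `sample`, `legacy_keys`,
#'   `insert_lo`, `insert_hi`, `anomalous_patterns`, `coverage_ops`,
#'   `include_secondary`, `include_duplicates`).
#' @param partition_size Records per partition.
#' @param workers Declared worker count.
#' @return KV tibble (`key`, `value`), sorted by key.
#' @export
qa_feature <- function(sam, job, ..., partition_size = 1e5, workers = 1L) {
  if (is.character(job)) {
    reg <- feature_job_registry()
    if (!job %in% names(reg)) {
      stop("unknown job name: ", job, call. = FALSE)
    }
    job <- reg[[job]]
  }
  params <- .feature_defaults(sam, list(...))
  run_partitioned(job, sam, params, partition_size = partition_size,
                  workers = workers)
}

#' @rdname qa_feature
#' @export
qa_coverage <- function(sam, ...) qa_feature(sam, "coverage", ...)

#' @rdname qa_feature
#' @export
qa_read_frequency <- function(sam, ...) qa_feature(sam, "readfreq", ...)

#' @rdname qa_feature
#' @export
qa_mapping_quality <- function(sam, ...) qa_feature(sam, "mapq", ...)

#' @rdname qa_feature
#' @export
qa_mapping_ratio <- function(sam, ...) qa_feature(sam, "ratio", ...)

#' @rdname qa_feature
#' @export
qa_read_statistics <- function(sam, ...) qa_feature(sam, "readstats", ...)

#' @rdname qa_feature
#' @export
qa_chromosome_check <- function(sam, ...) qa_feature(sam, "chromcheck", ...)

#' @rdname qa_feature
#' @export
qa_structural_variation <- function(sam, ...) qa_feature(sam, "sv", ...)

#' Whole-file read statistics
#'
#' The tabular companion to [read_statistics_job()]: totals, per-group
#' counts, read-length range and the MAPQ distribution over mapped reads.
#'
#' @param sam A [sam_file()] object.
#' @return A list with `total_reads`, `mapped_reads`, `reads_per_group`
#'   (tibble), `length_min`, `length_mean`, `length_max`, `mapq_mean`,
#'   `mapq_histogram` (tibble `mapq`, `n`).
#' @export
read_stats <- function(sam) {
  r <- sam$records
  len <- ifelse(!is.na(r$seq), nchar(r$seq),
                suppressWarnings(query_span(r$cigar)))
  len[is.na(len)] <- 0
  mapped <- !is_flag_set(r$flag, "unmapped")
  rg <- tag_value(r, "RG")
  rg[is.na(rg)] <- "__no_rg__"
  list(
    total_reads = nrow(r),
    mapped_reads = sum(mapped),
    reads_per_group = dplyr::count(tibble::tibble(read_group = rg),
                                   .data$read_group, name = "n"),
    length_min = if (nrow(r)) min(len) else NA_real_,
    length_mean = if (nrow(r)) mean(len) else NA_real_,
    length_max = if (nrow(r)) max(len) else NA_real_,
    mapq_mean = if (any(mapped)) mean(r$mapq[mapped]) else NA_real_,
    mapq_histogram = dplyr::count(tibble::tibble(mapq = r$mapq[mapped]),
                                  .data$mapq, name = "n")
  )
}
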