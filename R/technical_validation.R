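# Exact per-record messages that downstream consumers pattern on.
# These three strings are a compatibility contract and must not be edited.
MSG_CIGAR_ON_UNMAPPED <- "CIGAR should have zero elements for unmapped read"
MSG_MAPQ_ON_UNMAPPED <- "MAPQ should be 0 for unmapped read"
MSG_UNKNOWN_READ_GROUP <- "RG ID on SAMRecord not found in header"

#' The registered validation rule catalogue
#'
#' Three families: `header` (dictionary/read-group consistency), `syntax`
#' (field-level adherence to the SAM specification), `functional`
#' (relationships between fields), plus file-level pairing-census rules.
#' Rule ids are stable machine-parsable strings; messages may evolve but ids
#' may not.
#'
#' @return Tibble with columns `rule_id`, `severity`, `family`, `description`.
#' @export
rule_catalogue <- function() {
  tibble::tribble(
    ~rule_id, ~severity, ~family, ~description,
    "header.no_sequences", "ERROR", "header", "header has an empty sequence dictionary",
    "header.no_read_groups", "WARNING", "header", "header declares no read groups",
    "header.duplicate_sequence", "ERROR", "header", "duplicate sequence name in dictionary",
    "header.nonpositive_length", "ERROR", "header", "reference sequence with non-positive length",
    "header.duplicate_read_group", "ERROR", "header", "duplicate read group id",
    "syntax.invalid_qname", "ERROR", "syntax", "query name violates the SAM character/length rule",
    "syntax.flag_range", "ERROR", "syntax", "FLAG outside [0, 65535]",
    "syntax.pos_range", "ERROR", "syntax", "POS or PNEXT negative or beyond 2^31-1",
    "syntax.unknown_reference", "ERROR", "syntax", "mapped record references a sequence absent from the dictionary",
    "syntax.seq_qual_mismatch", "ERROR", "syntax", "SEQ and QUAL lengths differ",
    "syntax.zero_length_read", "ERROR", "syntax", "record carries a zero-length read",
    "syntax.invalid_cigar", "ERROR", "syntax", "CIGAR string is malformed",
    "functional.cigar_on_unmapped", "ERROR", "functional", MSG_CIGAR_ON_UNMAPPED,
    "functional.mapq_on_unmapped", "ERROR", "functional", MSG_MAPQ_ON_UNMAPPED,
    "functional.unknown_read_group", "ERROR", "functional", MSG_UNKNOWN_READ_GROUP,
    "functional.maps_beyond_reference", "ERROR", "functional", "alignment extends past the end of its reference sequence",
    "functional.adjacent_indel", "ERROR", "functional", "adjacent insertion/deletion in CIGAR",
    "functional.proper_pair_without_pairing", "ERROR", "functional", "proper-pair flag set on an unpaired record",
    "functional.invalid_nm", "ERROR", "functional", "NM tag present but not a non-negative integer",
    "file.all_unpaired", "WARNING", "file", "file was completely unpaired in sequencing",
    "file.contains_unpaired", "WARNING", "file", "file contains unpaired reads",
    "file.empty", "WARNING", "file", "file contains no records",
    "file.single_read_group", "WARNING", "file", "fewer than two read groups: correlation undefined"
  )
}

# Severity lookup for finding construction.
.rule_severity <- function(rule_id) {
  cat <- rule_catalogue()
  sev <- cat$severity[match(rule_id, cat$rule_id)]
  if (anyNA(sev)) stop("unregistered rule id: ",
                       paste(rule_id[is.na(sev)], collapse = ", "), call. = FALSE)
  sev
}

empty_findings <- function() {
  tibble::tibble(rule_id = character(), severity = character(),
                 message = character(), file_id = character(),
                 record_index = integer(), qname = character())
}

# Build a findings tibble for record-level hits; record_index is 0-based.
finding_rows <- function(rule_id, message, file_id, idx, qname) {
  if (!length(idx)) return(empty_findings())
  tibble::tibble(rule_id = rule_id, severity = .rule_severity(rule_id),
                 message = message, file_id = file_id,
                 record_index = as.integer(idx), qname = qname)
}

file_finding <- function(rule_id, message, file_id) {
  tibble::tibble(rule_id = rule_id, severity = .rule_severity(rule_id),
                 message = message, file_id = file_id,
                 record_index = NA_integer_, qname = NA_character_)
}

#' Header-consistency checks
#'
#' Reports an empty sequence dictionary, missing read groups, duplicate
#' sequence names, non-positive sequence lengths and duplicate read-group
#' ids. Findings are returned, never thrown: the tool's purpose is to report
#' errors, not to crash on them.
#'
#' @param header A [sam_header()].
#' @param file_id File identifier used in findings.
#' @return Findings tibble.
#' @export
check_header <- function(header, file_id = "sample") {
  out <- list()
  if (!nrow(header$sequences)) {
    out <- c(out, list(file_finding("header.no_sequences",
                                    "header has an empty sequence dictionary", file_id)))
  }
  if (!nrow(header$read_groups)) {
    out <- c(out, list(file_finding("header.no_read_groups",
                                    "header declares no read groups", file_id)))
  }
  dup_sq <- unique(header$sequences$name[duplicated(header$sequences$name)])
  for (nm in dup_sq) {
    out <- c(out, list(file_finding("header.duplicate_sequence",
                                    paste0("sequence '", nm, "' listed more than once"), file_id)))
  }
  bad_len <- header$sequences$name[!is.na(header$sequences$length) &
                                     header$sequences$length <= 0]
  for (nm in bad_len) {
    out <- c(out, list(file_finding("header.nonpositive_length",
                                    paste0("sequence '", nm, "' has non-positive length"), file_id)))
  }
  dup_rg <- unique(header$read_groups$id[duplicated(header$read_groups$id)])
  for (id in dup_rg) {
    out <- c(out, list(file_finding("header.duplicate_read_group",
                                    paste0("read group '", id, "' declared more than once"), file_id)))
  }
  dplyr::bind_rows(c(list(empty_findings()), out))
}

# SAM v1.3 QNAME: printable characters excluding '@', length 1-255.
.qname_ok <- function(qname) {
  nchar(qname) >= 1 & nchar(qname) <= 255 & grepl("^[!-?A-~]+$", qname)
}

#' Specification-adherence (syntax) checks per record
#'
#' Field-level checks: query-name character/length rule, FLAG and position
#' ranges, reference names present in the dictionary (mapped records only),
#' SEQ/QUAL length agreement, zero-length reads, malformed CIGAR strings.
#'
#' @param records Records tibble.
#' @param header A [sam_header()] providing the sequence dictionary.
#' @param file_id File identifier used in findings.
#' @return Findings tibble, in record order within each rule.
#' @export
check_syntax <- function(records, header, file_id = "sample") {
  if (!nrow(records)) return(empty_findings())
  r <- records
  i0 <- seq_len(nrow(r)) - 1L
  unmapped <- is_flag_set(r$flag, "unmapped")
  hit <- function(rule, cond, msg) {
    w <- which(cond)
    finding_rows(rule, msg, file_id, i0[w], r$qname[w])
  }
  max_pos <- 2^31 - 1
  seq_len_of <- ifelse(is.na(r$seq), 0L, nchar(r$seq))
  qual_len_of <- ifelse(is.na(r$qual), 0L, nchar(r$qual))
  read_len <- ifelse(!is.na(r$seq), nchar(r$seq),
                     suppressWarnings(query_span(r$cigar)))
  read_len[is.na(read_len)] <- 0L
  dplyr::bind_rows(
    hit("syntax.invalid_qname", !.qname_ok(r$qname),
        "query name violates the SAM character/length rule"),
    hit("syntax.flag_range", r$flag < 0 | r$flag > 65535,
        "FLAG outside [0, 65535]"),
    hit("syntax.pos_range",
        (!is.na(r$pos) & (r$pos < 0 | r$pos > max_pos)) |
          (!is.na(r$pnext) & (r$pnext < 0 | r$pnext > max_pos)),
        "mapping position outside [0, 2^31-1]"),
    hit("syntax.unknown_reference",
        !unmapped & !is.na(r$rname) & !(r$rname %in% header$sequences$name),
        "reference name not present in sequence dictionary"),
    hit("syntax.seq_qual_mismatch",
        !is.na(r$seq) & !is.na(r$qual) & seq_len_of != qual_len_of,
        "SEQ and QUAL lengths differ"),
    hit("syntax.zero_length_read", read_len == 0,
        "record carries a zero-length read"),
    hit("syntax.invalid_cigar", !cigar_is_valid(r$cigar),
        "CIGAR string is malformed")
  )
}

#' Functional-relationship checks per record
#'
#' Cross-field rules: unmapped records must carry no CIGAR and MAPQ 0; RG
#' tags must resolve in the header; alignments must not extend past their
#' reference; CIGARs must not contain adjacent indels; the proper-pair flag
#' requires the paired flag; NM, when present, must be a non-negative
#' integer. Unmapped records are exempt from position/reference checks.
#'
#' @inheritParams check_syntax
#' @return Findings tibble.
#' @export
check_functional <- function(records, header, file_id = "sample") {
  if (!nrow(records)) return(empty_findings())
  r <- records
  i0 <- seq_len(nrow(r)) - 1L
  unmapped <- is_flag_set(r$flag, "unmapped")
  hit <- function(rule, cond, msg) {
    w <- which(cond)
    finding_rows(rule, msg, file_id, i0[w], r$qname[w])
  }
  rg <- tag_value(r, "RG")
  nm <- tag_value(r, "NM")
  span <- suppressWarnings(reference_span(r$cigar))
  ref_len <- header$sequences$length[match(r$rname, header$sequences$name)]
  beyond <- !unmapped & !is.na(r$pos) & !is.na(span) & !is.na(ref_len) &
    (r$pos + span - 1 > ref_len)
  dplyr::bind_rows(
    hit("functional.cigar_on_unmapped", unmapped & !is.na(r$cigar),
        MSG_CIGAR_ON_UNMAPPED),
    hit("functional.mapq_on_unmapped", unmapped & r$mapq != 0,
        MSG_MAPQ_ON_UNMAPPED),
    hit("functional.unknown_read_group",
        !is.na(rg) & !(rg %in% header$read_groups$id),
        MSG_UNKNOWN_READ_GROUP),
    hit("functional.maps_beyond_reference", beyond,
        "alignment extends past the end of its reference sequence"),
    hit("functional.adjacent_indel", cigar_has_adjacent_indel(r$cigar),
        "adjacent insertion/deletion in CIGAR"),
    hit("functional.proper_pair_without_pairing",
        is_flag_set(r$flag, "proper_pair") & !is_flag_set(r$flag, "paired"),
        "proper-pair flag set on an unpaired record"),
    hit("functional.invalid_nm",
        !is.na(nm) & !grepl("^[0-9]+$", nm),
        "NM tag present but not a non-negative integer")
  )
}

# Pairing census: flag-based. All records unpaired -> one file-level rule;
# a mixture -> another. (Mate-record lookup is a second-pass design this
# tool deliberately avoids.)
check_pairing_census <- function(records, file_id = "sample") {
  if (!nrow(records)) return(empty_findings())
  frac_unpaired <- mean(!is_flag_set(records$flag, "paired"))
  if (frac_unpaired == 1) {
    file_finding("file.all_unpaired",
                 "file was completely unpaired in sequencing", file_id)
  } else if (frac_unpaired > 0) {
    file_finding("file.contains_unpaired",
                 sprintf("file contains unpaired reads (%.1f%% of records)",
                         100 * frac_unpaired), file_id)
  } else {
    empty_findings()
  }
}

#' Validate a complete alignment file
#'
#' Runs the header, syntax, functional and pairing-census checks and
#' aggregates per-rule counts. Finding order is deterministic: header
#' findings, then per-record findings grouped by rule in file order, then
#' file-level census findings.
#'
#' @param sam A [sam_file()] object.
#' @return A `sam_validation` object: list with `findings` (tibble),
#'   `counts` (tibble `rule_id`, `n`), `n_records`, `file_id`. Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] to extract.
#' @export
validate_sam <- function(sam) {
  findings <- dplyr::bind_rows(
    check_header(sam$header, sam$file_id),
    check_syntax(sam$records, sam$header, sam$file_id),
    check_functional(sam$records, sam$header, sam$file_id),
    check_pairing_census(sam$records, sam$file_id),
    if (!nrow(sam$records)) {
      file_finding("file.empty", "file contains no records", sam$file_id)
    }
  )
  counts <- findings |>
    dplyr::count(.data$rule_id, name = "n") |>
    dplyr::arrange(.data$rule_id)
  structure(list(findings = findings, counts = counts,
                 n_records = nrow(sam$records), file_id = sam$file_id),
            class = "sam_validation")
}

#' @export
print.sam_validation <- function(x, ...) {
  cat("<sam_validation> '", x$file_id, "': ", nrow(x$findings),
      " findings over ", x$n_records, " records\n", sep = "")
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' @rdname validate_sam
#' @param x A `sam_validation` object.
#' @param ... Unused.
#' @method tidy sam_validation
#' @export
tidy.sam_validation <- function(x, ...) x$findings

#' @rdname validate_sam
#' @method glance sam_validation
#' @export
glance.sam_validation <- function(x, ...) {
  tibble::tibble(
    file_id = x$file_id,
    n_records = x$n_records,
    n_findings = nrow(x$findings),
    n_errors = sum(x$findings$severity == "ERROR"),
    n_warnings = sum(x$findings$severity == "WARNING"),
    n_rules_hit = nrow(x$counts)
  )
}

#' Serialise findings to the tab-separated report format
#'
#' @param findings Findings tibble (from [validate_sam()] or [tidy()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_findings_tsv <- function(findings, path) {
  out <- findings
  out$record_index <- ifelse(is.na(out$record_index), ".",
                             as.character(out$record_index))
  out$qname <- ifelse(is.na(out$qname), ".", out$qname)
  lines <- c(
    paste(c("rule_id", "severity", "file", "record_index", "qname", "message"),
          collapse = "\t"),
    paste(out$rule_id, out$severity, out$file_id, out$record_index, out$qname,
          out$message, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Findings as key-value error counts
#'
#' Converts per-rule counts to the KV stream form
#' `ERROR_<sample>_<rule_id> -> count` (tokens sanitised per the key
#' grammar).
#'
#' @param validation A `sam_validation` object.
#' @return KV tibble (`key`, `value`).
#' @export
findings_kv <- function(validation) {
  if (!nrow(validation$counts)) {
    return(tibble::tibble(key = character(), value = double()))
  }
  tibble::tibble(
    key = kv_key("ERROR", validation$file_id, metric = validation$counts$rule_id),
    value = as.double(validation$counts$n)
  ) |> dplyr::arrange(.data$key)
}
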