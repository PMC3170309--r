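#' Construct a SAM header object
#'
#' @param sequences Tibble with columns `name`, `length` — the reference
#'   sequence dictionary (@SQ lines). Lengths must be positive.
#' @param read_groups Tibble with columns `id`, `sample`, `platform`,
#'   `platform_unit` (@RG lines). May have zero rows.
#' @param programs Tibble with columns `id`, `name`, `version` (@PG lines).
#' @param sort_order One of `"unknown"`, `"unsorted"`, `"queryname"`,
#'   `"coordinate"`.
#' @return A `sam_header` object.
#' @export
sam_header <- function(sequences = empty_sequences(),
                       read_groups = empty_read_groups(),
                       programs = empty_programs(),
                       sort_order = "unknown") {
  sort_order <- match.arg(sort_order, c("unknown", "unsorted", "queryname", "coordinate"))
  structure(
    list(
      sequences = tibble::as_tibble(sequences),
      read_groups = tibble::as_tibble(read_groups),
      programs = tibble::as_tibble(programs),
      sort_order = sort_order
    ),
    class = "sam_header"
  )
}

empty_sequences <- function() tibble::tibble(name = character(), length = integer())
empty_read_groups <- function() {
  tibble::tibble(id = character(), sample = character(),
                 platform = character(), platform_unit = character())
}
empty_programs <- function() {
  tibble::tibble(id = character(), name = character(), version = character())
}

#' @export
print.sam_header <- function(x, ...) {
  cat("<sam_header> ", nrow(x$sequences), " sequences, ",
      nrow(x$read_groups), " read groups, sort order ", x$sort_order, "\n", sep = "")
  invisible(x)
}

.header_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (!length(hit)) NA_character_ else sub(paste0("^", tag, ":"), "", hit[1])
}

#' Parse SAM header lines
#'
#' @param lines Character vector of lines beginning with `@`.
#' @return A [sam_header()] object.
#' @export
parse_sam_header <- function(lines) {
  lines <- lines[startsWith(lines, "@")]
  fields_of <- function(tag) {
    strsplit(sub("^@..\t?", "", grep(paste0("^@", tag, "\t"), lines, value = TRUE)), "\t")
  }
  sq <- fields_of("SQ")
  sequences <- tibble::tibble(
    name = vapply(sq, .header_tag, character(1), tag = "SN"),
    length = suppressWarnings(as.integer(vapply(sq, .header_tag, character(1), tag = "LN")))
  )
  rg <- fields_of("RG")
  read_groups <- tibble::tibble(
    id = vapply(rg, .header_tag, character(1), tag = "ID"),
    sample = vapply(rg, .header_tag, character(1), tag = "SM"),
    platform = vapply(rg, .header_tag, character(1), tag = "PL"),
    platform_unit = vapply(rg, .header_tag, character(1), tag = "PU")
  )
  pg <- fields_of("PG")
  programs <- tibble::tibble(
    id = vapply(pg, .header_tag, character(1), tag = "ID"),
    name = vapply(pg, .header_tag, character(1), tag = "PN"),
    version = vapply(pg, .header_tag, character(1), tag = "VN")
  )
  hd <- grep("^@HD\t", lines, value = TRUE)
  so <- "unknown"
  if (length(hd)) {
    so_tag <- .header_tag(strsplit(sub("^@HD\t", "", hd[1]), "\t")[[1]], "SO")
    if (!is.na(so_tag) && so_tag %in% c("unknown", "unsorted", "queryname", "coordinate")) {
      so <- so_tag
    }
  }
  sam_header(sequences, read_groups, programs, so)
}

#' Serialise a header to SAM text lines
#' @param header A [sam_header()] object.
#' @return Character vector of `@`-prefixed lines.
#' @export
format_sam_header <- function(header) {
  out <- paste0("@HD\tVN:1.3\tSO:", header$sort_order)
  if (nrow(header$sequences)) {
    out <- c(out, paste0("@SQ\tSN:", header$sequences$name,
                         "\tLN:", header$sequences$length))
  }
  if (nrow(header$read_groups)) {
    rg <- header$read_groups
    out <- c(out, paste0("@RG\tID:", rg$id, "\tSM:", rg$sample,
                         "\tPL:", rg$platform, "\tPU:", rg$platform_unit))
  }
  if (nrow(header$programs)) {
    pg <- header$programs
    out <- c(out, paste0("@PG\tID:", pg$id, "\tPN:", pg$name, "\tVN:", pg$version))
  }
  out
}

# The 11 mandatory SAM columns, in file order.
.sam_columns <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                  "rnext", "pnext", "tlen", "seq", "qual")

#' Parse SAM alignment lines into a records tibble
#'
#' Parsing is deliberately lenient: a syntactically decodable record that
#' violates the SAM specification is returned so the validators can report
#' it. Only structurally undecodable input (fewer than 11 fields, or a
#' non-numeric value in a numeric column) raises an error.
#'
#' Unset fields use `NA` internally: `"*"` rname/cigar/rnext/seq/qual and
#' position 0 are converted once here and restored at serialisation, so no
#' sentinel strings circulate inside the model.
#'
#' @param lines Character vector of tab-delimited alignment lines (no `@`
#'   header lines).
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `tags` (raw
#'   tab-joined optional fields, `""` when none).
#' @export
parse_sam_lines <- function(lines) {
  if (!length(lines)) return(empty_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("SAM record on line ", bad, " has ", nf[bad],
         " fields; 11 are required", call. = FALSE)
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(i, name, integer_ok = TRUE) {
    raw <- col(i)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop("field '", name, "' is not numeric on line ", bad,
           ": '", raw[bad], "'", call. = FALSE)
    }
    val
  }
  unset <- function(x) ifelse(x == "*", NA_character_, x)
  pos <- num(4, "pos")
  pnext <- num(8, "pnext")
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else ""
  }, character(1))
  tibble::tibble(
    qname = col(1),
    flag = as.integer(num(2, "flag")),
    rname = unset(col(3)),
    pos = ifelse(pos == 0, NA_real_, pos),
    mapq = num(5, "mapq"),
    cigar = unset(col(6)),
    rnext = unset(col(7)),
    pnext = ifelse(pnext == 0, NA_real_, pnext),
    tlen = num(9, "tlen"),
    seq = unset(col(10)),
    qual = unset(col(11)),
    tags = tags
  )
}

#' @rdname parse_sam_lines
#' @param line A single alignment line.
#' @export
parse_sam_line <- function(line) {
  stopifnot(length(line) == 1L)
  parse_sam_lines(line)
}

empty_records <- function() {
  tibble::tibble(
    qname = character(), flag = integer(), rname = character(),
    pos = double(), mapq = double(), cigar = character(),
    rnext = character(), pnext = double(), tlen = double(),
    seq = character(), qual = character(), tags = character()
  )
}

#' Serialise records to SAM alignment lines
#'
#' Inverse of [parse_sam_lines()]: `NA` fields become `"*"` (or 0 for
#' positions), so `parse_sam_lines(format_sam_lines(r))` is the identity on
#' any records tibble.
#'
#' @param records Records tibble.
#' @return Character vector of tab-delimited lines.
#' @export
format_sam_lines <- function(records) {
  star <- function(x) ifelse(is.na(x), "*", x)
  zero <- function(x) ifelse(is.na(x), "0", format(x, scientific = FALSE, trim = TRUE))
  fnum <- function(x) format(x, scientific = FALSE, trim = TRUE)
  base <- paste(
    records$qname, fnum(records$flag), star(records$rname), zero(records$pos),
    fnum(records$mapq), star(records$cigar), star(records$rnext),
    zero(records$pnext), fnum(records$tlen), star(records$seq),
    star(records$qual),
    sep = "\t"
  )
  ifelse(records$tags == "", base, paste(base, records$tags, sep = "\t"))
}

#' @rdname format_sam_lines
#' @export
format_sam_line <- function(records) {
  stopifnot(nrow(records) == 1L)
  format_sam_lines(records)
}

#' Extract an optional-field (tag) value from records
#'
#' @param records Records tibble.
#' @param tag Two-letter tag name, e.g. `"RG"` or `"NM"`.
#' @return Character vector of raw tag values (`NA` where the tag is absent).
#' @export
tag_value <- function(records, tag) {
  pat <- paste0("(?:^|\t)", tag, ":[AifZHB]:([^\t]*)")
  m <- regexpr(pat, records$tags, perl = TRUE)
  out <- rep(NA_character_, nrow(records))
  hit <- m != -1L
  out[hit] <- vapply(regmatches(records$tags, m), function(s) {
    sub(paste0("^\t?", tag, ":[AifZHB]:"), "", s)
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Bundle a header and records into a SAM file object
#'
#' @param header A [sam_header()].
#' @param records A records tibble (see [parse_sam_lines()]).
#' @param file_id Identifier used in findings and key-value output; defaults
#'   to `"sample"`.
#' @return A `sam_file` object (list with `header`, `records`, `file_id`).
#' @export
sam_file <- function(header, records, file_id = "sample") {
  structure(list(header = header, records = tibble::as_tibble(records),
                 file_id = file_id),
            class = "sam_file")
}

#' @export
print.sam_file <- function(x, ...) {
  cat("<sam_file> '", x$file_id, "': ", nrow(x$records), " records, ",
      nrow(x$header$sequences), " reference sequences\n", sep = "")
  invisible(x)
}

#' Read a SAM text file
#'
#' @param path Path to a SAM file.
#' @param file_id Sample identifier; defaults to the basename without
#'   extension.
#' @return A [sam_file()] object.
#' @export
read_sam <- function(path, file_id = NULL) {
  if (is.null(file_id)) file_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sam_file(parse_sam_header(lines[is_hdr]), parse_sam_lines(lines[!is_hdr]),
           file_id = file_id)
}

#' Write a SAM text file
#'
#' @param sam A [sam_file()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  writeLines(c(format_sam_header(sam$header), format_sam_lines(sam$records)),
             path)
  invisible(path)
}

#' Read a BAM file through Rsamtools
#'
#' Binary decoding is delegated to an established reader; the result honours
#' the same records contract as [read_sam()]. Only the RG and NM optional
#' fields are materialised (the ones the validators consult).
#'
#' @inheritParams read_sam
#' @return A [sam_file()] object.
#' @export
read_bam <- function(path, file_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package", call. = FALSE)
  }
  if (is.null(file_id)) file_id <- sub("\\.[^.]*$", "", basename(path))
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  targets <- hdr$targets
  sequences <- tibble::tibble(name = names(targets),
                              length = as.integer(unname(targets)))
  txt <- hdr$text
  hdr_lines <- vapply(seq_along(txt), function(i) {
    paste(c(names(txt)[i], txt[[i]]), collapse = "\t")
  }, character(1))
  header <- parse_sam_header(hdr_lines)
  if (!nrow(header$sequences)) header$sequences <- sequences
  p <- Rsamtools::ScanBamParam(what = Rsamtools::scanBamWhat(), tag = c("RG", "NM"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  na_chr <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | x == "" | x == "*", NA_character_, x)
  }
  rg <- b$tag$RG
  nm <- b$tag$NM
  n <- length(b$qname)
  tags <- rep("", n)
  if (!is.null(rg)) {
    has <- !is.na(rg)
    tags[has] <- paste0("RG:Z:", rg[has])
  }
  if (!is.null(nm)) {
    has <- !is.na(nm)
    tags[has] <- ifelse(tags[has] == "", paste0("NM:i:", nm[has]),
                        paste0(tags[has], "\tNM:i:", nm[has]))
  }
  records <- tibble::tibble(
    qname = b$qname,
    flag = as.integer(b$flag),
    rname = na_chr(b$rname),
    pos = ifelse(is.na(b$pos) | b$pos == 0, NA_real_, as.numeric(b$pos)),
    mapq = ifelse(is.na(b$mapq), 0, as.numeric(b$mapq)),
    cigar = na_chr(b$cigar),
    rnext = na_chr(b$mrnm),
    pnext = ifelse(is.na(b$mpos) | b$mpos == 0, NA_real_, as.numeric(b$mpos)),
    tlen = ifelse(is.na(b$isize), 0, as.numeric(b$isize)),
    seq = na_chr(b$seq),
    qual = na_chr(b$qual),
    tags = tags
  )
  sam_file(header, records, file_id = file_id)
}

#' Read an alignment file, dispatching on extension
#'
#' `.bam` goes through [read_bam()]; anything else is treated as SAM text.
#'
#' @inheritParams read_sam
#' @return A [sam_file()] object.
#' @export
read_alignments <- function(path, file_id = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    read_bam(path, file_id)
  } else {
    read_sam(path, file_id)
  }
}
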