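# Key grammar: CATEGORY "_" SAMPLE ("_" QUALIFIER)* "_" METRIC.
# Tokens are underscore-delimited, so underscores inside sample names,
# read-group ids or chromosome names are replaced by "-" at key-build time.
.kv_categories <- c("BIN", "FILE", "GROUP", "CHROM", "PU", "CORR", "ERROR")

#' Sanitise a token for use in a compound key
#'
#' The key grammar is underscore-delimited; underscores inside tokens are
#' replaced by `"-"`. Emit the original/sanitised mapping with
#' [kv_sanitize_map()] when it matters.
#'
#' @param x Character vector of raw tokens.
#' @return Sanitised tokens.
#' @export
kv_sanitize <- function(x) gsub("_", "-", x, fixed = TRUE)

#' Mapping comment lines for sanitised tokens
#' @param x Character vector of raw tokens.
#' @return Character vector of `#map` comment lines, one per changed token.
#' @export
kv_sanitize_map <- function(x) {
  changed <- unique(x[x != kv_sanitize(x)])
  if (!length(changed)) return(character(0))
  paste0("#map\t", changed, "\t", kv_sanitize(changed))
}

#' Build a compound key
#'
#' @param category One of `BIN`, `FILE`, `GROUP`, `CHROM`, `PU`, `CORR`,
#'   `ERROR`.
#' @param sample Sample identifier token.
#' @param ... Qualifier vectors (possibly none), recycled against each other
#'   and `metric` in the usual way.
#' @param metric Final token(s).
#' @return Character vector of keys.
#' @export
kv_key <- function(category, sample, ..., metric) {
  stopifnot(category %in% .kv_categories)
  quals <- lapply(list(...), function(q) kv_sanitize(as.character(q)))
  do.call(paste, c(list(category, kv_sanitize(sample)), quals,
                   list(kv_sanitize(as.character(metric))), sep = "_"))
}

#' Format a KV value the way the stream prints it
#'
#' Integer-valued numbers print without a decimal point; fractional values
#' are rounded to 7 decimal places with trailing zeros stripped (the
#' stream's canonical precision); undefined values print as `"NA"`.
#'
#' @param value Numeric vector (may contain `NA`).
#' @return Character vector.
#' @export
format_kv_value <- function(value) {
  out <- character(length(value))
  na <- is.na(value)
  out[na] <- "NA"
  whole <- !na & value == round(value) & abs(value) < 2^53
  out[whole] <- format(value[whole], scientific = FALSE, trim = TRUE)
  frac <- !na & !whole
  if (any(frac)) {
    s <- sprintf("%.7f", value[frac])
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
    out[frac] <- s
  }
  out
}

#' Serialise KV pairs to text lines
#'
#' One pair per line, key and value separated by a tab.
#'
#' @param kv Tibble with columns `key`, `value`.
#' @return Character vector of lines.
#' @export
format_kv <- function(kv) {
  paste0(kv$key, "\t", format_kv_value(kv$value))
}

#' Write a KV stream to file
#'
#' Output is sorted by key (C collation) and byte-identical across repeated
#' runs on identical input. Provenance goes into `#`-prefixed comment lines,
#' which the parser ignores. Duplicate keys are refused: every key in one
#' run's output must be unique.
#'
#' @param kv Tibble with columns `key`, `value`.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (leading `#`
#'   added if missing).
#' @return `path`, invisibly.
#' @export
write_kv <- function(kv, path, comments = character(0)) {
  if (anyDuplicated(kv$key)) {
    stop("duplicate key in KV output: ",
         kv$key[duplicated(kv$key)][1], call. = FALSE)
  }
  kv <- dplyr::arrange(kv, .data$key)
  if (length(comments)) {
    comments <- ifelse(startsWith(comments, "#"), comments, paste0("#", comments))
  }
  writeLines(c(comments, format_kv(kv)), path)
  invisible(path)
}

#' Parse a KV stream
#'
#' Inverse of [format_kv()]/[write_kv()]. Comment lines beginning `#` are
#' ignored. Malformed lines (no tab, empty key), unknown categories and
#' duplicate keys raise parse errors naming the line or key.
#'
#' @param lines Character vector of lines, or a file path of length 1 that
#'   exists on disk.
#' @return Tibble with columns `key`, `value` (`NA` for literal `"NA"`).
#' @export
parse_kv <- function(lines) {
  if (length(lines) == 1 && !grepl("\t", lines) && file.exists(lines)) {
    lines <- readLines(lines)
  }
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(tibble::tibble(key = character(), value = double()))
  has_tab <- grepl("\t", lines, fixed = TRUE)
  if (any(!has_tab)) {
    stop("malformed KV line ", lineno[!has_tab][1], ": no tab separator",
         call. = FALSE)
  }
  key <- sub("\t.*$", "", lines)
  val_str <- sub("^[^\t]*\t", "", lines)
  if (any(!nzchar(key))) {
    stop("malformed KV line ", lineno[!nzchar(key)][1], ": empty key",
         call. = FALSE)
  }
  category <- sub("_.*$", "", key)
  bad_cat <- !(category %in% .kv_categories)
  if (any(bad_cat)) {
    stop("unknown key category '", category[bad_cat][1], "' on line ",
         lineno[bad_cat][1], call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicate key in KV stream: ", key[duplicated(key)][1], call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(val_str))
  bad_val <- is.na(value) & val_str != "NA"
  if (any(bad_val)) {
    stop("malformed KV value on line ", lineno[bad_val][1], ": '",
         val_str[bad_val][1], "'", call. = FALSE)
  }
  tibble::tibble(key = key, value = value)
}

#' Split a compound key into its tokens
#'
#' @param key Character vector of keys.
#' @return Tibble with columns `category`, `sample`, `qualifiers`
#'   (list-column), `metric`.
#' @export
parse_kv_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  tibble::tibble(
    category = vapply(parts, `[[`, character(1), 1),
    sample = vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_,
                    character(1)),
    qualifiers = lapply(parts, function(p) {
      if (length(p) > 3) p[3:(length(p) - 1)] else character(0)
    }),
    metric = vapply(parts, function(p) p[[length(p)]], character(1))
  )
}
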