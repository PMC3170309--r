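#' CIGAR operation consumption table
#'
#' The nine CIGAR operation codes with their consumption semantics: whether
#' each operation advances the reference cursor and/or the query (read)
#' cursor. M, =, and X consume both; I and S consume the query only; D and N
#' consume the reference only; H and P consume neither.
#'
#' @format A tibble with columns `op`, `consumes_reference`, `consumes_query`.
#' @export
cigar_op_table <- function() {
  tibble::tibble(
    op = c("M", "I", "D", "N", "S", "H", "P", "=", "X"),
    consumes_reference = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    consumes_query = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
}

# C-level lookup vectors; names are op codes
.cigar_ref_ops <- c(M = TRUE, I = FALSE, D = TRUE, N = TRUE, S = FALSE,
                    H = FALSE, P = FALSE, `=` = TRUE, X = TRUE)
.cigar_query_ops <- c(M = TRUE, I = TRUE, D = FALSE, N = FALSE, S = TRUE,
                      H = FALSE, P = FALSE, `=` = TRUE, X = TRUE)

.cigar_regex <- "^([0-9]+[MIDNSHP=X])+$"

#' Test whether a CIGAR string is syntactically valid
#'
#' @param cigar Character vector of CIGAR strings; `NA` (the unset "*" form)
#'   counts as valid.
#' @return Logical vector.
#' @export
cigar_is_valid <- function(cigar) {
  is.na(cigar) | grepl(.cigar_regex, cigar)
}

#' Decompose a CIGAR string into its operations
#'
#' @param cigar A single CIGAR string, or `NA` for the unset form.
#' @return A tibble with columns `length` (integer) and `op` (character);
#'   zero rows for `NA` input.
#' @examples
#' cigar_ops("50M10I40M")
#' @export
cigar_ops <- function(cigar) {
  stopifnot(length(cigar) == 1L)
  if (is.na(cigar)) {
    return(tibble::tibble(length = integer(), op = character()))
  }
  if (!grepl(.cigar_regex, cigar)) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  tibble::tibble(length = lens, op = ops)
}

#' Number of reference bases spanned by an alignment
#'
#' Sum of lengths of reference-consuming operations (M, D, N, =, X). An
#' unmapped record (`NA` CIGAR) spans zero bases.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of spans; malformed strings yield `NA` with a
#'   warning (the syntax validator reports them separately).
#' @export
reference_span <- function(cigar) {
  .op_span(cigar, .cigar_ref_ops)
}

#' Number of query (read) bases accounted for by an alignment
#'
#' Sum of lengths of query-consuming operations (M, I, S, =, X). Used as the
#' read length when SEQ is unset.
#'
#' @inheritParams reference_span
#' @return Integer vector.
#' @export
query_span <- function(cigar) {
  .op_span(cigar, .cigar_query_ops)
}

.op_span <- function(cigar, consumes) {
  out <- integer(length(cigar))
  out[is.na(cigar)] <- 0L
  todo <- which(!is.na(cigar))
  if (!length(todo)) return(out)
  ok <- grepl(.cigar_regex, cigar[todo])
  if (any(!ok)) {
    warning("malformed CIGAR string(s) treated as span NA", call. = FALSE)
    out[todo[!ok]] <- NA_integer_
    todo <- todo[ok]
  }
  lens <- regmatches(cigar[todo], gregexpr("[0-9]+", cigar[todo]))
  ops <- regmatches(cigar[todo], gregexpr("[MIDNSHP=X]", cigar[todo]))
  out[todo] <- vapply(seq_along(todo), function(i) {
    sum(as.integer(lens[[i]])[consumes[ops[[i]]]])
  }, integer(1))
  out
}

#' Does a CIGAR contain adjacent insertion/deletion operations?
#'
#' Adjacent I/D (either order) in a CIGAR is a canonical aligner artefact:
#' the two should have been merged or realigned.
#'
#' @inheritParams reference_span
#' @return Logical vector; `FALSE` for `NA` or malformed strings.
#' @export
cigar_has_adjacent_indel <- function(cigar) {
  !is.na(cigar) & (grepl("[0-9]+I[0-9]+D", cigar) | grepl("[0-9]+D[0-9]+I", cigar))
}

#' Reference intervals covered by an alignment
#'
#' Walks the CIGAR operations advancing a reference cursor from `pos`,
#' returning the 1-based inclusive intervals covered by the operations in
#' `count_ops`. With the default set (all reference-consuming ops) this is
#' the single interval `[pos, pos + reference_span - 1]`; restricting to
#' aligned ops (M, =, X) splits the footprint at deletions and skips.
#'
#' @param cigar A single CIGAR string.
#' @param pos 1-based leftmost mapping position.
#' @param count_ops Ops counted as covering; default `c("M","D","N","=","X")`.
#' @return Tibble with columns `start`, `end` (1-based, inclusive).
#' @export
cigar_ref_intervals <- function(cigar, pos, count_ops = c("M", "D", "N", "=", "X")) {
  ops <- cigar_ops(cigar)
  cur <- pos
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$length[i]
    if (.cigar_ref_ops[[op]]) {
      if (op %in% count_ops) {
        starts <- c(starts, cur)
        ends <- c(ends, cur + len - 1L)
      }
      cur <- cur + len
    }
  }
  # merge adjacent intervals so output is canonical
  if (length(starts) > 1L) {
    keep_start <- c(TRUE, starts[-1] != ends[-length(ends)] + 1L)
    grp <- cumsum(keep_start)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends))
}
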