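# SAM FLAG bit definitions (v1.3): name -> bit value
.sam_flag_bits <- c(
  paired = 0x1, proper_pair = 0x2, unmapped = 0x4, mate_unmapped = 0x8,
  reverse = 0x10, mate_reverse = 0x20, first_in_pair = 0x40,
  second_in_pair = 0x80, secondary = 0x100, qc_fail = 0x200, duplicate = 0x400
)

#' Query a SAM FLAG bit by name
#'
#' @param flag Integer vector of FLAG values (or a records tibble, in which
#'   case its `flag` column is used).
#' @param bit One of `"paired"`, `"proper_pair"`, `"unmapped"`,
#'   `"mate_unmapped"`, `"reverse"`, `"mate_reverse"`, `"first_in_pair"`,
#'   `"second_in_pair"`, `"secondary"`, `"qc_fail"`, `"duplicate"`.
#' @return Logical vector, the value of that bit per record.
#' @examples
#' is_flag_set(4L, "unmapped")
#' is_flag_set(c(99L, 147L), "proper_pair")
#' @export
is_flag_set <- function(flag, bit) {
  if (is.data.frame(flag)) flag <- flag$flag
  if (!bit %in% names(.sam_flag_bits)) {
    stop("unknown flag name: ", bit, call. = FALSE)
  }
  bitwAnd(as.integer(flag), .sam_flag_bits[[bit]]) != 0L
}

#' Names of the addressable SAM FLAG bits
#' @return Character vector of flag names accepted by [is_flag_set()].
#' @export
sam_flag_names <- function() names(.sam_flag_bits)
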