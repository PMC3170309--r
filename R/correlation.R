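#' Pearson product-moment correlation coefficient
#'
#' Direct evaluation of the product-moment formula. Undefined — returned as
#' `NA` — when fewer than two observations are supplied or either vector
#' has zero variance (an `NA` is deliberately never collapsed to 0, which
#' would masquerade as a meaningful result).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single number in `[-1, 1]`, or `NA`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) return(NA_real_)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Per-read-group megabase bin vectors
#'
#' Builds one vector per read group: either binned coverage (aligned
#' reference-consuming bases per megabase bin / bin size, exactly as the
#' coverage job computes at that bin size) or the mean MAPQ of mapped reads
#' starting in each bin. Records without an RG tag pool into the synthetic
#' group `__no_rg__`.
#'
#' @param sam A [sam_file()] object.
#' @param metric `"coverage"` or `"mapq"`.
#' @param mb_bin_size Bin size in bases (default 1e6, megabase regions).
#' @return Tibble with columns `read_group`, `chrom`, `bin`, `value`.
#' @export
build_group_vectors <- function(sam, metric = c("coverage", "mapq"),
                                mb_bin_size = 1e6) {
  metric <- match.arg(metric)
  params <- .feature_defaults(sam, list(bin_size = mb_bin_size))
  r <- .eligible_mapped(sam$records, sam$header, params)
  if (!nrow(r)) {
    return(tibble::tibble(read_group = character(), chrom = character(),
                          bin = integer(), value = double()))
  }
  rg <- tag_value(r, "RG")
  rg[is.na(rg)] <- "__no_rg__"
  if (metric == "coverage") {
    span <- reference_span(r$cigar)
    keep <- span > 0
    iv <- tibble::tibble(read_group = rg[keep], chrom = r$rname[keep],
                         start = r$pos[keep],
                         end = r$pos[keep] + span[keep] - 1)
    bs <- mb_bin_size
    first_bin <- (iv$start - 1) %/% bs
    last_bin <- (iv$end - 1) %/% bs
    nb <- as.integer(last_bin - first_bin + 1)
    idx <- rep.int(seq_len(nrow(iv)), nb)
    bin <- first_bin[idx] + sequence(nb) - 1
    lo <- pmax(iv$start[idx], bin * bs + 1)
    hi <- pmin(iv$end[idx], (bin + 1) * bs)
    tibble::tibble(read_group = iv$read_group[idx], chrom = iv$chrom[idx],
                   bin = as.integer(bin), bases = hi - lo + 1) |>
      dplyr::group_by(.data$read_group, .data$chrom, .data$bin) |>
      dplyr::summarise(value = sum(.data$bases) / bs, .groups = "drop")
  } else {
    tibble::tibble(read_group = rg, chrom = r$rname,
                   bin = as.integer((r$pos - 1) %/% mb_bin_size),
                   mapq = r$mapq) |>
      dplyr::group_by(.data$read_group, .data$chrom, .data$bin) |>
      dplyr::summarise(value = mean(.data$mapq), .groups = "drop")
  }
}

#' Pairwise read-group correlation over megabase bins
#'
#' For every unordered pair of read groups, aligns the two bin vectors on
#' the union of (chromosome, bin) keys where either group has reads —
#' filling 0 for the absent group, so coverage dropout in one group is
#' visible rather than silently intersected away — and computes the Pearson
#' coefficient genome-wide across all pooled bins.
#'
#' @param vectors Output of [build_group_vectors()].
#' @param sample Sample identifier for KV keys.
#' @param metric Token used in the emitted key (`"COVERAGE"` or `"MAPQ"`).
#' @return A `qa_correlation` object: list with `results` (tibble `group_a`,
#'   `group_b`, `metric`, `r`, `n_bins`), `kv` (tibble), and `findings`
#'   (file-level WARNING when fewer than two groups are present).
#' @export
pairwise_group_correlation <- function(vectors, sample = "sample",
                                       metric = "COVERAGE") {
  groups <- sort(unique(vectors$read_group))
  empty <- tibble::tibble(group_a = character(), group_b = character(),
                          metric = character(), r = double(),
                          n_bins = integer())
  if (length(groups) < 2) {
    out <- list(
      results = empty,
      kv = tibble::tibble(key = character(), value = double()),
      findings = file_finding("file.single_read_group",
                              "fewer than two read groups: correlation undefined",
                              sample)
    )
    class(out) <- "qa_correlation"
    return(out)
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  results <- purrr::map_dfr(pairs, function(p) {
    wide <- vectors |>
      dplyr::filter(.data$read_group %in% p) |>
      tidyr::pivot_wider(names_from = "read_group", values_from = "value",
                        values_fill = 0) |>
      dplyr::arrange(.data$chrom, .data$bin)
    # a group with no bins at all contributes no column; skip the pair
    if (!all(p %in% names(wide))) {
      return(tibble::tibble(group_a = p[1], group_b = p[2], metric = metric,
                            r = NA_real_, n_bins = 0L))
    }
    tibble::tibble(group_a = p[1], group_b = p[2], metric = metric,
                   r = pearson_r(wide[[p[1]]], wide[[p[2]]]),
                   n_bins = nrow(wide))
  })
  kv <- tibble::tibble(
    key = kv_key("CORR", sample, results$group_a, results$group_b,
                 metric = metric),
    value = results$r
  ) |> dplyr::arrange(.data$key)
  structure(list(results = results, kv = kv, findings = empty_findings()),
            class = "qa_correlation")
}

#' Read-group correlation tests for a file
#'
#' Convenience wrapper combining [build_group_vectors()] and
#' [pairwise_group_correlation()] for one or both metrics.
#'
#' @param sam A [sam_file()] object.
#' @param metric `"coverage"`, `"mapq"` or `"both"`.
#' @param mb_bin_size Megabase bin size in bases.
#' @return A `qa_correlation` object (results/kv/findings concatenated over
#'   metrics).
#' @export
qa_correlation <- function(sam, metric = c("both", "coverage", "mapq"),
                           mb_bin_size = 1e6) {
  metric <- match.arg(metric)
  wanted <- if (metric == "both") c("coverage", "mapq") else metric
  parts <- lapply(wanted, function(m) {
    vec <- build_group_vectors(sam, m, mb_bin_size)
    pairwise_group_correlation(vec, sample = sam$file_id,
                               metric = toupper(ifelse(m == "coverage",
                                                       "COVERAGE", "MAPQ")))
  })
  out <- list(
    results = dplyr::bind_rows(lapply(parts, `[[`, "results")),
    kv = dplyr::bind_rows(lapply(parts, `[[`, "kv")) |>
      dplyr::distinct(.data$key, .keep_all = TRUE) |>
      dplyr::arrange(.data$key),
    findings = dplyr::bind_rows(lapply(parts, `[[`, "findings")) |>
      dplyr::distinct()
  )
  class(out) <- "qa_correlation"
  out
}

#' @export
print.qa_correlation <- function(x, ...) {
  cat("<qa_correlation> ", nrow(x$results), " group pair(s)\n", sep = "")
  if (nrow(x$results)) print(x$results)
  invisible(x)
}

#' @rdname pairwise_group_correlation
#' @param x A `qa_correlation` object.
#' @param ... Unused.
#' @method tidy qa_correlation
#' @export
tidy.qa_correlation <- function(x, ...) x$results

#' @rdname pairwise_group_correlation
#' @method glance qa_correlation
#' @export
glance.qa_correlation <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$results),
    n_defined = sum(!is.na(x$results$r)),
    min_r = suppressWarnings(min(x$results$r, na.rm = TRUE)),
    max_r = suppressWarnings(max(x$results$r, na.rm = TRUE))
  )
}
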