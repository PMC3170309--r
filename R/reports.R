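#' Count modes of a kernel density estimate
#'
#' Estimates the density of `x` with a Gaussian kernel at the documented
#' default bandwidth (Silverman's rule-of-thumb, `stats::bw.nrd0`) and
#' counts local maxima whose height is at least `min_height_frac` of the
#' tallest peak — the guard that keeps estimation wiggles from being counted
#' as modes. Used to flag multi-modal per-file metric distributions (the
#' platform batch-effect signature).
#'
#' @param x Numeric vector (at least 3 finite values).
#' @param bw Kernel bandwidth; default `stats::bw.nrd0(x)`.
#' @param min_height_frac Minimum peak height as a fraction of the maximum.
#' @return Integer number of modes.
#' @export
count_density_modes <- function(x, bw = stats::bw.nrd0(x),
                                min_height_frac = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) return(NA_integer_)
  d <- stats::density(x, bw = bw, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] >= min_height_frac * max(y))
}

# The per-file summary metrics extracted from a KV stream.
.summary_metrics <- c(
  mapq_mean = "FILE_*_MAPQ_MEAN",
  mean_bin_coverage = "FILE_*_MEAN_BIN_COVERAGE",
  genome_coverage = "FILE_*_GENOME_COVERAGE",
  mapping_ratio = "FILE_*_MAPPING_RATIO"
)

#' Summarise KV output across files
#'
#' Parses each KV file, extracts the per-file summary metrics (mean MAPQ,
#' mean bin coverage, genome coverage, mapping ratio) and tabulates them
#' across the batch, including a detected-mode count per metric.
#'
#' @param kv_files Character vector of KV file paths (at least one).
#' @return A `kv_summary` object: list with `per_file` (tibble `file`,
#'   `metric`, `value`) and `table` (tibble `metric`, `n_files`, `min`,
#'   `median`, `max`, `n_modes`).
#' @export
summarize_kv <- function(kv_files) {
  if (!length(kv_files)) stop("no KV files supplied", call. = FALSE)
  per_file <- purrr::map_dfr(kv_files, function(path) {
    kv <- parse_kv(path)
    purrr::map_dfr(names(.summary_metrics), function(m) {
      hit <- kv[.glob_match(.summary_metrics[[m]], kv$key), , drop = FALSE]
      if (!nrow(hit)) return(NULL)
      tibble::tibble(file = sub("\\.[^.]*$", "", basename(path)),
                     metric = m, value = hit$value[1])
    })
  })
  table <- per_file |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      n_files = dplyr::n(),
      min = min(.data$value, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      max = max(.data$value, na.rm = TRUE),
      n_modes = count_density_modes(.data$value),
      .groups = "drop"
    )
  structure(list(per_file = per_file, table = table), class = "kv_summary")
}

#' @export
print.kv_summary <- function(x, ...) {
  cat("<kv_summary> ", length(unique(x$per_file$file)), " file(s)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @rdname summarize_kv
#' @param x A `kv_summary` object.
#' @param ... Unused.
#' @method tidy kv_summary
#' @export
tidy.kv_summary <- function(x, ...) x$per_file

#' @rdname summarize_kv
#' @method glance kv_summary
#' @export
glance.kv_summary <- function(x, ...) x$table

#' Density plot of a per-file metric across a batch
#'
#' @param summary A `kv_summary` object.
#' @param metric One of `"mapq_mean"`, `"mean_bin_coverage"`,
#'   `"genome_coverage"`, `"mapping_ratio"`.
#' @return A ggplot object.
#' @export
plot_metric_density <- function(summary, metric = "mapq_mean") {
  stopifnot(metric %in% names(.summary_metrics))
  dat <- dplyr::filter(summary$per_file, .data$metric == !!metric)
  if (nrow(dat) < 2) {
    stop("need at least two files to draw a density", call. = FALSE)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_rug() +
    ggplot2::labs(x = metric, y = "density",
                  title = paste0("Per-file ", metric, " (n = ", nrow(dat), ")")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metric_density
#' @param object A `kv_summary` object.
#' @param ... Passed to [plot_metric_density()].
#' @method autoplot kv_summary
#' @export
autoplot.kv_summary <- function(object, ...) {
  plot_metric_density(object, ...)
}

#' Bar chart of findings per rule
#'
#' @param object A `sam_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sam_validation
#' @export
autoplot.sam_validation <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = stats::reorder(.data$rule_id, .data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "findings",
                  title = paste0("Findings: ", object$file_id)) +
    ggplot2::theme_minimal()
}

#' Verdict status counts for a batch
#'
#' @param object A `batch_verdicts` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot batch_verdicts
#' @export
autoplot.batch_verdicts <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$status, y = .data$n,
                               fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(PASS = "seagreen", WARN = "orange",
                                          FAIL = "firebrick"), guide = "none") +
    ggplot2::labs(x = NULL, y = "files") +
    ggplot2::theme_minimal()
}
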