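#' Define a map/combine/reduce QA job
#'
#' A job maps a block of alignment records to a tibble of keyed accumulator
#' columns, combines accumulators per key with per-column associative and
#' commutative operations, and reduces combined accumulators to final
#' key-value pairs. Because every shipped combine operation is an integer
#' sum, min or max, combining per partition and then across partitions gives
#' *exactly* (not approximately) the same result as one global combine —
#' which is what makes output independent of partitioning and of whether
#' the combiner runs at all.
#'
#' @param name Job name, e.g. `"OutputCoverage"`.
#' @param map Function `(records, header, params) -> tibble` with a `key`
#'   column plus numeric accumulator columns.
#' @param combine Named character vector giving the combine operation per
#'   accumulator column: `"sum"`, `"min"` or `"max"`.
#' @param reduce Function `(combined, params) -> tibble(key, value)`.
#' @return A `qa_job` object.
#' @export
qa_job <- function(name, map, combine, reduce) {
  stopifnot(is.character(name), is.function(map), is.function(reduce),
            all(combine %in% c("sum", "min", "max")))
  structure(list(name = name, map = map, combine = combine, reduce = reduce),
            class = "qa_job")
}

#' @export
print.qa_job <- function(x, ...) {
  cat("<qa_job> ", x$name, " (accumulators: ",
      paste(names(x$combine), x$combine, sep = "=", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

# Combine accumulator rows by key with the job's per-column operations.
combine_by_key <- function(tbl, combine) {
  if (!nrow(tbl)) return(tbl)
  fns <- lapply(names(combine), function(col) {
    op <- combine[[col]]
    switch(op, sum = sum, min = min, max = max)
  })
  names(fns) <- names(combine)
  tbl |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(names(combine)),
                                   ~ fns[[dplyr::cur_column()]](.x)),
                     .groups = "drop")
}

#' Run a QA job serially (reference semantics)
#'
#' Maps every record, groups by key, reduces each group, and sorts output by
#' key (C collation). This is the semantics every partitioned run must
#' reproduce exactly.
#'
#' @param job A [qa_job()].
#' @param sam A [sam_file()] object.
#' @param params Named list of job parameters (bin sizes, sample name, ...).
#' @return Tibble with columns `key`, `value`, sorted by `key`.
#' @export
run_serial <- function(job, sam, params = list()) {
  mapped <- job$map(sam$records, sam$header, params)
  out <- job$reduce(combine_by_key(mapped, job$combine), params)
  dplyr::arrange(out, .data$key)
}

#' Run a QA job over partitions
#'
#' Splits the records into contiguous blocks, maps each block (applying the
#' per-partition combiner unless `use_combiner = FALSE`), merges, combines
#' globally, and reduces. Output is exactly equal to [run_serial()] for
#' every partitioning and worker count — the engine's central contract.
#'
#' `workers` is accepted for interface compatibility with multi-worker
#' deployments; the contract makes the result worker-count-agnostic, and
#' this in-process engine executes partitions sequentially.
#'
#' @inheritParams run_serial
#' @param n_partitions Number of contiguous partitions; overrides
#'   `partition_size`.
#' @param partition_size Records per partition (default 1e5).
#' @param workers Declared worker count (>= 1); does not affect results.
#' @param use_combiner Apply the per-partition combiner (default `TRUE`).
#' @return Tibble with columns `key`, `value`, sorted by `key`.
#' @export
run_partitioned <- function(job, sam, params = list(), n_partitions = NULL,
                            partition_size = 1e5, workers = 1L,
                            use_combiner = TRUE) {
  stopifnot(workers >= 1L)
  n <- nrow(sam$records)
  if (is.null(n_partitions)) {
    n_partitions <- max(1L, ceiling(n / partition_size))
  }
  idx <- partition_indices(n, n_partitions)
  pieces <- lapply(idx, function(i) {
    mapped <- job$map(sam$records[i, , drop = FALSE], sam$header, params)
    if (use_combiner) combine_by_key(mapped, job$combine) else mapped
  })
  merged <- dplyr::bind_rows(pieces)
  if (!nrow(merged)) {
    merged <- job$map(sam$records[0, , drop = FALSE], sam$header, params)
  }
  out <- job$reduce(combine_by_key(merged, job$combine), params)
  dplyr::arrange(out, .data$key)
}

# Contiguous, disjoint, covering row-index blocks.
partition_indices <- function(n, n_partitions) {
  if (n == 0L) return(list(integer(0)))
  n_partitions <- min(n_partitions, n)
  bounds <- floor(seq(0, n, length.out = n_partitions + 1))
  lapply(seq_len(n_partitions), function(k) seq.int(bounds[k] + 1L, bounds[k + 1L]))
}

#' Check a job's combiner contract on random key groups
#'
#' Property check used in tests and available to job authors: draws random
#' accumulator tables and verifies that combining a random two-block split,
#' in either order, equals one global combine (associativity and
#' commutativity over values sharing a key).
#'
#' @param combine Named combine-op vector as in [qa_job()].
#' @param n_trials Number of random trials.
#' @param seed RNG seed.
#' @return `TRUE` invisibly if the contract holds; otherwise stops with the
#'   first violating case.
#' @export
check_combiner_contract <- function(combine, n_trials = 50, seed = 1L) {
  withr::with_seed(seed, {
    for (t in seq_len(n_trials)) {
      n <- sample(2:40, 1)
      tbl <- tibble::tibble(key = sample(letters[1:4], n, replace = TRUE))
      for (col in names(combine)) tbl[[col]] <- sample.int(1000L, n, replace = TRUE)
      whole <- dplyr::arrange(combine_by_key(tbl, combine), .data$key)
      cut <- sample.int(n - 1L, 1)
      shuffled <- tbl[sample.int(n), , drop = FALSE]
      parts <- dplyr::bind_rows(
        combine_by_key(shuffled[seq_len(cut), , drop = FALSE], combine),
        combine_by_key(shuffled[-seq_len(cut), , drop = FALSE], combine)
      )
      again <- dplyr::arrange(combine_by_key(parts, combine), .data$key)
      if (!identical(whole, again)) {
        stop("combiner contract violated on trial ", t, call. = FALSE)
      }
    }
  })
  invisible(TRUE)
}
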