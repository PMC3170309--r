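#' Construct a threshold configuration
#'
#' @param rules Tibble with columns `pattern` (glob over KV keys),
#'   `bound_type` (`"min"` or `"max"`), `bound` (finite number), `action`
#'   (`"FAIL"` or `"WARN"`).
#' @param technical_fail_rules Character vector of validation rule ids that
#'   force FAIL when present in the findings.
#' @param required_tests Character vector of key globs that must match at
#'   least one KV key, otherwise FAIL (a missing required test is itself a
#'   failure).
#' @return A `threshold_config` object.
#' @export
threshold_config <- function(rules,
                             technical_fail_rules = character(0),
                             required_tests = character(0)) {
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("pattern", "bound_type", "bound", "action") %in% names(rules)),
            all(rules$bound_type %in% c("min", "max")),
            all(rules$action %in% c("FAIL", "WARN")),
            all(is.finite(rules$bound)), all(nzchar(rules$pattern)))
  structure(list(rules = rules,
                 technical_fail_rules = technical_fail_rules,
                 required_tests = required_tests),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config> ", nrow(x$rules), " bound rule(s), ",
      length(x$technical_fail_rules), " technical fail rule(s)\n", sep = "")
  print(x$rules)
  invisible(x)
}

#' The EXAMPLE threshold configuration
#'
#' Thresholding requires domain expertise: what counts as a failing mapping
#' ratio differs between, say, clinical tumour cohorts and yeast population
#' panels, so no defaults can claim authority. This config is an EXAMPLE
#' that makes the tool runnable out of the box: mapping ratio below 0.5
#' fails; mean mapping quality below 20 warns; anomalous-chromosome read
#' fraction above 0.05 warns; any per-record technical ERROR rule forces
#' FAIL. Override with [read_threshold_config()] for real cohorts.
#'
#' @return A [threshold_config()].
#' @export
example_threshold_config <- function() {
  threshold_config(
    rules = tibble::tribble(
      ~pattern, ~bound_type, ~bound, ~action,
      "FILE_*_MAPPING_RATIO", "min", 0.5, "FAIL",
      "FILE_*_MAPQ_MEAN", "min", 20, "WARN",
      "GROUP_*_MAPQ_MEAN", "min", 20, "WARN",
      "FILE_*_ANOMALOUS_FRACTION", "max", 0.05, "WARN"
    ),
    technical_fail_rules = rule_catalogue() |>
      dplyr::filter(.data$severity == "ERROR",
                    .data$family %in% c("syntax", "functional")) |>
      dplyr::pull("rule_id")
  )
}

#' Read a threshold configuration from a TSV file
#'
#' Format: tab-separated with a header line `pattern bound_type bound
#' action`; optional comment lines start with `#`. Lines of the form
#' `#technical_fail <rule_id>` and `#required <glob>` populate the
#' corresponding config fields.
#'
#' @param path Path to the config file.
#' @return A [threshold_config()].
#' @export
read_threshold_config <- function(path) {
  lines <- readLines(path)
  tf <- sub("^#technical_fail\\s+", "",
            grep("^#technical_fail\\s", lines, value = TRUE))
  req <- sub("^#required\\s+", "", grep("^#required\\s", lines, value = TRUE))
  req <- req[nzchar(req)]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 2) {
    stop("threshold config needs a header line and at least one rule",
         call. = FALSE)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  hdr <- parts[[1]]
  rows <- parts[-1]
  get <- function(row, col) row[[match(col, hdr)]]
  rules <- tibble::tibble(
    pattern = vapply(rows, get, character(1), col = "pattern"),
    bound_type = vapply(rows, get, character(1), col = "bound_type"),
    bound = as.numeric(vapply(rows, get, character(1), col = "bound")),
    action = vapply(rows, get, character(1), col = "action")
  )
  threshold_config(rules, technical_fail_rules = tf, required_tests = req)
}

#' Write a threshold configuration to TSV
#' @param config A [threshold_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_config <- function(config, path) {
  lines <- c(
    if (length(config$technical_fail_rules)) {
      paste0("#technical_fail ", config$technical_fail_rules)
    },
    if (length(config$required_tests)) {
      paste0("#required ", config$required_tests)
    },
    "pattern\tbound_type\tbound\taction",
    paste(config$rules$pattern, config$rules$bound_type,
          format(config$rules$bound, scientific = FALSE, trim = TRUE),
          config$rules$action, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

.glob_match <- function(pattern, x) {
  grepl(utils::glob2rx(pattern), x)
}

#' Assign a pass/warn/fail verdict to one file
#'
#' FAIL when any finding's rule id is in `technical_fail_rules` (automatic
#' rejection on technical errors), when any KV value violates a FAIL-action
#' bound, or when a required test left no key in the stream. WARN when only
#' WARN-action bounds are violated (or an `NA` metric was encountered —
#' `NA` never triggers a numeric bound). PASS otherwise. A pure function of
#' its inputs: identical across runs.
#'
#' @param kv KV tibble (`key`, `value`).
#' @param findings Findings tibble.
#' @param config A [threshold_config()].
#' @param file_id File identifier.
#' @return A `file_verdict` object: list with `file_id`, `status`,
#'   `reasons` (tibble `trigger`, `observed`, `bound`, `action`).
#' @export
apply_thresholds <- function(kv, findings, config, file_id = "sample") {
  reasons <- tibble::tibble(trigger = character(), observed = double(),
                            bound = double(), action = character())
  tech <- intersect(unique(findings$rule_id), config$technical_fail_rules)
  for (rule in tech) {
    reasons <- dplyr::bind_rows(reasons, tibble::tibble(
      trigger = rule, observed = sum(findings$rule_id == rule),
      bound = 0, action = "FAIL"
    ))
  }
  for (i in seq_len(nrow(config$rules))) {
    rule <- config$rules[i, ]
    hit <- kv[.glob_match(rule$pattern, kv$key), , drop = FALSE]
    na_hit <- hit[is.na(hit$value), , drop = FALSE]
    for (k in na_hit$key) {
      reasons <- dplyr::bind_rows(reasons, tibble::tibble(
        trigger = paste0("na_metric:", k), observed = NA_real_,
        bound = rule$bound, action = "WARN"
      ))
    }
    hit <- hit[!is.na(hit$value), , drop = FALSE]
    viol <- if (rule$bound_type == "min") hit$value < rule$bound else hit$value > rule$bound
    for (j in which(viol)) {
      reasons <- dplyr::bind_rows(reasons, tibble::tibble(
        trigger = hit$key[j], observed = hit$value[j],
        bound = rule$bound, action = rule$action
      ))
    }
  }
  for (pat in config$required_tests) {
    if (!any(.glob_match(pat, kv$key))) {
      reasons <- dplyr::bind_rows(reasons, tibble::tibble(
        trigger = paste0("missing_required:", pat), observed = NA_real_,
        bound = NA_real_, action = "FAIL"
      ))
    }
  }
  status <- if (any(reasons$action == "FAIL")) "FAIL"
            else if (nrow(reasons)) "WARN" else "PASS"
  structure(list(file_id = file_id, status = status, reasons = reasons),
            class = "file_verdict")
}

#' @export
print.file_verdict <- function(x, ...) {
  cat("<file_verdict> '", x$file_id, "': ", x$status, "\n", sep = "")
  if (nrow(x$reasons)) print(x$reasons)
  invisible(x)
}

#' @rdname apply_thresholds
#' @param x A `file_verdict` object.
#' @param ... Unused.
#' @method tidy file_verdict
#' @export
tidy.file_verdict <- function(x, ...) {
  dplyr::mutate(x$reasons, file_id = x$file_id, status = x$status,
                .before = 1)
}

#' @rdname apply_thresholds
#' @method glance file_verdict
#' @export
glance.file_verdict <- function(x, ...) {
  tibble::tibble(file_id = x$file_id, status = x$status,
                 n_reasons = nrow(x$reasons),
                 n_fail_reasons = sum(x$reasons$action == "FAIL"))
}

#' Verdicts over a batch of files
#'
#' @param sample_results List of lists, each with elements `file_id`, `kv`,
#'   `findings`.
#' @param config A [threshold_config()].
#' @return A `batch_verdicts` object: list with `verdicts` (tibble
#'   `file_id`, `status`, `n_reasons`), `reasons` (long tibble), `summary`
#'   (tibble `status`, `n` over PASS/WARN/FAIL), and `exit_code` (nonzero
#'   iff any FAIL — the pipeline-integration contract).
#' @export
batch_verdicts <- function(sample_results, config) {
  verdicts <- lapply(sample_results, function(s) {
    apply_thresholds(s$kv, s$findings, config, s$file_id)
  })
  vt <- purrr::map_dfr(verdicts, glance)
  if (!nrow(vt)) {
    vt <- tibble::tibble(file_id = character(), status = character(),
                         n_reasons = integer(), n_fail_reasons = integer())
  }
  reasons <- purrr::map_dfr(verdicts, tidy)
  summary <- tibble::tibble(status = c("PASS", "WARN", "FAIL")) |>
    dplyr::left_join(dplyr::count(vt, .data$status, name = "n"), by = "status") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(list(verdicts = vt, reasons = reasons, summary = summary,
                 exit_code = as.integer(any(vt$status == "FAIL"))),
            class = "batch_verdicts")
}

#' @export
print.batch_verdicts <- function(x, ...) {
  cat("<batch_verdicts> ")
  cat(paste0(x$summary$status, "=", x$summary$n, collapse = " "), "\n")
  invisible(x)
}

#' @rdname batch_verdicts
#' @param x A `batch_verdicts` object.
#' @param ... Unused.
#' @method tidy batch_verdicts
#' @export
tidy.batch_verdicts <- function(x, ...) x$reasons

#' @rdname batch_verdicts
#' @method glance batch_verdicts
#' @export
glance.batch_verdicts <- function(x, ...) {
  tibble::tibble(n_files = nrow(x$verdicts),
                 n_pass = x$summary$n[x$summary$status == "PASS"],
                 n_warn = x$summary$n[x$summary$status == "WARN"],
                 n_fail = x$summary$n[x$summary$status == "FAIL"],
                 exit_code = x$exit_code)
}

#' Write verdicts to the TSV report format
#'
#' @param batch A `batch_verdicts` object (or single `file_verdict`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts_tsv <- function(batch, path) {
  if (inherits(batch, "file_verdict")) {
    vt <- glance(batch)
  } else {
    vt <- batch$verdicts
  }
  lines <- c("file_id\tstatus\tn_reasons",
             paste(vt$file_id, vt$status,
                   if ("n_reasons" %in% names(vt)) vt$n_reasons else 0L,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
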