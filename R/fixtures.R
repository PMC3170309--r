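#' Specification for a synthetic alignment fixture
#'
#' Describes a deterministic synthetic SAM file: reference dictionary, read
#' groups with per-group MAPQ regimes, read count and length, an optional
#' per-kilobase depth profile, and a list of violations to plant. The same
#' spec (including seed) always produces a byte-identical file.
#'
#' No reference FASTA is ever consulted: positions are asserted, not
#' computed by alignment, because the QA tests never read the reference
#' sequence itself.
#'
#' @param seed RNG seed (integer).
#' @param references Tibble with columns `name`, `length`.
#' @param read_groups Tibble with columns `id`, `platform`, `platform_unit`,
#'   `mapq_mean`, `mapq_sd` (and optionally `sample`).
#' @param n_reads Number of records.
#' @param read_length Read length in bases.
#' @param depth_profile Optional numeric vector of relative weights over
#'   kilobase bins (recycled along each reference); `NULL` for flat depth.
#' @param paired Generate reads flagged as proper pairs (default `TRUE`).
#' @param insert_range Two-element vector: template lengths are drawn
#'   uniformly from this range (defaults inside the structural-variation
#'   job's default concordance bounds).
#' @param frac_unmapped Fraction of reads generated as unmapped records.
#' @param plants Tibble with columns `rule_id`, `count` of violations to
#'   plant, or `NULL`.
#' @param file_id Sample identifier (also the default SM field).
#' @return A `fixture_spec` object (validated list).
#' @export
fixture_spec <- function(seed = 1L,
                         references = tibble::tibble(name = "chr1", length = 10000L),
                         read_groups = tibble::tibble(
                           id = "rg1", platform = "ILLUMINA",
                           platform_unit = "lane1", mapq_mean = 50, mapq_sd = 5
                         ),
                         n_reads = 1000L,
                         read_length = 100L,
                         depth_profile = NULL,
                         paired = TRUE,
                         insert_range = c(150L, 900L),
                         frac_unmapped = 0,
                         plants = NULL,
                         file_id = "sample") {
  references <- tibble::as_tibble(references)
  read_groups <- tibble::as_tibble(read_groups)
  if (!"sample" %in% names(read_groups)) read_groups$sample <- file_id
  stopifnot(nrow(references) >= 1, all(references$length > 0),
            n_reads >= 0, read_length >= 1,
            insert_range[1] <= insert_range[2],
            frac_unmapped >= 0, frac_unmapped <= 1)
  if (read_length > min(references$length)) {
    stop("read_length exceeds the shortest reference length", call. = FALSE)
  }
  if (!is.null(plants)) {
    plants <- tibble::as_tibble(plants)
    stopifnot(all(c("rule_id", "count") %in% names(plants)))
  }
  structure(list(seed = as.integer(seed), references = references,
                 read_groups = read_groups, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 depth_profile = depth_profile, paired = paired,
                 insert_range = insert_range, frac_unmapped = frac_unmapped,
                 plants = plants, file_id = file_id),
            class = "fixture_spec")
}

empty_manifest <- function() {
  tibble::tibble(record_index = integer(), rule_id = character(),
                 details = character())
}

.random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Draw 1-based start positions approximating the depth profile over
# kilobase bins, clamped so the read fits on the reference.
.draw_positions <- function(n, ref_len, read_len, profile) {
  max_pos <- ref_len - read_len + 1L
  if (is.null(profile)) {
    return(sample.int(max_pos, n, replace = TRUE))
  }
  n_bins <- ceiling(ref_len / 1000)
  w <- rep_len(profile, n_bins)
  bin <- sample.int(n_bins, n, replace = TRUE, prob = w)
  pos <- (bin - 1L) * 1000L + sample.int(1000L, n, replace = TRUE)
  pmin(pos, max_pos)
}

#' Generate a clean synthetic SAM file
#'
#' Produces a spec-conformant file that yields zero findings from the
#' validators: valid query names, consistent header, in-range positions,
#' proper-pair flags, RG and NM tags resolving correctly. MAPQ is drawn per
#' read group from a normal distribution, clamped to [0, 254] and rounded —
#' the integer-only construction that makes output byte-deterministic under
#' a fixed seed.
#'
#' @param spec A [fixture_spec()]; its `plants` must be empty.
#' @return List with `sam` (a [sam_file()]) and `manifest` (empty tibble).
#' @export
generate_clean <- function(spec) {
  if (!is.null(spec$plants) && nrow(spec$plants)) {
    stop("generate_clean requires a spec without plants; use plant_errors",
         call. = FALSE)
  }
  header <- sam_header(
    sequences = spec$references,
    read_groups = spec$read_groups[, c("id", "sample", "platform", "platform_unit")],
    programs = tibble::tibble(id = "samqc", name = "samqc", version = "0.1.0"),
    sort_order = "unsorted"
  )
  n <- spec$n_reads
  if (!n) {
    return(list(sam = sam_file(header, empty_records(), spec$file_id),
                manifest = empty_manifest()))
  }
  records <- withr::with_seed(spec$seed, {
    ref_idx <- sample.int(nrow(spec$references), n, replace = TRUE,
                          prob = spec$references$length)
    rg_idx <- sample.int(nrow(spec$read_groups), n, replace = TRUE)
    pos <- integer(n)
    for (ri in unique(ref_idx)) {
      sel <- ref_idx == ri
      pos[sel] <- .draw_positions(sum(sel), spec$references$length[ri],
                                  spec$read_length, spec$depth_profile)
    }
    mapq <- round(pmin(254, pmax(0, stats::rnorm(
      n, spec$read_groups$mapq_mean[rg_idx], spec$read_groups$mapq_sd[rg_idx]
    ))))
    unmapped <- stats::runif(n) < spec$frac_unmapped
    tlen <- sample(seq.int(spec$insert_range[1], spec$insert_range[2]),
                   n, replace = TRUE)
    first <- seq_len(n) %% 2L == 1L
    flag <- integer(n)
    if (spec$paired) {
      flag <- ifelse(first, 99L, 147L) # paired, proper, mate-strand, 1st/2nd
      flag[unmapped] <- 101L # paired, unmapped, mate reverse
    } else {
      flag <- ifelse(first, 0L, 16L)
      flag[unmapped] <- 4L
    }
    seqs <- .random_seq(n, spec$read_length)
    tibble::tibble(
      qname = sprintf("r%06d", seq_len(n)),
      flag = flag,
      rname = ifelse(unmapped, NA_character_, spec$references$name[ref_idx]),
      pos = ifelse(unmapped, NA_real_, as.numeric(pos)),
      mapq = ifelse(unmapped, 0, as.numeric(mapq)),
      cigar = ifelse(unmapped, NA_character_,
                     paste0(spec$read_length, "M")),
      rnext = ifelse(unmapped | !spec$paired, NA_character_, "="),
      pnext = ifelse(unmapped | !spec$paired, NA_real_,
                     pmax(1, pos + tlen - spec$read_length)),
      tlen = as.numeric(ifelse(unmapped | !spec$paired, 0,
                               ifelse(first, tlen, -tlen))),
      seq = seqs,
      qual = strrep("I", spec$read_length),
      tags = paste0("RG:Z:", spec$read_groups$id[rg_idx], "\tNM:i:0")
    )
  })
  list(sam = sam_file(header, records, spec$file_id),
       manifest = empty_manifest())
}

# One mutation per plantable rule: turns a clean record into a minimal
# violation of exactly that rule (plus, for unpairing mutations, the
# unavoidable file-level pairing-census note).
.plant_mutations <- function() {
  list(
    "functional.cigar_on_unmapped" = function(r) {
      r$flag <- 5L; r$mapq <- 0; r
    },
    "functional.mapq_on_unmapped" = function(r) {
      r$flag <- 5L; r$cigar <- NA_character_; r$mapq <- 37; r
    },
    "functional.unknown_read_group" = function(r) {
      r$tags <- "RG:Z:ghost-group\tNM:i:0"; r
    },
    "functional.maps_beyond_reference" = function(r, ref_len) {
      r$pos <- as.numeric(ref_len - 9L); r
    },
    "functional.adjacent_indel" = function(r) {
      r$cigar <- "45M5I5D45M"; r
    },
    "functional.proper_pair_without_pairing" = function(r) {
      r$flag <- 2L; r
    },
    "functional.invalid_nm" = function(r) {
      r$tags <- sub("NM:i:[0-9]+", "NM:i:-1", r$tags); r
    },
    "syntax.unknown_reference" = function(r) {
      r$rname <- "chrMISSING"; r
    },
    "syntax.seq_qual_mismatch" = function(r) {
      r$qual <- substr(r$qual, 1, nchar(r$qual) - 1L); r
    },
    "syntax.zero_length_read" = function(r) {
      r$seq <- NA_character_; r$qual <- NA_character_
      r$cigar <- NA_character_; r
    },
    "syntax.invalid_qname" = function(r) {
      r$qname <- "bad qname"; r
    },
    "syntax.invalid_cigar" = function(r) {
      r$cigar <- "10M5"; r
    },
    "syntax.flag_range" = function(r) {
      r$flag <- 65635L; r
    },
    "syntax.pos_range" = function(r) {
      r$pnext <- 3e9; r
    }
  )
}

#' Rules the fixture generator can plant
#' @return Character vector of rule ids.
#' @export
plantable_rules <- function() names(.plant_mutations())

#' Plant rule violations into a clean file
#'
#' Mutates exactly `count` randomly chosen records per plant into minimal
#' violations of that rule and records them in the manifest. A record is
#' never chosen for two plants, and non-planted records remain finding-free.
#'
#' @param sam A clean [sam_file()] (from [generate_clean()]).
#' @param plants Tibble with columns `rule_id`, `count`.
#' @param seed RNG seed for choosing victim records.
#' @return List with `sam` (mutated) and `manifest` (tibble `record_index`
#'   0-based, `rule_id`, `details`).
#' @export
plant_errors <- function(sam, plants, seed = 1L) {
  plants <- tibble::as_tibble(plants)
  plants <- plants[plants$count > 0, , drop = FALSE]
  if (!nrow(plants)) return(list(sam = sam, manifest = empty_manifest()))
  muts <- .plant_mutations()
  unknown <- setdiff(plants$rule_id, names(muts))
  if (length(unknown)) {
    stop("cannot plant unregistered rule(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  total <- sum(plants$count)
  n <- nrow(sam$records)
  if (total > n) stop("more plants than records", call. = FALSE)
  victims <- withr::with_seed(seed, sample.int(n, total))
  rule_per_victim <- rep(plants$rule_id, plants$count)
  records <- sam$records
  ref_len <- sam$header$sequences$length[
    match(records$rname, sam$header$sequences$name)]
  for (k in seq_along(victims)) {
    i <- victims[k]
    rule <- rule_per_victim[k]
    f <- muts[[rule]]
    row <- records[i, , drop = FALSE]
    row <- if (rule == "functional.maps_beyond_reference") {
      f(row, ref_len[i])
    } else {
      f(row)
    }
    records[i, ] <- row
  }
  manifest <- tibble::tibble(
    record_index = as.integer(victims - 1L),
    rule_id = rule_per_victim,
    details = paste0("planted ", rule_per_victim)
  ) |> dplyr::arrange(.data$record_index)
  list(sam = sam_file(sam$header, records, sam$file_id), manifest = manifest)
}

#' Generate a fixture file (clean + plants) from one spec
#'
#' @param spec A [fixture_spec()]; `plants` may be set.
#' @return List with `sam` and `manifest`.
#' @export
generate_fixture <- function(spec) {
  clean_spec <- spec
  clean_spec$plants <- NULL
  clean <- generate_clean(clean_spec)
  if (is.null(spec$plants) || !nrow(spec$plants)) return(clean)
  # plant seed offset keeps victim choice independent of read generation
  plant_errors(clean$sam, spec$plants, seed = spec$seed + 104729L)
}

#' Write a plant manifest to TSV
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  lines <- c("record_index\trule_id\tdetails",
             paste(manifest$record_index, manifest$rule_id, manifest$details,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plant manifest from TSV
#' @param path Path to a manifest TSV.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)[-1]
  if (!length(lines)) return(empty_manifest())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    record_index = as.integer(vapply(parts, `[[`, character(1), 1)),
    rule_id = vapply(parts, `[[`, character(1), 2),
    details = vapply(parts, `[[`, character(1), 3)
  )
}

#' Generate a population of fixture files
#'
#' Writes one SAM file and one `.manifest.tsv` per spec into `dir` and
#' returns the merged manifest. Suitable as a batch-verdict test bed; a
#' spec with `frac_unmapped = 1` emulates a file containing only unmapped
#' reads (the automatic-rejection case).
#'
#' @param specs Non-empty list of [fixture_spec()] objects with unique
#'   `file_id`s.
#' @param dir Output directory (created if needed).
#' @return Tibble with columns `file_id`, `path`, `manifest_path`, plus the
#'   merged manifest as attribute `"manifest"` (columns `file_id` +
#'   manifest columns).
#' @export
generate_population <- function(specs, dir) {
  if (!length(specs)) stop("at least one fixture spec required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(specs, function(spec) {
    fx <- generate_fixture(spec)
    path <- file.path(dir, paste0(spec$file_id, ".sam"))
    mpath <- file.path(dir, paste0(spec$file_id, ".manifest.tsv"))
    write_sam(fx$sam, path)
    write_manifest(fx$manifest, mpath)
    tibble::tibble(file_id = spec$file_id, path = path, manifest_path = mpath,
                   n_plants = nrow(fx$manifest))
  })
  if (anyDuplicated(rows$file_id)) {
    stop("fixture specs must have unique file_ids", call. = FALSE)
  }
  merged <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    m <- read_manifest(rows$manifest_path[i])
    if (nrow(m)) m$file_id <- rows$file_id[i]
    m
  })
  attr(rows, "manifest") <- merged
  rows
}

#' Fixture specs for a two-platform batch population
#'
#' Emulates a cohort sequenced on two platforms with well-separated
#' mapping-quality regimes (means 12 and 55, sd 3), the structure that makes
#' the per-file mean-MAPQ distribution bimodal. Optionally includes files
#' consisting entirely of unmapped reads.
#'
#' @param n_files Total number of files (split evenly across platforms).
#' @param seed Base RNG seed; file `i` uses `seed + i`.
#' @param n_reads Reads per file.
#' @param n_unmapped_files How many additional all-unmapped files to append.
#' @return List of [fixture_spec()] objects.
#' @export
two_platform_specs <- function(n_files = 20L, seed = 1L, n_reads = 500L,
                               n_unmapped_files = 0L) {
  regimes <- list(
    list(platform = "ILLUMINA", mapq_mean = 55, mapq_sd = 3),
    list(platform = "SOLID", mapq_mean = 12, mapq_sd = 3)
  )
  specs <- lapply(seq_len(n_files), function(i) {
    reg <- regimes[[(i - 1L) %% 2L + 1L]]
    fixture_spec(
      seed = seed + i,
      read_groups = tibble::tibble(
        id = paste0("rg", i), platform = reg$platform,
        platform_unit = paste0("pu", i),
        mapq_mean = reg$mapq_mean, mapq_sd = reg$mapq_sd
      ),
      n_reads = n_reads,
      file_id = sprintf("s%02d", i)
    )
  })
  if (n_unmapped_files > 0) {
    specs <- c(specs, lapply(seq_len(n_unmapped_files), function(j) {
      fixture_spec(
        seed = seed + n_files + j,
        n_reads = 200L,
        frac_unmapped = 1,
        file_id = sprintf("u%02d", j)
      )
    }))
  }
  specs
}
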