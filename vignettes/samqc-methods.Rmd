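---
title: "Quality assurance for alignment files: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assurance for alignment files: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samqc)
library(dplyr)
```

## The problem

Large sequencing cohorts accumulate quality problems at every level: sample
purity, amplification bias, instrument-specific artefacts, and the mixture of
aligners and aligner versions used across centres. Before any downstream
analysis, each alignment file should clear two kinds of checks:

* **Technical checks** — does the file obey the SAM specification? These are
  mechanical, fully automatable, and a failure is grounds for automatic
  rejection.
* **Biological plausibility checks** — is the content *believable*? Low
  mapping ratios, collapsed read lengths, reads piling onto unplaced
  ("random") contigs, excess discordant pairs, or read groups whose coverage
  profiles do not correlate are all signatures of batch effects or failed
  runs, but deciding how much is too much requires a domain expert and a
  threshold.

samqc implements both layers for desk-scale use, plus the scaffolding that
makes them trustworthy: a partition-parallel execution engine whose output is
provably independent of how the input is split, and a synthetic-data
generator that plants known violations so every rule can be tested against
ground truth.

## Technical validation

The rule catalogue (`rule_catalogue()`) covers three families:

* **header** — empty sequence dictionary, missing read groups, duplicate
  sequence names or read-group ids, non-positive sequence lengths;
* **syntax** — per-field adherence: query-name character/length rule, FLAG
  and position ranges, reference names resolving in the dictionary, SEQ/QUAL
  length agreement, zero-length reads, malformed CIGAR strings;
* **functional** — cross-field relationships: an unmapped read must carry no
  CIGAR and MAPQ 0, RG tags must resolve in the header, an alignment must
  not extend past its reference, CIGARs must not contain adjacent
  insertions/deletions, the proper-pair flag requires the paired flag, NM
  must be a non-negative integer when present.

Three per-record messages are a byte-exact compatibility contract, because
downstream tooling patterns on them:

```
CIGAR should have zero elements for unmapped read
MAPQ should be 0 for unmapped read
RG ID on SAMRecord not found in header
```

Parsing is deliberately lenient: a decodable but spec-violating record is
returned, not rejected, because the tool's purpose is to *report* errors.
Only structurally undecodable input (fewer than 11 fields, non-numeric
numeric columns) raises a parse error; at the batch level that file fails
with reason `io_error` and the batch continues.

Severity is graded: per-record rules are `ERROR` (these feed automatic
rejection), while advisory conditions — missing read groups, the pairing
census, single-read-group files — are `WARNING`. The pairing census is
flag-based (fraction of records with the paired flag clear; a file-level
finding when that fraction is 1, another when it is strictly between 0
and 1). A mate-record lookup would require a second queryname-grouped pass
and is deliberately out of scope.

Unmapped records are exempt from position/reference checks: an unmapped
read's POS may legitimately be unset or stale.

## Coordinates and binning

Coordinates follow SAM: 1-based, inclusive. Bins are 0-based; bin $b$ of
size $s$ covers positions $[bs + 1,\,(b+1)s]$. The conversion happens in
exactly one place (the bin-assignment expression `(pos - 1) %/% bin_size`
inside the binning jobs), which is the single most effective guard against
off-by-one drift we know of.

Unset fields are represented as `NA` inside the model; the sentinel forms
(`"*"`, position 0) exist only at the serialisation boundary.

## Feature extraction

Each biological test is a map/combine/reduce job emitting compound
key-value pairs (`<KEY>\t<value>` lines, e.g.
`BIN_example_0_COVERAGE  9.4126293`):

* **Coverage** (1 kb bins by default): aligned reference-consuming bases per
  bin divided by bin size, with reads apportioned *base-by-base* across bin
  boundaries. Deletions (D) and skips (N) consume reference and count as
  covering by default; `coverage_ops = c("M", "=", "X")` restricts to
  aligned bases. Because integer base counts are accumulated before the one
  final division, coverage conservation — sum over bins of (value × bin
  size) equals the summed reference spans — holds exactly, not
  approximately.
* **Read frequency**: mapped reads counted once, in the bin of their
  leftmost position. Keeping one whole-read count and one base-apportioned
  measure distinguishes "few reads here" from "thin coverage here".
* **Mapping quality**: mean MAPQ over mapped reads per file and per read
  group, plus the full per-file MAPQ histogram. Per-file means across a
  cohort are where platform bimodality shows up.
* **Mapping ratio**: mapped/total reads; 0 for a file of only unmapped
  reads (the canonical auto-reject), no key for an empty file.
* **Read statistics**: count and length min/mean/max per file and group;
  read length falls back to the query-consuming CIGAR span when SEQ is
  unset.
* **Chromosome check**: reads mapped to anomalously named references
  (defaults: contains `random`, `chrUn` prefix, `hap`/`alt` suffixes;
  fully configurable, an empty pattern set disables the test), plus the
  overall anomalous fraction of mapped reads.
* **Structural variation**: discordant-pair counts per bin. "Discordant"
  is our proxy definition — paired and (proper-pair flag clear, or mate on
  a different chromosome, or |TLEN| outside configurable bounds, default
  0–1000 bp). This is the standard read-pair SV signal; bin-level counts
  only, no breakpoint calling. Per platform unit we also emit the
  discordant fraction, a projected batch-level SV burden.

Secondary (0x100) and duplicate (0x400) reads are *included* by default —
QC should see everything — and excludable by flag.

### Key grammar

`CATEGORY_SAMPLE[_QUALIFIER...]_METRIC` with category one of BIN, FILE,
GROUP, CHROM, PU, CORR, ERROR. Tokens are underscore-delimited, so
underscores inside sample names, read-group ids or chromosome names become
`-` at key-build time (`kv_sanitize()`; the original/sanitised mapping can
be emitted as `#map` comment lines). BIN keys carry a chromosome token by
default; `legacy_keys = TRUE` reproduces the 4-token form
(`BIN_<sample>_<bin>_<METRIC>`) for single-reference files. Values render
with up to 7 decimal places, integers without a decimal point, undefined
values as the literal `NA` (never 0, which would masquerade as a result).
One merged, key-sorted stream is written per sample; keys are unique
within a run by construction and the parser enforces it.

## The partition engine

Every job is expressed as `map` (records block → keyed integer
accumulators), `combine` (per-column `sum`/`min`/`max` within a key) and
`reduce` (combined accumulators → final values). Restricting combine
operations to integer sums, minima and maxima — means and ratios are formed
only in `reduce` — is what turns "combiner-safe" from a convention into a
theorem: integer arithmetic in doubles is exact below 2^53, so combining
per partition and then across partitions is *identical*, byte for byte, to
one global pass, for every partitioning and worker count. The engine
refuses non-associative combine operations at construction time, and
grouped accumulators are always processed in sorted key order, so even the
floating-point reductions (means of bin values) see a fixed summation
order.

The partitioning unit is a contiguous block of records (default 10^5 per
partition), not a genomic region: all shipped tests are record-local, and
key-based combining makes region awareness unnecessary. `workers` is part
of the interface contract (results must be worker-count-agnostic) and this
in-process engine executes partitions sequentially.

## Read-group correlation

For each read group, per-megabase-bin vectors of coverage (same
computation as the coverage job) or mean MAPQ are built; every unordered
pair of groups is correlated with Pearson's product-moment coefficient,
computed genome-wide across all pooled (chromosome, bin) keys. Two design
points:

* The bin universe per pair is the **union** of bins where either group has
  reads, with 0 filled for the absent group. Intersection-only would blind
  the test to coverage dropout — which is precisely the batch effect being
  hunted.
* Correlations are undefined (`NA`) when fewer than two bins exist or
  either vector has zero variance.

All pairs are computed (quadratic in group count — alignment files rarely
carry more than a handful of read groups); results are emitted once per
pair with lexicographically ordered group names. Significance testing and
multiple-testing control are out of scope; thresholds are the verdict
layer's business.

## Verdicts

A verdict is a pure function of (key-value stream, findings, config):
`FAIL` if any finding's rule id is in the configured technical-fail set, any
key-value violates a FAIL-action bound (glob pattern over keys, min or max
bound), or a required test left no key; `WARN` for WARN-action violations
and `NA` metrics; `PASS` otherwise, with every violation listed with its
observed value and bound. Relaxing a bound can never flip a verdict toward
FAIL (tested as a randomised monotonicity property). At the batch level the
process exit code is nonzero iff any file fails, which is the whole
pipeline-integration contract.

Numeric thresholds are domain judgements, not facts about the format, so
the shipped defaults are explicitly an **EXAMPLE** config
(`example_threshold_config()`): mapping ratio ≥ 0.5 or FAIL; mean MAPQ ≥ 20
or WARN; anomalous-chromosome fraction ≤ 0.05 or WARN; all per-record
technical `ERROR` rules force FAIL. Glob-over-key matching means new tests
need no verdict-layer changes.

## The synthetic-data generator

The generator emulates the study conditions this tool is exercised under:
multi-read-group, multi-platform populations with per-group MAPQ regimes,
optional per-kilobase depth profiles, proper pairs with template lengths
drawn uniformly from 150–900 bp (inside the SV job's default 0–1000
concordance bounds, so clean files carry no discordance signal), constant
Phred qualities and uniform random A/C/G/T sequences. No reference FASTA
exists anywhere: positions are asserted, not computed, because none of the
QA tests read the reference sequence itself.

Determinism is a hard contract: identical spec (including seed) produces a
byte-identical file, which requires integer-only record construction and a
fixed MAPQ rounding rule (normal draw, clamp to [0, 254], `round`).

`plant_errors()` mutates randomly chosen records into *minimal* violations
of a requested rule — 14 rules are plantable — and records them in a
machine-readable manifest, which is the ground truth the validator is
tested against (exactly k findings with matching 0-based record indices for
k planted violations; zero findings on clean files). Two plants never hit
the same record. The only intentional side effect: unpairing mutations
(e.g. proper-pair-without-pairing) necessarily also move the file-level
pairing census, a different, file-scoped rule.

The two-platform population (`two_platform_specs()`) uses MAPQ means 12
and 55 with sd 3 — regimes chosen to be unambiguous on a 20-file batch
(modes separated by far more than the within-mode spread) — and can append
all-unmapped files to exercise the auto-rejection path.

What passing these tests does **not** show about real data: the generator
has no chemistry error profiles, no GC bias, no realistic quality strings,
no genuinely mated pairs (mates are flag-consistent, not cross-record
consistent), and its depth profiles are piecewise-constant. Tests against
it demonstrate that the *measurements and rules* are correct, not that the
example thresholds are well calibrated for any particular cohort.

## Numerical and degenerate-input choices

* Empty file: no feature keys, a file-level `file.empty` warning.
* All reads unmapped: mapping ratio 0 (never a missing key), coverage and
  MAPQ keys absent.
* Undefined correlation: literal `NA` in the stream; the verdict layer
  reports `na_metric` as WARN and never applies numeric bounds to it.
* Records on reference names missing from the dictionary are findings for
  the validator and are skipped (with a classed warning) by feature jobs.
* Mode counting for batch summaries uses a Gaussian kernel density at
  Silverman's rule-of-thumb bandwidth (`stats::bw.nrd0`), counting local
  maxima at least 5% of the tallest peak — the cutoff that ignores
  estimation wiggle without suppressing genuine platform modes.
* Key sorting uses C-locale radix order everywhere, so output is
  byte-identical across runs and platforms.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
every property decisive yet quick on a laptop: 10^4 reads over a 10^5 bp
reference for the coverage oracle; 100 random small fixtures for
conservation; 3 × 10^3 reads across 1/2/7 partitions for engine invariance;
20 000 reads over 200 kilobase bins for the correlation regression (about
50 reads per bin per group, enough that the shared-profile correlation
clears 0.9 with margin); a 20-file population for the bimodality check.

## Worked example

```{r example}
specs <- two_platform_specs(n_files = 4, seed = 42, n_reads = 200,
                            n_unmapped_files = 1)
dir <- file.path(tempdir(), "samqc-demo")
out <- file.path(dir, "out")
pop <- generate_population(specs, dir)
run <- qa_run(dir, tests = c("validate", "mapq", "ratio", "coverage"),
              output_dir = out, log_level = "error")
run$batch$summary
glance(summarize_kv(list.files(out, pattern = "samqa", full.names = TRUE)))
```

The all-unmapped file `u01` fails (mapping ratio 0 under the example
config), the low-MAPQ platform files warn, and the exit code
(`run$exit_code`) is 1 — exactly what a pipeline wrapper needs.

## Known limitations

* No CRAM, no BAM writing, no reference-FASTA-aware checks (NM is
  validated for type/range only — recomputing edit distance needs the
  reference).
* Mate-pair cross-record consistency is not checked (single-pass design).
* The SV score is a bin-level discordance count, not an SV caller.
* Correlation is genome-wide across pooled bins; a per-chromosome variant
  would be a small extension.
* The engine is in-process; the partition contract is what makes results
  portable to distributed execution, but no distributed runtime ships here.
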