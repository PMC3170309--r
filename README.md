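# samqc

Quality assurance for sequenced-read alignment files (SAM/BAM), built for
people who run cohorts, not single samples: sequencing cores, analysis
centres and pipeline authors who need every file checked against the SAM
specification and screened for biologically implausible content *before*
secondary analysis, with a machine-readable verdict per file.

## What it computes

**Technical validation.** A catalogue of header, syntax and functional
rules against SAM v1.3: dictionary/read-group consistency; per-field
adherence (query-name rule, FLAG and position ranges, SEQ/QUAL agreement,
CIGAR well-formedness); and cross-field relationships — an unmapped read
must carry no CIGAR and MAPQ 0, RG tags must resolve in the header, an
alignment must not run past its reference (POS + reference span − 1 ≤ L),
no adjacent I/D in a CIGAR, NM a non-negative integer. Findings carry
stable rule ids, severities and 0-based record locators.

**Biological features**, emitted as compound key-value pairs
(`CATEGORY_SAMPLE[_QUALIFIER...]_METRIC`):

- per-kilobase coverage, `cov(b) = (aligned bases in bin b) / s`, with
  reads apportioned base-by-base across bin boundaries so that
  `Σ_b cov(b)·s = Σ_reads reference_span(CIGAR)` holds *exactly*;
- per-kilobase read frequency (whole reads, start-bin);
- mapping ratio `mapped/total`, mean MAPQ and MAPQ histograms per file and
  read group, read count and length min/mean/max;
- reads on anomalously named references (`random`, `chrUn*`, `*hap*`,
  `*alt`) and their fraction;
- discordant-pair counts per bin and per platform unit (pairs that are
  improper, inter-chromosomal, or with |TLEN| outside configured bounds) —
  a bin-level structural-variation signal;
- Pearson correlation of per-megabase coverage and mean-MAPQ vectors
  across every pair of read groups (the batch-effect detector),

  r = Σ(xᵢ−x̄)(yᵢ−ȳ) / √(Σ(xᵢ−x̄)² Σ(yᵢ−ȳ)²)

**Verdicts.** Glob-over-key thresholds (min/max, FAIL/WARN) plus automatic
rejection on technical errors give each file PASS/WARN/FAIL with every
trigger, observed value and bound listed; the batch exit code is nonzero
iff any file fails. Shipped bounds are an EXAMPLE config — thresholds are
domain judgements.

**Engine.** Every feature is a map/combine/reduce job over contiguous
record partitions. Combine operations are restricted to integer
sum/min/max, so output is byte-identical for *every* partitioning, worker
count, and with the combiner on or off — a tested guarantee, not a hope.

**Fixtures.** A deterministic generator builds clean SAM files (zero
findings by construction), plants minimal violations of any of 14 rules
with ground-truth manifests, and emulates multi-platform populations —
so the entire pipeline is testable with no external data.

## Worked example

```r
library(samqc)

# a 4-file, two-platform batch plus one all-unmapped file
specs <- two_platform_specs(n_files = 4, seed = 42, n_reads = 200,
                            n_unmapped_files = 1)
dir <- file.path(tempdir(), "samqc-demo"); out <- file.path(dir, "out")
generate_population(specs, dir)

run <- qa_run(dir, tests = c("validate", "mapq", "ratio", "coverage"),
              output_dir = out, log_level = "error")
run$batch$summary
#> # A tibble: 3 × 2
#>   status     n
#>   <chr>  <int>
#> 1 PASS       2
#> 2 WARN       2
#> 3 FAIL       1

glance(summarize_kv(list.files(out, pattern = "samqa", full.names = TRUE)))
#> # A tibble: 4 × 6
#>   metric            n_files   min median   max n_modes
#>   <chr>               <int> <dbl>  <dbl> <dbl>   <int>
#> 1 genome_coverage         4   2      2     2         1
#> 2 mapping_ratio           5   0      1     1         2
#> 3 mapq_mean               4  11.7   33.4  55.1       2
#> 4 mean_bin_coverage       4   2      2     2         1
```

The all-unmapped file fails (mapping ratio 0 — the automatic-rejection
case), the two low-MAPQ-platform files warn under the example MAPQ ≥ 20
bound, the per-file mean-MAPQ distribution is bimodal (`n_modes == 2`, the
two-platform signature), and `run$exit_code` is 1 for the pipeline wrapper.
Each sample's KV stream looks like:

```
BIN_s01_chr1_0_COVERAGE	1.724
BIN_s01_chr1_1_COVERAGE	2.592
...
FILE_s01_MAPPING_RATIO	1
FILE_s01_MAPQ_MEAN	54.82
```

A thin CLI wraps the same functions:

```sh
exec/samqc all --input batch_dir/ --output-dir out/ --config thresholds.cfg
exec/samqc fixtures --out fixtures/ --seed 7 --n-files 20
exec/samqc summarize --input out/*.samqa.tsv --plots --output-dir out/
```

Exit codes: 0 all pass, 1 any FAIL, 2 usage/IO error.

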