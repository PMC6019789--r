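---
title: "Filtering BAM cohorts and scanning read pairs for inversions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering BAM cohorts and scanning read pairs for inversions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamsieve)
```

## The filtering model

A filter job is a conjunction of optional per-record criteria — a
`filter_spec` — applied independently to every alignment record of every
BAM file in a cohort. An absent criterion never excludes a record, so the
empty spec is the identity filter, and adding a criterion can only shrink
the matched set (monotonicity; asserted by property tests). The criteria:

| criterion | meaning | units / form |
|---|---|---|
| `mapq_min` | minimum mapping quality, inclusive | phred-scaled integer |
| `flag_required` | all set bits present in FLAG | 12-bit SAM mask |
| `flag_excluded` | no set bit present in FLAG | 12-bit SAM mask, disjoint from required |
| `tlen_min`, `tlen_max` | inclusive bounds on \|TLEN\| | base pairs |
| `seq_pattern` | substring SEQ must contain | A/C/G/T/N literal, case-insensitive |
| `cigar_regex` | regex the CIGAR must *fully* match | anchored both ends |
| `tag_regex` | regex on the optional-tag block | tags serialized as `TAG:TYPE:VALUE`, tab-joined, original order |
| `regions` | start-containment intervals | 1-based inclusive `chrom:start-end` |
| `samples`, `populations` | cohort subset | resolved against the manifest, file-level |

Three of these fix conventions that a record-level contract needs pinned
down:

* **\|TLEN\| rather than signed TLEN.** SAM TLEN is signed — positive on
  the leftmost mate, negative on the rightmost — so a signed bound would
  give the two mates of one pair different verdicts. Bounds on the
  magnitude treat a pair symmetrically, which is what a template-length
  reduction means physically.
* **Start-containment regions.** A record belongs to a region iff its
  leftmost position lies in the interval. This is reproducible without
  CIGAR arithmetic and matches streaming behaviour; it differs from
  read-*overlap* semantics at interval edges by at most one read length.
  Region fetches through the BAM index (which are overlap-based) are
  post-filtered to this convention, so indexed and full-scan paths agree
  exactly.
* **Anchored CIGAR matching.** `cigar_regex = "[0-9]+M"` means the whole
  CIGAR is one match segment — the purity requirement the inversion scan
  relies on — not merely that a match segment occurs somewhere.

Degenerate inputs have defined behaviour: records with CIGAR `"*"` or the
unmapped bit fail any CIGAR or region criterion but remain eligible under
flag-only filters.

## The engine

A job is planned into exactly one task per BAM file — the granularity at
which cohort data is naturally sharded (one file per individual) — and
tasks are executed by an in-process pool: at most `workers` concurrent
workers, each pulling the next pending task from one shared queue as it
becomes free (realized with `parallel::mclapply(mc.preschedule = FALSE)`,
which forks one process per task up to the pool size). Because every task
is independent and output files are namespaced by job and individual, the
merged output record multiset is invariant to the worker count and
scheduling order; the suite asserts this for pools of 1, 2, 4 and 8.

Failures are isolated per task: a retryable I/O error (unreachable source)
gets one automatic retry and then marks only that task failed; parse
errors and validation errors fail immediately. One retry keeps behaviour
deterministic while still absorbing transient read failures.

Sinks follow a two-method stateless contract — `put(name, bytes) →
locator`, `get(locator) → bytes` — implemented for local directories.
`run_job` also writes a `<job_id>.status.json` summary into the sink, so
`job_status()` and `collect_results()` (and the CLI `status`/`collect`
subcommands) work from a different process than the one that ran the job.

Two classical metrics are exposed: throughput (total bytes streamed across
tasks divided by job wall time, from deployment to completion of the last
task) and scaled speedup ((T₁/Tₙ)/n, exactly 1 at n = 1, with 1.0 the
linear-scaling bound). At desk scale their absolute values reflect the
local machine; the package tests only their closed forms and invariances.

## The inversion scan

Paired-end sequencing of a genome carrying an inversion produces read
pairs in which one mate falls inside the inverted segment and is mapped in
the opposite orientation: both reads end up on the same strand, and the
apparent template length is inflated by roughly the inverted span. The
scan therefore works on alignments that already passed a template-length
reduction (|TLEN| ≥ 600 bp by default — above any plausible fragment size
of standard short-insert protocols) and applies, in order:

1. **Orientation**: keep records whose strand bit (0x10) equals the
   mate-strand bit (0x20) — both forward or both reverse. Evaluating the
   pair condition from a single record's two bits avoids mate lookups and
   gives both mates the same verdict. Unpaired records are dropped.
2. **Purity**: keep records whose CIGAR is a single full-length match
   (`nnM`) and that carry no XA alternative-alignment tag. Soft-clips,
   indels and multi-mapping reads are the dominant noise classes mimicking
   discordant geometry.
3. **Support**: project each record to a (chromosome, ⌊pos₀/1 kb⌋,
   ⌊|TLEN|/1 kb⌋) bin and require at least 20 *distinct individuals* in
   the bin. Recurrent artefacts from one genome count once; a real
   polymorphism recurs across carriers at the same locus and span.
4. **Summary**: per chromosome, a dense matrix over (⌊pos₀/1 Mb⌋,
   ⌊|TLEN|/10 kb⌋) display bins whose cells are the fraction of cohort
   individuals with ≥ 1 surviving alignment in the bin.

The support binning (kb) and the display binning (Mb × 10 kb) are two
separate projections of the same records, not a rescaling of one another:
evidence is assessed at kb resolution, presentation at map resolution.
Binning is floor division of the 0-based start (`pos − 1`) and of |TLEN|;
orientation and purity are per-record predicates and commute, while the
support filter depends on the surviving set and deliberately does not.

**Population contrasts.** For two selectors A and B (a code matching the
manifest's population or superpopulation column; `nonX` is the
complement), frequencies are computed per population with that
population's size as denominator, and the contrast is the cellwise
difference fᴀ − f_B ∈ [−1, 1], positive where A is more affected. The
support filter is applied once, on the full input record set, before any
population split — support is a cohort-wide evidence criterion, not a
per-population one; applying it per population would make small
populations unable to clear the threshold by construction.

**Counting unit.** Frequencies count distinct individuals per bin at the
record level. Both mates of a surviving pair usually fall in different
start bins (they sit a template length apart) but contribute the same
individual, so distinct-individual sets make mate double-counting
harmless.

**Heat maps.** Start bins on the y axis, |TLEN| bins on the x axis,
intensity log₁₀(frequency) by default; zero cells are masked to the
background colour, since log 0 is undefined and zero bins are "no
evidence", not "low frequency". Contrast matrices (which carry negative
cells) always use a linear diverging palette.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the pipeline consumes: one
coordinate-sorted, indexed BAM per individual, a manifest
(file/individual/population/superpopulation), and planted events with a
ground-truth sidecar listing every planted record's kb and display bins.

* Background pairs are properly oriented (flags 99/147 or 83/163) with
  insert sizes from a normal(400 bp, 50 bp) truncated to
  (read length, 1 kb). Mean 400/sd 50 is a typical short-insert library;
  the upper truncation guarantees a planted event's kb-scale TLEN bin is
  determined by its span alone, keeping ground truth exact.
* Inversion carriers get pairs with equal 0x10/0x20 bits (both-forward or
  both-reverse, at random) and TLEN = span + insert; deletion carriers get
  the same TLEN inflation with ordinary forward/reverse orientation —
  passing the template-length reduction but failing the orientation
  filter, which is exactly the confusion class the scan must reject.
* Left-read starts jitter uniformly within 200 bp of the event locus, so
  all planted records of one event share kb bins while still exercising
  the binning arithmetic.
* `inject_noise()` rewrites a stated fraction of records with soft-clipped
  CIGARs and a disjoint fraction with XA tags — the two impurity classes
  the purity filter discards — with counts `round(fraction × n)`,
  deterministically sampled.
* TLEN signs follow SAM (leftmost mate positive), exercising the |TLEN|
  convention; SEQ is random A/C/G/T since the pipeline consumes alignment
  geometry, not base content.
* One seed fixes all output bytes; two runs of the same spec produce
  md5-identical BAMs.

What the generator does *not* emulate: realistic coverage (a handful of
pairs per individual rather than 4–8×), alignment error correlated with
sequence context, reference bias, duplicates, or chimeric/supplementary
alignments. Passing tests therefore demonstrate the *contracts* — correct
predicates, conservation across workers, exact recovery of planted
geometry — not calling performance on real data, where noise is
structured rather than independent.

## Study conditions used by the test suite

The end-to-end recovery check runs a 100-individual cohort (30 background
pairs each) with one inversion of 900 kb at 30 Mb carried by 30
individuals, one sub-threshold inversion carried by 10, one deletion
carried by 40, and 10% + 10% noise, through the |TLEN| ≥ 600 reduction and
the scan at support 20: the result is exactly one nonzero display cell, at
(30 Mb, 90 × 10 kb), with frequency 0.30. Scheduling invariance uses an
8-file cohort at 1/2/4/8 workers; the filter-oracle equivalence check runs
1,000 randomized records against 100 randomized specs against an
independent clause-by-clause evaluator; format round trips use 10,000
property-generated records. These sizes give sub-second to a-few-seconds
single checks and a full suite in about a minute on a laptop-class
machine, while leaving every contract load-bearing.

## Numerical and API choices

* Flags are 12-bit masks; encoding/decoding are mutually inverse over all
  4096 values (exhaustively tested). Flag options accept decimal and
  0x-hex.
* The IAF byte layout — individual, region, then the 11 SAM columns and
  tags, tab-joined, LF-terminated, no header — is a convention fixed by
  this package (leading placement keeps records grepable by sample);
  parsing and re-serializing reproduce the bytes exactly, and a malformed
  line is reported with its line number.
* Region labels in IAF are `"all"` when the job had no region constraint:
  self-containment requires a value.
* Chromosome names pass through verbatim (no `chr` normalization).
* `run_scan` validates that every individual in the records appears in the
  manifest — the denominator must be well-defined — and returns an empty
  list when nothing survives.
* Empty inputs yield empty-but-valid outputs everywhere (header-only BAM,
  zero-line IAF, all-zero matrices).

## Limitations

The scan flags *regions of interest*, not calls: no breakpoint resolution,
no genotyping, no comparison against curated structural-variant sets.
Support ≥ 20 is an evidence heuristic tuned for cohort-scale data; on
small cohorts it should be lowered deliberately, not silently. The engine
is single-host by design — the dispatch model (one queue, one task per
file, pluggable sources and sinks) is the part that generalizes, the pool
implementation is not. HTTP/FTP sources are streamed through htslib;
region queries against remote sources require the index to be fetchable,
and are rejected rather than degraded when it is not.
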