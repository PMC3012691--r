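---
title: "Overlap criteria, consensus and novelty screening for array CNV calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap criteria, consensus and novelty screening for array CNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrpipe)
```

## The problem

Copy number variants (CNVs) on SNP genotyping arrays are not observed
directly: they are inferred from per-probe hybridization intensity (the
log2 R ratio, LRR) and allelic intensity ratio (the B-allele frequency,
BAF) by calling algorithms that disagree with each other substantially —
different algorithms applied to the same subjects can differ more than
thirty-fold in the number of events they report. Two methodological
choices then dominate everything downstream: **how two CNVs are declared
to "overlap"** (which drives merging into CNV regions, consensus between
algorithms, and comparison against reference databases), and **which
algorithms must agree** before an event is believed. This package
implements that post-processing machinery as a tested pipeline, with a
synthetic-data generator standing in for subject-level genotype data,
which is never publicly deposited in studies of this kind.

## Coordinate and type conventions

All intervals are 1-based and fully closed: a single base is `[p, p]`,
`size = end - start + 1`, and adjacent intervals (`end + 1 == start`)
share no base. BED input is 0-based half-open and is converted on read.
Only autosomes are handled; sex-chromosome records are dropped at I/O,
as mixed-sex cohort studies report autosomal events only. A
subject-level call is typed `loss` or `gain`, never `both`; `both`
arises only in literature databases (a locus reported as both gained
and lost across individuals) and as the type of a merged region
containing such a record.

## The two overlap criteria

`overlap_criterion()` fixes the rule for a whole run:

* **any** — the intervals share at least one base pair;
* **pct_either** — the shared length is at least a threshold fraction
  (default 0.40) of the size of *at least one* of the two intervals.
  Because the overlap can never exceed the smaller interval, this is
  equivalent to "at least 40% of the smaller CNV". The comparison is
  inclusive (`>=`), reading "at least 40%" literally.

A reciprocal mode (`pct_both`, "40% of each") is exposed for
completeness but is not part of the replication pipelines. Gains are
only ever compared with gains or `both`; losses with losses or `both`.

## Merging into CNV regions

`merge_records()` collapses calls or database records into regions whose
span is the union (minimum start, maximum end) of their members. Under
`any` this is the classic interval union per type. Under `pct_either`
the operation is **not confluent**: as a group's span grows it can newly
pass, or fail, the 40% test against a later record, so the result
depends on the order of agglomeration. We therefore fix a deterministic
schedule: records are sorted by (chromosome, start, end, type, id,
source); each record is tested left to right against the spans of the
groups already formed (single linkage, first qualifying group wins); and
whole passes repeat until the grouping stops changing. The group count
is non-increasing across passes, so a fixed point is guaranteed. The
candidate is always tested against the group's *current union span*,
matching the picture of overlapping CNVs being merged into one widened
CNV; a `linkage = "member"` switch instead takes the transitive closure
of the criterion over the original records, for users who prefer
span-independent grouping. A region is typed `both` exactly when some
member is `both` — gains and losses can only end up in one group via
such a bridging record.

Looser thresholds merge less: the number of regions under
`pct_either(0.40)` is always at least the number under `any`, a pattern
the test suite asserts on every fuzzed input and which matches the
direction seen when published normal-subject databases are merged both
ways.

## Consensus between algorithms

`consensus_calls()` keeps only events reported, with qualifying overlap,
by every algorithm in a required set, within each subject / chromosome /
type. Matching is by connected component of the overlap graph: if one
algorithm splits an event into two calls that both overlap another
algorithm's single call, the component counts once — the wording "the
CNVs had to overlap" does not resolve this case, and components are
deterministic and symmetric; a stricter `matching = "clique"` variant is
provided. The consensus interval is the union span of the component, the
probe count the maximum member count, and components missing any
required source emit nothing. Growing the required set can only shrink
the output, which the tests assert as the two-way/four-way pattern.

## The four-stage novelty flow

`run_novelty_flow()` reproduces the screening cascade used to ask
whether a study discovered anything new:

1. screen all study calls against the merged normals literature
   database;
2. keep only case-subject survivors not present in the study's own
   controls;
3. screen the disease-literature records themselves against the merged
   normals database and merge the survivors;
4. screen the stage-2 survivors against those regions.

Screens are all-or-nothing — one qualifying, type-comparable overlap
eliminates a call, with no interval trimming — and every eliminated call
is blamed on the first eliminating region in (chromosome, start) scan
order. One criterion is used throughout a run; the two published result
sets correspond to two runs. Stage 2 compares case survivors against
*all* control calls of the input set (raw calls, not merged regions and
not only control survivors; the distinction is almost always empty,
because a control call eliminated by the normals database would
typically eliminate the matching case call at stage 1 too).
Database preprocessing (`preprocess_ref_table()`) drops sex-chromosome
records, records under 10 bp, records whose gain/loss observation
counts are both absent or zero (re-deriving the type from the counts
otherwise), and records from excluded studies (by default the `hgdp`
tag, whose subjects had neurological conditions in the source
literature).

Reference tables must arrive in a single genome build; build lift-over
is out of scope.

## The event classifier

The caller applies three rules, in precedence order, to candidate
segments of a subject's LRR/BAF track (first match wins):

| rule                | min probes | min span | signal conditions |
|---------------------|-----------|----------|-------------------|
| homozygous deletion | 3         | 1 kb     | mean LRR < −1 |
| hemizygous deletion | 10        | 1 kb     | mean LRR < −0.25, het proportion < 10% |
| amplification (gain)| 10        | 1 kb     | mean LRR > 0.25, mean \|BAF − 0.5\| at het SNPs > 0.05 |

The heterozygous proportion is computed over called polymorphic
genotypes only (intensity-only `NP` probes carry no genotype and are
excluded from the denominator); a segment with no called polymorphic
probes fails the het-proportion and BAF-deviation conditions (fail
closed). The BAF-deviation condition is read as a *mean* over
heterozygous SNPs rather than a per-probe requirement — the looser and,
in our judgement, intended reading. Span is the probe-span interval
(last position − first position + 1).

Candidate segments come from Viterbi decoding of a sticky Gaussian HMM
over the LRR track. We use **four** states centred at the copy-state
means (−2.0, −0.5, 0, +0.35; shared SD 0.2; self-transition 0.999), not
three: with a single deletion state at −1.0, a hemizygous signal at
−0.5 is exactly equidistant between the deletion and neutral state
means, so noise-free hemizygous implants would be undecidable — a
candidate generator whose states match the signal classes the rules
distinguish removes that degeneracy. All parameters are configurable
(`caller_config()`). Two numerical consequences are worth knowing:
the sticky transition (switch penalty ≈ 8 nats) means a short neutral
gap of up to ~5 probes between two opposite-signed events can be
absorbed into one event's run to save a transition; and candidate runs
are split by direction (low/high), so adjacent deletion and gain events
remain distinct regardless of gap. Segment boundaries on noise-free
tracks are exact, which the tests assert probe-for-probe.

The post-call filters mirror standard practice: minimum size (10 bp,
inclusive), minimum probe count (3/5/10, inclusive), and a confidence
floor housing the Log Bayes Factor (calls below 30 dropped; exactly 30
kept). Calls spanning a centromere are split into one call per arm,
with probe counts recomputed from the track when it is supplied and set
to `NA` (exempt from probe filters, with a warning) otherwise.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 48 cases + 48 controls; all
22 autosomes with 46,875 markers placed uniformly per chromosome
(order-statistic spacings are then exponential-like with the array's
~59 kb mean gap; the published spacing SD of 228 kb reflects a heavier
tail than this model reproduces — a deliberate simplification); 69%
of markers polymorphic; implanted CNVs at 10 per subject (Poisson),
log-uniform sizes 5–500 kb spanning the small-deletion to large-event
range such call sets report, losses twice as common as gains, losses
split evenly between homozygous and hemizygous. The signal model puts
LRR state means at 0 / −0.5 / −2.0 / +0.35 with SD 0.2 and BAF bands at
0/0.5/1 (neutral), 0/1 (hemizygous), uniform noise with genotype `NC`
(homozygous deletion) and 1/3 / 2/3 at heterozygotes (gain) with SD
0.03 — values chosen once so the classifier's thresholds (−1, −0.25,
+0.25, 0.05) sit between state means with comfortable margin, since
per-platform signal parameters are never published. The
pseudo-algorithm panel (four sources with sensitivities 0.95–0.80,
boundary jitter 0–2 probes, Poisson false positives, confidences
uniform on [5, 100] so an LBF-30 filter bites) provides controlled
discordance for consensus and concordance tests; reference databases
cover a configured fraction of the implanted truth exactly, so each
event's fate in the novelty flow is known a priori. Every generator is
a pure function of (config, seed) and restores the session RNG.

What passing tests on this generator do **not** show: robustness to GC
waves, batch effects, genotyping error, population structure in allele
frequencies, or the heavy-tailed marker spacing of a real CNV-enriched
array. The generator's role is to make the *bookkeeping* of the
pipeline — merging, consensus, screening, counting — exactly auditable,
not to imitate raw Illumina data.

## Problem sizes and numerical choices

The analysis scripts run the workflow at a reduced scale chosen for
fast iteration (12 + 12 subjects, chromosomes 1–4, 14,900 markers —
preserving the 59 kb density); the acceptance script uses similar
scales, with 200 implanted fifteen-probe homozygous deletions for the
recall/FDR measurement (noise SD 0.15). Ties in merging are resolved by
the deterministic sort (chromosome, start, end, type, id, source);
region output is sorted the same way. Size classes split at 100 kb with
the boundary in the upper class. Size statistics use the sample SD
(n − 1); the choice is not documented in the table conventions this
mirrors, and sample SD is the field default. Per-person means are
reported at full precision and displayed rounded to one decimal, half
away from zero — `round_half_out(3765 / 96, 1) = 39.2` exactly
reproduces the printed per-person means from printed totals. Degenerate
inputs are defined: empty call sets produce empty, schema-valid
outputs; single-member classes report `NA` SD; a call entirely inside
the centromere vanishes on splitting.

## Known limitations

* The `pct_either` fixed point is schedule-defined; other schedules are
  defensible and can group differently on adversarial inputs. The
  `member` linkage is provided as the schedule-free alternative.
* Segmentation quality is bounded by the simple sticky-HMM smoother;
  real callers use richer models (BAF-informed emissions, distance-
  dependent transitions). Only the classification rules, filters and
  everything downstream are contracts of this package.
* No burden testing (case-control event-count comparison) and no
  molecular-validation bookkeeping.
* Reference-database curation (schema mapping from public downloads) is
  documented but not automated; tests use synthetic databases.
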