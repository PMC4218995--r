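---
title: "Census-based taxonomic profiling: model, parameters and design choices"
author: "microcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-based taxonomic profiling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcensus)
```

## The problem and the estimator

A shotgun metagenome is a pool of *n* short reads drawn from an unknown
mixture of organisms. Mapping all *n* reads to a comprehensive reference is
the accurate but expensive way to estimate the mixture; `microcensus`
instead treats profiling as a survey-sampling problem. It repeatedly draws
small subsamples of *m* ≪ *n* reads, maps only those, and aggregates the
*i* per-iteration profiles ("subagging": subsample aggregating). The
abundance estimate for a clade is the mean of its per-iteration sample
fractions, which equals its total hit count over *m·i* — the pooled
estimator. Because the *i* subsamples are independent draws from the same
pool, the spread of the per-iteration fractions is a direct, assumption-light
measure of the estimator's stability.

Subsampling alone would also report every clade that happens to catch a
stray misaligned read. The census therefore applies a presence filter: a
clade is retained only if it is observed (at least one read) in strictly
more than *p·i* of the *i* iterations. With the defaults *p* = 0.8 and
*i* = 50 a clade must show up in at least 41 of 50 subsamples, which a
rare misalignment essentially never does, while a genuine clade at
proportion *q* does so with the power computed below.

## The perfect-alignment design model

The design calculator (`presenceProbability()`, `detectionPower()`,
`estimationError()`, `simulateDesign()`, `recommendSubsampleSize()`,
`designTable()`) works under an explicit idealization: every sampled read
aligns to its true source organism. Then for a clade at proportion *q*:

* its read count in one iteration is Binomial(*m*, *q*), so per-iteration
  presence is Bernoulli with π = 1 − (1 − *q*)^*m*;
* the number of iterations containing it is X ~ Binomial(*i*, π), and the
  detection power is the exact tail P(X > *p·i*) — the same strict
  boundary the census filter uses, shared through one internal helper so
  the two modules cannot drift apart;
* the pooled estimator is T/(*m·i*) with T ~ Binomial(*m·i*, *q*), and its
  mean absolute error E|T/(*m·i*) − *q*| is computed by full probability
  mass summation (in blocks; beyond *m·i* = 10^7 the function refuses and
  points to the Monte-Carlo route, whose error at that scale is far below
  any planning-relevant resolution).

The model is optimistic in exactly one way: it ignores cross-clade
misalignment between closely related genomes. Power against a reference
with near-identical relatives is therefore an upper bound; the census
filter's robustness to such misalignment is a separate property, exercised
empirically in the tests. `simulateDesign()` also reports the expected
half-width of the implemented abundance interval, since that quantity has
no closed form under the filter.

At the defaults (*i* = 50, *p* = 0.8) the exact calculator gives
`r sprintf("%.4f", detectionPower(0.1, 25, 50)@power)` power at *q* = 10%
with *m* = 25, `r sprintf("%.4f", detectionPower(0.01, 250, 50)@power)` at
*q* = 1% with *m* = 250, and
`recommendSubsampleSize(q = 0.001, i = 50, p = 0.8, targetPower = 0.99)` =
`r recommendSubsampleSize(0.001, 50, 0.8, 0.99)` reads per iteration for
*q* = 0.1%.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `m` | 250 | reads/iteration | > 99% power at 1% abundance; raise to ~2500 for 0.1%, lower to 25–100 if only ≥ 10% clades matter |
| `iterations` (`i`) | 50 | count | at least 50 keeps the presence filter sharp and the across-iteration sd a usable uncertainty; more iterations stabilize, more reads per iteration detect rarer clades |
| `p` | 0.8 | fraction | strict majority rule; higher values filter more aggressively and monotonically never grow the retained set |
| `depth` | 3 | parent hops from root | reporting level of the taxonomy slim; depth 0 is the root |
| `minIdentity` | 90 | % | stringent short-read mapping floor |
| `evalueCutoff` | 1e-6 | — | standard significance floor for nucleotide search |

## Procedure details and numerical choices

**Read picker.** The pool is indexed once into an array of per-record byte
offsets; a subsample is *m* uniform draws over record positions using R's
Mersenne-Twister generator, materialized by seeking. Within one iteration
reads are drawn *without* replacement (a subsample should not count one
read twice); across iterations subsamples are independent and may overlap.
Both behaviours are exposed (`replacement` flag) since either convention is
defensible. Iteration *j* uses the seed
`(seed·69069 + j·1234567) mod (2^31 − 1)`, a fixed linear hash, so each
iteration's draw is independent of execution order.

**Boundary arithmetic.** Retention compares an integer presence count
against *p·i*, which is rarely exact in binary floating point (0.8·50 is
not exactly 40). The shared cutoff helper adds a 1e−9 guard before
flooring, making the strict rule exact for all sensible *p* and *i*. The
boundary itself is strict: presence in exactly *p·i* iterations is
filtered.

**Statistics over iterations.** Min/max/mean/median/sd are computed over
all *i* fractions, with zeros for iterations where the clade was absent.
Restricting to present iterations would bias means upward and disconnect
the census estimate from the pooled estimator analyzed by the design
module. The reported interval is mean ± 1.96·sd across iterations,
truncated to [0, 1] — a deliberate, logged choice (it describes the spread
of a single iteration's estimate; divide by √*i* for a standard error of
the mean if that is what you need). It is recorded in `log.txt` of every
run.

**Best-hit alignment.** The built-in backend is an exhaustive ungapped
scan (in C++): the placement of the full read, on either strand, with the
fewest mismatches over all subjects and offsets, reported only if it meets
the identity floor. Ties break deterministically — lexicographically
smallest subject id, forward strand, leftmost offset — so golden-file
tests are byte-stable. Its e-value is a monotone surrogate of the score,
adequate only for thresholding. The backend is substitution-only by
construction, which exactly matches the synthetic generator's error model;
indels are outside its scope. An external megablast-compatible backend
(probed on PATH at run time, never assumed) handles real gapped data
through the standard 12-column tabular format; on substitution-only
fixtures the two backends select the same subject for ≥ 95% of hit reads,
which the test suite checks.

**Taxonomy.** Trees load from taxdump-dialect `nodes.dmp`/`names.dmp`
files; depth is computed by traversal from the root (the self-parent
node), with orphans and cycles rejected as structure errors. Depth counts
parent hops from the root — the origin is a convention, so the slim level
of a clade can be adjusted only by supplying a pruned tree, not by a flag.
Subject-to-taxid resolution is a local two-column table (accession2taxid
dialect); unmapped subjects resolve to an `NA` sentinel and surface as the
`unresolved` category rather than an error, keeping the conservation
invariant (counts + unaligned + unresolved = *m*) intact. Merged or
deleted taxids are not handled: maps are validated against the tree at
load.

**Host depletion.** For samples dominated by one organism (clinical
samples and the human genome being the canonical case) the census can
first remove reads that align to a host reference — at least 80% of the
read length aligned with at most 10% mismatches of the *aligned* length
(the aligned-length denominator is the documented choice; with the
ungapped backend the two denominators coincide) — and then profile only
the remainder. The removed fraction is logged.

## What the synthetic generator does and does not emulate

`makeReferenceFixture()` + `simulateReads()` produce a community of toy
genomes at fixed proportions (default six components at
0.50/0.20/0.20/0.07/0.02/0.01, 50 bp reads, 1% substitution error,
constant matching Phred qualities, true source recorded in each definition
line). Genomes are uniform-random sequences, rejection-checked so that no
read-length window of one genome aligns to another at ≥ 90% identity. That
makes truth unambiguous and the perfect-alignment model *exactly* realizable
— which is the point: end-to-end tests can compare census output against
known labels with binomial tolerances.

The generator deliberately does not emulate: real inter-genome homology
(so cross-clade misalignment, the design model's stated blind spot, is not
exercised), indels, position-dependent quality profiles, chimeras, or GC
bias. Passing tests therefore demonstrate the sampling, filtering and
aggregation machinery — not robustness to reference databases with
near-identical relatives, which requires marker or pan-genome strategies
downstream of this tool.

Problem sizes used by the shipped tests are the package's chosen
desk-scale study conditions: 1000 bp genomes, 20,000-read pools, censuses
at *m* = 250, *i* = 50, and a 20-seed end-to-end recovery study in which
all six components (the rarest at 1%) must be retained with estimates
within 4·√(q(1−q)/(m·i)) of the realized label composition.

## Known limitations

* The naive backend is exhaustive; it is meant for fixture-scale
  references (kilobases to a few megabases), not for nt-scale databases —
  use the external backend there.
* Gapped alignment, paired-end awareness and quality trimming are out of
  scope; FASTQ input must be strict 4-line records.
* The abundance interval is a normal approximation across iterations; with
  very few iterations it can be too narrow, which is one more reason the
  default is *i* = 50.
* Rank-based slims (species/genus) are not supported; the slim is purely
  depth-based.
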