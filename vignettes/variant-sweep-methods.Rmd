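---
title: "Sweep-line integration of variant lists with whole-genome feature tracks"
author: "VariantSweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep-line integration of variant lists with whole-genome feature tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantSweep)
```

## The problem

Genome-wide experiments routinely report hundreds of thousands to millions
of loci at which a sample differs from the reference genome. Deciding which
of those variants deserve follow-up means crossing the list with many
whole-genome feature tracks — open chromatin, histone-mark signal,
transcription-factor binding, conservation, catalogs of known variants —
and asking, for each variant, what lies at or near its position. Two costs
dominate at this scale: moving the variant list around, and joining it with
tens of tracks that each hold hundreds of thousands of intervals.
VariantSweep addresses both with a compact location codec and a pair of
linear-time sort-merge (sweep-line) joins over pre-sorted data.

## Coordinates and variant classification

Internally everything is 0-based with half-open intervals `[start, end)`,
the BED convention; VCF and whitespace-delimited inputs are 1-based and
converted on parse. Each variant is reduced to one representative point:

* SNV, insertion, point-only record: the exact location, `pos - 1`;
* deletion whose REF spans `[s, s + L)`: the mid-point
  `floor((s + s + L - 1) / 2)`.

The floor makes the mid-point deterministic for even-length spans; any
fixed tie-break would do, but it must be fixed for results to be
reproducible. Records with equal-length REF and ALT longer than one base
(multi-nucleotide substitutions) are treated like SNVs at their first
base. Only the first ALT of a multi-allelic VCF record is used; the
remaining alternates are ignored rather than split into extra records.

A variant's point occupies `[p, p + 1)`, and its flanking window at flank
`w` is `[max(0, p - w), p + w + 1)`. `w` is *per side* — "a 100 bp
window" here means 100 bp of context on each side — and is capped at
1 Mb, the distance beyond which flanking context stops being a useful
proxy for genetic linkage. Windows are clipped at zero but not at the
chromosome's right end: overhang past the last feature region cannot
create or destroy overlaps, so chromosome lengths are not needed at join
time.

## The location codec

For transfer, a variant list is reduced to its (chromosome, point) pairs:
per chromosome, the first point is stored absolute and each subsequent
point as a non-negative delta, both as unsigned LEB128 varints. Sorting
makes the deltas small — for 3 million uniform variants on a human-scale
genome the mean intra-chromosome gap is about 1 kb, which fits in two
varint bytes — so the whole payload lands under 6 MB, roughly 6 % of the
50 MB envelope the design targets for 3 million variants. The layout
(magic `VASC`, version byte, chromosome count, then per chromosome a name,
a count and the varints) is deterministic byte for byte, and decoding is
the exact inverse on locations. The codec deliberately keeps nothing but
locations: alleles, genotypes and INFO fields do not survive compression.
Duplicate loci are retained; deduplication happens only where a report
asks for unique loci.

## The feature store

Each feature track is persisted sorted by (chromosome, start, end) in a
fixed-width binary record file. A directory at the head of the file maps
every chromosome name to the byte offset of its first record, so a scan of
chromosome 17 seeks there directly instead of reading past sixteen other
chromosomes; tests verify the access pattern through the offsets and
record counts the scan reports. Pointers are chromosome-level only;
finer-grained intra-chromosome bins would cut seek-to-first-hit latency
for sparse queries but add nothing to the full-chromosome scans the joins
perform, so they are left as an extension. Overlapping and nested regions
are stored as imported — real tracks overlap, and merging would corrupt
per-region values. Numeric values are held as 32-bit floats (tracks of
signal values do not carry more precision in practice), and a footer keeps
the sorted array of all region values for percentile lookups. At the
scales this package targets the exact sorted array is affordable; a
quantile sketch would only be worth its complexity if stores grew far
beyond desk scale, and would be acceptable only within ±0.1 percentile of
exact.

## The two joins

Both integration modes are sort-merge sweeps over one chromosome at a
time. Events are processed in coordinate order with a fixed priority at
ties — region end, then window end, then region start, then variant point
or window start — which encodes the half-open convention directly: a
region ending at `c` is gone before anything starting at `c` is
considered, and a region starting at `c` is open before a variant point
at `c` is annotated.

*Exact-location join*: at a region start, the region joins the feature
queue; at its end it leaves; at a variant point, the variant is annotated
with everything currently in the queue.

*Flanking-window join*: windows behave like intervals too. At a window
start the variant joins the variant queue and picks up all open regions;
at a region start the region picks up all open windows. Each (variant,
region) pair is therefore discovered exactly once — by whichever of the
two intervals opens second — so no deduplication pass is needed.

The "queues" are identity-keyed active sets with O(1) insert and
remove-by-identity, not FIFO queues: nested regions close in a different
order than they opened, so removal must name the region it removes. Each
region enters and leaves its active set exactly once per join (and each
variant likewise in the windowed join); the implementation counts
insertions and removals and the tests assert the counts equal the input
sizes exactly, which pins the linear-pass claim independently of wall
clocks. A quadratic all-pairs oracle (`bruteForceJoin`) provides the
correctness reference in the test suite, alongside an independent
cross-check against `GenomicRanges::findOverlaps`.

Unsorted region input is detected during the scan and rejected rather
than silently repaired; sortedness is the contract the store guarantees.
Chromosome names are normalized to the `chr`-prefixed form on both sides
before matching, since mixed naming conventions are the most common cause
of silently empty joins.

## Summaries and the report

For a numeric feature, the regions overlapping a variant (or its window)
are summarized by their unweighted arithmetic mean `m` — the plainest
reading of "average feature value around the variant"; a base-pair-
weighted mean would emphasize long regions and is noted as an alternative
rather than implemented. The mean is then placed among all of the
feature's region values genome-wide by the mid-rank percentile

\[ p = 100 \cdot \frac{C_{<} + 0.5\,C_{=}}{N} \]

with `C_<` values strictly below `m`, `C_=` values equal to it, and `N`
the total region count. Mid-ranking is symmetric, bounded in `[0, 100]`,
handles ties, and is strictly increasing over distinct values. For a
categorical feature the report carries the distinct labels of the
overlapping regions instead.

The report has one row per input variant, in input order, and one column
group (count, value, percentile) per feature, in selection order. Variants
with no overlap anywhere still appear as rows of blanks — a dropped row
and an un-annotated row must be distinguishable. Output is plain TSV,
byte-deterministic for identical inputs; spreadsheet export is declined
with a configuration error since any spreadsheet program imports TSV
directly. Each job can carry a 512-bit identifier drawn from the operating
system's cryptographic entropy source (identifiers gate access to results,
so a weak generator is refused outright rather than substituted).

## What the synthetic data emulates — and what it does not

The generators exist so every claim in the test suite can be exercised
without downloading anything:

* `hg19GenomeModel()` reproduces the 24 nuclear chromosome lengths of
  hg19 (~3.1 Gb). Size claims about the codec depend on coordinate
  magnitudes and gap sizes, so the size experiment runs at true human
  scale: 3,000,000 variants, the largest list the design targets.
* `simulateVariants()` places points uniformly, chromosomes weighted by
  length. Real variant lists cluster (genes, mutational hotspots, LD);
  clustering only shrinks deltas, so uniform placement is the
  conservative case for compression claims.
* `simulateFeature()` draws region lengths and values uniformly and lets
  regions overlap and nest. No attempt is made to imitate ENCODE-like
  signal autocorrelation, peak shapes, or allele-frequency structure.
* `plantedInstance()` lays out non-interacting slots with known overlaps
  and known non-overlaps (separation greater than `w` plus the maximum
  region length), so the expected pair set is known by construction, not
  by running any join.

Passing tests on these inputs demonstrates algorithmic correctness —
overlap semantics, tie rules, linearity, codec exactness — on interval
configurations that include the adversarial cases (nesting, duplicates,
shared endpoints). They do not demonstrate anything about biological
signal: a real track's value distribution, and hence the meaning of a
percentile, is whatever the user's track makes it.

One bundled fixture is real: the 31 printed variant rows from five
published personal genomes (`pgpExampleVariants()`), which collapse to 21
unique loci and drive the worked example in the README. The feature store
used alongside them is synthetic (one width-1 region per locus) and is
named accordingly; it stands in for curated disease-variant tracks that
are not redistributable.

## Verification scale and numerical choices

The suite verifies oracle equivalence on 100 seeded instances of 1,000
variants × 500 regions at flanks of 0, 10 and 1,000 bp, chosen to keep
hundreds of active-set interactions per instance while the brute-force
oracle stays fast; codec round-trips run over 100 seeded lists on both
toy and human-scale genomes. The soft scaling check times the sweep at
200,000 and 400,000 inputs and asserts the doubling stays under 3× —
event sorting is O(n log n), so the expected ratio is just above 2;
anything approaching 4× would indicate accidental quadratic behavior.
Wall-clock comparisons against other tools are explicitly out of scope:
they measure hardware, not algorithms.

Remaining numerical conventions, fixed once: chromosome blocks are
ordered lexicographically by name everywhere (only consistency matters to
the sweep, not the particular order); megabyte means 10^6 bytes in all
size reporting; numeric cells are written with up to 15 significant
digits so TSV round-trips reproduce doubles exactly.

## Limitations

* Coordinates are capped at 2^31 − 1 by the store's u32 record fields and
  R's integer type — ample for any human chromosome (< 2.5 × 10^8) but
  not for concatenated or polyploid-genome coordinate schemes.
* The store is uncompressed and unversioned beyond its format byte;
  bigWig/bigBed/tabix inputs must be converted to BED-style text
  upstream.
* Multi-allelic VCF records contribute only their first alternate.
* The windowed mean is unweighted; regions barely clipped by a window
  count as fully as regions centered on it.
* Percentiles compare a variant's *mean* against *single-region* values;
  with very wide windows the mean of many regions is less extreme than
  any single region, which compresses percentiles toward the middle.
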