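---
title: "Local haplotagging of long reads: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local haplotagging of long reads: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotagr)
```

## The problem

A diploid genome carries two haplotypes. Long reads (PacBio HiFi at
roughly 0.1–1% error, ONT at 2–5%) each come from one of them, and many
downstream analyses — small-variant calling above all — improve when each
read is labelled with its haplotype (an `HP` tag of 1 or 2) together with
a phase-set identifier (`PS`) naming the block within which those labels
are internally consistent. `haplotagr` produces such labels directly from
a coordinate-sorted BAM and a reference FASTA, with no variant calls as
input: it is a *local approximation* to read-backed phasing, trading
chromosome-scale phase blocks for speed and simplicity.

## The model

**Candidate sites.** A pileup column is a candidate heterozygous site when
at least one non-reference base passes: minimum alternate read count
(default 2), alternate allele fraction within
`[min_alt_fraction, 1 - min_alt_fraction]`, minimum base quality (10 —
failing bases are ignored entirely), minimum mapping quality (5,
primary alignments only). Only SNVs are considered: indel alleles would
entangle candidate detection with alignment dialects while contributing
the same kind of linkage evidence, and left-alignment ambiguity makes
exact string matching fragile. Up to `max_alleles` (4) alleles are kept
per site, dropping the weakest alternates first, since the dynamic
program is quartic in alleles per site.

**The allele graph.** Within an interval, sites are ranked 1..N by
position (the DP runs on ranks; base-pair positions only matter for
chunking and for `PS` anchors). Every allele at every site is a vertex;
an edge joins an allele at site n−1 to an allele at site n when at least
one read is observed at both. Each vertex stores its supporting read set
and its *fresh* reads — reads whose first overlapped site is n, which
carry new evidence not represented on any incoming edge. A read with a
dropout (deletion, masked base, third allele) at an intermediate site
simply lacks an observation there and contributes linkage only between
consecutively observed site ranks.

**Scoring.** For an ordered allele pair (i, j) at site n — i on phase-1,
j on phase-2; the diagonal i = j is legal so that effectively homozygous
sites pass through without splitting the block — the score is the exact
integer count of reads consistent with the best assignment ending there.
Block starts initialize `S(i, j)` to the size of the union of the two
support sets; later sites extend the best predecessor pair over existing
edges, adding the union of the two spanning-read sets and the fresh reads
of both current vertices. Because the initialization is symmetric in
(i, j) and labels within a block are arbitrary, block-start sites
materialize only the i ≤ j triangle; every ordered pair is materialized
from the second site of a block onward, and the recursion ranges over the
stored predecessor cells. Any optimal ordered path mirrors into this
convention, so no optimality is lost — the suite's exhaustive-enumeration
oracle (`brute_force_phase()`, which enumerates all pair sequences under
the same edge semantics) confirms equality on 100+ random instances.

**Degenerate connectivity.** A vertex with no incoming edge is connected
to all previous-site vertices by *artificial edges* that contribute empty
read sets — they keep the recursion defined without inventing evidence.
If no vertex at a site has a real incoming edge, the phasing cannot be
extended: scores reinitialize and a new phase block begins, anchored (for
`PS`) at the 1-based position of its first site. Ties in the recursion
max break toward the smallest predecessor pair (k, l); backtracking picks
the maximal final-site cell, ties toward the smallest (i, j). Both rules
exist purely to make output deterministic.

**Read tagging.** Each read votes with the phased alleles it overlaps:
an observation of the phase-1 allele at a site is one phase-1 vote, and
likewise for phase-2; observations of unphased alleles (a dropped third
allele, or a site where both slots hold the same allele) contribute
nothing. A strict majority sets the tag; ties — including the common
1-vs-1 case of a read spanning exactly two discordant sites — and empty
votes leave the read untagged. Because labels are only comparable within
a block, a read votes only in the single block containing most of its
observations (ties toward the earlier block).

**Chunking and merging.** Contigs are tiled into 25 kb chunks, each
processed on a window extended by 5 kb on both sides. A chunk emits tags
for reads whose leftmost aligned base falls in `[start − margin, end)`,
so reads starting inside the left margin are deliberately emitted by two
neighbouring chunks: these shared reads are the evidence the merge uses.
Walking chunks left to right, a chunk's labels are flipped wholesale when
the majority of its shared reads disagree with the running merge — the
unique order-independent rule that uses only information the chunks
already emit. A read tagged by several chunks keeps the record with the
larger vote total (more of the read's sites were visible to that chunk);
if totals tie and tags still conflict after flipping, the read is
untagged. Merging is idempotent and equivariant under global label swaps;
with `merge = FALSE` chunks keep their own orientations, which the
switch-aware evaluator treats identically because phase sets remain
per-block either way.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `chunk_size` | 25000 | bp | locality scale of the approximation; blocks never cross chunks |
| `overlap_margin` | 5000 | bp | boundary-read sharing for merge reconciliation |
| `min_alt_count` | 2 | reads | permissive floor for calling a column a candidate |
| `min_alt_fraction` | 0.12 (module) / 0.25 (pipeline) | fraction | see below |
| `min_baseq` | 10 | phred | drop uninformative bases before counting |
| `min_mapq` | 5 | phred | drop ambiguous alignments |
| `max_alleles` | 4 | alleles | DP cost is quartic per site |

The two allele-fraction defaults are deliberate. `find_candidates()`
keeps a permissive 0.12, the right contract for a module whose consumers
may genotype candidates downstream. The phasing pipeline
(`run_haplotag()`, CLI `tag`) tightens it to 0.25 — alternate fraction
within [0.25, 0.75] — because phasing wants sites whose allele balance is
*plausibly heterozygous*. At 30x, a true het site leaves that window with
probability below 0.3%, while a column driven by recurrent sequencing
errors essentially never reaches a 25% minor fraction at either HiFi or
ONT error rates. Skewed sites are worse than uninformative here: the
score prefers to route both phase chains through the dominant allele (the
homozygous diagonal), a pass-through that carries no linkage, after which
the relative orientation of the two block halves is an exact tie decided
by the deterministic tie-break — a coin-flip switch error in disguise.
Filtering to balanced sites is the same practice read-backed phasers and
genotype-aware taggers follow before phasing.

## The simulator: what it emulates, and what it does not

`simulate_diploid()` draws a uniform-random reference, plants
heterozygous SNVs at 1 per kb (each alternate allele assigned to one
haplotype fairly), and samples reads of lognormal length (mean 18 kb,
sdlog 0.3 — HiFi-like; the ONT preset uses 30 kb and 3% error) uniformly
along the genome, each from a fairly chosen haplotype, with i.i.d.
substitution errors at the configured rate and base qualities calibrated
to it. It emits a FASTA, a sorted+indexed BAM with reads placed at their
known positions (substitution-only errors make alignment exact by
construction), a truth table, and — alternatively — a direct
read-observation table that feeds the graph with no alignment file at
all; the two routes produce identical observations, which the suite
asserts.

It does **not** emulate: indel errors (so candidate detection is never
stressed by gap placement), basecaller-realistic quality profiles
(qualities are flat at the phred of the error rate, so the base-quality
filter is exercised only by explicit tests), coverage biases, chimeras,
or mapping ambiguity (every read is a primary alignment at its true
locus, MAPQ 60). Passing the end-to-end tests therefore demonstrates the
phasing machinery under clean alignment conditions, not robustness to
alignment artefacts — on real data the mapping-quality and base-quality
filters carry weight that the simulator cannot measure.

Problem sizes in the test-suite and acceptance runs were chosen to keep
each end-to-end scenario in the tens of seconds: 200 kb at 30x for the
platform-accuracy checks (about 200 het sites, 330 reads), 75 kb for the
chunk-merge property, 30–40 kb for module-level fixtures. Accuracy at
these scales is already dominated by the per-site and per-read error
processes rather than genome length.

## Numerical and degenerate-input choices

Scores are integers throughout — set cardinalities added along paths —
so there is no floating-point tolerance anywhere in the DP. Zero-coverage
regions, empty candidate lists and empty graphs all produce empty (not
failing) results. A site whose every allele lacks support initializes to
all-zero scores. Duplicate (read, site) observations are rejected loudly,
naming the read, since they indicate an upstream extraction bug rather
than data noise. Ordered cells a block-start triangle cannot reach stay
unmaterialized rather than defaulting to zero, so an impossible state can
never win a max. The evaluator reports both normalizations — correct
over compared, and correct over truth-tagged (untagged predictions
counting against) — because which one a published accuracy figure uses is
often unstated; it reports `NA`, not 100, when nothing is comparable.

## Known limitations

Phase blocks never exceed a chunk, by design: this is a local method, and
N50-style phasing metrics are out of scope. Votes are unweighted counts,
matching the method's integer arithmetic; base qualities gate observation
admission but do not weight votes. Indel candidates are excluded by
default and, when enabled upstream representations differ, exact string
matching may under-link. Cross-chunk reads keep a single block's phase
set; a read genuinely split across two blocks reports votes only from its
home block. The merge's flip rule needs shared reads — chunks separated
by a coverage gap wider than the margin merge trivially as independent
phase sets, which is the correct, if modest, behaviour.
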