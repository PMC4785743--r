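---
title: "Calibrated identity thresholds for multi-rank OTU annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated identity thresholds for multi-rank OTU annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprofiler)
```

## The problem

Amplicon metabarcoding of microbial phototrophs — here modelled on a
375-bp tufA metabarcode — produces OTUs that must be annotated against a
reference database by best-hit percent identity. A single universal cutoff
is indefensible: clades at different ranks are cohesive at very different
identity levels, and those levels are a property of the marker and the
database, not a constant of nature. This package treats the per-rank
cutoffs as quantities to be *calibrated* from the annotated reference
alignment itself, and builds the surrounding pipeline (read processing,
dual OTU clustering, abundance profiling) so the calibrated thresholds can
be applied end to end.

## The calibration model

Let `PI(x, y)` be the percent identity between two aligned records,
computed over columns where both carry a non-gap, non-missing character
(pairwise deletion). Records with more than 20 bp of gap/missing data at
either alignment end are excluded first: with pairwise deletion, a heavily
truncated record is compared over a short, biased set of columns and its
identities are inflated. The bound is strict (`> 20` excludes; exactly 20
is kept). Ambiguity codes match when their base sets intersect (W matches
A); a strict mode is available for data where ambiguity codes should count
against identity.

At a rank `r`, every pair of records resolved at `r` is either
*intra-clade* (same label) or *inter-clade* (different labels). Two
threshold families are derived:

* **Conservative**: `raw = max(inter-clade PI)`. Since every cross-clade
  pair sits at or below this value, a best hit whose identity is strictly
  above it must share the query's clade at `r`. Rounding *up* to the
  integer threshold preserves the guarantee (every inter-clade identity is
  `<= raw <= ceiling(raw)`, and annotation requires identity
  `>= ceiling(raw)`).
* **Relaxed**: each record is queried leave-one-out against the rest; its
  best hit is scored correct or incorrect at `r` by label equality;
  `raw = max(PI of incorrect best hits)`. Above this value no best hit was
  empirically misclassified. When every best hit is correct the threshold
  is *unbounded below* and reported as such together with the minimum
  correct-hit identity — a sentinel, not a zero.

The per-rank intra/inter distributions are allowed to overlap, and the
conservative threshold at a high rank may exceed a lower rank's — rank
non-monotonicity is a genuine property of marker databases, so the code
records it rather than asserting it away. The only invariant enforced is
internal: every inter-clade identity is at most its rank's raw threshold.

High ranks (domain, phylum, class) are calibrated on the full record set;
low ranks (order, suborder, family) on a configurable clade subset,
mirroring how such databases are dense only within a focal class. Where a
rank has a single clade in scope, its inter-clade distribution is empty
and the threshold is reported `NA` with a diagnostic flag rather than
fabricated.

**Open design points, and what was chosen.** Whether printed thresholds of
this kind derive from the maximum inter-clade identity or the minimum
intra-clade identity cannot be decided from threshold values alone; this
package computes both (the minimum intra-clade identity is reported as
`min_intra`) and uses max-inter as the operative definition, because it is
the only reading under which "identity above threshold implies same clade"
actually holds. Best-hit ties at equal identity with conflicting taxonomy
are resolved toward the majority lineage of the tied hits, falling back to
`UNRESOLVED` at ranks where no majority exists. Internal alignment gaps are
treated as missing (pairwise deletion) rather than mismatches, consistent
with the end-missing exclusion rationale; a flag on `percent_identity()`
exposes the strict alternative for ambiguity codes.

## Annotation

`annotate_otu()` finds the best-identity reference by exhaustive global
alignment (Needleman-Wunsch via Biostrings, match +1 / mismatch -1, gap
opening 5, extension 2 — k-mer prefilters are treated as optimizations
that must never change the argmax, so the default is exhaustive). The
threshold set is walked deepest-first: the OTU inherits the hit's labels
down to the deepest rank whose threshold is at or below the best-hit
identity; deeper ranks stay `UNRESOLVED`. Species assignment is handled by
its own identity band (default `>= 97.87 %`, i.e. at most 8 substitutions
over 375 bp; the corresponding 1-2-substitution bound 99.47 % is the
stricter alternative), because species boundaries on this marker sit far
above any clade threshold.

## The processing chain and its one-off traps

Stage defaults follow the standard run: expected error
`E = sum(10^(-Q/10))` with *exclusion* rule `E > 0.5` (a read exactly at
0.5 is kept); size window 400-440 bp with both bounds inclusive; 20 bp
5'-crop and 50 bp 3'-crop applied after size selection; dereplication with
deterministic ordering (decreasing abundance, ties lexicographic);
denoising removes dataset-wide totals `<= 3` (singletons through
tripletons); demultiplexing tolerates zero index mismatches (an index
error is indistinguishable from tag hopping) and one primer mismatch.
These boundary semantics are each a one-off-error trap and are pinned by
dedicated tests.

Merging resolves overlap conflicts toward the higher-quality base and
keeps the maximum quality on agreement — common practice where the
upstream tools specify nothing. The chimera screen is a reference-based
bimera model: parents are pre-screened by shared 8-mers, and an amplicon
is flagged when the best two-parent splice both gains >= 3 identity points
over any single parent and itself reaches 99 % — parameters exposed in the
run configuration, chosen as sensible defaults rather than inherited
constants. The contaminant screen keeps amplicons with a local alignment
of >= 60 % identity over >= 50 % coverage against any reference.

Dual clustering: the global algorithm is greedy centroid clustering at
97 % (each amplicon joins the best-identity qualifying centroid, ties to
the more abundant one, else founds an OTU); the local algorithm grows
swarms by `d`-step Levenshtein agglomeration (Levenshtein, not Hamming,
because trimmed amplicons may vary in length), whose partition equals the
connected components of the `<= d` graph. An OTU is **core** when its
global centroid is also a local seed (exact sequence match) — the
narrowest defensible reading of producing an OTU "concordantly"; a
member-set Jaccard >= 0.5 criterion is available behind a flag because the
choice is genuinely open. Read mapping back onto core OTUs uses the same
97 % identity, and abundance cells with fewer than 3 reads are zeroed
(reported as a separate "corrected" tally), since isolated 1-2 read cells
are indistinguishable from index hopping.

## What the synthetic generator emulates — and what it does not

`sim_config()` defines the simulated study conditions: a clade hierarchy
(default 2 domains x 2 phyla x 2 classes x 1 order x 2 suborders x 2
families x 3 species = 96 records) evolved by copy-with-substitution from
a random 445-bp template (20 bp 5' pad + 375-bp metabarcode + 50 bp 3'
pad, so global trimming recovers exactly the metabarcode), with per-rank
substitution counts of 110/80/50/35/24/14/2 from domain to species over
the metabarcode. The species band (2 substitutions) deliberately sits
below the 97 % clustering radius (~11 bp), mirroring the finding that
species boundaries on this marker (1-8 substitutions) are finer than OTU
resolution; pipeline-recovery tests therefore use a separable plan
(species >= 8 substitutions) when they assert exact species recovery.
Reads default to 2 x 250 bp pairs at constant Q35 with a 0.1 % per-base
substitution error rate, four samples of 200 reads with 1/rank community
weights (few dominant species, long tail), 8-bp indexes and a 23-bp
degenerate forward primer; chimera and contaminant injection are off
unless enabled.

Realized divergences are what the manifest records — substitutions
collide, so tests compare against realized, not nominal, values. The
generator does not model indels by default (so Hamming equals Levenshtein
on fixtures; an alignment-exercising path uses explicit gapped fixtures
instead), nor PCR amplification bias, chimera formation kinetics, or
quality-score decay along the read. Passing tests on these fixtures
therefore demonstrate the correctness of the algorithms under controlled
divergence structure, not robustness to every artefact of real sequencing
chemistry.

## Numerical choices and degenerate inputs

Identity values are kept at full precision internally and printed at 2 dp;
thresholds are rounded up, never half-up. Substitution/identity
conversions round half-up at 2 dp (`subs_to_identity(8, 375) = 97.87`).
All orderings are total (abundance, then lexicographic) so every stage is
bit-reproducible; reruns under a fixed seed are asserted identical down to
the abundance matrix. Zero-overlap pairs, empty FASTQ input, single-clade
ranks, all-correct leave-one-out hits, and amplicons with no shared k-mers
each take a defined path (tallied drop, zero ledger, `NA` + flag,
unbounded sentinel, unflagged) rather than erroring mid-pipeline; the two
genuine configuration errors — crops that would consume the minimum read
length, duplicate sample indexes — fail before any stage runs.

The barcode-gap partitioner is labelled *simplified* in its outputs: it
scans log-spaced intraspecific priors (0.001-1, 100 steps), splits by
single linkage at the first distance gap above the prior wider than half
the prior, recurses within groups, and returns the partition stable over
the widest prior range preferring any split over the trivial single group.
It uses uncorrected p-distances and none of the model corrections of the
full method it stands in for; its species counts on real data should be
read accordingly.

## Problem sizes

The bundled tests and the acceptance script run on deliberately small
problems — tens to a few hundred reads, reference databases of 4-100
records, 20-seed parameter-recovery sweeps — chosen so the full suite
documents the algorithms' guarantees (exact species recovery on a clean
channel, 3-SE recovery of planted community proportions, oracle equality
for both clustering algorithms, exact threshold recovery across seeds) at
desk scale. Nothing in the implementation is specific to these sizes; the
identity-matrix and best-hit searches are quadratic and exhaustive by
design, so very large databases would want the (argmax-preserving) k-mer
prefilter before the alignment stage.

## Known limitations

Alignments are inputs: the package computes no multiple sequence
alignment. Melting temperature is reported by the Wallace rule for
orientation only and excluded from validated metrics, since no simple
formula reproduces published Tm values for degenerate primers. The
relaxed/conservative threshold pair can invert on unusual databases
(relaxed above conservative); this is recorded, not corrected. Tag-jump
mitigation and error-model denoising are out of scope — denoising here is
purely abundance-based.
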