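---
title: "Models and methods behind metalag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metalag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long-read metagenomics of under-sampled habitats can reveal bacterial
clades that short-read assembly never showed — and, in the hardest case,
clades that *no* assembly shows, because the population's internal
nucleotide diversity (strain clouds differing at several percent of
sites) breaks the overlap consistency every assembler relies on. The
analysis route `metalag` implements recovers and quantifies such
populations from the reads themselves: marker genes betray the clade,
seeded read binning collects its reads, fragment recruitment and ANIr
measure its abundance and diversity, and standard binning/QC machinery
handles everything that *does* assemble.

Every step is exercised end-to-end on synthetic communities with complete
ground truth, so the package's claims about recovery are measured, not
asserted.

# The synthetic-community model

`generate_genome()` samples a genome from an **order-3 Markov chain**
whose 64 x 4 transition table is drawn (Dirichlet, unit shape) from a
per-genome `signature_seed`, then rescaled so that the chain's stationary
GC equals `gc_target`: the G and C columns are reweighted by a common
factor solved with `uniroot()` on the stationary distribution of the
64-state chain. This gives each genome a *distinct, stable
tetranucleotide signature* — the property the composition-based binning
steps rely on — while pinning GC anywhere in [0.25, 0.75]. For genomes of
50 kb and longer the realised GC is within ±0.01 of the target (binomial
fluctuation ~0.002–0.003 at that length).

**Populations** are modelled by `diversify_population()`: each strain
receives Binomial(L, d) substitutions at uniformly chosen sites,
independently per strain. Substitutions only — no indels — so strains
stay length-aligned with the parent, and every test oracle (identity of
a read to its source, expected ANIr) reduces to counting mismatches.
Two strains then differ at ≈ 2d of sites for small d. The per-site rate
d is capped at 0.05, the regime in which "unassemblable" populations
live.

**Reads.** Long mode draws lengths from a normal truncated at
`min_length` (defaults: mean 14.3 kb, sd 5 kb, min 3 kb — the CCS-like
regime, where the mean is the one summary statistic the motivating data
report; the spread and floor are stated defaults, not claims). Start
positions are uniform; on circular replicons a read may span the origin
(the truth interval is recorded with `end` past the genome length), on
linear genomes starts are drawn from the valid range so reads are
truncated only when longer than the genome (then flagged). Short mode
emits 150 bp pairs from normal-insert fragments. The error process —
applied after extraction — is a per-base rate split 80/20 between
substitutions and length-preserving small indels (a deletion paired with
an insertion elsewhere), keeping read lengths exact while still
exercising gapped alignment; defaults are 0.5% (long) and 0.1% (short),
so the pipeline's 95–99% identity gates remain meaningful. No
quality-value simulation and no chimeras: tests that pass here say the
*method logic* is right, not that real instrument artefacts are handled.

Every read carries a truth-table row (source genome, strain, 0-based
half-open interval, strand), and identical specs + seeds reproduce
byte-identical FASTA — both are tested invariants.

# The alignment engine

All identity/length thresholds in the package run through one
seed-and-extend local aligner (C++): k-mer anchors from a sorted flat
index, diagonal clustering, longest-increasing-subsequence chaining,
affine-gap alignment of inter-anchor gaps, and banded x-drop terminal
extension. Scoring is match +1 / mismatch −2, gap open 5 / extend 2, and
**identity is matches / alignment columns with gaps counted as columns**
— the convention behind every published threshold the pipeline encodes
(95/50, 99/50, 97, 99/1000, 80/50, 95/250).

Numerical and design choices:

* Seed size k = 15 for contracts at >= 90% identity, k = 11 below
  (ANIr's 80% gate, marker search); at the stated minimum lengths the
  probability that a true alignment yields no seed is far below 1e-3.
  Query seeds are sampled with a stride chosen so that an exact stretch
  of max(min_len, 2k) bases still yields the required anchors.
* Repeat-induced anchors on slightly shifted diagonals are pruned when
  sandwiched between colinear neighbours, so exact repeats do not
  acquire spurious indels (self-ANI is exactly 100 because of this).
* Inter-anchor gaps larger than 400 bases split the chain; at the
  divergences the pipeline operates on (<= 5% + read error), true anchor
  gaps are one to two orders of magnitude smaller.
* `best_hit` ties are broken by higher identity, then lexicographically
  smallest subject id, then smallest subject start — recruitment counts
  are reproducible run-to-run by construction.
* Tests compare the engine against a full dynamic-programming local
  aligner (`Biostrings::pairwiseAlignment`) on sequences up to 2 kb:
  identity must agree within 0.5 points and intervals within ±5 bases,
  except where the engine returns a co-optimal alignment (equal or
  better score with shifted endpoints), which the oracle cannot
  distinguish either.

The practical sensitivity floor of a seeded nucleotide aligner is well
above the nominal 30% identity retention gate in fragment ANI: distant
genome pairs simply return no retained fragments ("missing", as the ANI
convention intends). Every use the pipeline makes of ANI operates at
>= 90%.

# Composition, ordination, and their conventions

Tetranucleotide (contigs) and trinucleotide (reads) frequencies are
counted with `Biostrings::oligonucleotideFrequency`; windows containing
ambiguity codes are skipped rather than recoded, avoiding composition
bias near masked regions. **Canonical (strand-merged) counting is the
default** because reads arrive from both strands and profiles must be
strand-symmetric to be comparable; the strand-naive mode is retained for
strict reproduction of wordfreq-style counting, and the choice is a
flag. PCA is done on the frequencies directly (no log-ratio transform):
that matches the procedure the pipeline reproduces; component signs are
fixed (largest-magnitude loading positive) for determinism. PCoA is the
classic double-centering of −D²/2 with negative eigenvalues dropped and
reported; on Euclidean inputs it reproduces inter-point distances to
1e-6 (tested), and `stats::cmdscale` serves as a cross-check.

# Binning

**Contig binning** follows the published recipe's feature set —
taxonomy, tetranucleotide PCA, GC, differential coverage — but the
original procedure was human-curated; the automated surrogate here is a
deterministic neighbourhood-radius (density) clustering within each
taxonomy stratum. Features are blocks: top-3 tetranucleotide PCs, GC,
and log10(RPKG + 0.1) per metagenome (RPKG spans orders of magnitude,
hence the log; 0.1 keeps zeros finite). Each block is centred and scaled
by its *leading column's* spread rather than per-column z-scored:
z-scoring every column would inflate pure-noise dimensions (minor PCs,
uninformative metagenomes) to the same weight as signal, which
measurably breaks the benchmark. Within a stratum, contigs closer than
`eps_mult` (default 2.5) times the median nearest-neighbour distance are
linked, and connected components become bins; unclassified contigs are
attached to the nearest cluster within its 95th-percentile internal
radius, else left unbinned. On the five-genome benchmark (distinct
signatures, GC 35–65%, three differential-coverage metagenomes, contigs
5–50 kb) the assignment reaches adjusted Rand index 1.0; two genomes
constructed to be indistinguishable (same signature seed, GC and
coverage) merge into one bin — the documented failure mode of any
composition + coverage method.

**Seeded read binning** mirrors reference-free long-read binners that
cluster on composition + coverage, with the marker-bearing reads as
seeds: (1) reads matching known genomes at >= 97% identity over half
their length are removed; (2) each read gets trinucleotide PCs
(block-scaled) plus a coverage term — log10 of the read's median 15-mer
multiplicity across the read set, centred but *not* rescaled, so a
10-fold depth difference weighs like the full composition spread and a
small one weighs little; (3) seeds closer than the gate merge, and each
read joins its nearest seed group within the gate (default 0.8,
calibrated once on synthetic three-population communities at 2%
internal divergence, where per-bin purity is 1.0 against truth). How the
original tool's "sensitivity" parameter maps onto a distance gate is not
recoverable; the gate is an explicit config parameter instead.

**Redundancy removal** reproduces cd-hit's
`-G 0 -aS 0.9 -c 0.99 -g 1` semantics: greedy longest-first, local
alignment, redundancy requires >= 99% identity with the alignment
covering >= 90% of the *shorter* sequence, and each redundant read is
assigned to its best-matching (not first-matching) kept representative.
The operation is idempotent (tested). **Scaffolding** builds an overlap
graph from end-to-end dovetails (99% / >1000 bp, <= 20 bases overhang
tolerated) and merges only unambiguous simple paths — any read end
involved in two overlaps is a fork and never merged through; at
disagreeing columns the earlier read's base wins.

# Recruitment, presence, ANIr

RPKG = best-hit reads / (genome kb x metagenome Gb), with rRNA intervals
(supplied as 0-based half-open masks) excluded from both the mapping
target and the genome length. Breadth is the union of best-hit subject
intervals over unmasked positions — one alignment per read, so
multi-hit reads cannot inflate it. Presence requires RPKG >= 3 *and*
breadth >= 0.7; both thresholds are inclusive exactly as the decision
rules are phrased ("less than three RPKG ... not present"). ANIr is the
*unweighted* mean identity of best-hit reads at the 80%/50 bp gate —
the read-averaged convention — with a length-weighted switch available.
Recovery is tested at divergences {0, 1, 2, 4}%: ANIr lands within 0.3
points of {100, 99, 98, 96}.

AAI/OF networks use full Smith–Waterman (BLOSUM62, affine 11/1) within
each genome pair; reciprocal best hits must also cover >= 70% of the
shorter peptide — without the coverage gate, chance local alignments
between unrelated 150-aa peptides average just above the 30% AAI floor
and produce phantom edges. Edges below 25% OF or 30% AAI are dropped;
the unfiltered table is retained.

# Assembly QC

Circularity: a terminal window of 2 x 250 bases bounds "aligns to either
sequence end", so mid-genome hits cannot count. The verdict is circular
when one independent contig aligns >= 250 bases at >= 95% to *both* end
windows in junction-consistent orientation (its right-end piece precedes
its left-end piece on the contig, same strand, within 50 bases) — the
same-contig reading of an underspecified rule, chosen because two
unrelated contigs touching one end each are weak evidence. A direct
terminal repeat >= the same floor is reported separately as an
assembler-style signal, so the contig-based rule remains isolable.
Completeness/contamination use a pluggable single-copy marker list
(counts of present / duplicated labels over the set; the conventional
43-marker set is the default size in the demo pipeline), and the
reference-genome filter discards at completeness < 40% or contamination
> 5% — strict inequalities, boundary values kept.

# Orchestration and problem sizes

`run_pipeline()` executes simulate → profile → classify → bin → markers
→ read-bin → scaffold → recruit → QC → AAI → report, writing each
stage's TSV and the resolved config; a rerun with the same config is
byte-identical. The demo community is five genomes of 150 kb (GC
0.35–0.65, two circular, three strains each at 2% divergence), three
short-read metagenomes of 10,000 reads with independent abundance
vectors, and 500 long reads. The test suite and the acceptance script
use deliberately scaled problem sizes — genomes of 25–150 kb, read sets
of 150–10,000 — chosen so the full battery demonstrates every recovery
property (abundance ratios to 3 multinomial SDs, ANIr to 0.3 points,
binning ARI >= 0.9, read-bin purity >= 0.8, circularity 20/20) on a
single CPU in minutes; all sizes are config, not constants.

# Known limitations

* The simulator's error model is substitution-dominated with
  length-preserving indels and flat FASTQ qualities; it does not emulate
  instrument-specific error profiles, homopolymer artefacts or chimeras.
* The aligner's sensitivity is bounded by seeding: alignments below
  ~75–80% identity are not found, so fragment ANI between distant
  genomes is "missing" rather than a number (consistent with how ANI is
  used, but not a general-purpose distant-homology search).
* Contig binning is an automated surrogate for what was originally a
  human-curated step; genomes identical in signature, GC and coverage
  merge, by construction.
* The long-read classification identity floor is applied at 80% (the
  short-read value); the published rule does not state a separate
  long-read floor, and the choice is exposed in config.
* Gene tables are inputs (or simulated); no gene calling is performed.
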