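---
title: "Methods: scanning, dating and tracing RNA G-quadruplex motifs"
author: "rg4evo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, dating and tracing RNA G-quadruplex motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4evo)
```

## The problem

RNA G-quadruplexes (rG4s) form when four tracts of consecutive guanines,
separated by short loops, stack into two or more planar G-quartets.
Experimental rG4 mapping (reverse-transcriptase stalling under K^+^ versus
Li^+^ conditions) produces call tables of motif intervals; everything that
follows those calls — classifying motifs, placing them on gene regions and
codons, dating the gene families that carry them, and measuring how the
underlying quadruplex sequences (QSs) survive across species and ancestors
— is what this package implements. The package consumes standard formats
(GTF, FASTA, BED-like tables, MAF, Newick) and never performs read
processing, rG4 calling, alignment computation or liftover itself.

## Motif grammars and the canonicality score

`scan_pqs()` recognizes four putative-quadruplex (PQS) grammars, in
priority order:

* **canonical** (G~3~L~1–7~): four tracts of ≥ 3 G, loops 1–7 nt;
* **long loop**: four tracts of ≥ 3 G, loops 1–12 nt, not tilable with all
  loops ≤ 7 (so at least one loop is 8–12 nt);
* **bulge**: three pure tracts of ≥ 3 G plus exactly one bulged tract
  (G~1–2~·[ACU]·G~1–2~ with ≥ 3 G in total), loops 1–7 nt;
* **two-quartet**: four tracts of ≥ 2 G, loops 1–7 nt, not matching any
  grammar above.

The first two form three stacked quartets (group G3), the last two form
two (group G2). "Variant G2" motifs are intentionally not scanned; they
are excluded from all analyses here. All loop bounds are surfaced in
`scan_params()` because the published motif taxonomy does not pin the
long-loop ceiling or bulge placement; the defaults above are our working
assumptions. Loops are allowed to contain guanines (they are whatever the
tiling leaves between tracts); a consequence is that long pure-G stretches
can satisfy the grammars, which is biologically unusual but keeps the
definition total and testable.

**Canonicality** is the number of tracts containing a guanine run of
length ≥ 3, capped at 4. A tract of four or more guanines counts once; a
motif with five GGG tracts is classed together with 4. Canonical and
long-loop motifs always score 4, bulged motifs 3, and two-quartet motifs
0–3; a pure two-quartet motif (four GG tracts) scores 0.

Three choices the motif definition leaves open are made deterministic:

* **Class of a substring.** A candidate substring is assigned the
  highest-priority grammar it can tile, so classes partition the
  candidate set.
* **Overlap policy.** The default `GREEDY_NONOVERLAP` mode reports the
  leftmost-first maximal non-overlapping hit set: at the leftmost start
  carrying any candidate, the highest-priority class is taken with its
  longest feasible span. Conservation asks a presence/absence question, so
  non-overlapping hits suffice; `ALL` mode (one maximal hit per start and
  class) exists for enumeration-style testing.
* **Tract decomposition.** When a span tiles several ways (e.g. GGGGG can
  be split around either end), the decomposition maximizes canonicality,
  then takes the earliest tract starts, then the longest tracts.

The scanner is a dynamic programme over G-run structure; the test suite
holds it against an independent brute-force oracle that enumerates every
substring and tests membership with backtracking regular expressions, on
a thousand random sequences per run.

## Gene regions, codons and enrichment

Transcript models carry exon structure and CDS spans with 0-based
half-open coordinates throughout (GTF is converted on read). Region
assignment (5′UTR/CDS/3′UTR) uses the motif midpoint; a midpoint exactly
on a CDS boundary goes to the CDS. One isoform per gene — longest CDS,
then longest transcript — represents the gene in region and codon
analyses. Transcripts whose CDS is not a positive multiple of 3 are
flagged and excluded from codon analyses but retained for region counts;
codons containing N are dropped from tallies.

`codon_enrichment()` compares codon frequencies inside CDS motifs against
the concatenated CDSs of the distinct motif-harboring genes (each
harboring gene's canonical CDS counted once, however many motifs it
carries). A codon belongs to a motif's tally when **at least 2 of its 3
bases** lie in the motif span — the majority rule avoids double-counting
flank codons and is our documented choice where the counting convention is
otherwise unstated. Because the baseline includes the motif codons
themselves, a planted enrichment of factor $k$ over $m$ motif codons in an
$L$-codon CDS is recovered as $k / (1 + \frac{m}{L}(k-1))$; with the
generator's defaults ($m = 12$, $L \approx 600$) this bias is ≈ 7% and
lies inside the ±15% recovery band used by the calibration tests.

G-tracts inside CDSs are decomposed into their codon spans
(`decompose_tract()`): a GG or GGG tract covers one codon or two
consecutive codons; runs longer than 3 nt are truncated to their leading
three bases and classed with GGG. Bulged tracts are not pure guanine runs
and are excluded from tract-level codon statistics.

## Feature overlap

Overlaps are computed on the natural axis of each feature: genomic
coordinates for repetitive elements and microRNA seeds, peptide residues
for low-complexity regions (LCR detection itself is consumed as input).
All intervals are half-open, so touching intervals do not overlap. The
"within ±10 nt" seed rule is implemented as intersection with the motif
footprint widened symmetrically by the window (nearest-edge
interpretation); a seed whose closest base is the 10th nucleotide away is
flagged, the 11th is not. Splice-junction overlap requires an exon-exon
boundary properly inside the motif interval.

## Gene-family ages and ohnologs

Each gene family is dated by the age of the last common ancestor of its
species set on an ultrametric species tree (`lca_age()`); single-species
families date to 0. Species names are reconciled by lowercasing and
space/underscore normalization only — unmatched names are dropped with a
warning, and a family with no resolvable species is an error. Clade labels
come from a configurable mapping of labels to species sets (innermost
first), so the age binning is reproducible and swappable.
`harboring_fraction()` reports, per clade, the fraction of families with
at least one member gene carrying an rG4 (optionally filtered by region),
and `ohnolog_contrast()` repeats the computation on the subset of families
containing genes retained from the vertebrate whole-genome duplications.

## Conservation from whole-genome alignments

For each rG4, `extract_windows()` collects the alignment columns of the
motif plus 30 nt of reference flank from all covering MAF blocks. Windows
are assembled per reference position: a species missing from a covering
block contributes gaps there, and insertion columns interior to the window
are retained so PQS scanning sees the full species sequence. A species
counts as *aligned* when it has any non-gap character over the window; a
species *possesses a positionally conserved PQS* when scanning its
(gap-free, sense-strand) window sequence yields any motif class. PQS
presence is never reported for unaligned species.

Sequence identity divides the number of matching columns by the
**reference motif length**: gaps, missing blocks and truncated coverage
all count as mismatches, and flanks are excluded from the denominator (the
motif-only reading of "the human/mouse sequence length"; the alternative
including flanks would dilute motif divergence with flank divergence). Per
rG4, the average identity is taken over aligned species, with the special
value 0.0 reserved for rG4s aligned in no species.

Species are grouped into nested clades; because published usage is
ambiguous about whether the per-clade panels use disjoint or cumulative
species sets, `clade_summary()` emits both: disjoint "rings" (each species
in its innermost clade) and cumulative nested sets.

Positional conservation at the family level maps motifs into per-family
codon-aware alignments; two motifs from different species are positionally
conserved when their column ranges share at least one column, and partner
status is graded no-alignment / aligned-no-PQS / aligned-PQS-no-rG4 /
aligned-rG4. UTR motifs, which have no family alignment, are compared via
partner coordinates pre-mapped (lifted over) into the same genome, again
with ≥ 1 shared base as the criterion.

## Ancestral reconstruction and canonicality drift

Ancestral windows at a named clade (e.g. Mammalia, Tetrapoda) are
reconstructed by per-column Fitch small parsimony over the five-state
alphabet {A, C, G, T, gap}, using only the clade's aligned species (at
least two are required; otherwise the window is flagged and excluded).
Root-set ties are broken by the reference base when it is in the set, then
by the fixed order A < C < G < T < gap; gap states are removed from the
final sequence. Parsimony was chosen over likelihood reconstruction
because it is deterministic, dependency-free and desk-checkable against
exhaustive minimum-mutation enumeration; externally computed (e.g.
maximum-likelihood) ancestral sequences can be supplied instead through
`drift_analysis(ancestral_seqs = ...)`.

The ancestral PQS compared against a modern rG4 is the scanned hit with
the largest column overlap with the modern motif (ties: higher
canonicality, then leftmost) — the tie rule is ours, since a single
ancestral canonicality must be chosen when several PQSs occupy one
window. Drift is then GAIN, LOSS or UNCHANGED by comparing canonicality
values, with ancestral windows lacking any PQS reported separately rather
than entering the comparison.

## The synthetic-data generator

`make_transcriptome()`, `make_alignment()`, `make_families()` and
`make_feature_tracks()` emulate every input with known truth:

* Transcripts have 5′UTR (80–160 nt), CDS (120–220 codons; 550–650 when
  calibrating codon spikes so the motif occupies ≈ 2% of its parent CDS),
  and 3′UTR (100–220 nt), 1–3 exons, and an even strand mix, each gene on
  its own chromosome. Background composition is slightly G-poor (20% G) so
  planted motifs dominate the signal.
* Planted PQSs are constructed per class and canonicality with G-free
  loops, and surrounded by 15-nt G-free guard zones. Since no loop may
  exceed 12 nt, no candidate can bridge a guard zone, so a full-sequence
  scan provably returns exactly the planted span, class and canonicality.
  CDS embeddings are realized as explicit codon recipes placed on codon
  boundaries with C-only loops (no in-frame stop can arise).
* Codon-spike intervals sample each codon as the target codon with
  probability $k/61$ (uniform sense-codon background), at most one
  interval per gene.
* Alignments evolve a root window down a phylogeny with per-site
  independent substitutions, uniform over the three alternative bases, so
  expected identity across a branch of probability $p$ is exactly $1-p$ —
  the closed form used by the recovery tests. Optional single-base
  deletions never hit the planted motif by default and never the
  reference row (columns deleted in the reference are dropped), keeping
  the emitted MAF reference gap-free. Insertions are not simulated.
* Gene families take whole clades as species sets, so their LCA age is the
  clade node age by construction, with age-dependent harboring
  probabilities and an ohnolog subset at a boosted rate.

One RNG stream is derived per artifact from the master seed by a stable
label hash; identical configurations are bit-reproducible.

What the generator does **not** emulate: realistic base composition and
isochores, overlapping genes and alternative isoforms, codon-model
sequence evolution, alignment error, and insertion columns. Passing tests
therefore demonstrate correctness of the computations under the stated
statistical model, not robustness to every artifact of real alignments.

## Problem sizes and numerical conventions

The test suite runs at desk scale by design: scanner/oracle equivalence on
1,000 random 200-nt sequences; identity recovery over 200 replicate
alignments per substitution probability (0, 0.05, 0.2); codon-spike
recovery over 500 embedded motifs across 500 genes; Fitch versus
exhaustive enumeration on all rooted topologies with ≤ 4 leaves plus
random topologies with 5–8 leaves, 100 columns each; and gene-family
gradients over 500–800 families. Headline counts from full rG4-seq
datasets and 100-way alignments are not reproducible at these sizes and
are not targeted.

Conventions: all intervals 0-based half-open; canonicality is an integer
0–4; identities and fractions lie in [0, 1]; ties are always broken by
documented deterministic rules (midpoint-to-CDS, leftmost tract starts,
reference-base-then-alphabet in Fitch). Empty inputs yield empty tables,
never errors.

## Known limitations

* The scanner's grammars are configurable but the defaults encode
  assumptions where the motif taxonomy is silent (long-loop ceiling 12,
  bulge sides ≤ 2 G).
* MAF handling reads `s` lines only and assumes the reference rows are on
  the + strand; minus-strand motifs are handled by reverse-complementing
  extracted windows.
* The parsimony reconstructor ignores branch lengths; rate heterogeneity
  across branches will bias ancestral states toward densely sampled
  subclades.
* Liftover, MSA computation and LCR detection are consumed, not
  performed; coordinate builds must match across inputs.
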