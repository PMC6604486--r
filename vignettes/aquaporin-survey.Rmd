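---
title: "Surveying a plant aquaporin (MIP) gene family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying a plant aquaporin (MIP) gene family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipsurvey)
library(dplyr)
```

# The problem

Aquaporins (major intrinsic proteins, MIPs) are channel proteins with a
strongly conserved architecture — six transmembrane helices, two
Asn-Pro-Ala (NPA) boxes in loops B and E, and a four-residue
aromatic/arginine (ar/R) selectivity filter — whose family size and
subfamily composition (PIP, TIP, NIP, SIP, XIP in most dicots) vary widely
across plant genomes. A genome-wide family survey asks, for a proteome and
its gene annotation: which proteins are aquaporins, which subfamily and
named ortholog group does each belong to, what do their structural
hallmarks look like, how did the family expand (tandem and segmental
duplication, and under what selective pressure), and how are the members
expressed across tissues and under stress.

`mipsurvey` implements that survey as composable, deterministic tidyverse
functions, together with a synthetic-data generator that plants known
truth for every stage so the whole pipeline is testable end to end.

# Candidate screening and the identity ladder

Candidates are screened by optimal global (Needleman–Wunsch) alignment
against a curated reference set (classically the 35 *Arabidopsis*
aquaporins), in place of heuristic database search. The alignment scoring
is BLOSUM62 with affine gap penalties (open 10, extend 0.5 — classic
`needle` defaults), configurable in `pairwise_global_align()`.

Two definitional choices matter and are fixed here so results are exact
and reproducible:

* **Identity** is identical columns divided by *all* alignment columns,
  including gap columns. This is the stricter denominator and is
  order-independent.
* **Query coverage** is the number of columns where both sequences are
  aligned (neither is a gap), divided by query length. In a global
  alignment every query residue appears in the alignment, so the naive
  "aligned query residues" reading would always give 100%; columns aligned
  against an actual reference residue are what coverage is meant to
  measure.

Screening retains a protein when its best reference hit has identity
≥ 30% and coverage > 50%. The family ladder is then applied to the best
identity: > 40% calls an aquaporin; a retained protein at or below 40% is
a candidate member of a new MIP-like family; the subfamily (parsed from
the best reference's name) is assigned only above 60%. Ties for the best
reference break by higher alignment score, then lexicographic reference
id. E-value screening is deliberately not reproduced: it is a statistic
of a particular search tool and database size, whereas identity and
coverage are properties of the sequences alone.

Nomenclature follows the field's convention: queries sharing a best
reference ortholog (say `PIP1;4`) are suffixed `a`, `b`, `c`, … in order
of chromosome (lexicographic) then start coordinate; singletons carry no
suffix. Beyond ten paralogs the suffixes simply continue (`k`, `l`, …)
with a warning, since published tables rarely exhibit more than `a`–`j`.

# Motif profiling by template anchoring

The structural hallmarks — NPA boxes, the ar/R tetrad (positions H2, H5,
LE1, LE2) and Froger's positions P1–P5 — are positional concepts defined
on a reference alignment. Rather than re-implementing multiple sequence
alignment, `mipsurvey` ships one **synthetic template per subfamily**
(built in code by `aqp_templates()`): an idealized aquaporin with six
hydrophobic stretches, both NPA boxes, the subfamily's canonical ar/R
tetrad and literature-standard Froger residues at fixed, annotated
columns. A query is globally aligned to its template (or to all
templates, best score wins) and each annotated column is read off at the
aligned query residue; a gap yields `-`. This makes the positional
semantics exact, testable, and idempotent on the template itself. The
templates are synthetic anchors, not biological sequences; on real data a
user may substitute curated, annotated subfamily representatives with the
same structure.

NPA triplets are read as three consecutive query residues from the mapped
NPA column, so a box mutated to `NLA` (a known proline-to-leucine
variant) is reported verbatim with `canonical = FALSE`; degenerate or
single-NPA proteins yield a non-canonical slot rather than an error. A
regex fallback (`scan_npa()`) exists for template-less use and is
flagged as lower confidence.

ar/R group assignment is a first-match rule table covering the nine
groups seen across the five subfamilies, including the hallmark tetrads
(F/V, H, T, R) for PIPs, the TIP-I/IIa/IIb/III split, the NIP-I group
with both the WVAR and the silicon-channel GSGR tetrads, NIP-II
(A/T, I/V, G/A, R), SIP-I, SIP-II and XIP. Unresolved positions act as
wildcards; fewer than three resolved positions returns `unclassified`.
The SIP-I/SIP-II discriminating tetrads are only loosely standardized in
the literature; the rule table here places SIP-I (P/G/A, F/S/N, V/I/F,
H/V) before a distinct SIP-II pattern (S/G, H/S, G/P, A/S) — an explicit
rule-table choice, configurable by editing the table.

Transmembrane segments are predicted from a Kyte–Doolittle sliding-window
hydropathy profile: maximal runs with windowed mean ≥ 1.6 and length
≥ 15, window 19 — standard heuristics, all configurable. These defaults
are conservative for tightly packed 21-residue helices separated by short
loops (the window straddles helix boundaries); a window of 11 with
min_len 9 resolves all six helices on idealized sequences and is what the
package's own tests use when segment *count* is the property under test.

# Gene structure

Introns are gaps between consecutive exons of the representative
transcript — the isoform with the largest summed exon length, ties broken
by smallest transcript id (the annotation's choice of "representative" is
otherwise arbitrary). Exon features are used rather than CDS features, so
UTR-containing exons count, matching how gene-structure figures are
customarily drawn from gene GFF files. All coordinates are 1-based
inclusive (the GFF3 convention) throughout; an intron's length is
`next_start − prev_end − 1`.

# Duplication and selection

**Tandem pairs** follow a three-clause window rule: at most 5 annotated
genes between the two (counted strand-agnostically over the whole
annotation, not just family members), nearest-boundary distance at most
100 kb, and protein global-alignment identity above 70%. "Similarity" is
interpreted as protein identity under the screening module's definition —
the survey's other criteria are all protein-level. The implementation
scans sorted per-chromosome neighborhoods; its defining property,
verified exhaustively in tests, is exact agreement with the O(n²)
all-pairs filter.

**Ka/Ks** uses the Nei–Gojobori (1986) codon-counting method, authored
in-package: per-codon synonymous site fractions averaged over both
sequences; observed differences averaged with equal weight over all
minimal mutation paths per codon; Jukes–Cantor correction
`d = −(3/4)·ln(1 − 4p/3)`. Conventions fixed here: mutations that would
create a stop codon count as nonsynonymous in site counting; mutation
paths passing through a stop codon are excluded unless every path is
blocked; codons containing gaps, ambiguity characters or stops (in either
sequence) are excluded entirely. Unequal-length pairs are codon-aligned
by back-threading a protein global alignment. `p ≥ 3/4` leaves the
corrected rate undefined (`NA`), as does `omega` when `Ks = 0`.
Selection calls: `purifying` below 1, `positive` above, `neutral~1`
within a configurable ±0.05 band.

Segmental (collinearity-derived) pairs are consumed from PGDD-style TSV
files, not computed: collinearity detection is a genome-scale problem
with its own dedicated tools, and published surveys download these files
rather than recompute them. Ka/Ks is recomputed when coding sequences are
supplied.

# Phylogeny

Distances come from an externally supplied alignment (p-distance or
Poisson-corrected, pairwise deletion of gap/ambiguity columns);
re-implementing progressive alignment is out of scope. Neighbor joining
is Saitou–Nei via `ape::nj()` — exact on additive matrices, which is the
property the tests verify on random trees. Negative branch-length
estimates are clamped to zero with a flag, matching the common
presentation. Bootstrap supports resample alignment columns with
replacement and score each internal bipartition of the point-estimate
tree across replicates; the resampling is seeded, and the point-estimate
topology is seed-independent. "Rooted" display trees are midpoint-rooted,
the natural choice when no outgroup is designated; monophyly checks run
on the midpoint-rooted tree.

# Expression and qPCR

Expression values are FPKM, normalized as `log2(FPKM + 1)`; the transform
is refused on an already-normalized matrix. Hierarchical clustering uses
average linkage on correlation distance (1 − Pearson) by default, with
euclidean available; rows with zero variance, where correlation is
undefined, sit at the maximum correlation distance of 2.

Tissue breadth classes use the survey's one stated expression threshold,
FPKM 5: `high_all_tissues` when every sample reaches it, `low_all` when
none does, `tissue_specific` when at most 30% of samples do (rounded up)
— the 30% breadth cutoff is this package's operationalization of what is
otherwise a visual judgement, and is a parameter.

Salt-stress response is likewise operationalized: `induced` when some
timepoint has treated ≥ 2× its control (or 2× the first-timepoint
baseline when no control series exists) and that value clears the FPKM-5
floor; `repressed` symmetrically; `low_expression` when the whole profile
stays under the floor; a gene qualifying in both directions keeps the
direction of the larger maximal fold change. Peak time is the argmax of
the treated series, earliest on ties — a tie-break that deliberately
favors "rapid" responders. Peak-time bias between two species'
ortholog sets reports per-pair `Δpeak` and counts pairs with opposite
early-phase slopes over the first two timepoints.

qPCR uses the Livak 2^−ΔΔCt method with amplification efficiency fixed at
100% (the assumption the formula embodies): replicate Ct values are
averaged *before* Δ computation, replicate variability is propagated as
`sd(ΔCt) = sqrt(sd_target² + sd_reference²)`, and the calibrator sample
has fold 1 by construction. Group comparisons use the classical one-way
fixed-effects ANOVA with explicit degenerate handling (zero within-group
variance with separated means gives `F = ∞, p = 0`; all-identical data
gives `F = 0, p = 1`).

# The synthetic-data generator

Every stage has a generator that plants recoverable truth, and every
generator is a pure function of its arguments and a seed (the global RNG
stream is saved and restored):

* `sim_proteins()` copies a subfamily template and mutates *background*
  positions only, at a rate calibrated so expected identity to the
  template is `100 − divergence`; annotated motif columns are untouched
  unless explicitly perturbed. Divergence above 60% is refused — beyond
  it the identity ladder the generator is meant to exercise loses
  meaning.
* `sim_protein_at_identity()` plants an exact mutation count for
  boundary-behavior tests around the 40/60 ladder.
* `sim_cds_pair()` evolves a descendant from a uniformly sampled
  sense-codon ancestor by uniform single-nucleotide proposals (stops
  forbidden): synonymous proposals always accepted, nonsynonymous with
  probability ω, until the accepted synonymous count reaches the target
  implied by the requested Ks. Requests outside the Jukes–Cantor
  correction's reliable range are refused.
* `sim_annotation()` lays out chromosomes with planted tandem arrays
  (~96% identity copies in adjacent genes) and planted negatives that
  each violate exactly one clause of the tandem rule — span, intervening
  count, or identity.
* `sim_expression()` plants tissue classes and salt time courses
  (fold 8 at a planted peak hour against flat controls) under
  multiplicative log-normal noise, coefficient of variation 0.1 by
  default.
* `sim_ct()` plants qPCR folds as Ct shifts of `−log2(fold)` with
  normal replicate noise of 0.15 cycles.

Noise models are standard choices, not estimates from any particular
dataset: log-normal multiplicative noise for FPKM, normal noise on the
Ct (cycle) scale.

**What passing on synthetic data does and does not show.** The generator
emulates the *statistical structure* the analysis assumes: gapless
homology to a template, independent site-wise substitution, flat
controls, lognormal expression noise. Real proteomes contain indels,
domain rearrangements, alternative isoforms and annotation errors; real
expression data have correlated noise and batch structure. Green tests
certify the algorithms implement their definitions exactly and recover
planted truth under those assumptions — not that the thresholds are
optimal for any particular genome.

# Problem sizes and numerical choices

The shipped test-and-verification workloads use: 100 random chromosomes
(12–20 genes each) for the tandem-rule/brute-force equivalence; 50
replicate 500-codon pairs at planted ω = 0.3 for Ka/Ks recovery
(tolerance ±0.1 on the mean); 100 random 5–12-taxon additive matrices
for neighbor joining (branch lengths to 1e−9); 200 planted proteins per
subfamily at 20% background divergence for motif recovery (exact); and
200 bootstrap replicates for planted-clade support. These sizes were
chosen as the smallest cohorts at which the stochastic checks are stable
across seeds.

Other numerical conventions: alignment-score ties break
deterministically (score, then lexicographic id); NJ joins break ties by
smallest index pair (inherited from `ape`); clustering leaf order is
deterministic given the input order; peak-time ties take the earliest
timepoint; all thresholds (30/50 screen, 40/60 ladder, 5-gene/100-kb/70%
tandem, FPKM 5, fold 2) are plain function arguments with the survey's
standard values as defaults.

# Known limitations

* Domain confirmation (MIP Pfam domain, profile-HMM search) is not
  computed; an external annotation can be joined onto the screen table
  but the screen itself is purely alignment-based.
* Segmental duplication detection, read mapping and FPKM quantification
  are out of scope by design; their outputs are inputs here.
* The NG86 estimator saturates near `p = 3/4`; deeply diverged pairs
  return `NA` rather than an extrapolated rate.
* Exact Froger P1–P5 coordinates vary across the literature; the
  templates fix one consistent set of columns, which is sufficient for
  relative comparisons within a survey but not for cross-study
  coordinate-level comparisons.
* Tree inference is distance-based NJ only — the survey's standard — not
  maximum likelihood or Bayesian.
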