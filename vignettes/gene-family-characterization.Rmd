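---
title: "Characterizing a plant gene family: duplication modes, Ka/Ks, promoters and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a plant gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`famscan` implements the downstream analysis that a genome-wide gene-family
survey performs once family members have been identified: renaming members
by chromosomal order, protein physicochemistry, promoter cis-element and
SSR scanning, collinearity-based duplication-mode classification with
Ks-dated whole-genome-duplication (WGD) assignment, Nei–Gojobori Ka/Ks, and
expression summarization.  Upstream steps that require external services or
databases — HMMER/BLAST family identification, phylogeny construction,
motif discovery, GO/KEGG annotation, read mapping — are out of scope; their
outputs (a member list, a homology hit table, a Newick tree, a count
matrix) are inputs here.

# Duplication-mode classification

Every gene's *rank* is its order index among the genes of its chromosome
(0-based, ties on start broken by end then ID).  Classification follows the
successive re-labeling scheme used with MCScanX-style collinearity
analysis:

1. a member with no homology hit surviving the filter is a **singleton**;
2. every duplicate starts as **dispersed**;
3. a same-chromosome partner at rank distance 2–19 upgrades it to
   **proximal** (strictly less than 20; distance 1 is reserved);
4. a same-chromosome partner at rank distance 1 upgrades it to **tandem**;
5. membership as an anchor of any collinear block upgrades it to
   **wgd_or_segmental**.

The order realizes "re-labeled" as a precedence `dispersed < proximal <
tandem < wgd_or_segmental`: the highest label any partner supports wins.
Cross-chromosome partners can only support dispersed or, through blocks,
wgd_or_segmental.

Hit filtering keeps `evalue < 1e-5` (strictly), removes self-hits, retains
the five best subjects per query by bitscore (ties by subject ID) and
symmetrizes.  The thresholds mirror the defaults of the tools this
workflow is normally run with and are all configurable.

## Collinear blocks

Anchors (hits mapped to rank pairs) are chained per chromosome pair by an
exact O(n²) dynamic program, separately for both orientations.  A chain
must be strictly monotone in both rank coordinates with at most `max_gap
= 25` skipped ranks between consecutive anchors on either side, and blocks
need `min_anchors = 5` anchors.  Chains are scored `match_score = 50` per
anchor minus `gap_penalty = 1` per skipped rank step — the 50:1 weighting
MCScanX uses.  The weighting matters: after heavy post-WGD gene loss
(fractionation), consecutive anchors on the ancestral chromosome are
several ranks apart, and a gap weight near the match weight would make
extending a true WGD block score-negative and truncate it.  Blocks are
extracted greedily (best chain first, anchors removed, repeat), so each
anchor joins at most one block per orientation.  The test suite proves the
DP equal to exhaustive chain enumeration on hundreds of small random
instances.

## WGD vs segmental

MCScanX-style classification cannot separate WGD from segmental
duplication.  The package follows the Ks-dating route: the median NG86 Ks
over a block's anchor pairs estimates the block's age; blocks whose median
falls inside an externally supplied Ks window (the dated WGD event of the
genome under study) and that have at least `min_anchors_wgd` anchors are
labeled WGD, all other blocks segmental.  Members called
`wgd_or_segmental` follow their best block (most anchors, ties to the
lowest median Ks).  The window is deliberately a mandatory configuration
input: it comes from a genome-wide Ks distribution dated elsewhere, not
from the family itself.  For the reference simulation (event Ks 1.2) the
packaged analyses use the window (0.84, 1.56), i.e. ±30% around the dated
event — wide enough for estimation noise, narrow enough to exclude the
younger segmental events planted at Ks ≤ 0.66.  Block "complementarity"
(regions covered by multiple blocks) is reported descriptively but never
used as a hard filter, since no operational definition exists.

# NG86 Ka/Ks

The Nei–Gojobori (1986) estimator is implemented in full, with the
dominant stop-codon conventions:

* **Sites.**  At each codon position the synonymous fraction is taken over
  the single-base changes that do not create a stop codon (stop mutations
  leave the denominator), so every compared codon contributes exactly
  three sites and `S + N = 3 × codons` holds to 1e-9 (a tested
  invariant).
* **Differences.**  All minimal substitution pathways between two codons
  are enumerated; pathways through stop intermediates are excluded and the
  survivors weighted equally.  If every pathway is blocked, all pathways
  are used rather than dropping the codon.
* **Correction.**  Proportions are Jukes–Cantor corrected,
  `d = -(3/4)·log(1 - 4p/3)`, with `p ≥ 0.75` flagged as saturated and
  reported `NA`.  `ω = Ka/Ks` is `NA` (not 0, not ∞) when Ks is 0 or
  saturated; downstream purifying-selection summaries count only defined
  ω.

Codon alignments are produced by global protein alignment (BLOSUM62,
affine gaps 10/0.5, via `Biostrings::pairwiseAlignment`) back-translated
onto the CDS pair; gap-containing codon columns are dropped pairwise.
Both the site/difference counting and the aligner are checked against
independent brute-force oracles (pathway enumeration over all 61×61
sense-codon pairs; exhaustive alignment-space search at short lengths).
The method is recorded in the output so other estimators could be added;
absolute Ks values are method-dependent, which is why the package's
validation rests on simulations with known ages rather than on published
family tables.

# Promoters, cis-elements and SSRs

Promoters are the 2000 bp upstream of the annotated gene start (not the
ATG — the choice is explicit and configurable), strand-aware, truncated
and flagged at sequence boundaries.  Scanning is catalogue-driven: the
catalogue is an editable TSV of named IUPAC patterns with function
categories, standing in for a motif web service so results are
reproducible offline.  Every occurrence on either strand is reported,
overlaps and duplicates included (a `dedupe` option exists); minus-strand
hits carry plus-strand coordinates.  An `N` in a promoter matches only the
pattern letter `N`.  Catalogue entries without a function category are
scanned but excluded from category summaries.

SSRs are maximal perfect tandem repeats of 1–6 bp units, with per-unit
minimum repeat counts `{1:10, 2:6, 3:5, 4:5, 5:5, 6:5}` — standard
SSR-survey practice, fully configurable and stamped into output.  Units
are reported in observed phase alongside their canonical (least-rotation)
form; a unit that is itself periodic is reported at its shortest period;
compound SSRs stay separate records.  The scanner is validated against a
sliding-window oracle.

# Expression

TPM is computed as length-normalized rates scaled to one million per
sample; the column-sum invariant is tested at 1e-6 relative tolerance.
Heatmap matrices are `log2(TPM + 1)` followed by per-gene row scaling with
the n−1 standard deviation (the "scale"/"Normalized" convention;
documented because n vs n−1 changes every heatmap value).  Constant rows
scale to zero and are flagged.  Replicate TPM is averaged before the log
transform by default; both orders are supported.  qPCR fold changes use
the Livak 2^-ddCT method with replicate dCTs averaged per condition
(per-replicate folds are also emitted for error bars); the calibrator
condition has fold 1 by construction.  Gene order in expression output can
follow a Newick tree's leaf order; the tree is parsed for ordering only.

# The simulator: what it emulates, and what it does not

`simulate_genome()` generates the inputs the analysis assumes, with
recorded ground truth.  The reference configuration — 4 chromosomes × 250
genes, one WGD at Ks 1.2 with retention 0.3, 15 tandem, 15 proximal and 30
dispersed events, 300-codon CDS evolved at ω = 0.2 — is a desk-scale
caricature of a fractionated eudicot genome: one dated polyploidy, heavy
duplicate loss, small-scale duplication dominated by dispersed copies, and
purifying selection on a regulatory family.  Event ages are drawn ±10%
around their configured means so block medians are informative rather than
degenerate.  The WGD is applied before small-scale events, so
tandem/proximal copies of WGD survivors exist and stress the classifier's
precedence rules.  Dispersed copies always land on another chromosome, so
they can never satisfy the proximal rule by accident.  Small-scale event
ages default to Ks 0.15 (tandem), 0.3 (proximal) and 0.6 (dispersed),
reflecting the usual observation that tandem duplicates are young; their
exact values only matter for being clearly below the WGD window.

`evolve_cds()` proposes uniform single-base changes, accepts synonymous
ones at rate 1 and nonsynonymous ones at rate ω, rejects stop-creating
changes, and stops when the accepted synonymous substitutions reach
`target_Ks × S` with `S` the ancestor's NG86 synonymous site count.
Median NG86 estimates recover planted Ks within a few percent at 300
codons (tested at Ks 0.1/0.5/1.0 and ω 0.2/1.0, 50 replicates each).

The simulator deliberately omits: indels within CDS (alignments of
simulated pairs are gapless), intergenic sequence evolution, transposon
machinery behind dispersed duplication, GC/codon-usage bias,
read-level RNA-seq noise, and genome rearrangement after the WGD (block
complementarity is therefore trivial in simulation).  Passing recovery
tests consequently demonstrate correctness of the *counting and chaining
machinery under the stated model*, not robustness to annotation errors,
alignment ambiguity or assembly artifacts in real genomes.

Promoter backgrounds for motif/SSR validation are rejection-sampled until
they contain no catalogue match and no SSR, so planted-recall assertions
are exact rather than probabilistic.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 is read and written
  1-based inclusive.  When a gene has several mRNAs, the isoform with the
  longest summed CDS represents it.
* pI uses the Bjellqvist/ProtParam pKa set (with residue-specific
  N-terminal pKa) and bisection on [0, 14] to 0.001 pH, reported to two
  decimals and verified against a dense-grid oracle.  Other pKa tables
  differ in the second decimal; the table ships as data and is swappable.
* Molecular weights use average (not monoisotopic) masses.  Ambiguous
  residues are a hard error by default; `skip_ambiguous` drops them with
  a warning, because silently guessing a mass or charge corrupts results.
* Zero-length promoters (gene abutting a sequence edge) are returned as
  flagged empty records, not errors.
* Block median Ks excludes saturated/undefined anchors and records the
  exclusion count; an all-undefined block has undefined age and is never
  called WGD.
* Reruns of the pipeline from one configuration are byte-identical; the
  run manifest records package version, parameters, seed and input
  checksums.

# Problem sizes

The packaged validation uses the reference simulation above (~1400 genes
after events), 50 replicates per Ka/Ks recovery condition at 300 codons,
200 random chaining instances of ≤ 12 anchors against exhaustive
enumeration, all 3721 sense-codon pairs against the NG86 oracle, and 100
planted 2 kb promoters — sizes chosen so every oracle comparison is exact
and the full suite runs on a single CPU in minutes.

# Module interfaces

The package's functions, the simulator and this vignette are the
interface; the `run_pipeline()`/`pipeline_config()` pair orchestrates the
stages over files (TSV in, TSV + JSON manifest out) for scripted use, and
`summarize_family()` joins the per-member table whose modal duplication
label answers the headline question — which duplication mode drove the
family's expansion.
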