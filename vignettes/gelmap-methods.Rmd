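---
title: "Methods: conservation liftover, signal-score comparison and degradome filtering"
author: "gelmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation liftover, signal-score comparison and degradome filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelmap)
```

## The scientific setting

Gelatinase A (MMP2 in mammals, Mmp2 in zebrafish) is a secreted matrix
metalloproteinase that is also found, reproducibly, inside striated muscle
cells. Three computational observations support the view that this
intracellular pool is maintained by selection rather than accident, and
gelmap implements each of them as a reusable, testable stage:

1. **Secretion-signal comparison.** SignalP-style S-mean scores summarise
   how recognisable a protein's N-terminal secretion signal is. Comparing
   S-mean distributions across orthologue families (gelatinase A versus
   other secreted MMPs and an efficiently secreted control such as
   vitronectin) asks whether gelatinase A's signal is *systematically*
   poorly recognised across taxa.
2. **Phosphosite conservation.** NetPhos-style phosphorylation predictions
   are made per orthologue, in each orthologue's own residue coordinates.
   Deciding whether "the same" site is predicted across species requires a
   coordinate liftover through a multiple sequence alignment; sites
   conserved in essentially all orthologues argue for functional
   regulation by intracellular kinases.
3. **Degradome filtering.** TAILS N-terminomics compares neo-N-termini
   between proteomes with and without MMP inhibition. Peptides enriched in
   the uninhibited (control) channel are candidate MMP substrates; their
   P1′ residues (the first residue of the neo-N-terminus) carry the
   protease's sequence specificity — Ile/Leu/Val at P1′ is characteristic
   of gelatinase A.

## The gap-map liftover

For one aligned row, `build_gapmap()` records the strictly increasing map
from residue index to alignment column and its partial inverse (undefined
at gap columns). Lifting a site from orthologue *o* to the reference is the
composition `seq_to_aln(o)` then `aln_to_seq(ref)`.

Numerical and degenerate-input choices:

* Coordinates are 1-based and closed, matching biological residue
  numbering and the domain intervals used for annotation (signal 1–29,
  propeptide 30–107, catalytic 118–446, hemopexin 463–657, inter-domain
  between and beyond).
* A lookup at a reference gap column returns an explicit `NA`, never the
  nearest residue: silently snapping to a neighbour would fabricate
  conservation at positions the reference does not have.
* Gap characters are `-` and `.` (normalised to `-`); any other non-letter
  character is an error rather than a silent skip.
* An all-gap row is legal (zero mapped residues); every residue lookup on
  it is a coordinate error.

Round-trip identity (`aln_to_seq(seq_to_aln(p)) == p`), strict
monotonicity, and agreement with a brute-force column scan are enforced as
property tests over random gapped rows.

## Conservation tallying and tiering

A reference position is *supported* by an orthologue when that orthologue
has a predicted site with score strictly greater than the threshold
(default 0.65, "higher than"), whose liftover lands on the position, and
whose residue satisfies the residue-match mode. Orthologues are counted
once per position, the reference's own prediction counts like any other
orthologue's, and sites unmappable onto the reference are excluded and
reported separately.

Tier fractions (default 100%, 99%, 97%) are inclusive ("at least"):
`min_count_for_fraction(n, f)` is the smallest integer count whose
fraction of *n* reaches *f* — for a family of 208 orthologues the 97% rule
requires 202. Because the banding convention differs between reports,
`tier_sites()` emits both cumulative counts per threshold and disjoint
bands (each site assigned only to its highest tier).

Two genuinely open choices, and the defaults taken:

* **Residue matching.** Default `"exact"`: a serine call supports only a
  serine at the reference position, since serine/threonine/tyrosine sites
  are biologically distinct substrates. `"acceptor-class"` (any S/T/Y call
  at the homologous column) is available for a looser reading.
* **Band semantics.** Whether published 99%/97% classes are cumulative or
  disjoint is ambiguous; both are computed, neither is privileged.

## Secretion-signal statistics

S-mean scores are bounded in (0, 1) and typically skewed, so distributions
are compared with a two-sided Mann–Whitney rank-sum test rather than a
t-test. The statistic is computed from its definition (pairwise wins plus
half-ties); p-values come from exhaustive enumeration of all assignments
of the pooled sample when both groups have at most eight observations (or
ten pooled), and otherwise from the normal approximation with continuity
correction and tie-corrected variance. The exact path is validated against
an independent permutation oracle and, in tie-free cases, against
`stats::wilcox.test`.

Pairwise p-values are Holm-adjusted (step-down, via `stats::p.adjust`) and
thresholded at `alpha` (default 0.05) into a significance matrix. Letters
are then assigned by the insert-and-absorb algorithm: one group holding
all families is split by each significantly different pair, and subset
groups are absorbed. The output always satisfies the two display axioms —
indistinguishable pairs share a letter, distinguishable pairs share none —
and letter order is deterministic (first use over families sorted by
name). No installed package offers a standalone compact-letter display
over an arbitrary significance matrix, so this step is implemented here.

The test and level behind any published letter grouping are rarely stated;
results therefore always carry the configured test and `alpha`, and both
are exposed as parameters rather than asserted as anyone's original
procedure.

## Degradome filtering

`summarize_degradome()` applies, in order: optional median-centring of
log2 ratios (off by default — tables labelled "normalized" are taken at
face value), the strict enrichment filter (`hl_ratio > 3`), keyword-based
category annotation on the protein description (case-insensitive
substring; default rule: `myosin`), P1′ extraction (first residue of the
peptide) and gelatinase A-likeness (P1′ in {I, L, V}). Percentages are
rounded half-to-even to integer percent, so a 12-of-49 category reports as
24%. An empty passing set reports undefined (`NA`) fractions, never 0/0
collapsed to zero. Peptide-to-protein assignment is taken from the input
table; re-mapping peptides to a proteome is out of scope.

## The synthetic-data generator

Every stage can be exercised without downloads because the generator emits
all four input dialects with known ground truth:

* **Orthologue families** (`simulate_orthologue_family()`): the alignment
  is built around the reference row, which is never gapped, so alignment
  columns coincide with reference coordinates and every planted site has a
  defined reference position. Other rows receive independent per-column
  gaps and per-residue substitutions that never touch planted columns.
  Site presence is planted by quota: exactly `round(presence * n)`
  orthologues, chosen at random, carry a high-scoring site. A Bernoulli
  draw per orthologue was considered and rejected: at a family size of 208
  its sampling noise (sd ≈ 2 sequences at presence 0.98) straddles the
  202- and 206-count tier boundaries, making tier recovery a coin flip for
  presences near a boundary, whereas the quota design makes the realised
  conservation fraction equal the requested one by construction. Present
  sites score uniformly on (0.65, 1], absent ones on [0, 0.65), so the
  strict 0.65 filter separates them perfectly in the noiseless case.
  Defaults are a family of 208 orthologues, reference length 120, with
  sites planted at presences 1.00, 0.99, 0.97 and 0.50.
* **Signal scores** (`simulate_signal_scores()`): Beta distributions
  parameterised by mean and spread (sd), so samples live strictly in
  (0, 1) with expectation equal to the stated family mean; spread 0
  degenerates to a point mass. Companion C/Y/D scores are bounded jitter,
  present only to fill the summary dialect.
* **Degradomes** (`simulate_degradome()`): log-normal H/L ratios (defaults
  meanlog 0.28, sdlog 0.8, putting roughly 15% of 321 peptides above the
  enrichment cut-off, the scale of the embryo experiment), Bernoulli
  myosin labelling, and an optional P1′ bias. The log-normal tail is
  analytically checkable: `P(ratio > 3) = 1 - pnorm((log 3 - meanlog) /
  sdlog)`.
* **Profile pairs** (`simulate_profiles()`): offset sinusoids with a
  controlled phase shift; phase 0.5 with zero noise is exactly anti-phased
  (Pearson r = −1), emulating two channels that alternate along a
  sarcomere. Gaussian noise is added before clipping at zero.

What the generator deliberately does **not** emulate: phylogenetic
correlation between orthologues (rows are i.i.d. around the reference),
realistic amino-acid composition or indel length distributions, predictor
score correlation along a sequence, peptide-spectrum noise, or image
formation. Passing tests therefore demonstrate the correctness of the
coordinate arithmetic, filters and statistics under controlled truth — not
that any biological claim re-derives from real data.

## Problem sizes and determinism

The validation suite runs the full family size (208 orthologues, 100
seeds) for tier recovery, 1000 random rows for gap-map equivalence,
exhaustive rank-test enumeration for all pooled sizes up to 10, and 500
random significance matrices for the letter-display axioms; these sizes
were chosen so the whole suite completes in well under a minute while
keeping every Monte-Carlo bound at three standard errors. All randomness
flows from explicit seeds; fixed seeds give byte-identical generator
output, and pipeline outputs embed a provenance header (package version,
config hash, seed).

## Known limitations

* Alignment trimming is taken as given; the curation window rule is
  applied to the provided block, with the window counted in alignment
  columns (the start-divergence rule judges leading gaps, the gap rule
  internal gaps).
* Predictor outputs are consumed, never recomputed: the package does not
  contain SignalP's or NetPhos's networks, and its conclusions inherit
  their calibration.
* The published line-profile correlation coefficients depend on the
  underlying micrographs and cannot be recomputed here; the correlation
  stage reproduces the sign structure on synthetic profiles only.
* Percentage reporting is integer-rounded for summary tables; exact
  fractions are always available alongside.
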