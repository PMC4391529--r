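---
title: "Models and procedures behind OsmoOmics"
author: "OsmoOmics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures behind OsmoOmics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OsmoOmics)
```

OsmoOmics bundles the five computational procedures of a bacterial
hyperosmotic-stress study — comparative-genomic screening for osmolyte
genes, probe-level microarray differential expression, 2D-gel spot
statistics, GC-MS relative quantification and an integrated treemap
view — together with synthetic-data generators that plant known truth in
each input type. This vignette explains the models, the parameters that
matter, the numerical choices, and what the generators do and do not
emulate.

## The reciprocal best-hit screen

A seed gene is declared present in a target organism when the best-hit
relation holds in both directions. Forward: among all target sequences
whose Smith–Waterman local alignment with the seed reaches the score
threshold and covers at least the overlap fraction of the hit, take the
one with the highest identity. Backward: search that hit against the
source proteome under the same rule. Presence requires the back-search to
return the seed itself — identity of ids, not merely of scores — so a
duplicated paralog that captures the back-search correctly yields an
absent call.

Parameters, defaults and rationale:

* `minScore = 100` (substitution-matrix units) and `minOverlap = 0.75`:
  the screen's operating thresholds. Overlap is measured as
  subject-aligned length over full subject length, reading "the hit" as
  the found ORF.
* `substitutionMatrix = "BLOSUM62"`, `gapOpen = 11`, `gapExtend = 1`: the
  screen itself does not pin these down, so the package adopts the most
  widely reproduced protein-alignment defaults and leaves them
  configurable. A gap of length $L$ costs $11 + L$. Because the matrix
  and penalties are a free choice, identity shadings of a published
  presence matrix are reproducible in pattern but not bit-for-bit.
* Identity is identical columns divided by *all* alignment columns, gap
  columns included — stated explicitly because conventions differ; this
  is the more conservative of the common definitions.
* Ties on identity are broken by higher score, then lexicographically
  smallest subject id, making every call deterministic.

The dynamic programming is delegated to
`Biostrings::pairwiseAlignment(type = "local")`; the test suite holds it
against an independently coded full-matrix DP oracle (exact agreement on
hundreds of random pairs) rather than trusting either implementation
alone.

## Probe-level differential expression

The array design places 9–11 probes per gene across a window of −300 to
+200 bp around the translational start at +1 (there is no position 0).
Probe midpoints define the offsets; only probes at offsets ≥ +1 — i.e.
inside the transcript's coding region rather than the promoter — enter
the fold-change estimate. Probe log2 ratios of a gene are averaged per
biological replicate, and the call is

* **up** if the mean exceeds +1 (strictly) in *all three* replicates,
* **down** if it falls below −1 in all three,
* **unchanged** otherwise,
* **not_evaluated** if no probe passes the positional filter.

The `not_evaluated` outcome is deliberate: silently folding such genes
into "unchanged" would misstate what the data can support. The replicate
rule is applied to per-replicate *gene means* (probes averaged first);
the alternative reading — requiring every probe individually to pass —
is stricter but leaves the gene mean undefined as the reported quantity,
so the package implements the former. No multiple-testing correction is
applied: the criterion is replicate-consistent fold change only, and the
package keeps that operating characteristic rather than grafting a
different error model onto it.

The direct sucrose-versus-NaCl contrast is called with the same rule on
sucrose/NaCl ratios and drives the response groups: G1 (higher under
sucrose in the direct contrast, or up only under sucrose), G2 (down only
under sucrose), G3 (higher under NaCl in the direct contrast, or up only
under NaCl), G4 (down only under NaCl). The published grouping mixes
direct-contrast and single-condition wording without a formal rule, and
its G1/G4 direct-contrast readings overlap ("higher under sucrose" is
"lower under NaCl"); the package resolves this by letting the direct
contrast take precedence (up → G1, down → G3) and then assigning the
single-condition routes in order G1..G4, so each gene lands in at most
one group. This operationalization is a design choice and is tested as
such.

## 2D-gel spot statistics

Raw spot volumes (grey-level integrals) are normalized to percent of
total gel quantity, making gels comparable and every gel sum exactly
100 %. Spots below 0.02 % on *every* image are eliminated — one image at
or above the cut-off rescues the spot. Per retained spot, a one-way
fixed-effects ANOVA compares the three condition groups (control, NaCl,
sucrose) at α = 0.1; "considering both the stress types" is read as both
stresses entering a single three-level analysis rather than two separate
two-level ones, an interpretation documented here. Standardization
(mean-centering, division by the sample sd) is provided for display and
clustering; since the F statistic is location- and scale-invariant, raw
and standardized values give the identical F and p, which the tests
assert to 1e-9 rather than assume. Fold changes are computed on condition
means of *normalized* volumes (standardized values are dimensionless per
spot and unsuitable for ratios) with strict two-fold bounds: a ratio of
exactly 2.0 is not "exceeding two-fold". RSD (100·sd/mean, sample sd
throughout) is reported per spot and condition against the 35 %
reproducibility benchmark. The identification rule — at least two Mowse
scores ≥ 50 and coverage ≥ 30 %, coverage-only failures deferred to
MS/MS — is implemented with inclusive score/coverage bounds as printed.

## GC-MS relative quantification

Each analyte's peak area is divided by the ribitol internal-standard area
of the same sample; norvaline and camphorsulfonic acid are carried as QC
columns but never used for normalization, since the quantification is
defined against ribitol alone. Condition means are compared by a
two-sided pooled-variance Student t-test (df $n_1 + n_2 - 2$; a Welch
variant is available behind a flag but is not the default, matching the
named test and $n = 3$ per group). Degenerate zero-variance inputs are
resolved by the means (equal → p = 1, unequal → p = 0). Significance is
strict p < 0.05. Output rows are sorted by analyte name in the C locale
so the table is invariant to input row order. The published table reports
only condition means, no per-replicate values, so its printed p values
cannot be recomputed and are not used as oracles; the t-test is instead
validated against a closed-form incomplete-beta implementation.

## The treemap

Genes are nested main role → sub-role → operon → gene with leaf weight 1
(no published weighting rule exists, and equal weights make cell area an
honest gene count). The layout is an ordered slice-and-dice partition:
children tile their parent exactly, in order, along an axis that
alternates with depth. This was chosen over squarified or Voronoi layouts
because it makes the ordering guarantee provable: consecutive siblings
always share a full edge, hence genome-consecutive genes of an operon
occupy edge-adjacent cells. The price is elongated cells in unbalanced
hierarchies; `layoutTreemap(minAspect =)` flags leaves thinner than a
chosen aspect ratio as a sanity check. Node order at every level follows
the smallest genome index contained, keeping the genome walk coherent
across the whole plane.

Colors interpolate linearly in RGB from blue (−clip) through grey (0) to
orange (+clip), with `clip = 2` log2 units by default — two-fold beyond
the DE threshold saturates the ramp — and dark grey for genes with no
assigned value. Exact hues are configurable; the defaults are
ColorBrewer-adjacent picks, since no published hex values exist. mRNA
values color the gene circles (radius 30 % of the shorter cell side) and
the operon connectors (colored by the mean of the two linked genes);
protein values color the cells. The SVG writer emits fixed-precision
markup, so identical inputs produce byte-identical files — tested, not
assumed.

## Synthetic data: what it emulates, and what not

The generators reproduce the statistical structure the analyses assume,
at the study's own operating conditions, with truth tables for every
planted signal:

* **Genome pairs**: planted orthologs are point-mutated copies
  (substitutions only, never to the same residue), so realized identity
  is exactly $(L - k)/L$ — controllable and recorded. Decoys are random
  sequences. Defaults plant 50 orthologs at identities 0.4–1.0 and
  lengths 200–400 among 20 decoys. Indel robustness is exercised by
  handcrafted fixtures in the tests instead, because indels would
  decouple requested from realized identity.
* **Probe tables**: Gaussian noise on the log2 scale (the standard
  two-color model), planted genes shifted by ±2 log2 units in every
  replicate, probe offsets uniform over the design window. The noise sd
  (default 0.2) is a free parameter — no probe-level noise magnitude is
  published.
* **Spot tables**: lognormal abundances and replicate noise (multiplicative,
  unit mean at the requested CV). Planted spots are multiplied by the
  planted fold under both stresses, and the surplus is redistributed
  proportionally over non-planted spots so each gel's total stays
  constant — mimicking pulse labeling with fixed total incorporation, and
  making the planted fold survive total-quantity normalization exactly at
  zero noise.
* **Peak tables**: analyte areas constructed so the expected ribitol
  ratio equals the target mean (defaults: the six published metabolite
  condition means), with lognormal noise at the requested CV.
* **Annotation**: operons of size 1–5 walked along the genome, each
  assigned one (role, sub-role) pair from a two-level catalogue.

Passing tests on these inputs show the *rules* are implemented exactly
and recover planted truth under the assumed noise models. They do not
show robustness to what real data add: dye bias and spatial artifacts on
arrays, gel warping and mismatched spots, chromatographic drift, operon
mispredictions, or biological covariation between genes — all of which
the upstream instruments or external software handle in a real study.

## Problem sizes and numerical choices

The shipped tests run the alignment oracle on hundreds of random pairs of
length ≤ 30 (where exhaustive DP is exact and fast), the recovery screen
on 50 planted orthologs plus 20 decoys, the DE comparison on 200 genes ×
3 contrasts, the ANOVA null calibration on 2000 spots (rejection rate
0.10 ± 0.02), and the treemap audit on 100 random hierarchies of ≤ 50
leaves; these sizes make the Monte-Carlo checks decisive while keeping a
full run in tens of seconds. Strict inequalities are used exactly where
the printed rules use "exceeding"/"less than", inclusive bounds where
they say "at least". RNG streams are derived per generator from one seed,
so a configuration is a complete, byte-reproducible description of a
synthetic study; generators restore the caller's RNG state.

## Known limitations

* The screen compares annotated protein sequences only; nucleotide-level
  search and domain annotation are out of scope.
* Array normalization, gel image processing and MS spectrum scoring are
  upstream of this package; it consumes their tabular outputs.
* The treemap is rectangular; published figures of this style often use
  Voronoi tessellations, which look different though they encode the
  same hierarchy.
* Published headline counts (numbers of regulated genes, printed p
  values) depend on the deposited experimental data and proprietary
  array design; the package reproduces the *procedures* and validates
  them on planted truth instead.
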