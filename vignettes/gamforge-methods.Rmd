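---
title: "Models and methods behind gamforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gamforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gamforge)
```

Genome Architecture Mapping (GAM) estimates 3D chromatin contacts from the
co-occurrence of genomic windows in thin nuclear sections. This vignette
documents the statistical models, the tunable parameters with their defaults
and units, the numerical conventions, and the design choices made where the
methodology was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Window calling and QC

Detection of a window in a nuclear-profile (NP) sample is called from the
nucleotide coverage of that window. The threshold is selected per sample by
scanning integer percentiles 0–99 of the *strictly positive* coverage values
and choosing the percentile whose detection pattern (coverage **strictly
greater** than the threshold) minimises the fraction of *orphan windows* —
positive windows flanked by negative windows on both sides. Orphans are a
noise proxy: genuine nuclear content arrives in contiguous stretches of
windows, isolated positives are enriched for contamination and mapping
artefacts.

Conventions that had to be fixed:

* **Percentile 0 means "keep every positive-coverage window"**. A strict
  `>` rule combined with a threshold equal to the minimum positive value
  would otherwise always discard the lowest-coverage windows, and the
  degenerate case of constant positive coverage would detect nothing. The
  threshold at percentile 0 is therefore 0.
* **Zero-coverage windows are excluded from the percentile distribution.**
  Including them would collapse the lower half of the grid onto threshold 0
  for typical sparse GAM samples without changing the attainable optima.
  (Flagged as a sensitivity point; the full grid is returned so users can
  inspect it.)
* **Chromosome-edge positives with one negative neighbour count as
  orphans** — the conservative reading of "flanked by negative windows"
  when only one flank exists.
* **Ties in orphan fraction break towards the lowest percentile**, which
  retains more windows at equal orphan quality (maximises sensitivity).

Sample QC applies three strict cut-offs: orphan fraction < 0.70, uniquely
mapped reads > 50,000, and a cross-well contamination score < 0.4, the
latter being the maximum Jaccard index between the sample's detection
pattern and any sample on the same collection plate (plate structure is a
user-supplied sample-to-plate map). `pair_sampling_coverage()` reports the
fraction of intrachromosomal pairs of ever-detected windows co-detected in
at least one sample, the dataset-level saturation metric.

## 2. NPMI contact matrices

With `p(x)` the detection frequency of window `x` across samples and
`p(x,y)` the co-detection frequency,

    PMI  = log( p(x,y) / (p(x) p(y)) )
    NPMI = PMI / (−log p(x,y))

NPMI is bounded in [−1, 1]: 1 iff `p(x,y) = p(x) = p(y)` (perfect
co-occurrence), 0 at exact independence. The logarithm base cancels;
natural log is used. Entries with `p(x,y) = 0`, a zero marginal, or
`p(x,y) = 1` (vanishing normaliser) are undefined and carried as `NA`,
excluded from every downstream mean. Defined values are clamped to
[−1, 1] against floating-point drift.

Distance normalization is a per-diagonal Z-score with **population**
standard deviation (this is a normalization, not an inference, so no
degrees-of-freedom correction applies); diagonals with fewer than two
finite entries or zero spread are set to 0 rather than left undefined, so
degenerate distances contribute neutrally to differential analysis.

## 3. Differential contacts

`D = z_A − z_B` on window pairs surviving three filters:

* window detection frequency at or above the 2nd percentile of the
  detected-window frequency distribution of its chromosome, **in both
  datasets** (removals are the union);
* genomic distance within 0.5–5 Mb (both bounds inclusive; a 0.05 Mb lower
  bound variant is available through `d_min` since usage varies);
* NPMI above 0.15 **in at least one dataset** — the permissive reading,
  chosen so that contacts completely lost in one cell type (the biologically
  interesting case) are not filtered away.

The top `ceiling(q × n_pairs)` pairs by `D` are A-specific, by `−D`
B-specific, `q = 0.05`. When the differential matrix is identically zero the
top sets would be arbitrary ties, so an empty set is returned with a
warning. Aggregate pileups pool all cells of the (2r+1)×(2r+1) patches
(r = 4 bins) around the contacts of a chromosome into one arithmetic mean,
then average the per-chromosome means.

## 4. Insulation and TAD boundaries

The insulation score of bin *i* at square size *k* bins is the mean of the
finite contact values in the square `[i−k, i−1] × [i+1, i+k]`; it is
missing wherever the square leaves the chromosome. The standard ladder is
100 kb to 1 Mb in 100-kb steps at 50-kb bins; boundaries are called at the
500-kb scale.

Boundary calling: strict local minima against the nearest finite neighbour
on each side; plateaus of equal minima form one candidate centred on their
first bin (no prominence threshold by default — `min_prominence` is
available and defaults to 0, since the source methodology applies none).
Candidates whose 3-bin intervals touch or overlap (centre separation ≤ 3
bins) are merged, keeping the bin with the lowest insulation. Each boundary
is reported as that minimum bin ± one window (150 kb at 50-kb bins).

Multiway comparison clusters boundaries across datasets by transitive
closure of "centres separated by less than 200 kb" (equivalently:
150-kb intervals separated by less than one 50-kb bin edge-to-edge).
Transitive closure is used because the pairwise rule is not transitive and
closure yields deterministic, order-independent exclusive categories for
UpSet-style counting. Chromosome Y is excluded. Note the two phrasings of
the rule in circulation ("separated by at least 200 kb centre-to-centre"
vs "> 50 kb edge-to-edge") disagree at exactly 50 kb of gap; the
centre-to-centre form is authoritative here: 200 kb separation means
*different* boundaries.

## 5. A/B compartments

Per chromosome, at 250-kb bins: the observed co-segregation matrix `O` is
divided by the expected value `E(d)` (mean finite `O` per distance) to give
`O/E`; `C` is the column-correlation matrix of `O/E` (pairwise-complete
Pearson; bins with under 50% finite entries are dropped — the source is
silent here and 50% discards only uninformative bins); PCA is run on the
column-centred `C` and, among the first three components, the one with the
highest |Pearson r| to GC content is chosen and sign-flipped so the
correlation is positive. Bins with positive values are compartment A,
negative B; exact zeros get a missing label rather than an arbitrary side.
For display and cross-dataset correlation, A values are scaled by the
chromosome maximum and B values by |minimum|, mapping each side onto
(0, 1] and [−1, 0). Whole chromosomes are used (no arm splitting), and
Pearson correlation is assumed throughout. Transitions between datasets are
classified per bin (A→A, A→B, B→A, B→B) over bins defined in both tracks,
with an optional replicate-consensus pre-filter.

## 6. Domain melting score

For long genes — length strictly above 300 kb *and* covering at least 8
whole 50-kb bins (the two criteria are deliberately separate parameters;
together they imply an effective 400-kb floor for aligned genes) — the
score asks whether the gene's chromatin lost insulation in a query cell
type relative to a reference, across all 10 square sizes at once:

* insulation values are converted to **genome-wide percentile ranks per
  scale per dataset** before pooling. This is the package's calibration
  choice: raw insulation scales differ between datasets (sampling depth,
  detection rates), and percentile ranks make the two CDFs comparable
  without assuming any parametric relation. `normalize = FALSE` pools raw
  values for users who want the uncalibrated comparison.
* pooled values over gene bins × scales give one empirical CDF per dataset;
  the one-sided Kolmogorov–Smirnov statistic is `D = sup(F_query − F_ref)`
  (query stochastically smaller = insulation lost = melting);
* `p = exp(−2 m D²)`, `m = n_ref n_query / (n_ref + n_query)`, floored at
  1e-300 (capping scores at 300); Bonferroni correction by the number of
  genes actually tested in the run; melting score `= −log10(p)`; genes
  with score > 5 (corrected p < 1e-5) are melting.

The closed form is the standard one-sided asymptotic. At the pooled sizes
the score operates on in practice (≥ 80 values per side) it tracks a
permutation null to within a few percent, which the test suite asserts. At
very small pooled sizes (tens) the asymptotic is systematically
conservative by more than Monte-Carlo error; `method = "permutation"`
provides an exact-by-simulation alternative there. Note also that pooled
insulation values are spatially autocorrelated (neighbouring bins share
matrix entries, scales are nested), so the effective sample size is smaller
than the nominal count and scores of a few units can arise between
independent samplings of identical structure; the threshold of 5 absorbs
most, but not all, of this pseudo-replication, which is why genes
immediately flanking a genuinely melted region — whose large insulation
squares physically include melted-region contacts — are not valid negative
controls for it.

The trans–cis ratio at 250-kb bins divides the mean interchromosomal NPMI
of a bin by its mean intrachromosomal NPMI, after removing bins detected in
fewer than 3% or more than 75% of samples; genes are summarised by the
median over their whole bins. Length-scaled reads per million is
`overlaps / (length_Mb × fragments_M)`.

## 7. TF feature pairs

A window carries motif *f* when an accessible-chromatin peak supported by
at least 10% of single cells overlaps the window and contains a hit of *f*.
Motif scanning is deliberately external (an off-the-shelf step); the
package consumes interval hit tables. All `F(F+1)/2` unordered pairs
(heterotypic + homotypic) are scored on two differential contact sets: a
contact counts for pair `(f1, f2)` when one window carries `f1` and the
other `f2` in either orientation (homotypic pairs need the motif on both
sides). Scores are the frequency ratio
`(count_A/total_A)/(count_B/total_B)` — infinite enrichments are flagged,
not dropped — and the information gain (bits) of the contact's cell-type
label given pair presence. The shortlist is the union of top-10 by
information gain and top-5 by each direction's enrichment, with
lexicographic tie-breaking for determinism. Network edges require a pair on
at least 20% of a cell type's contacts, weighted by contact count
(community detection is delegated to igraph/leiden; a resolution of 1.01
reproduces the published communities).

## 8. The in-silico GAM simulator

The simulator is a *stated world*, not a curve-fitting device: its defaults
are fixed from the physical setting and are the conditions under which the
recovery tests run.

Generative model per structure (units: bead diameter σ):

1. a 3D Gaussian random walk with per-block step sd `step_sd × step_factor`
   (defaults 1 and 1; a melted block uses `step_factor = 2`, doubling its
   spatial extent and hence its gyration radius);
2. block compaction: beads of each block are contracted towards the block
   centroid by `compaction = 0.6`, creating TAD-like contact enrichment and
   insulation dips at block junctions;
3. compartments: each block centroid is displaced by
   `comp_strength = 0.8` of the way towards an anchor at
   `± comp_separation = 6` σ along a random unit vector (A blocks one
   pole, B blocks the other), producing the long-range checkerboard that
   compartment calling detects. The axis is redrawn per structure so the
   ensemble stays isotropic.

`compaction`, `comp_strength` and `comp_separation` were chosen once such
that simulated matrices show domains and compartments of visually realistic
contrast relative to published GAM matrices, and were then frozen; the
ensemble size default of 450 structures follows the scale of published
equilibrium-conformation ensembles, and 3 NPs per sample with ~500 samples
matches real multiplex-GAM designs.

Slicing: each NP picks a structure uniformly, a slab orientation uniformly
on the sphere, and a slab offset uniform over the structure's extent along
that axis; the slab width is `thickness × extent` with `thickness = 0.05`,
the ~220-nm section to micron-scale nucleus ratio. Slabs may nearly miss
the structure — empty NPs are allowed, as in real data. A window is
detected when any of its beads (5 per window by default, matching published
bead-to-window ratios) falls inside the slab; a sample is the union of 3
NPs. For a locus at the centre of a spherically symmetric cloud this
geometry gives per-NP detection probability equal to `thickness`, and
`1 − (1 − p)³` under 3-NP pooling, which the tests verify.

The ground-truth contact matrix for reconstruction checks is the ensemble
mean of `1/(1 + d_ij)` over window-centroid distances — any monotone
proximity function would do; this one is smooth, bounded and fixed for
reproducibility.

**What the simulator does not emulate**: excluded-volume and polymer
entanglement, sequencing noise and mappability variation in coverage,
plate-level contamination structure, chromosome territories beyond a single
chromosome, and locus-specific binder-driven folding. A green recovery test
therefore establishes that the analysis code extracts planted structure
from geometrically sliced ensembles of the stated size — not that it is
robust to every artefact of real immunoGAM data.

## 9. Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere; chromosome names match
  literally (no "chr" stripping), and mismatching name sets raise an error
  listing both.
* Masked matrix entries are `NA`, never 0; all means are finite-value
  means.
* All-zero coverage samples warn and return empty detection with orphan
  fraction 0. Degenerate (constant) correlation matrices and chromosomes
  with fewer than 10 usable bins are skipped with a warning, yielding
  missing compartment labels.
* Every stochastic routine takes an explicit `seed`; ensembles and sliced
  tables are bit-reproducible given it.
* Round-trips: integer/boolean tables are exact; real-valued matrix text
  export holds 12 significant digits (asserted ≥ 9 in tests).

## 10. Known limitations

* The melting score inherits the pseudo-replication of pooled insulation
  values (§6); its p-values are calibrated for ranking and thresholding at
  score 5, not for literal frequentist interpretation.
* Boundary calling applies no prominence filter by default, so weak local
  minima inside noisy domains are reported; `min_prominence` is the remedy
  when precision matters more than recall.
* `npmi_genomewide()` materialises the full windows × windows matrix and is
  meant for trans–cis analysis at 250-kb bins or coarser, not for 50-kb
  genome-wide matrices.
* Compartment calling uses whole chromosomes; arm-level PCA (sometimes
  preferred for metacentric chromosomes) is not implemented.
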