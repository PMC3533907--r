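---
title: "Selecting homologs by spatial autocorrelation of conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting homologs by spatial autocorrelation of conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspacr)
```

## The problem

Functional regions of a protein — catalytic sites and their surroundings —
tend to appear as spatial clusters of evolutionarily conserved residues on
the molecular surface. Detecting them from a multiple sequence alignment
hinges on which homologs enter the alignment: close homologs make
everything look conserved; distant, functionally diverged homologs (a
paralog whose active site has moved, as in C-type lysozyme versus
alpha-lactalbumin) erase the conservation signal exactly where it matters.
`dspacr` selects the homolog set *from the structure itself*: among nested
candidate sets ordered by sequence identity to the query, it adopts the
one under which conservation is most strongly spatially autocorrelated on
the protein surface.

## The model and its statistics

**Surface graph.** The structure is reduced to one representative atom per
residue (C-beta; C-alpha for glycine) and tessellated together with a
synthetic solvent shell. Two residues are in contact when their Voronoi
cells share a facet — equivalently, when they form a Delaunay edge of the
joint point set. A residue whose cell touches a solvent point is a surface
residue; one touching another chain is an interface residue; the rest are
inner. All statistics run on surface residues only, on the assumption that
functional sites are at least partly solvent accessible.

**Neighborhoods.** Residue `j` is a neighbor of surface residue `i` when
(1) their representative atoms are within `D` angstrom (`D` swept from 5.0
to 9.0 by 0.5 by default), and (2) their separation degree — shortest path
length on the surface-induced contact graph — is at most 3. The path bound
removes residues that are close through space but far apart along the
surface.

**Conservation.** For alignment column `i`,

$$\mathrm{Cons}(i) = \frac{\sum_{j<k} W_j W_k\,
\mathrm{Mut}(s_j(i), s_k(i))}{\sum_{j<k} W_j W_k},$$

where `Mut` is the BLOSUM62 score min–max normalized to [0, 1] over the
standard 20x20 table (gaps and nonstandard letters score 0) and the
`W` are Henikoff–Henikoff position-based sequence weights, which damp
taxonomic redundancy. A fully conserved tryptophan column scores exactly 1;
a fully conserved alanine column scores 8/15 — the formula is applied
literally, with no per-column rescaling.

**DSPAC.** The Moran scatterplot pairs each scored surface residue's
standardized conservation `x_i` with the average centered conservation of
its neighbors, `A_i = \sum_{j \in N(i)} (y_j - \bar y)/n_i`. The degree of
spatial autocorrelation is reported as the Pearson correlation of this
scatter. With a z-scored x-axis, the regression slope and the correlation
agree up to the scale of the `A` axis; the correlation is the headline
number because it is scale-free and bounded in [-1, 1], and the raw OLS
slope is returned alongside (`slope`). Its significance is the standard
two-sided no-correlation t-test with `n - 2` degrees of freedom.

**Candidate sweep.** Hits are length-filtered (80–150% of the query,
inclusive), aligned, and thresholded into nested candidate sets at
`X = 85, 80, ..., 10` percent identity (16 conditions; identity is
computed on the pairwise projection of the master alignment with a
union-non-gap denominator). Sets with fewer than 10 sequences (query
included; exactly 10 is eligible) are skipped. Each eligible set is
realigned, mapped onto the structure, and scored by DSPAC at every `D`;
the cell with maximal DSPAC is adopted, ties breaking toward larger `X`,
then smaller `D`.

**LMIC and its null.** Conserved clusters are then located with a local
Moran statistic of conservation,

$$\mathrm{LMIC}_i = \frac{(\mathrm{Cons}_i - \overline{\mathrm{Cons}})
\sum_{j \in N(i)} (\mathrm{Cons}_j - \overline{\mathrm{Cons}})}{\sigma^2},$$

with the mean and the population (1/N) standard deviation taken over all
scored surface residues. Significance is assessed by a conditional Monte
Carlo test: residue `i`'s own value and position are held fixed and the
remaining conservation values are permuted over the remaining residues
(mathematically identical to the exchange of the other residues'
coordinates, and cheaper); 10,000 replicates by default. The threshold is
the 500th largest permuted value — the lowest score of the top 5% — and
`i` is flagged when its observed LMIC strictly exceeds it *and* its
conservation exceeds the surface mean. The observed value is not pooled
into the reference set, and **no multiple-testing correction is applied
across residues**: the flag rate among above-mean residues is ~5% under
the null by construction, which the calibration test verifies.

**Prediction and evaluation.** Each flagged residue seeds a predicted
region consisting of itself plus its neighborhood; the prediction is the
union over seeds. The reference functional region is the catalytic
residues plus every residue within 9 angstrom of their geometric center.
Predictions are scored over the universe of scored surface residues
(configurable to all residues) by sensitivity TP/(TP+FN), specificity
TP/(TP+FP) (a precision, in this convention), selectivity TN/(TN+FP) and
the F-score — the harmonic mean of sensitivity and specificity. Any 0/0
ratio reports 0, except selectivity with no true-or-false positives in
the denominator, which reports 1.

## Numerical and design choices

* **Tessellation.** Voronoi facet-sharing is computed as the Delaunay
  edges of the joint point set via an internal Bowyer–Watson kernel, with
  a final empty-circumsphere verification of every tetrahedron. A
  fixed-seed uniform jitter of 1e-4 angstrom breaks the exact
  co-sphericity of the cubic solvent grid; it is chemically negligible
  (PDB coordinates carry 1e-3 precision) while comfortably above
  double-precision predicate noise at protein coordinate magnitudes.
* **Solvent shell.** A cell-centered cubic grid (spacing 3.0, clash 2.5,
  margin 8.0 angstrom) stands in for scattered waters: deterministic,
  dependency-free, and sufficient to classify exposure. The parameters are
  configurable; the published water-scattering density they emulate is not
  documented, so these are this package's own choices.
* **Missing atoms.** A non-glycine residue without a C-beta falls back to
  its C-alpha (recorded); residues with neither atom are dropped with a
  warning. The first-listed altloc wins; insertion codes are part of the
  residue identity.
* **Degenerate cells.** Candidate cells with a constant conservation
  vector or a constant neighbor-average axis have no defined correlation;
  they are reported as degenerate and can never be adopted.
* **Weights.** Henikoff gap cells contribute no weight at their column and
  gaps do not count as a residue type; weights are normalized to sum to 1
  (the conservation formula is scale-invariant in the weights, so this is
  free and simplifies testing).
* **Separation degree** is computed on the subgraph induced by surface
  residues, matching the intent of excluding residues distant along the
  molecular surface.

## What the synthetic fixtures emulate

`toy_structure()` builds deterministic geometries: a hollow Fibonacci
sphere (every node classifies surface), an onion with an icosahedral core
(the core classifies inner), and a two-layer slab. Node spacing defaults
to 3.8 angstrom — the closest C-beta–C-beta packing distance in folded
proteins — which also keeps nearest-neighbor contacts immune to solvent
intrusion (half the spacing is below the 2.5 angstrom clash distance).

`simulate_family()` realizes the scenario that motivates DSPAC-based
selection: an in-group of 15 homologs whose identity targets span 85 down
to 45 percent conserves the planted surface patch exactly while diverging
elsewhere by BLOSUM62-conditional substitutions (realized identity is
counted, not assumed, and recorded); an out-group of 5 sequences is a
coherent functionally diverged subfamily clustered just below the 40
percent split, carrying its *own* conserved consensus at the antipodal
relocated patch — divergent from the root, as a real paralog's site would
be. Because the out-group enters the nested candidate sets as a block,
the DSPAC-versus-X curve rises as in-group divergence grows, then drops
when the out-group floods in: the convex signature, peaking at the split.

The scenario experiments fix the neighbor threshold at `D = 5.0`
angstrom — the grid value covering the generator's first contact shell —
and sweep only `X`. This mirrors the idealized exposition of the
selection mechanism, which assumes `D` known in advance: with a spatially
independent background the DSPAC profile over `D` is flat, so a joint
sweep would draw `D` essentially at random. Joint optimization over the
full 16 x 9 grid remains the default for real input, where background
conservation has spatial structure of its own. Problem sizes used by the
tests and the acceptance script (a 150-residue sphere, 20 replicates,
1,000 permutation replicates for the scenario runs) are chosen to make
the Monte Carlo assertions stable.

What passing these simulations does *not* show: real alignments contain
indels (the generator is indel-free, so its identity alignment is exact
and the external aligner is bypassed in tests), real backgrounds have
spatially structured conservation (secondary structure, buried cores),
and real functional regions are not perfect caps. The fixtures validate
the statistical machinery and the selection mechanism, not field
performance on PDB-scale data.

## Known limitations

* Monomers only: interface labeling exists, but the pipeline neither
  infers quaternary structure nor merges chains.
* No multiple-testing correction across residues, by design; predicted
  regions should be read as cluster seeds, not per-residue calls.
* The no-correlation test for DSPAC treats scatter points as independent,
  which neighboring residues are not; its p-value is heuristic and is not
  used for selection, only reported.
* Retrieval (BLAST) and alignment (MAFFT) are external: the package
  consumes FASTA hit lists and either precomputed alignments or a
  user-supplied aligner command.

## A worked run

```{r example, eval = FALSE}
ts  <- toy_structure("sphere", n = 150, patch_size = 10, seed = 1)
fam <- simulate_family(ts, seed = 1)
g   <- contact_graph(read_structure(ts$pdb_text, "A"))
sel <- select_homologs(fam$seqs, "query", g, aligner = identity_aligner(),
                       D_grid = 5)
glance(sel)
mc   <- lmic_mc_test(sel$adopted$scores, g, D = 5, n_perm = 1000, seed = 1)
pred <- predict_regions(mc, g, D = 5)
prediction_metrics(pred$node_id, functional_region(ts$patch, g), mc$node_id)
```
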