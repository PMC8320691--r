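---
title: "Paired mass distances as a reaction-level view of untargeted HRMS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired mass distances as a reaction-level view of untargeted HRMS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactomics)
```

## The model

Untargeted high-resolution mass spectrometry (HRMS) measures thousands of
features, most of which are never identified. Chemical reactions, however,
leave a simpler fingerprint than chemical identities: a substrate/product
pair differs by the mass of the atoms exchanged. The **paired mass
distance** (PMD) between two monoisotopic masses, `pmd(m1, m2) = |m1 - m2|`
rounded to a fixed decimal precision, is therefore a reaction-level
observable that can be computed directly from a peak table without
annotating any compound.

For a reaction with substrates $S_1,\dots,S_n$ and products
$P_1,\dots,P_m$ ($n, m \ge 1$), the package forms the full $n \times m$
grid of absolute mass differences, takes each substrate's minimum over the
products (the pair most likely to share a molecular framework),

$$\mathrm{PMD}_{S_k} = \min_i |S_k - P_i|,$$

and defines the reaction PMD as the deduplicated set
$\mathrm{PMD}_R = \{\mathrm{PMD}_{S_1},\dots,\mathrm{PMD}_{S_n}\}$. When
formulas are known, each value is annotated with the signed
element-count difference of its pair -- `+2H` for a hydrogenation,
`+2C3H`, `+2C4H/-O` and so on. Mining a reaction database (each reaction
contributing each of its values once) or a compound database (each
unordered unique-compound pair contributing once) yields a PMD frequency
database whose high-frequency values represent recurring chemistry.

```{r}
r00025 <- reaction_tbl(
  "R00025",
  substrates = data.frame(
    id = c("ethylnitronate", "oxygen", "reduced_FMN"),
    formula = c("C2H4NO2", "O2", "C17H23N4O9P")),
  products = data.frame(
    id = c("acetaldehyde", "nitrite", "FMN", "water"),
    formula = c("C2H4O", "HNO2", "C17H21N4O9P", "H2O")))
reaction_pmd(r00025, digits = 3)
```

Because a PMD is a difference, any mass shift common to both members of a
pair -- the same adduct, the same neutral loss, the same charge -- cancels
exactly. The PMD of two neutral compounds equals the PMD of their ions as
long as both carry the same adduct, which is what lets PMDs be read
straight off experimental m/z values.

## Static and dynamic PMDs, and biomarker reactions

In a peak table, two features at a matching mass difference may or may not
reflect one chemical relationship. The package separates:

* **static PMD pairs** -- the per-sample intensity ratio is stable:
  relative standard deviation (RSD) of the ratio below 30% *and* Pearson
  correlation above 0.6. These behave like two readouts of one underlying
  quantity and are usable for relative quantification;
* **dynamic PMD pairs** -- the ratio changes across samples; excluded
  from quantification.

The ratio is fixed as lower-m/z over higher-m/z intensity (RSD is
orientation-sensitive, so the convention matters and is tested). Samples
with a zero intensity on either side are excluded pairwise, and a pair
needs at least 3 usable samples before statistics are computed; pairs
without statistics are conservatively dynamic. Both thresholds are
arguments (`rsd_cutoff`, `cor_cutoff`); setting `cor_cutoff = -1`
reproduces the RSD-only variant some analyses use.

Relative quantification sums, per sample, the intensities of the union of
features participating in static pairs at one PMD (a feature in several
pairs counts once). `differential_pmd()` then compares two groups with a
Welch two-sample t-test. The published analyses test a single PMD; a
screening tool tests many, so Benjamini-Hochberg adjusted p-values are
reported across the tested set. A PMD whose summed intensity separates
the groups is a **biomarker reaction**: a reaction-level finding available
even when no contributing feature is identifiable.

## PMD networks and source appointment

Linking features (or database compounds) whose mass differences match a
set of high-frequency PMDs yields an undirected multigraph: parallel edges
with distinct PMD labels are kept, and PMD-0 edges mark isomer pairs
(excluded from `top_k_pmds()` by default). For peak networks an edge
additionally requires intensity correlation above `cor_cutoff`. The
targeted variant, `recursive_target_network()`, expands breadth-first
from a feature of interest, admitting features one PMD step away from the
frontier; every feature is admitted at most once, so the search terminates
and its node set equals the seed's connected component of the global
network -- a property the tests verify against an independent
graph-component oracle.

Topology summaries report the multigraph average degree $2E/N$
(self-loops count 2) and the average path length, read as the mean
unweighted shortest-path edge count over connected node pairs -- the
"edges end-to-end" view of how far chemistry can walk through the data.
Source appointment uses the empirical contrast that metabolites connected
by common biochemical PMDs form dense networks while xenobiotics sit in
sparse fragments: a node whose component's average degree exceeds 3 is
called endogenous, below exogenous, with the component's path length
reported as supporting (not vetoing) evidence. The classification is
deliberately made on the component average rather than the single node's
degree, which is noisy at the periphery of a dense module; the node degree
is still reported. `resample_degree_contrast()` repeats the pooled
mine-top-PMDs/build-network/average-degree computation over resampled
exogenous draws and reports percentile intervals, seeded and
bit-reproducible.

## Halogen screening

Brominated compounds betray themselves twice: a strongly negative mass
defect, and a $^{81}$Br/$^{79}$Br isotopologue partner ~1.998 Da above the
monoisotopic peak at roughly 1:1 intensity. `halogen_screen()` implements
the isotopologue test (partner at the spacing, median per-sample intensity
ratio within a window, default 0.5-2); `mass_defect_screen()` provides
the plain defect-window filter as a configurable secondary screen, since
no single defect window suits every acquisition.

## Numerical choices

* **Element masses.** Monoisotopic masses of the most abundant isotopes,
  NIST/AME values at full published precision, shipped as
  `element_masses()`. Compound masses are kept at full double precision;
  rounding happens only when a PMD is taken.
* **Rounding.** PMDs are rounded with a decimal-aware round-half-even:
  inputs are often themselves decimal-rounded masses (databases print 4
  decimals), which makes exact decimal halves like 27.0235 a real case
  rather than a measure-zero event; binary `round()` falls on the wrong
  side of such halves. Database PMDs default to 3 decimals, experimental
  matching to 2 -- matching the precision at which instruments separate
  reaction PMDs -- and both are arguments everywhere.
* **Matching.** Pairs match by rounding to `digits` decimals rather than a
  ppm window, mirroring how reference PMD values are tabulated. Rounding
  keeps matching transitive and reproducible across tools.
* **Tie-breaks.** When two products tie for a substrate's minimum, the
  first product in input order is reported; the PMD value is unaffected.
  Duplicate values within one reaction collapse to one entry with
  composition annotations unioned. `top_k_pmds()` breaks frequency ties by
  increasing PMD value, so selections are deterministic.
* **Composition deltas** are reported heavier-compound minus
  lighter-compound, the only direction consistent with annotating an
  absolute difference (`+2C4H/-O` for the oxygen/acetaldehyde pair, where
  the substrate is the lighter species).
* **Charged species.** Masses are used as supplied; no electron-mass
  correction is applied, because PMDs cancel it whenever both members
  share the adduct and charge state -- the only situation in which an
  experimental PMD is meaningful anyway.
* **Degenerate inputs.** Empty networks summarize to zeros with a
  warning; a quantification with no static pair returns an empty result
  with a warning; reactions with compounds lacking both mass and formula
  are skipped from database builds with a warning count.

## What the synthetic generators emulate

The generators exist so that every operation is testable against known
ground truth without downloading databases or repository data.

* `gen_reactions()` plants composition deltas (default: `+2H` in 30 of 50
  reactions) into single-substrate/single-product reactions, so database
  frequencies are known by construction.
* `gen_peak_table()` emulates an LC-MS feature table: log-normal
  between-sample variation (sd 0.5 on the log scale) times log-normal
  technical noise (default sigma 0.1, a typical QC-level intensity CV);
  static pairs share one latent per pair, dynamic pairs use independent
  latents. The default study design mirrors the biomarker-reaction
  setting: 100 samples split 50 cases / 50 controls, a planted
  dehydrogenation biomarker (two static pairs at 2.0157 Da, four
  features) reduced 30% in cases, plus five static and five dynamic
  pairs at a CH2 step. Planted m/z spacings are exact at the writer's
  4-decimal precision, so rounding behaviour is exercised by the matching
  `digits`, not hidden in the generator. Optional Br doublets sit at
  1.998 Da with a 0.97 intensity ratio.
* `gen_compound_pools()` reproduces the endogenous/exogenous connectivity
  contrast: endogenous compounds lie on chains sharing a CH2 mass step, so
  the pooled top-frequency PMDs (the step and its low multiples) link each
  chain into a near-complete subgraph; chain lengths are mixed to land the
  mean degree on the 4.5 target. Exogenous compounds form sparse pairs and
  triplets on the same step, mixed 30/70 to land on 1.7. A fully
  unstructured exogenous pool would have mean degree near zero, which
  would make the contrast trivial and unrepresentative -- real xenobiotics
  do share occasional transformation steps, they just do not form dense
  modules. Realized degrees run a few percent above the targets because
  chain-offset coincidences contribute extra top-frequency values; the
  generator's contract (within 20% of target) is asserted in the tests.

What passing these tests does *not* show: the generators have no
chromatographic structure, no adduct/fragment redundancy beyond the Br
doublet, no missing-value mechanism, and feature intensities are
independent across planted structures. Real peak tables violate all four,
which is why the retention-time gap filter, the isotopologue screen and
the configurable thresholds exist as explicit knobs rather than baked-in
behaviour.

## Problem sizes and reproducibility

The test suite and the acceptance script run the statistical checks at
deliberately modest sizes -- 100-replicate power runs on 100-feature,
100-sample tables; 200-replicate null calibrations on 10-feature tables;
100-replicate resampling contrasts on pools of 55 + 120 compounds --
which keeps a full run near half a minute while leaving every conclusion
comfortably inside its binomial tolerance. Every stochastic entry point
takes a `seed` argument and is bit-reproducible under it.

## Known limitations

* PMD analysis needs high mass resolution: at 2 decimal places, distinct
  reactions separated by a few mDa collapse; the `digits` arguments
  expose, but cannot remove, that limit.
* Redundant peaks (adducts, isotopologues, in-source fragments) of one
  compound produce pairs that are chemically trivial; the retention-time
  gap and isotopologue screens mitigate but do not eliminate them, and
  whether to exclude such pairs before quantification is left as an
  explicit option.
* Compound networks built from pairwise mass differences assert *possible*
  relationships, not pathway membership; the endogenous/exogenous call is
  a prior, not an identification.
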