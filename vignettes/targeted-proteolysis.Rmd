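---
title: "Quantifying time-resolved targeted proteolysis with proteocut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying time-resolved targeted proteolysis with proteocut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteocut)
library(dplyr)
```

## The problem

When a protease digests a *folded* protein, the observable products tell a
story in two dimensions: *where* the enzyme cuts (sequence and surface
accessibility) and *when* (early cuts at exposed bonds relax the fold and
expose previously buried bonds, so proteolysis proceeds as sequential
unfolding). A time-resolved targeted-proteolysis experiment samples a
protease–substrate digest at a series of time points, identifies the peptide
products by LC-MS, and quantifies each product's intensity across replicates.
proteocut turns those replicate peptide-intensity tables into:

* per-residue **relative cut frequencies** over time, the core statistic;
* a **specificity profile** of the residues surrounding the scissile bond
  (positions P5–P1 and P1′–P5′ in Schechter–Berger nomenclature);
* per-residue **structural context** (secondary structure, B-factors,
  solvent accessibility, sequence conservation);
* an explicit, reproducible **cleavage-event ordering** — the computational
  form of a sequential-unfolding model;
* and a **stochastic digestion simulator** with accessibility-gated site
  kinetics, used throughout the test suite as a ground-truth generator.

Coordinates are 1-based and inclusive; a cleavage site is identified by its
P1 residue, the residue N-terminal to the scissile bond. Except at the chain
termini, every product is the evidence of two cuts: one at `start - 1`
(where the product's first residue is P1′) and one at `end` (P1).

## The relative cut frequency

For each peptide, digest intensities are averaged over retained replicates
at each time point, counting non-detections as zero. The average is set to
zero wherever the peptide is not significantly enriched over the
protease-free control at that time point. Each peptide's averages are then
converted to ratios against its *first* positive average along the time
course, and the relative frequency of cuts at a P1 site at time $t$ is

$$ f_{P1}(t) \;=\; \sum_{\text{peptides } p \,\ni\, P1} \frac{\bar I_p(t)}{\bar I_p(t_{\mathrm{ref}(p)})}, $$

the sum of the ratios of all peptides sharing that scissile bond. The ratio
construction makes the statistic invariant to a peptide's absolute intensity
scale (ionisation efficiency), which is what makes sums across peptides
meaningful.

Two readings of the definition were open and are both implemented:

* **Bond support.** A peptide evidences both of its bounding bonds; by
  default it contributes its ratio to both (`both_bonds = TRUE`). A
  C-terminal-only mode is available, since some tools group products only by
  their P1 (C-terminal) cut.
* **"Experiment".** Averages are taken per *time point* across replicates,
  because ratios are subsequently formed *along* time points — the only
  reading under which the algorithm composes.

Sites are classified by the *maximum* of their frequency profile using
half-open bins. Two presets mirror the two study designs the statistic was
built around: `"anxa1"` (undetected, 1–10, 11–19, ≥20), for a
conformation-selective protease on an all-helical substrate, and `"mdh"`
(undetected, 1–20, 21–30, ≥30) for a sequence-selective protease. The
narrative boundary "between 21 and 30" overlaps "≥30"; we resolve it with
half-open bins, assigning 30 to the top class.

## Filtering

The filter stack reproduces a standard targeted-proteolysis configuration:
identification score ≥ 50, significance level α = 0.05, log2 intensity
transform, and replicate exclusion below a mean pairwise Pearson correlation
of 0.4 (computed per condition × time point on jointly detected, log2
intensities).

The relevance filter is a **homogeneity-of-regression-slopes test**: for each
peptide, transformed intensity is regressed on time × group (digest vs
control) and the interaction F-test (1 and $n-4$ degrees of freedom) asks
whether the digest slope differs from the control slope. A product of
genuine proteolysis accumulates in the digest and stays flat in the control.

Two transform details matter and are deliberate:

* Zero intensities are *missing* for correlations (dropout is non-detection,
  and a shared floor would inflate correlations), but enter the slope and
  per-time-point tests as `log2(x + 1)` floor-level measurements. Protease-free
  controls are structurally zero for every product; treating their zeros as
  missing would leave the tests without a comparison group at all.
* The per-time-point test is a one-sided Welch test (digest > control),
  because products can only be enriched over controls. When both groups are
  essentially constant (exactly the situation in noise-free simulations) the
  t statistic is undefined and we decide by the group means (p = 0 or 1).

No multiple-testing correction is applied by default, matching the plain
α = 0.05 configuration; Benjamini–Hochberg is available via
`filter_config(adjust = "BH")`. Both tests are calibrated empirically in the
test suite: under null simulations with log-normal intensity noise (log-scale
Gaussian) at 1,000 replicates their type-I error stays within 0.05 ± 0.02.

## The digestion simulator

`simulate_digestion()` is an exact, per-molecule stochastic simulation. Each
substrate copy carries a set of cleavage sites; site $i$ has an intrinsic
rate $k_i$ (s⁻¹) and, optionally, a conjunctive *gate*: a set of
prerequisite sites that must already be cut on that molecule before site $i$
becomes cleavable. Every cleavable bond fires as an independent exponential
clock. Because clocks are independent and a cut only ever *unlocks* other
sites, the firing time of site $i$ on a molecule is distributed exactly as

$$ T_i = \max_{j \in \mathrm{gate}(i)} T_j + \mathrm{Exp}(k_i), $$

which we sample site-by-site in topological order for the whole ensemble at
once — an exact draw from the event-driven process, vectorised across
molecules. Gates must be acyclic; cyclic definitions are rejected at
construction.

Products are the maximal intervals between consecutive cuts on a molecule;
only those whose length falls in the detectable window (default 7–25
residues, the peptide-length range of a standard identification search) are
observable, and the remainder are retained for residue mass-balance checks.
Measurement noise is multiplicative log-normal (default sdlog 0.5, roughly a
50% CV typical of label-free MS), with dropout probability 0.2 per
measurement, intensity scale 10⁶ per molecule, and an optional detection
limit in molecules (default 0). Controls carry exactly zero product
intensity. Four replicates and an 11-point 0–3600 s sampling grid are the
default study conditions.

**What the simulator does not emulate:** enzyme–substrate binding kinetics,
sequence-dependent rates, missed cleavages as a chemical process, charge
states, retention times, or intensity-dependent identification bias. Passing
tests on simulated data therefore validate the *statistical machinery* —
coordinate bookkeeping, filtering, the frequency statistic, ordering — not
the chromatographic or spectral behaviour of a real instrument.

### Shipped scenarios

`scenario_pseudo_anxa1()` is the default ground truth: a fixed 346-residue
pseudo-substrate with three fast ungated "surface" sites (P1 41, 82, 107;
k = 0.04/0.03/0.02 s⁻¹), six gated second-wave sites unlocked by them, a
four-site C-terminal block with steeply decreasing rates
(0.002 → 10⁻⁴ s⁻¹) gated in a chain, and eleven ungated minor sites
(k = 0.015 s⁻¹) scattered along the chain. The minor sites play the role of
the secondary low-affinity cuts that accompany major sites in real digests,
and they guarantee that every major site has at least one observable
flanking product. Rates are free parameters of the scenario — the
experimental system provides no kinetic constants — chosen so that the
3600-s window spans the onset of every reachable site.

`scenario_rate_ladder()` exists for one purpose: rank-recovery validation.
At the first sampled time point every detected peptide's ratio is 1 by
construction, so a site's first-time frequency is a *count* of detected
supporting products; whether that count grades with the site's rate is a
question of detection geometry, not abundance. The ladder therefore spaces
45 ungated sites 3 residues apart (several potential partner products per
site inside the detectable window) and assigns a geometric ladder of rates
(2×10⁻⁴–4×10⁻³ s⁻¹) as a "tent" along the chain — slowest at the ends —
so that chain-end sites, which have fewer partners, carry rates whose counts
are uninformative anyway. A count-model power analysis of this design gives
Spearman ρ ≈ 0.95 at 10,000 molecules.

### Ordering and the detection floor

Cleavage events are ordered by onset time (first time point with positive
frequency), then maximum frequency (descending), then position — an explicit
encoding of "early onset plus high frequency marks the initiating cuts". The
output is a model hypothesis, not an observed trajectory; per-molecule truth
lives only in the simulator's event log, against which
`order_concordance()` computes Kendall's τ and the fraction of
(prerequisite → dependent) gate pairs ranked in the causal direction.

Recovering causal order needs two regimes chosen deliberately. First, the
evaluation reduces the protease ten-fold (`protease_multiplier = 0.1`), the
standard experimental trick for spreading early events across the sampling
grid. Second, it sets the simulator's detection limit to 10 molecules (0.1%
conversion): with a single-molecule floor, every site's onset collapses to
the first time point at ensemble size 10⁴ — one molecule in ten thousand
fires even deeply gated chains almost immediately — and onset carries no
information. A real instrument cannot see single molecules either; the
detection floor is what makes onset a meaningful observable. Sites that
never reach the floor within the sampled window (the two deepest C-terminal
sites under the reduced-protease regime) yield no rank and their gate pairs
are excluded as unmeasurable rather than counted as ordered or misordered.

## Structure and conservation tracks

Structures are read from PDB files (one chain; altloc duplicates resolved by
highest occupancy; hydrogens dropped). Secondary structure comes from the
file's HELIX/SHEET records — the assignment deposited with the crystal
structure — with helix precedence on overlap and loop elsewhere; no DSSP
reimplementation. Residue numbering is reconciled with the substrate by
finding the constant offset at which every modelled residue matches, the same
mechanism used to map a truncated recombinant construct onto native
numbering.

Solvent accessibility is numerical Shrake–Rupley: 960 quasi-uniform test
points per atom (golden-section spiral) on the solvent-expanded sphere
(van der Waals radius + 1.4 Å probe), occluded by neighbouring expanded
spheres. Residue ASA is normalised to relative solvent accessibility with
the Tien et al. (2013) theoretical maxima, clamped to [0, 1]; residues at
RSA ≥ 0.2 are classified surface. The binary surface/buried track published
with such experiments states no cutoff or method; our RSA rule is an
explicit, documented stand-in, not a claim of equivalence. The 960-point
default agrees with a 10,000-point reference within 2% on a 50-atom test
structure (checked in the suite), and the sphere count only trades accuracy
for time.

Conservation symbols follow the Clustal convention — `*` identical, `:` all
residues within one strong group, `.` weak group, blank otherwise (any gap
in the column gives a blank) — mapped to substrate numbering through the
gapped reference row.

## Specificity

`aa_distribution()` tallies the residues at window positions P5–P1 and
P1′–P5′ (±5 residues, the standard window) over the sites cut by a given
time. By default each significant site counts once; weighting by frequency
is optional — published percentage tables rarely state their weighting, so
both modes are provided and labelled. The terminus padding symbol `-`
participates in normalisation as its own category, so columns always sum to
100%. Consensus takes the per-position argmax, breaks ties alphabetically
(flagged), and reports positions whose maximum falls below 10% in lower
case. Condition comparison uses per-position total variation distance in
percentage points, and `specificity_convergence()` traces that distance over
time — the signature of a folded digest converging on its denatured
counterpart as unfolding proceeds.

## Numerical choices and degenerate inputs

* Ratios of an all-zero average series are all zero; the ratio is zero
  before the reference time and wherever the average is zero.
* Ambiguously mapping peptides (multiple exact occurrences) are discarded by
  default with a warning — a wrong coordinate corrupts every downstream
  per-site statistic — or kept at their first occurrence by option.
* Fragment merging treats overlap and immediate adjacency (gap 0) as one
  fragment; the merge is delegated to IRanges, whose default `reduce()`
  semantics are exactly this rule, and is verified against a boolean
  coverage-mask oracle in the tests.
* Replicate QC requires at least 3 jointly detected peptides per pair;
  groups where no correlation is computable (e.g. all-zero controls) are
  retained with `mean_r = NA`. If exclusion would leave fewer than two
  samples in a group, the best samples are kept with a warning.
* `classify_sites()` bins are half-open on lower bounds, so non-integer
  maxima classify unambiguously.
* The initiator methionine is never trimmed automatically: the FASTA
  sequence provided is authoritative for numbering.
* All randomness flows through explicit seeds; identical configuration and
  seed reproduce every output byte-for-byte (checked in the suite).

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
ensembles of 10,000 molecules for distributional checks (exponential law,
mass balance, rank and order recovery over 20 seeds), 2,000 molecules for
the noisy end-to-end run, 1,000 replicates for test calibration, and
1,000 random interval sets for the fragment-grouping oracle. These sizes
were chosen as the smallest at which the binomial/Monte-Carlo tolerances
used in the assertions are comfortably above their standard errors.

## Known limitations

* The statistic is relative by construction: no absolute quantification and
  no kcat/KM estimates can come out of it.
* Peptides from poorly cleaved sites are detected irreproducibly in real
  data; interpretation should focus on well-cleaved sites, and the
  simulator's dropout model only crudely mimics this.
* The event ordering is substrate-global (one timeline), mirroring the way
  such models are drawn; it does not model per-molecule heterogeneity beyond
  what the gate-recovery statistics report.
* Sequence windows near the termini are padded, and the padding symbol is a
  reportable category; comparisons across substrates of very different
  lengths should use the per-residue tables, not the consensus strings.
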