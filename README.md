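# proteocut

Quantitative analysis of **time-resolved targeted proteolysis** (degradomics)
experiments: how a protease digests a single folded substrate, site by site,
over time.

A digest of a protease–substrate pair is sampled at a series of time points;
the peptide products are identified by LC-MS and quantified across replicates
together with protease-free controls. Starting from that peptide-intensity
table (a MaxQuant `peptides.txt`-style TSV) and the substrate FASTA,
proteocut computes:

* **Relative cut frequency per P1 site.** Peptides sharing a scissile bond
  (the residue N-terminal to the bond is P1, Schechter–Berger nomenclature)
  are grouped; each peptide's replicate-averaged intensities are expressed as
  ratios against its first positive average along the time course, and the
  frequency at a site is the sum of its peptides' ratios:
  `f_P1(t) = Σ_p Ī_p(t) / Ī_p(t_ref(p))`. The ratio construction cancels
  per-peptide ionisation efficiency, so sites are comparable.
* **Filtering against controls.** Score ≥ 50, replicate Pearson QC at 0.4, a
  homogeneity-of-regression-slopes (ANCOVA interaction) F-test for peptide
  relevance, and a one-sided Welch test per time point that zeroes averages
  not enriched over the protease-free control (α = 0.05, log2 transform).
* **Fragment maps** — gapless coverage intervals per time point, with peptide
  and cleavage-site counts.
* **Specificity profiles** — amino-acid percentages at window positions
  P5–P1/P1′–P5′ around the cut, consensus strings, and total-variation
  distances between conditions over time.
* **Structure annotation** — secondary structure from PDB HELIX/SHEET
  records, per-residue B-factors, numerical Shrake–Rupley solvent
  accessibility (RSA on the Tien 2013 scale; surface at RSA ≥ 0.2), and
  Clustal-style conservation symbols from a multiple sequence alignment.
* **Cleavage-event ordering** — sites ranked by onset time, then maximum
  frequency, then position, with a stepwise fragmentation timeline: the
  computational form of a sequential substrate-unfolding model.
* **A stochastic digestion simulator** — per-molecule exponential-clock
  kinetics with *accessibility gates* (a buried site becomes cleavable only
  after prerequisite cuts on the same molecule), detectable-length windows,
  log-normal noise, dropout, and protease-free controls. It writes the same
  table dialect the analysis reads and keeps its event log as ground truth.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` methods for profiles,
fragment maps, specificity matrices and timelines.

## Worked example

Simulate the default scenario — a 346-residue pseudo-substrate with three
fast surface sites, gated second-wave sites and a slow C-terminal block —
then run the full analysis:

```r
library(proteocut)
library(dplyr)

gt   <- scenario_pseudo_anxa1(n_molecules = 2000)
tab  <- simulate_peptide_table(gt, seed = 42)   # 4 replicates, 0-3600 s, controls
qc   <- replicate_qc(tab$peptides)              # Pearson 0.4 exclusion
kept <- score_filter(apply_qc(tab$peptides, qc), 50)
rel  <- peptide_relevance(kept)                 # slope-homogeneity F-test
mapped <- map_peptides(filter(kept, sequence %in% rel$sequence[rel$relevant]),
                       gt$substrate)
prof <- relative_cut_frequency(mapped, gt$substrate)
glance(prof)
#> # A tibble: 1 × 4
#>   n_sites n_time_points max_frequency first_onset
#>     <int>         <int>         <dbl>       <dbl>
#> 1      19            11         3007.          15
```

Nineteen P1 sites carry signal; the first cuts are already visible at the
15 s time point. Ranking sites by onset, then maximum frequency:

```r
head(tidy(order_events(prof, min_frequency = 1)), 5)
#> # A tibble: 5 × 5
#>    rank    p1 onset_time max_frequency tie_break
#>   <int> <int>      <dbl>         <dbl> <chr>
#> 1     1   170         15         3007. onset
#> 2     2   134         15         1562. frequency
#> 3     3   142         15         1562. position
#> 4     4   126         15          285. frequency
#> 5     5   117         15          216. frequency
```

Classifying sites by their maximum frequency and profiling P1 preferences at
the final time point:

```r
classify_sites(prof) |> count(class)
#> # A tibble: 3 × 2
#>   class     n
#>   <fct> <int>
#> 1 1-10      5
#> 2 11-19     1
#> 3 >=20     13

aa_distribution(prof, gt$substrate, 3600) |>
  filter(position == "P1") |> arrange(desc(percentage)) |> head(3)
#> # A tibble: 3 × 3
#>   position residue percentage
#>   <fct>    <chr>        <dbl>
#> 1 P1       P            25
#> 2 P1       L            16.7
#> 3 P1       A             8.33
```

The percentages are fractions of the distinct cut sites detected by 3600 s,
per window position (columns always sum to 100%). `fragment_timeline()`
turns the ranked events into interval splits, and `order_concordance()`
scores an inferred order against the simulator's event log.
`run_pipeline()` drives all stages from a single YAML/list configuration and
writes TSV/JSON outputs plus a seed- and hash-stamped manifest. The methods
vignette (`vignettes/targeted-proteolysis.Rmd`) documents the statistic, the
simulator's model and its limits, and every numerical choice.

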