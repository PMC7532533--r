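# phylocomp

Cancer driver mutations are strongly selected *for* in tumors and
strongly selected *against* in organisms — yet some driver amino-acid
states occur as the wild type in other species. `phylocomp` is an R
package for asking how: it locates driver states across deep gene-family
phylogenies and infers the **compensatory mutation ensembles** that
plausibly neutralize them, for computational biologists working with
protein alignments, gene trees and tumor mutation tables.

## What it computes

Given a per-gene protein MSA (with a designated human reference row), a
rooted tree, taxon annotations, a per-tumor mutation table and
optionally a structure hit table, the pipeline:

- ranks mutations by tumor recurrence (rank = 1 + number of distinct
  mutations observed more frequently) and selects up to 9 drivers per
  gene with rank < 20 and at most 5 more-frequent distinct missense
  mutations;
- scores column conservation as sum-of-pairs **homogeneity**
  `H = (S − S_rand)/(S_hom − S_rand)` under BLOSUM62, with ±3-site
  neighborhood means and deep/shallow site classification;
- assigns **leaf weights** by a root-to-tip recursion (child weight
  `A·B/C`, where `A` is the child's incoming branch plus subtree length)
  that conserves the total tree weight and down-weights dense clades;
- reconstructs ancestral states per column by a **weighted two-pass
  (Fitch-style) procedure** with pseudo-conditional products, assigns a
  residue where its weight exceeds 0.5, and places transitions at branch
  midpoints;
- builds **compensatory ensembles**: minimal sets of states, transitioning
  on the same or ancestral branches as the driver, covering every
  driver-bearing leaf, arising at ≥ 2 independent nodes (each with ≥ 2
  driver leaves below), and individually improbable under the binomial
  tail `Σ_{k=N_pair}^{N_total} C(N_total,k) F^k (1−F)^{N_total−k}` at
  p < 0.01;
- scores mutation-pair association in tumors and in the leaf-weighted
  MSA with the signed Poisson log-tail
  `Score = −ln(1 − PCDF(exp, obs))` (obs > exp) or `ln PCDF(exp, obs)`
  (obs < exp), discarding |Score| ≤ 1, and classifies sign quadrants;
- summarizes clade-level driver prevalence (leaf-weighted frequencies,
  1000× bootstrap quartiles, species mode residues, target clades,
  species-frequency histograms);
- selects covering structures by Global/Local Score (bit score over
  protein/footprint length), best per site by `global² + local²` and
  best per driver/compensator pair by Local Score ≥ 1.9.

A fully seeded synthetic-data module (`simulate_gene_family()`)
generates trees, alignments with planted driver/compensator histories,
taxon tables, tumor tables and hit tables, so the whole chain runs and
is tested without any external database.

## Worked example

```r
library(phylocomp)

bundle <- simulate_gene_family(seed = 1)   # complete toy gene family
report <- run_gene(bundle$family, bundle$tumor_table,
                   hits = bundle$hits, n_tumors = bundle$n_tumors)
glance(report)
#> # A tibble: 1 × 6
#>   gene  n_candidates n_drivers n_ensembles n_kept_associations n_tumors
#>   <chr>        <int>     <int>       <int>               <int>    <dbl>
#> 1 GENE1           10         6           1                   0      500

tidy(report) |> dplyr::filter(accepted) |>
  dplyr::select(column, residue, n_total, n_pair, f, p, members)
#> # A tibble: 1 × 7
#>   column residue n_total n_pair     f       p members
#>    <int> <chr>     <int>  <int> <dbl>   <dbl> <chr>
#> 1     30 P             4      4 0.204 0.00173 15:D
```

Reading: the planted driver (alignment column 30, residue P) underwent 4
independent transitions in the reconstructed ancestry, all 4 descending
from transitions to the state D at site 15, which occupies 20.4% of the
tree — a pairing with probability 0.0017 under independence, so site
15:D is reported as the driver's compensatory ensemble (it is exactly
the planted compensator). `autoplot(report$conservation)`,
`plot_association_quadrants()`, `plot_clade_frequencies()` and
`plot_structure_coverage()` draw the standard displays, and
`write_report(report, dir)` emits all stage tables as TSV.

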