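---
title: "Detecting driver states and compensatory ensembles in deep gene-family phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver states and compensatory ensembles in deep gene-family phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocomp)
library(dplyr)
```

## The problem

Recurrent missense mutations in cancer genes ("drivers") are strongly
deleterious to the organism, yet the same amino-acid states occasionally
appear as the wild type in other species. The standard explanation is
intragenic compensation: another residue change, fixed earlier on the
same lineage, neutralizes the damage. `phylocomp` implements a complete
analysis chain for this question: it ranks tumor mutations, measures the
conservation of their sites, reconstructs ancestral states across a deep
gene-family phylogeny, searches for *compensatory ensembles* — minimal
sets of residue states that always accompany the driver state across
species and preceded it in the reconstructed history — and
cross-examines mutation pairs in tumor data and in the alignment with a
common association score. A seeded simulator generates gene families
with planted driver/compensator histories so every stage is testable
without any external database.

## Driver ranking and selection

Within a gene, every distinct non-polymorphism mutation is counted
across tumor samples and ranked: rank = 1 + the number of distinct
mutations observed in strictly more tumors, so ties share a rank.
Selected drivers are missense mutations with rank below 20 that are
observed less frequently than at most 5 distinct missense mutations, at
most 9 per gene (`rank_threshold`, `missense_threshold`, `max_per_gene`
in `run_config()`). "Below 20" is implemented strictly (`rank < 20`);
the rank counts mutations of any class while the second criterion counts
missense only, which is why both fields are kept. Truncation ties are
broken by tumor count, then rank, position and residue, so selection is
reproducible.

## Column homogeneity

Conservation of an alignment column is summarized by a sum-of-pairs
score under BLOSUM62, linearly rescaled so that a column of residues
drawn from the background amino-acid distribution scores about 0 and a
maximally self-scoring homogeneous column scores 1:

$$H = \frac{S - S_\mathrm{rand}}{S_\mathrm{hom} - S_\mathrm{rand}},$$

where $S$ is the column's sum-of-pairs score over its $n$ non-gap
residues, $S_\mathrm{rand} = \binom{n}{2}\sum_{a,b} f_a f_b M(a,b)$ is
the analytic expectation under the background frequencies $f$, and
$S_\mathrm{hom} = \binom{n}{2}\max_a M(a,a)$. With the default `"max"`
convention $H = 1$ is attainable only by the top self-scoring residue
(tryptophan under BLOSUM62); the `"consensus"` mode divides by the
column's own majority residue instead, making every homogeneous column
score exactly 1. Both the matrix and the background are arguments;
backgrounds default to the empirical residue frequencies of the scored
rows over the whole alignment. $S_\mathrm{rand}$ is computed in closed
form rather than by simulation so results are deterministic. Values
below 0 are possible and deliberately not clamped; columns with fewer
than two residues return `NA`, which is distinct from 0.

Neighborhood homogeneity is the mean over a site and its three
neighbors on each side (seven values in the interior); at the alignment
edges the mean runs over whatever neighbors exist. The tree-building
site filter keeps columns with gap fraction at most 0.5 and homogeneity
at least 0.1. A site is "deep" when at least one fungal or plant
sequence has a residue there, "shallow" otherwise.

## Leaf weights

Densely sampled clades would otherwise dominate every frequency, so
sequences are weighted by tree structure. The root is assigned the total
tree weight $T$ (the sum of all branch lengths) and each node passes its
weight to its children in proportion to $A$, the child's incoming branch
length plus the summed branch length of its entire subtree. Formally a
child's weight is $A \cdot B / C$ with $B$ the parent's weight and $C$
the sum of $A$ over the parent's children. Reading $A$ as "incoming
branch plus subtree" (rather than immediate child branches only) makes
weight conserved at every split, so the leaf weights always sum to $T$;
the alternative reading breaks this conservation, which is why it is not
offered. When all child branches and subtrees have zero length the
weight is split equally.

## Weighted ancestral reconstruction

For each alignment column, a bottom-up pass gives every node a character
weight vector: the per-residue sums of descendant leaf weights,
normalized to 1 (leaves gapped at the column carry no character). A
single top-down pass then forms each interior non-root node's
pseudo-conditional vector as the normalized elementwise product of its
own bottom-up vector with its parent's bottom-up vector; the root, which
has no ancestor, keeps its bottom-up vector, and leaves keep their
observed residue. A node is assigned the arg-max residue when its final
weight strictly exceeds 0.5, otherwise it is undefined; an exact
0.5/0.5 split therefore stays undefined. The product pass is single-pass
by design — iterating it to a fixed point would sharpen assignments but
has no obvious probabilistic reading.

Transitions are placed at the midpoints of branches whose endpoints
carry different defined residues. Undefined stretches are bridged: if
the nearest defined ancestor of a defined node carries a different
residue, one transition is recorded on the branch entering that node; if
the flanking residues agree, none is. Attributing the bridged transition
to the last branch (entering the first defined descendant) is the
conservative choice for compensator precedence queries, which treat the
whole undefined span as available "prior" territory.

## Compensatory ensembles

For a driver state (a column and residue), candidate compensators are
states at other sites with at least one transition on the same branch
as, or any ancestral branch of, a transition to the driver state. An
ensemble is accepted when all of the following hold:

1. every driver-bearing leaf carries at least one member state;
2. the co-occurrence probability (below) is under 1%;
3. the members' transitions occur at two or more independent nodes;
4. at least two driver-bearing leaves descend from each such node.

The probability model: with $N_\mathrm{total}$ transitions to the driver
state in the whole ancestral record, $N_\mathrm{pair}$ of them on or
below a transition to a compensatory state, and $F$ the fraction of
applicable branch length occupied by that state, the chance of the
observed pairing under independent placement is the binomial upper tail
$\sum_{k=N_\mathrm{pair}}^{N_\mathrm{total}} \binom{N_\mathrm{total}}{k}
F^k (1-F)^{N_\mathrm{total}-k}$. Occupancy $F$ counts branches whose two
endpoints both carry the state in full and transition branches at half
length, over the branches where the site's assignment is defined at both
endpoints.

For ensembles of several members the test is applied *per member*: each
member must individually satisfy the binomial criterion, and the
ensemble's probability is its weakest member's. We also evaluated the
alternative of a single pooled test with the union of the members'
occupied branches: it is badly anti-conservative, because the search is
free to assemble unions of individually unremarkable states that happen
to cover the driver's leaves — in null simulations with independent
placement roughly a third of drivers acquired such an ensemble. The
per-member rule restores calibration (no false ensembles in 200 null
families at the 1% threshold) while leaving genuine single compensators
untouched. The pooled pairing count and union occupancy are still
reported descriptively.

The search enumerates candidate subsets by increasing size when the
(individually viable) pool has at most 15 states, stopping one size
above the smallest accepted ensemble, since much larger ensembles than
the minimal one are not meaningfully interpretable; larger pools are
searched greedily from the best singleton, adding the candidate that
most improves the probability while extending coverage. Drivers present
in fewer than 4 leaves are skipped outright — below that the later
criteria cannot be satisfied non-trivially and a single sequencing error
could fabricate a signal. Across the drivers of a gene, accepted
ensembles are consumed in order of increasing probability and each state
may join at most one ensemble; remaining drivers are re-searched with
consumed states excluded.

Two open points were resolved as follows: criterion 3 pools transitions
over the ensemble's members (a per-member variant can be obtained by
building singleton ensembles); and branches where the member's site is
undefined are excluded from both the numerator and denominator of $F$,
so a partially alignable compensator is judged only on the branches
where its state is known.

## Association scores

For every pair of mutation states with at least one selected driver,
expected and observed co-occurrence counts are computed twice. In the
tumor table: $\mathrm{exp} = f_1 f_2 N$ over $N$ tumors with per-tumor
state frequencies $f_i$, and $\mathrm{obs}$ the number of tumors
carrying both. In the alignment: leaf weights are renormalized over
sequences with residues at both columns, and with $n$ such
nonzero-weighted sequences, $\mathrm{obs}$ is $n$ times the summed
weight of sequences carrying both residues and $\mathrm{exp}$ is $n$
times the product of the per-state summed weights (both may be
non-integer). The score is the signed Poisson log-tail

$$\mathrm{Score} = \begin{cases}
-\ln(1 - \mathrm{PCDF}(\mathrm{exp}, \mathrm{obs})) & \mathrm{obs} > \mathrm{exp}\\
\ \ \ \ln(\mathrm{PCDF}(\mathrm{exp}, \mathrm{obs})) & \mathrm{obs} < \mathrm{exp},
\end{cases}$$

with $\mathrm{PCDF}$ the Poisson cumulative distribution with mean
$\mathrm{exp}$, and 0 at equality (neither branch applies; the value is
discarded anyway). Tails are computed in log space via `ppois(...,
log.p = TRUE)` — scores of several tens correspond to tail masses far
below double-precision `1 - CDF`. Non-integer observed counts enter the
CDF at their floor by default, which is conservative and preserves
monotonicity; `"round"` and a continuous regularized-gamma
interpolation are provided as alternatives since the choice is not
dictated by the model. Pairs with $|\mathrm{Score}| \le 1$ in either
dataset are discarded as observed-about-as-expected; the rest are
classified into sign quadrants (concordant enrichment `++`, concordant
avoidance `--`, discordant `+-`/`-+`).

A caveat on the discard band: for a pair whose expected co-occurrence is
of order 1 or larger, the score of a perfectly independent pair falls
outside the unit band quite often (the band boundary corresponds to a
tail probability of $1/e$; the outside-band mass is roughly the chance
of seeing any co-occurrence at all, about $\mathrm{exp}$ itself when
$\mathrm{exp}$ is small), so the band is a ≥95% null filter only when
expected pair counts stay below about 0.05 — per-tumor frequencies
around a percent or less at a few hundred tumors, which is where
typical somatic point mutations live. The calibration property checked
by the test suite (at least 95% of independent pairs within the band)
is stated for that regime; at expected counts near 1 the same
independent pairs land outside the band about half the time, and the
band is then a granularity filter rather than a significance filter.

## Clade statistics

A species' *mode residue* at a column is the most frequent residue
(gaps included) among its sequences, with ties broken toward the human
reference residue and then lexicographically. A species *harbors* a
driver state when its mode residue equals the driver residue (an
any-sequence variant is available); the mode convention keeps
paralog-rich species from harboring a state by a single divergent copy.
Clade-level prevalence is the leaf-weighted frequency of the driver
residue among a clade's tree sequences with the site present; it is
invariant under uniform weight rescaling. Uncertainty is summarized by
resampling the per-driver frequencies with replacement (1000 times by
default) and reporting the quartiles of the resample means; drivers are
the resampling unit because the distributions being summarized are over
drivers.

The *target clade* of a driver condenses its taxonomic spread: the
largest taxonomy node where harboring species are the majority, or the
smallest node covering more than 90% of all harboring species,
whichever contains fewer species (the 90% clade on ties, and as
fallback when no majority node exists). Taxonomy nodes are all labels
on the root-to-species paths, with each species terminating its own
path, so a driver confined to one species resolves to that species.

## Structure coverage

Structure hits arrive as standard 12-column tabular search output. Each
hit gets a Global Score (bit score over the full reference protein
length) and a Local Score (bit score over the query footprint length).
Per site, the covering hit maximizing
$\mathrm{Global}^2 + \mathrm{Local}^2$ is chosen; for a
driver/compensator pair, the hit spanning both positions with the
highest Local Score, flagged usable at Local Score ≥ 1.9. "Protein
length" is the query reference length (not the structure chain), and
multiple hits to one structure are treated independently since no merge
rule is defined by the scores themselves.

## The synthetic generator

`simulate_gene_family()` emulates the full input bundle. Trees are
random binary topologies with i.i.d. exponential branch lengths (mean
0.1 substitutions/site); 96 leaves by default, partitioned along the
tree into the six major clades (vertebrates 35%, invertebrates 25%, the
rest 10% each) with a root–clade–family–species toy taxonomy.
Alignments (60 sites) evolve from a random root sequence under a
uniform Jukes–Cantor-style process at 0.1 substitutions per site per
unit branch length (about two substitutions per site across the tree —
a conserved but not frozen family). The planted history places the
compensator state at two independent origins and the driver as four
cherry-sized transitions beneath them, subject to two safeguards chosen
so the planted truth is exactly recoverable: at every strict ancestor of
a planted node the planted state's leaf weight stays below 0.45 (so no
ancestral node is dragged past the 0.5 assignment threshold), and the
origins' exact branch-length occupancy must make $F^{N}$ clear the 1%
criterion. Trees that admit no such configuration (about 40% at this
size; most smaller trees fail) are resampled from a derived seed. The
null variant plants only the driver, as cherries scattered independently
across the whole tree — scattering matters, because clustering driver
events under one subtree is itself a co-occurrence signal that any state
on the subtree's stem would correctly explain. Tumor tables draw each
mutation per tumor independently at its configured frequency (driver
0.08; background mutations 0.2–2%, the realistic somatic regime), with
optional 2×2 joint draws for configured pairs given an odds multiplier;
ground-truth event logs are returned alongside, so tests never re-derive
truth from simulator internals.

What the simulator does not emulate: realistic amino-acid substitution
matrices (WAG/LG), rate heterogeneity across sites, indels (gaps only
via masking), paralogy, alignment error, or correlated tumor mutational
processes. Passing tests therefore demonstrate the correctness and
calibration of the machinery under its own model, not performance on
real alignments.

## Numerical and interface conventions

Reference protein positions are 1-based as in protein-level mutation
nomenclature; alignment columns are also 1-based, the natural R
convention for matrix indexing. Offset-rule intervals are closed on both
ends. Unknown residues (B, Z, X, U and anything non-canonical) are kept
as an explicit symbol but counted as gaps everywhere, which avoids
phantom character states. Binomial and Poisson tails go through
`pbinom`/`ppois` in log space; the assignment threshold is strictly
greater than 0.5; bootstrap and simulation functions take explicit
seeds and are bit-reproducible. Problem sizes used by the test suite —
96-leaf families, 100 recovery and 200 null replicates, 500-instance
oracle sweeps — were chosen as the smallest sizes at which the
calibration properties are statistically meaningful.

## A worked run

```{r example, eval = FALSE}
bundle <- simulate_gene_family(seed = 1)
report <- run_gene(bundle$family, bundle$tumor_table,
                   hits = bundle$hits, n_tumors = bundle$n_tumors)
glance(report)
tidy(report) |> filter(accepted)
autoplot(report$conservation)
plot_association_quadrants(report$associations)
```

The bundle is written to plain files with `write_gene_family()` and read
back with `read_msa()`, `read_tree()`, `read_taxa()`,
`read_mutation_table()` and `read_structure_hits()`; `write_report()`
emits every stage table as TSV plus a YAML manifest, byte-identically
across reruns.

## Known limitations

The ensemble search is exact only for viable candidate pools of at most
15 states; beyond that the greedy search can miss the optimal ensemble.
The per-member probability rule is conservative for true multi-member
ensembles whose members individually occupy sizeable tree fractions.
Homogeneity depends on the substitution matrix and background choice;
only the defaults are tested against oracles. The target-clade search
is exhaustive over taxonomy nodes and assumes the taxonomy is a tree of
path prefixes. Coordinate remapping assumes at most one offset rule
interval matches a position, which the non-overlap validation enforces.
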