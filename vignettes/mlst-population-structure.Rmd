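---
title: "MLST population-structure analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MLST population-structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlstpop)
```

## The problem

Multilocus sequence typing characterises isolates of a bacterial species by
the alleles they carry at a small panel of housekeeping-gene fragments.
`mlstpop` implements the complete analysis chain of an MLST population
study of a haploid, largely clonal organism such as *Lactobacillus
fermentum*: allele and sequence-type (ST) assignment, per-locus diversity,
multilocus linkage disequilibrium, clonal-complex structure, and
distance-based phylogenetics including split networks. The shipped
`lf_scheme()` is an 11-locus scheme (fragments 589–748 bp, 7,592 bp
total); every function also accepts arbitrary `mlst_scheme()` objects.

## Typing model

An *allele* is a distinct fragment sequence at one locus, compared by exact
string match after uppercasing. This is why the default alphabet policy is
strict: a record containing `N` or an IUPAC ambiguity code has no
well-defined allele identity, so it is rejected (or dropped with a warning
under `alphabet = "lenient"`). Loci are fixed-length fragments; sequences
of deviating length are rejected rather than aligned, matching MLST
practice of trimming alleles to a constant window.

Allele numbers and ST numbers are assigned 1, 2, ... in order of first
observation. Public MLST databases fix their numbering by curation history;
a reimplementation cannot recover those labels, so the numbers here are
arbitrary but stable labels and **every downstream statistic is invariant
to relabelling** (this is property-tested). Consequences: reported ST
labels match a published study only up to a permutation, and cross-study
claims such as "ST-4 is the founder" translate to structural statements
("the most frequent ST is the founder of the largest complex").

## Diversity statistics

For each locus the package reports the count of distinct alleles,
polymorphic (segregating) sites, mean G+C %, nucleotide diversity and
dN/dS. Two conventions are deliberately explicit:

* **π unit** — π is the mean pairwise proportion of differing sites,
  *without* distance correction. Allele-oriented MLST tools compute it over
  *distinct alleles* with equal weight; population tools weight by allele
  frequency (all isolate pairs). The source studies do not state which was
  used, so `nucleotide_diversity(unit = "allele")` is the default and
  `unit = "isolate"` is a flag.
* **dN/dS** — Nei–Gojobori (1986) pathway counting over distinct-allele
  pairs; pairwise pN and pS are Jukes–Cantor corrected
  (d = −3/4·log(1 − 4p/3)) and averaged, and the reported ratio is the
  *ratio of the means*, which is stable when individual pairs have no
  synonymous difference. A fragment with no amino-acid change reports
  ratio 0 (dN = 0, the typical housekeeping outcome); dS = 0 with dN > 0
  reports the character sentinel `"UNDEFINED"` rather than a number.
  Fragments whose length is not a multiple of 3 have the trailing partial
  codon trimmed by default (`incomplete = "error"` restores strictness),
  because real published fragment sizes are rarely codon-aligned. Codon
  columns containing a stop in any allele are skipped with a warning: in
  simulated (random-sequence) data stops are expected and harmless, in real
  data the warning flags a likely frame error. The reading frame offset is
  configurable per call since fragment frames are generally unpublished.

Scheme totals report the summed polymorphic sites and fragment lengths and
their percentage. The percentage is *truncated* to two decimals, not
rounded: published diversity tables print 131/7,592 = 1.7255 % as 1.72 %,
and we follow that convention while exposing the exact value as
`polymorphism_rate_exact`.

## Linkage disequilibrium

`index_of_association()` implements the classic multilocus test of
recombination. With mismatch distribution variance V\_O over all isolate
pairs, per-locus gene diversity h\_j = (n/(n−1))(1 − Σ p\_i²) and
V\_E = Σ h\_j(1 − h\_j):

I\_A = V\_O/V\_E − 1,  I\_A^S = I\_A/(L − 1).

Conventions follow LIAN-style implementations where the source text is
silent: V\_O is the population variance (divide by the number of pairs) and
h\_j carries the unbiased n/(n−1) factor (`unbiased_h = FALSE` disables
it). The identity I\_A^S = I\_A/(L−1) is asserted on every result. The
permutation test shuffles each locus column independently (preserving
allele frequencies, destroying associations) and reports
p = (1 + #{I\_A^S(perm) ≥ observed})/(1 + B), so the smallest reportable
value at B = 999 is p < 0.001 — a published "p = 0.000" maps to that
floor. Analysis over all isolates is the default; `unique_sts = TRUE`
collapses to one profile per ST, since both units are common in the
literature and the choice is consequential (frequency-weighted LD versus
ST-topology LD).

## Clonal complexes, founders, MST

Complexes are single-linkage components of the ST graph joining profiles
that share at least `shared_loci` of L loci (default L − 2, i.e. 9 of 11:
members may be single- *or* double-locus variants of a neighbour). This
reconciles the published grouping, where double-locus variants belong to
the founder's complex, with classic SLV-only eBURST, which remains
available via `shared_loci = L - 1`. Components of size 1 are singletons,
distinct from "singleton STs" in the frequency sense (one isolate).

The founder of a complex is the member with the most SLVs inside the
complex — the eBURST criterion — with deterministic tie-breaks: DLV count,
then isolate count, then lowest ST number.

`build_mst()` runs Prim's algorithm on the complete profile-distance graph.
The named algorithm has unpublished tie rules in the original GUI
software, so ours are explicit and deterministic: among equal-weight
candidate edges, attach to the tree node with the most dataset-wide SLVs,
then the largest isolate count, then the lowest ST number (same keys for
the outside node). Total weight is verified against an independent Kruskal
implementation in the tests.

## Phylogenetics

Concatenated ST sequences (loci joined in scheme order; isolates of one ST
are identical by construction, so one taxon per ST) feed a p-distance
matrix by default — the distance model behind published MLST trees is
usually unstated, and at MLST-scale divergence (< 2 %) p, JC69 and K2P are
nearly affine transformations of each other; both corrections are
selectable. Neighbour joining is delegated to `ape::nj` (taxa pre-sorted
by label for deterministic tie-breaking); negative least-squares branch
lengths are clamped to zero with the deficit moved to the sibling branch,
preserving total tree length. Bootstrap support resamples alignment
columns with replacement; an internal edge of length ≈ 0 is treated as a
polytomy, not a resolved split, so star-like data report no supported
structure instead of arbitrary 100 % edges.

Split decomposition follows Bandelt–Dress: a bipartition A|B is retained
iff its isolation index

α(A,B) = ½ · min over a,a′ ∈ A; b,b′ ∈ B of
[max(d(a,b)+d(a′,b′), d(a,b′)+d(a′,b), d(a,a′)+d(b,b′)) − d(a,a′) − d(b,b′)]

is positive. The implementation inserts taxa incrementally, maintaining α
by the exact recurrence α(A∪{x}|B) = min(α(A|B), quadruples involving x).
Isolation indices at or below `1e-9 · max(d)` are treated as zero — on
tree metrics the theory gives exactly the tree's edges, and this tolerance
suppresses floating-point ghost splits without touching genuine MLST-scale
weights (≥ 1 difference / 7,592 sites ≈ 1.3e-4). A configurable cap
(default 5,000 splits) guards the worst-case exponential candidate set;
weakly compatible split systems of clonal data stay far below it. The fit
statistic is the percentage of total pairwise distance explained by the
split metric, which is a provable lower bound on the input metric
(property-tested).

## The simulator: what it emulates, and what a green test means

`simulate_population()` is a forward Wright–Fisher model of a haploid
clonal population: constant size, discrete generations, each offspring
copying a uniformly random parent within its lineage. Mutation is per site
per generation (rate μ, uniform random different base); recombination is
modelled as *whole-locus allele replacement* with probability r per locus
per generation from a random co-lineage donor — at MLST scale the
observable recombination event is an imported allele, not a within-fragment
crossover (a within-fragment mode would be an extension, not the default).
Lineages descend from founder haplotypes pairwise diverged at a configured
per-site rate and never exchange material by default, emulating the two
disconnected phylogroups seen in natural collections; a `migration` rate
can relax this.

Defaults state the emulated world: 203 isolates, the 11-locus scheme,
2 lineages, 300 generations (≈ 2N per lineage, approaching mutation–drift
balance), μ = 1.2e-5 and founder divergence 0.007. These were calibrated
once, during development, so that realized per-locus allele counts fall in
the observed 7–19 band and π in the observed 0.004–0.014 band across
seeds; they are not tuned per test. What the simulator does **not**
reproduce: selection (dN/dS of simulated data is neutral, ≈ 1 where
defined, unlike real housekeeping genes under purifying selection),
codon structure (random sequences contain stop codons), unequal lineage
sizes, demography, and within-fragment gene conversion. A green
simulation-based test therefore establishes that the statistics respond
correctly to genealogy, mutation and locus-level recombination — not that
the simulator is a generative model of any real dataset.

Three deterministic fixtures (`emit_fixtures()`) carry planted truth: a
star clonal complex (founder recovery), a two-lineage clonal population
(tree and split-graph separation), and an independent-loci panmictic
population (permutation-test calibration: the rejection rate at α = 0.05
is checked to sit in [0.03, 0.07] over hundreds of seeds, using 199
permutations per dataset — at that depth p ≤ 0.05 has probability exactly
0.05 under the null, and the reduced depth keeps the calibration loop
inside a desk-scale time budget).

## Numerical and degenerate-input choices

* I\_A is undefined (error) when no locus varies; permuted replicates with
  V\_E = 0 cannot occur once the observed data pass that gate.
* Jukes–Cantor saturation (p ≥ 3/4) leaves a pairwise distance undefined;
  this aborts the ratio only if the ratio actually needs it (dN > 0).
* NJ with 2 or 3 taxa uses the closed forms (midpoint split; star lengths
  (d\_ab + d\_ac − d\_bc)/2).
* All stochastic stages (simulation, permutation test, bootstrap) take
  mandatory seeds, thread one RNG locally, and restore the caller's RNG
  state, so identical configurations are bit-stable end to end — the
  pipeline writes byte-identical outputs under a fixed seed.

## Known limitations

Exact reproduction of a published dataset's ST labels, bootstrap
percentages, or BioNumerics/SplitsTree layout is out of scope: labels are
order-dependent, bootstrap values depend on the resampling stream, and the
original GUI tools' tie rules are unpublished. Analyses needing the
deposited sequence archive (e.g. reproducing "57 STs / 5 complexes" from
the public accessions) run only when those FASTA files are supplied
locally; the package itself ships no sequence data beyond its simulators.
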