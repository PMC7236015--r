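---
title: "Evaluating DNA barcode loci for species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode loci for species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodiv)
```

## The problem

A DNA barcode is a short, standardized genomic region used to tell species
apart from sequence alone — indispensable for groups like orchids whose
immature plants are morphologically indistinguishable, and for verifying
medicinal herbs against adulterants. Candidate loci (nuclear ITS and its
shorter ITS2 sub-segment; plastid *matK*, *rbcL* and the *trnH-psbA*
spacer) differ sharply in how well they separate species. `barcodiv`
implements the standard evaluation battery applied to an aligned
collection of barcode sequences with species labels:

1. **Site variability** — counts of variable, parsimony-informative and
   singleton columns, plus indel events, per region.
2. **K2P distances** — pairwise Kimura two-parameter divergences.
3. **Phylogeny** — neighbor joining followed by a maximum-likelihood
   refinement under the K80 model, rooted at a designated outgroup.
4. **Species resolution** — monophyly of each species on the rooted
   tree, with unresolved species rescued by diagnostic indels.
5. **Best match / best close match** — leave-one-out nearest-neighbor
   identification, with a distance threshold in the "close" variant.

A sequence simulator with controlled intraspecific/interspecific
divergence closes the loop: every stage can be validated against data
whose true structure is known.

## Models and procedures

### Site classification

Gaps and IUPAC ambiguity codes are treated as missing data, the
convention of the standard alignment-statistics tools. Among the
unambiguous bases of a column: *constant* means at most one distinct
base; *parsimony-informative* means at least two bases each carried by at
least two sequences; *singleton* means variable but not informative.
`variable = parsimony + singleton` holds by construction and is asserted
in the tests. Columns with no unambiguous base still count toward the
alignment length. Indels are counted either per gap-bearing column or —
the default — as *events*, merging adjacent gap columns whose gap
presence/absence pattern across sequences is identical, so a single
3-column deletion counts once. Both modes are exposed because published
tables rarely state which convention they used.

### K2P distance

For a sequence pair, sites where either member carries a gap or ambiguity
are excluded (*pairwise deletion* — the default of the common distance
software, and the choice here because complete deletion would let one
gappy sequence erase the signal of the whole matrix). With transition
proportion $P$ and transversion proportion $Q$ over the $n$ compared
sites,

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\,\big).$$

When the logarithm's argument is non-positive the estimator is undefined
(saturation). Saturated pairs are *flagged*, never numbered: they are
dropped from best-match candidate sets and cause the tree builder to fail
loudly, because silently substituting a large constant corrupts
topologies. When $Q = 2P$ (no transition bias) the formula collapses to
the Jukes–Cantor distance, a property-tested invariant.

### K80 likelihood and tree search

The K80 model has equal base frequencies and a single
transition/transversion rate ratio $\kappa$; its rate generator is
normalized to mean rate 1 so that branch lengths are expected
substitutions per site, $\kappa = 1$ reduces exactly to JC69, and branch
lengths are commensurable with K2P distances. Tree likelihoods use
Felsenstein pruning over compressed site patterns, with gaps/ambiguities
entering as partial-likelihood vectors of ones. The search is
deliberately simple and deterministic: NJ starting tree, per-edge
bounded univariate branch-length optimization, and
nearest-neighbor-interchange (NNI) hill climbing with first-improvement
acceptance in a fixed scan order and a tolerance of $10^{-6}$ log-units.
$\kappa$ is either fixed or estimated once on the starting tree by a 1-D
bounded search on $[0.1, 100]$. The accepted-move trace is
non-decreasing by construction. No bootstrap, Bayesian machinery or
among-site rate variation is provided.

The pure-R pruning implementation is comfortable up to a few dozen taxa;
the pipeline therefore exposes `tree_method = "ml"` and `"nj"`, and the
shipped analyses use ML refinement at small to moderate sizes (recovery
demonstrations at 6–8 taxa) and NJ at the 60-odd-sequence study scale,
where the distance signal is strong and NJ and ML topologies agree on
separable data.

### Species resolution

A species is *tree-resolved* when its sequences (study samples plus
reference accessions; a study-only mode exists) form a monophyletic group
on the outgroup-rooted tree. For an unresolved species the *entangled
set* is every other species with leaves inside its smallest containing
clade. A species represented by a single sequence cannot demonstrate
clustering: it is flagged `uninformative` and counts as resolved only
when its leaf is not nested inside another species' clade — the neutral
reading of what one sequence on its own branch can show.

A column is a *diagnostic indel* for a species pair when one species
uniformly carries a gap there and the other uniformly a residue; the
default demands strict within-species uniformity because the motivating
use case is fixed insertion/deletion differences between otherwise
inseparable sister species. The combined criterion rescues an unresolved
species only if at least one diagnostic column separates it from *every*
entangled species — the conservative reading; rescue against a single
chosen confounder would overstate resolution whenever three or more
species share a clade.

### Best match / best close match

Each sequence is queried against all others (leave-one-out). The tie set
is every neighbor within $10^{-12}$ of the minimum distance — an absolute
tolerance, appropriate because K2P distances are deterministic functions
of integer site counts. All-conspecific ties are `correct`, mixed ties
`ambiguous`, all-heterospecific `incorrect`. Best close match first
rejects queries whose nearest neighbor exceeds a threshold $\tau$
(`no_match`); a nearest distance exactly at $\tau$ passes. $\tau$
defaults to the conventional fixed 3%, with a percentile-of-intraspecific-
distances mode for the method's original calibration. Singleton queries
can never be correct; they are classified `incorrect` and flagged, so a
summary can exclude them explicitly rather than silently. Queries whose
distances are all undefined are reported as `unclassifiable`, outside the
four categories.

### Report formatting

Percentages in the summary tables are *truncated*, not rounded, to two
decimals: 19/24 renders as 79.16 (not 79.17) and 10/68 as 14.70 (not
14.71). The computation uses exact integer arithmetic
(`(10000 * count) %/% total`) so floating-point representation can never
flip a digit.

## The simulator

`simulate_dataset()` draws a random coalescent species-tree topology,
evolves a root sequence along it under K80, then evolves each sample from
its species ancestor. Defaults describe the target study shape: 24
species — 19 with 3 sequences (two study samples plus a reference
accession) and 5 singletons, matching collections that keep 2–3 samples
per species with a handful of species represented once — in a 639-column
ITS-length alignment, interspecific divergence 0.15 substitutions/site,
intraspecific 0.01, $\kappa = 2$ (a typical plant nuclear-locus
transition bias), and a distant outgroup attached at the root for
rooting.

One design choice deserves emphasis: a raw coalescent draw can place two
species ancestors arbitrarily close together, which would make
"interspecific divergence" a statement about tree depth rather than
about separability, and would let a nominally separable simulation
produce entangled species by luck of the draw. The generator therefore
compresses internal node heights linearly into the upper two-thirds of
the tree depth, guaranteeing every species pair at least
`inter_divergence/3` of separation while preserving the topology and the
ordering of divergence events. All randomness flows through R's global
RNG seeded once from the mandatory `seed`, so outputs are byte-identical
across runs.

What the simulator does *not* emulate: realistic indel evolution (gaps
are injected at stated columns after substitution, since the pipeline
consumes pre-aligned data), rate variation across sites, base-composition
bias, hybridization, and alignment error. Passing the closed-loop tests
therefore demonstrates correctness of the statistics and algorithms on
cleanly structured data, not robustness to the full messiness of real
barcode collections.

## A worked run

```{r example}
cfg <- sim_config(n_species = 8, samples_per_species = 3, length = 800,
                  inter_divergence = 0.15, intra_divergence = 0.01,
                  kappa = 2, seed = 1)
sim <- simulate_dataset(cfg)
report <- run_pipeline(list(ITS_SIM = sim$aln),
                       outgroup = "outgroup_taxon",
                       threshold = 3, tree_method = "nj", seed = 1)
report
```

With interspecific divergence 15 times the intraspecific level every
species is recovered monophyletic and every leave-one-out query is
correct; lowering the ratio toward 1 degrades both, which is exactly the
ranking signal the evaluation battery is designed to expose on real
loci.

## Numerical choices and degenerate inputs

* Branch lengths are optimized on $[0, 10]$ with tolerance $10^{-4}$;
  negative NJ branch lengths are clamped to zero.
* Likelihood pattern compression is exact (no change to the value, only
  to the work).
* Site likelihoods are accumulated in double precision without scaling,
  adequate below a few hundred taxa.
* Tie detection in best match uses an absolute $10^{-12}$ tolerance.
* Ragged alignments, table/alignment ID mismatches, empty inputs,
  out-of-range extraction coordinates, saturated distance matrices and
  missing outgroups all fail with specific errors rather than propagating
  quietly.
* `extract_region` uses 1-based inclusive coordinates on the ungapped
  reference, so published site numbers can be used directly; the slice
  retains columns where the reference itself is gapped inside the
  interval.

## Known limitations

* The additivity `variable = parsimony + singleton` is enforced; a
  published table violating it cannot be reproduced cell-for-cell.
* The NNI-only first-improvement search can stop at a local optimum on
  data with weak or conflicting signal; it is intended for the
  well-separated regimes the evaluation targets, and the NJ fallback is
  available at larger scales.
* Percentile thresholds use the sort-and-index (type-1) quantile; other
  software may interpolate.
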