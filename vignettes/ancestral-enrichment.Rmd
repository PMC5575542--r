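---
title: "Ancestral reconstruction and structural substitution-enrichment scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral reconstruction and structural substitution-enrichment scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoenrich)
```

## The question the package answers

Given a family of homologous protein sequences — the motivating case is the
Rubisco large subunit and its relatives, spanning oxygen-tolerant Form I
enzymes, Form II/III dimers from anoxic organisms and the Rubisco-like
proteins — did particular *structural* parts of the protein (subunit
interfaces, the alpha/beta barrel around the active site, loop 6, the
termini) accumulate amino-acid substitutions faster than the rest of the
protein during particular *episodes* of its history?

The package decomposes this into three reusable stages:

1. **Ancestral sequence reconstruction** on a fixed, rooted phylogeny under
   an empirical amino-acid model with discrete-gamma rate heterogeneity;
2. **Structural region annotation** of a catalytic dimer by explicit
   geometric rules applied to coordinate files;
3. **Substitution-enrichment testing** between successive ancestors with
   Fisher's exact test, one test per (region, phylogenetic window) pair.

A fourth component, the synthetic-data generator, exists so that every
stage can be exercised and calibrated without any external data.

## Stage 1: ancestral reconstruction

### Model

The substitution process is a reversible continuous-time Markov chain on
the 20 amino acids with rate matrix $Q_{ij} = S_{ij}\pi_j$ ($i \neq j$),
where $S$ is a symmetric exchangeability matrix and $\pi$ the stationary
frequencies. $Q$ is normalized so that the expected rate at stationarity,
$-\sum_i \pi_i Q_{ii}$, equals one, making branch lengths expected
substitutions per site. Two models ship with the package: **WAG** (the
Whelan–Goldman empirical matrix, the workhorse for deep protein
phylogenies) and **Poisson** (equal exchangeabilities, uniform
frequencies), which admits the closed form
$P_{ii}(t) = \tfrac{1}{20} + \tfrac{19}{20} e^{-20t/19}$ used by several
tests.

Among-site rate variation uses the discrete-gamma approximation: $K$
equal-probability categories whose rates are the means of the
$\Gamma(\alpha,\alpha)$ quantile bands, renormalized to average exactly
one. The default is $K = 4$, the common denominator across likelihood
software; site-specific rate classes (CAT-style) are deliberately not
implemented, as they are tied to particular heuristic implementations and
are not needed for reconstruction on a fixed topology.

### Likelihood and posteriors

`tree_log_likelihood()` implements Felsenstein pruning with per-node
scalar rescaling; gaps are missing data (all-ones partial likelihoods).
`marginal_ancestral_posteriors()` computes, for every internal node and
site, the empirical-Bayes posterior over the 20 amino acids: the product
of the partial likelihood below the node and the outside likelihood above
it, mixed over gamma categories with weights proportional to the
per-site category likelihoods. Both are verified in the test suite
against exhaustive enumeration over all internal-state assignments on
small trees, and against an independent library implementation
(`phangorn::pml`) on simulated data.

The ML ancestral sequence takes the argmax of each posterior column.
Exact ties are broken alphabetically by one-letter code — an arbitrary
but platform-independent rule. Per-node support is summarized by binning
per-site maximum posteriors into ten 10%-wide bins
(`bin_posteriors()`), and `sample_alternate_ancestors()` draws alternate
ancestors site-independently from the posteriors (five by default) for
downstream sensitivity analyses.

### Indels

Gap characters carry phylogenetic signal of insertion/deletion history,
not of amino-acid state. Site presence at ancestors is therefore decided
by Fitch parsimony on the binary presence/absence pattern of each column,
each column treated independently (`fitch_indel_reconstruction()`), and
never by the state posteriors. Ambiguity at the root is resolved to
"present" by default (configurable); the down-pass prefers the parent's
state, which makes the reconstruction deterministic. Sites reconstructed
absent appear as `-` in ML ancestral sequences and are excluded from
enrichment counts under the default gap policy.

### Branch lengths, model choice and branch support

Topology inference is out of scope — the tree is an input.
`optimize_branch_lengths()` re-fits branch lengths on the fixed topology
by coordinate-wise bounded 1-D maximization on $[10^{-8}, 20]$,
terminating when a full sweep gains less than `tol` log-likelihood units;
the bounds and tolerance are numerical-stability choices, not biological
ones. `aic_compare()` scores candidate models by
$\mathrm{AIC} = 2k - 2\ln L$ with $k$ = branch count plus one for the
gamma shape when $K > 1$ (the empirical exchangeabilities are fixed
constants, not fitted parameters). `branch_aLR()` reports branch support
as the likelihood ratio of the input resolution of an internal branch to
the better of its two nearest-neighbor-interchange alternatives, with the
five branch lengths adjacent to the interchange re-optimized for each
resolution; because the ratio can exceed floating range, the base-10
logarithm is reported alongside.

## Stage 2: structural regions

Nine region labels are produced (`REGION_LABELS`): three cross-model
interfaces (Form I large–large, Form I large–small, Form III
large–large), the within-dimer interface, the barrel strands, the
near-barrel shell, loop 6, and the N- and C-terminal domains.

The geometric rules, applied to `ATOM` records only (ligands, ions and
solvent dropped; modified residues such as carboxylated lysine renamed to
their parents via a configurable table):

* **Interfaces.** A residue is at an interface iff any of its
  non-hydrogen atoms lies strictly within the cutoff (default 5 Å, chosen
  to include nonpolar contacts) of a non-hydrogen atom across the
  interface. The strict inequality and the hydrogen exclusion are applied
  on both sides of every distance test. For the cross-model interfaces
  the query dimer is first superimposed onto the reference complex's
  catalytic dimer by least-squares rigid superposition (Kabsch via SVD,
  reflections excluded) and distances are measured to the reference's
  partner chains.
* **Subdomains.** Barrel strands, loop 6 and the termini are lists of
  residue numbers in the reference structure's numbering (they must be
  supplied in the configuration; no published list is assumed). They
  transfer to the query by nearest Cα after superposition, ties going to
  the lower residue index.
* **Near-barrel.** Residues with any heavy atom strictly within the
  cutoff of a barrel-strand heavy atom; barrel members themselves are
  excluded by default (configurable) so the label denotes a shell, not a
  superset.

Finally residue numbers are mapped to alignment columns through the
alignment row corresponding to the query structure
(`map_residues_to_alignment()`), tolerating a configurable mismatch
fraction; the two dimer chains are assumed to share residue numbering, as
they do in a homodimer. All region outputs are, by construction and by
test, invariant under rigid motion of the query and non-decreasing in the
cutoff.

## Stage 3: enrichment

A *phylogenetic window* is the path between two named ancestors, each
resolved as the MRCA of a configured taxon set; consecutive ancestors
along a root-to-tip path give consecutive windows (`define_windows()`).
For each window the ML ancestral sequences at its two endpoints are
compared site by site — endpoint comparison, not per-branch summation, so
multiple hits along a window count once. Each site falls into one of four
categories: substituted/unsubstituted × in-region/out-of-region; sites
where either endpoint is absent are excluded (default policy; an
alternative counts one-sided presence changes as substitutions). The 2×2
table goes into Fisher's exact test (two-sided by default; the one-sided
"greater" alternative is available), and the sample odds ratio
$(ad)/(bc)$ is reported with $+\infty$ when only the denominator
vanishes.

A (region, window) pair is flagged **significant iff OR > 1.5 and
p < .05**, both strictly; no multiple-testing correction is applied by
this rule, matching its original formulation, though a Benjamini–Hochberg
column is reported for the reader. With nine regions and five windows a
full scan is 45 tests; treating each region against its complement (which
contains the other, possibly overlapping regions) is intentional — each
test asks "this region versus the rest of the protein".

## The synthetic-data generator and what it does (not) show

`evolve_alignment()` draws the root from the model's stationary
frequencies and evolves each site down the tree with transition
probabilities $P(t \cdot g \cdot r)$, where $g$ is the site's gamma
category (assigned once per site) and $r$ is a rate multiplier $m$
applied only on configured branches and only in configured region
columns — exactly the alternative hypothesis the scan tests, with $m = 1$
as the null. A configurable fraction of columns carries a binary
presence/absence character evolved as a symmetric gain/loss process
(root present, default 0.2 flips per unit branch length — a stand-in
choice, since only per-column independence is assumed by the indel
model). True states are recorded at every node, so reconstruction
accuracy and substitution counts can be checked against truth.

Toy structures (`gen_toy_dimer()`) place pseudo-residues 20 Å apart on
widely separated chains so that *no* cross-chain contact exists except
the ones implanted at cutoff − 0.1 Å; hydrogen-only contacts can be
implanted to verify the heavy-atom rule. These fixtures make the
geometric rules exactly decidable, which real structures never are.

What the simulations do **not** emulate: alignment error, affine-gap
indel processes, site-correlated rates, covarion behaviour, compositional
drift across the tree, or any realistic structure evolution. Passing
calibration here shows the machinery is correct and conservative under
its own model, not that real data satisfy that model.

## Calibration choices

The calibration and power studies (`calibration_study()`) fix one design:
a ladder tree with eight leaves, every branch 0.4 substitutions/site
(matching the stated length of the implanted branch; the remaining
branch lengths are not separately specified anywhere, so one value is
used throughout), 400 columns, a 20% implant-target region, the eight
remaining region labels tiling the rest of the columns, six nested spine
ancestors giving five windows, and the implant on the middle window's
branch. Under the null ($m = 1$, 500 replicates, full
simulate→reconstruct→scan route) the per-cell rejection rate at
p < .05 stays below 7% — Fisher's exact test is conservative, and the
bound includes Monte-Carlo error. With $m = 5$ (200 replicates) the
implanted cell is flagged in well over 80% of replicates. These numbers
are recomputed by the test suite and by `scripts/acceptance.R`, not
quoted from anywhere.

Problem sizes in the tests (tree sizes 2–8, alignments of 40–500 columns,
500/200 calibration replicates, exhaustive Fisher enumeration to total 26
plus a seeded random sweep to 60) were chosen as the smallest designs
that still pin down each property; the enumeration oracles grow
exponentially and are kept to ≤ 4 leaves × ≤ 3 sites.

## Numerical notes and limitations

* Pruning uses per-node scalar rescaling; exact, and sufficient for
  hundreds of taxa at double precision.
* $P(t) = e^{Qt}$ comes from the symmetric eigendecomposition of
  $D^{1/2} Q D^{-1/2}$; entries are clamped to $[0,1]$ against roundoff.
* Branch-length optimization is coordinate-wise golden-section search; it
  is monotone by construction but, like any coordinate method, can stop
  short of the joint optimum on strongly correlated branches — acceptable
  for its role here (re-fitting lengths on a fixed topology).
* The aLR machinery assumes the focal branch is internal in the unrooted
  sense; pendant branches are rejected.
* All-gap columns have undefined posteriors and are flagged absent.
* Known limitation: the enrichment test compares ML point estimates of
  ancestors; reconstruction uncertainty is exposed through the sampled
  alternate ancestors but is not propagated into the p-values.
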