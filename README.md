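# paleoenrich

Ancestral protein reconstruction and structural substitution-enrichment
scans.

## What it is for

Deep protein families — the motivating case is Rubisco, whose forms span
anaerobic archaea (Form III), anoxic Rubisco-like proteins (Form IV) and
the oxygen-exposed Form I of cyanobacteria, algae and plants — preserve a
record of *when* different parts of the molecule changed. This package
asks that question quantitatively, for anyone with an alignment, a tree
and a reference structure: were amino-acid substitutions between
successive reconstructed ancestors **enriched** in specific structural
regions of the catalytic dimer (subunit interfaces, the alpha/beta barrel
around the active site, loop 6, the termini) during specific phylogenetic
windows?

The pipeline has three stages, each usable on its own:

1. **Ancestral sequence reconstruction** (`marginal_ancestral_posteriors`):
   Felsenstein pruning under WAG (or Poisson) with K discrete-gamma rate
   categories; empirical-Bayes marginal posteriors `p(i, j)` for every
   internal node, ML sequences with alphabetical tie-breaks, Fitch
   parsimony for insertion/deletion characters (each column independent),
   10%-bin posterior summaries, posterior-sampled alternate ancestors,
   branch-length optimization, AIC model comparison, and aLR branch
   support (likelihood ratio against the best NNI alternative).
2. **Region annotation** (`build_region_map`): nine region labels from
   geometric rules — a residue is at an interface iff any non-hydrogen
   atom is strictly within 5 Å of a non-hydrogen atom across the
   interface; cross-model interfaces by Kabsch superposition onto
   reference complexes; subdomains transferred by nearest Cα; a
   near-barrel shell — expressed as alignment columns.
3. **Enrichment scan** (`enrichment_scan`): for every (region, window)
   pair, the 2x2 table of substituted/unsubstituted x in/out-of-region
   sites between the window's endpoint ancestors, Fisher's exact test,
   the sample odds ratio `(ad)/(bc)`, and the significance rule
   **OR > 1.5 and p < .05** (both strict).

A synthetic-data module (`gen_tree`, `evolve_alignment`, `gen_toy_dimer`,
`gen_fixture_bundle`) generates alignments with implanted region-by-branch
rate multipliers, true ancestors, and toy dimer coordinates with contacts
placed by construction, so the whole pipeline is testable and calibratable
offline.

## Worked example

Simulate an alignment on an 8-leaf ladder tree with a 5x substitution-rate
multiplier implanted in one region (columns 1–80) on one internal branch,
reconstruct ancestors, and scan all nine regions over five windows:

```r
library(paleoenrich)
setup <- calibration_setup()                   # tree, windows, region map
cfg <- sim_config(n_leaves = 8, seq_length = 400,
                  region_columns = setup$region_columns,
                  multiplier_branches = setup$multiplier_branch,
                  rate_multiplier = 5, seed = 42)
ds  <- evolve_alignment(setup$tree, cfg)
rec <- marginal_ancestral_posteriors(setup$tree, ds$alignment,
                                     aa_model("WAG", alpha = 1, K = 4))
res <- enrichment_scan(rec, setup$windows, setup$region_map)
subset(res, significant,
       select = c(window, region, a, b, c, d, odds_ratio, p_value))
```

```
       window             region  a  b   c   d odds_ratio      p_value
15 anc2..anc3        near_barrel 18 22 102 257   2.061497 0.0440457283
19 anc3..anc4 FormI_LL_interface 39 41  81 236   2.771454 0.0001127522
```

The implanted cell — window `anc3..anc4`, region `FormI_LL_interface` —
is recovered with odds ratio 2.77 at p = 1.1e-4: of its 80 region columns,
39 substituted between the two endpoint ancestors versus 81 of 317
elsewhere. The `near_barrel` row at p = .044 is the kind of marginal hit
the unadjusted rule lets through (about 2 of 45 cells are expected at
p < .05 under the null); the reported `bh_q` column exposes this.

Posterior support for an ancestor is summarized in 10% bins:

```r
round(bin_posteriors(rec, "N4"), 3)
```

```
[0.0,0.1) [0.1,0.2) [0.2,0.3) [0.3,0.4) [0.4,0.5) [0.5,0.6) [0.6,0.7) [0.7,0.8)
    0.000     0.008     0.053     0.068     0.065     0.060     0.043     0.071
[0.8,0.9) [0.9,1.0]
    0.088     0.544
```

`run_pipeline(run_config(...))` chains every stage over files (FASTA,
Newick, PDB) and writes per-ancestor posterior tables, the region map,
the 45-row results table and a JSON run report; a thin command-line
wrapper lives at `inst/cli/paleo-enrich.R`.

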