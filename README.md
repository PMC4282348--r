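# refassess

Scoring and ranking of protein structure refinement predictions, in the
style of a CASP refinement-category assessment.

Refinement experiments release a near-native, template-based *starting
model* per target; groups submit up to five models each, trying to move it
closer to the withheld experimental structure.  Judging that requires
measures sensitive to subtle change, and a ranking robust to occasional
catastrophic submissions.  `refassess` implements the full pipeline:

* **Quality measures** against the native over the author-numbered residue
  correspondence: high-accuracy GDT (mean inlier percentage at 0.5/1/2/4 Å,
  each under its own best superposition, found by an exhaustive-at-small-n
  / seed-and-refit search), Cα RMSD after Kabsch superposition, side-chain
  GDC-SC (threshold-weighted mean over 0.5–5 Å on one characteristic atom
  per residue), SphereGrinder (per-residue 6 Å sphere superposition, 2 Å
  tolerance), and an externally supplied MolProbity-style score.
* **Ranking**: per-target deltas Δ_Q = Q(model) − Q(starting), robust
  Z-scores (median/MAD), clipping of unhelpful signs, the combined score
  S_p = Z_GDT-HA + Z_GDC-SC + Z_SphGr − Z_RMSD − Z_MP, a naive
  resubmitted-starting-model baseline, and median-S_p group tables with an
  eligibility threshold.
* **Comparisons**: one-tailed exact Wilcoxon signed-rank head-to-head
  tests (α = 0.01, exact with ties via dynamic programming), pooled-score
  cherry-picking and model-1 identification rates.
* **Side analyses**: geometric hydrogen-bond networks scored by
  precision/recall/F1, a Hookean Cα elastic-network deformation energy
  (thermal-ensemble filtering at ≤ 0.89 kcal/mol/residue, adventurousness
  reporting), and molecular-replacement viability from LLG scores
  (viable when LLG > 60).
* **Synthetic rounds**: a seeded generator of complete refinement rounds —
  ideal-geometry natives, perturbed starting models, and group submissions
  with planted skill/consistency/adventurousness/ranking-acumen profiles —
  so the whole pipeline is testable end to end with no external data.

## Worked example

Simulate a small round (3 targets, 4 groups of descending planted skill,
5 models each), assess it, and read the ranking:

```r
library(refassess)
man <- generate_round(11, n_targets = 3, profiles = default_group_profiles(4),
                      dir = "round", n_res_range = c(30, 40))
cfg <- assessment_config("round", out_dir = "round/reports", min_targets = 3)
bundle <- run_assessment(cfg)
bundle$ranking
#>   group     type n_targets median_sp
#> 1   G01     <NA>         3    10.273
#> 2   G02     <NA>         3     1.908
#> 3   G03     <NA>         3     0.558
#> 4   G04     <NA>         3     0.000
#> 5 naive baseline         3     0.000
```

The planted order (G01 a perfect refiner, skills descending) is recovered;
groups below the per-target median clip to an S_p of 0, as does the naive
baseline (resubmitting the starting model earns nothing when the median
group improves it).  Per-model detail sits in `bundle$model1`:

```r
head(bundle$model1[, c("target", "group", "d_gdt_ha", "d_rmsd", "s_p")], 3)
#>   target group d_gdt_ha d_rmsd   s_p
#> 1    T01   G01     45.0 -1.791  9.50
#> 2    T01   G02     31.2 -1.203  1.91
#> 3    T01   G03     26.2 -1.018  0.00
```

G01's model 1 gains 45 GDT-HA units and drops the Cα RMSD by 1.79 Å on
target T01; its combined S_p of 9.5 sums the five clipped Z-scores.  The
report bundle (`metrics.tsv`, `scores.tsv`, `ranking.tsv`,
`pairwise.tsv`, `cherrypick.tsv`, `hbonds.tsv`, `flexe.tsv`, `mr.tsv`,
`run_log.json`) is written under `round/reports/`, byte-identically on
rerun.

The package also ships the published molecular-replacement worked example
— LLG scores of starting vs best refined model for thirteen
crystallographic targets:

```r
mr <- mr_viability(casp10_mr_example(), threshold = 60)
sum(mr$per_target$rescued)
#> [1] 3
all(mr$per_target$best_llg > mr$per_target$starting_llg)
#> [1] TRUE
```

Three targets (TR663, TR671, TR747) cross the LLG > 60 viability line only
after refinement; the best model beats the starting model in all thirteen
cases.

A thin command-line front end is installed as `exec/refassess`
(`refassess simulate --seed 1 --dir round`, `refassess all --round round`).

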