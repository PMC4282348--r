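---
title: "Assessing protein model refinement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing protein model refinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refassess)
```

# The problem

In a refinement experiment of the CASP style, a near-native template-based
*starting model* is released for each target, and participating groups try to
move it closer to the (withheld) experimental structure, submitting up to
five ranked models per target.  Because starting models are already close to
the native state, an assessment needs measures sensitive to subtle change,
covering complementary aspects of quality, and a ranking scheme that is
robust to the occasional catastrophic submission.  `refassess` implements
that pipeline: per-model quality measures against the native, differences
against the starting model, target-wise robust standardisation, clipping and
combination into a single score, a naive baseline, head-to-head hypothesis
tests, and several side analyses (hydrogen-bond networks, elastic-network
deformation energy, molecular-replacement viability).

# Quality measures

Five measures are computed per model `p` against the native target, each
restricted to the residues paired by author numbering
(`map_common_residues()`):

* **GDT-HA** — mean over cutoffs $d \in \{0.5, 1, 2, 4\}$ Å of the largest
  percentage $c_d$ of paired Cα atoms that any superposition found by the
  search brings within $d$ of their native positions.
* **Cα RMSD** after the least-squares (Kabsch) superposition.
* **GDC-SC** — threshold-weighted mean $\sum_i w_i c_{d_i}$ over
  $d_i = 0.5 i$ Å, $i = 1..10$, computed on one characteristic side-chain
  atom per residue with linearly decreasing weights
  $w_i = (k - i + 1) / \binom{k+1}{2}$, $k = 10$ (weights sum to one; the
  tightest thresholds dominate).
* **SphereGrinder** — for each target residue, all target atoms within 6 Å
  of its Cα are superposed (as model counterparts) onto the native sphere
  and the fraction within 2 Å is retained; the score is the mean fraction
  over spheres, times 100.
* **MP** — a MolProbity-style stereochemistry score, consumed as an
  external scalar (the package never computes it).

## The superposition search

GDT-type scores are defined by a maximisation over superpositions, which is
not analytically solvable.  The search here: for small problems
($n \le 12$ paired atoms) every subset of at least three pairs seeds a
Kabsch fit — exhaustive within the seed-and-count semantics, and the
reference against which the heuristic is tested.  For larger problems,
contiguous sequence windows (lengths 3, 5, 7 and $n$) seed an iterative
refit: superpose on the current inlier set, reselect the atoms within the
cutoff, repeat to a fixed point (at most 20 rounds), remembering every
visited inlier set so merged trajectories are not refit twice.  Every
candidate superposition is scored against *all* requested cutoffs at once,
which makes the per-cutoff maxima non-decreasing in the cutoff by
construction and lets GDT-HA and GDC-SC share one search.  Ties in the
inlier count resolve toward the lower inlier RMSD, making results
deterministic.

Residue correspondence uses author numbering rather than sequence
alignment: refinement submissions inherit target numbering, so the two
coincide, and a residue-name mismatch at a shared number is flagged rather
than fatal.  Submissions with fewer heavy atoms than their starting model
(lost residues, non-all-atom models) are discarded before scoring.

# Ranking

For each measure $Q$ the delta $\Delta_Q(p) = Q(p) - Q(s)$ is taken against
the starting model $s$.  Per target, the deltas of all assessed model-1
predictions are converted to robust Z-scores,
$Z = (\Delta - \mathrm{median}) / \mathrm{MAD}$, with the plain median
absolute deviation (no 1.4826 consistency constant — configurable), a
standard-deviation fallback when the MAD degenerates to zero, and an
all-zero fallback beyond that.  Negative $Z$ is clipped to zero for
measures where higher is better (GDT-HA, GDC-SC, SphGr) and positive $Z$
for measures where lower is better (RMSD, MP) — adventurous groups are not
punished for failed experiments.  The combined score is

$$S_p = Z_{GDT\text{-}HA} + Z_{GDC\text{-}SC} + Z_{SphGr} - Z_{RMSD} - Z_{MP},$$

which is non-negative by construction; a missing MP score contributes zero
and is flagged, never imputed.  Groups are ranked by their median $S_p$
over predicted targets, with an eligibility threshold (default 23 targets).
A *naive baseline* — the starting model resubmitted — is scored with the
participants' per-target statistics (it never enters them) and appended as
a reference row: a refinement method is only interesting if it beats it.
A parametric mean/SD variant of the standardisation is available
(`variant = "mean_sd"`); in the planted-skill simulation below both
variants agree on the top of the table.

Head-to-head comparisons use a one-tailed Wilcoxon signed-rank test on
paired per-target deltas at $\alpha = 0.01$ with no multiple-testing
correction.  Zero differences are dropped (Pratt's variant is available),
tied magnitudes get average ranks, and for up to 25 non-zero pairs the
p-value comes from the exact null distribution, computed by dynamic
programming over doubled ranks — equivalent to enumerating all $2^n$ sign
assignments, and exact in the presence of ties, which
`stats::wilcox.test` cannot provide.  Above that, a normal approximation
with continuity correction takes over.

*Cherry-picking*: to ask whether groups' later models beat their model 1,
all assessed submissions for a target are pooled, $S_p$ is recomputed on
that population, and each group's best entry is selected (ties to the
lowest index).  By construction the pick's pooled $S_p$ is at least the
model-1 entry's.  The model-1 identification rate is the percentage of
five-model targets where the pick *is* model 1.

# Side analyses

**Hydrogen bonds.**  Structures carry no hydrogens, so bonds are assigned
from heavy-atom geometry: donor–acceptor distance ≤ 3.5 Å and
antecedent–donor–acceptor angle ≥ 90°, over backbone amides (except
proline) and standard side-chain N/O/S donors/acceptors, excluding
covalently adjacent pairs.  This deliberately simple criterion replaces
hydrogen-placement rules; both thresholds are arguments, and the contract
is ordinal comparison of groups (precision/recall/F1 of the model's bond
set against the native's, with degenerate denominators scoring 0), not
identity with any particular assignment program.  No solvent-accessibility
weighting is applied; over-predicted surface side-chain bonds in
MD-derived models are a known caveat of this kind of analysis.

**Elastic network.**  A Hookean Cα network (springs between all pairs
within 12 Å at their reference distance, uniform
$k = 1$ kcal/mol/Å², all three parameters configurable) gives a
deformation energy $\sum \frac{k}{2}(d_{ij} - d^0_{ij})^2$ between two
conformations.  Being a function of internal distances it needs no
superposition and ignores rigid motion.  It serves two ordinal purposes:
the *thermal-ensemble filter* (a starting model within ≤ 0.89
kcal/mol/residue of the native — boundary inclusive — is too close to be a
refinement challenge) and the *adventurousness report* (per group, the
mean/max energy of model-1 submissions relative to the starting model,
restricted to targets where the group improved GDT-HA).  Absolute values
are not calibrated against any published normal-mode formulation; only
orderings are meaningful.

**Molecular replacement.**  LLG scores are consumed as external scalars; a
model is a viable search model when LLG > 60 (strict, following the
published rule of thumb), and a target is *rescued* when the starting model
is below the threshold but the best submission is above it.  The package
ships the thirteen published starting/best LLG pairs
(`casp10_mr_example()`) as a worked example: three rescued targets, and
the best model above the starting model in all thirteen cases.

# The synthetic-data generator

`generate_round()` fabricates a complete refinement round so that every
stage is testable with no downloads.  What it emulates, and what it does
not:

* **Natives** are ideal-geometry backbones (N, Cα, C, O, CB) built by
  internal-coordinate chain construction from standard bond
  lengths/angles and fold torsions (α-helix −57°/−47°, strand
  −119°/113°, plus turns; the sheet-like fold closes its two strands
  with a four-residue turn whose torsions were fitted once against a
  ~4.9 Å antiparallel Cα registry, so the hairpin genuinely
  hydrogen-bonds), with 2° seeded torsional jitter.  Helices rise
  1.5 Å per residue at ~100° twist, and consecutive Cα sit 3.8 ± 0.1 Å
  apart, so superposition scores, hydrogen-bond patterns (the i → i+4
  helical ladder) and elastic networks behave realistically.  Side chains
  beyond CB, rotamers, and packing are *not* modelled; GDC-SC falls back
  to CB as the characteristic atom.
* **Starting models** add per-atom Gaussian noise (default σ = 1.0 Å)
  plus one rigid loop rotation — close, but not too close, to the native.
* **Submissions** interpolate starting → native by a fraction drawn from
  Normal(skill, consistency), clamped to [−0.5, 1], then add a
  sequence-smoothed displacement field with RMS amplitude equal to the
  group's adventurousness; with small probability a terminal residue is
  deleted, exercising the discard rule.  Group labels: the truly best of
  the five is labeled model 1 with probability `ranking_acumen`.
* **External score tables** are fabricated as deterministic functions of
  the coordinates (an MP-like score increasing with Cα RMSD from native;
  an LLG-like score increasing with the fraction of well-placed Cα), so
  identical structures always receive identical scores, and the tables
  are clearly marked synthetic.

The default round — 27 targets, 10 groups spanning skills 1.0 down to
−0.2 (including one deterministic perfect refiner, one naive-equivalent
group, and one skilled group with ranking acumen 0.2), 5 models per group
— is the panel under which all end-to-end claims are tested.  Per-target
sizes are drawn from 40–60 residues: large enough for stable sphere,
network and bond statistics, small enough that twenty full rounds run on
one CPU in minutes; real refinement targets (68–249 residues) are larger,
which changes compute cost but not the constructions being tested.
Passing these tests shows the pipeline recovers planted orderings under
its own generative model; it does not certify behaviour on real
experimental pathologies (crystal contacts, missing density, register
errors), which enter only through the residue-exclusion masks.

# Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy copy, first listed on ties.
* GDT membership is inclusive (≤ cutoff); sub-12-residue problems are
  searched exhaustively; tie-breaks go to lower inlier RMSD.
* Sphere membership comes from the target only; atoms the model lacks
  count as outside the 2 Å tolerance (penalise, don't skip); spheres with
  fewer than three matched atoms score 0; spheres with fewer than three
  target atoms are skipped.
* MAD = 0 falls back to the sample SD, then to all-zero Z — degenerate
  targets are deterministic, never NaN.
* An empty bond set, an all-zero delta vector, a group with no qualifying
  targets: all defined (0 / p = 1 / empty statistics), never errors.
* Every random artifact sits behind one seeded generator; rounds are
  byte-identical per seed, and `run_assessment()` itself uses no
  randomness at all.

# Scope

Out of scope by design: computing MolProbity scores or LLG values (both
are inputs), the LGA program's exact iteration schedule (the documented
search plus its exhaustive small-n reference defines this package's
semantics), any published normal-mode energy formulation, symmetry-mate
crystal-contact detection (masks are inputs), and mmCIF/ligand/nucleic
acid handling.
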