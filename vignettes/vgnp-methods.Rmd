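---
title: "Virtual nanoparticle surfaces and the logG/R nanohydrophobicity statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual nanoparticle surfaces and the logG/R nanohydrophobicity statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The hydrophobicity of an engineered nanoparticle — conventionally reported
as logP, the base-10 logarithm of its octanol–water partition coefficient —
drives its solubility, biodistribution and protein-binding behaviour, yet
it cannot be computed with small-molecule logP calculators: a gold
nanoparticle (GNP) is not one molecule but a metal core carrying tens to
hundreds of grafted surface ligands, and its effective hydrophobicity
depends on the core size, the ligand mixture and the grafting density, not
only on the ligand structures. `vgnp` predicts nanoparticle logP from
structure alone, before any synthesis, by simulating what the solvent
actually encounters: the particle's accessible surface.

## The model

The method has four stages, each an exported function family.

**1. Virtual particle construction** (`build_core()`, `place_ligands()`,
`build_vgnp()`). The core is an occluding sphere of radius
$r = 5\,d_\mathrm{nm}$ Å centred at the origin. Each ligand is parsed from
SMILES or MOL/SDF, given explicit hydrogens and one 3D conformer from a
seeded distance-geometry embedding, and grafted at anchor points drawn
uniformly on the core sphere (rejection sampling enforces a minimum anchor
separation). The ligand's attachment atom — a thiol/thiolate sulfur by
default — sits 2.4 Å above the surface along the outward normal, the
attachment-to-centroid axis is aligned radially, and a seeded random roll
about that axis completes the pose. Ligand identities are assigned to
anchors in random order, so mixed shells are interleaved, not patched.
Gold contributes occlusion only: it carries a zero lipophilicity
contribution, which is why the implicit sphere is the default core
representation (an atomistic Fibonacci-lattice shell is available for
visualisation).

We deliberately perform no energy minimisation or clash relaxation.
Overlapping ligand atoms are counted and warned about, but left in place:
buried atoms are invisible to the surface step below, which is the only
place geometry matters.

**2. Solvent-accessible surface** (`build_grid()`,
`identify_sas_points()`). The solvent-accessible (Connolly) surface is
discretised on a cubic grid of spacing $h$ anchored at the lower corner of
the particle's padded bounding box. With probe radius $p$ (1.4 Å, a water
molecule), a grid node $g$ is a SAS point iff

* no overlap: $\lVert g - c_i \rVert \ge R_i + p$ for **every** body $i$
  (atoms and the core sphere), and
* contact: $\lVert g - c_j \rVert \le R_j + p + h$ for **some** body $j$ —
  the probe is within one grid unit of touching the particle.

Distances are Euclidean; van der Waals radii are a Bondi-type table
(`vgnp_vdw_radii()`, overridable). The production implementation visits
only the nodes inside each body's contact band; `sas_points_bruteforce()`
evaluates the predicate exhaustively and the test suite requires exact set
equality between the two on random particles.

**3. Lipophilicity scoring** (`score_surface()`, `log_g_over_r()`). Every
SAS point receives a molecular lipophilicity potential (MLP)

$$\mathrm{mlp}(x) = \sum_i f_i\, w(\lVert x - a_i \rVert),$$

where $f_i$ are Wildman–Crippen atomic logP contributions (their sum over
a molecule is the molecule's atom-contribution logP) and $w$ is a
distance-weighting kernel. Hydrophobic (green) intensity is
$I_G = \sum_x \max(\mathrm{mlp}, 0)$, hydrophilic (red) intensity
$I_R = \sum_x \max(-\mathrm{mlp}, 0)$, and the particle-level statistic is

$$\log G/R = \log_{10} \frac{I_G}{I_R}.$$

Raw $|\mathrm{mlp}|$ sums enter the ratio; the min–max-normalised
intensity written by `write_scored_csv()` is for viewer colouring only
(per-particle normalisation would not cancel in the ratio).

**4. Calibration** (`fit_calibration()`, `predict_nanologp()`). A linear
map converts logG/R to predicted logP ("nanologP"). The shipped default
model is the published line

$$\mathrm{nanologP} = 0.7334 \cdot \log G/R - 2.4306,$$

fitted on a 41-particle GNP library with measured octanol–water logP.
`fit_calibration()` refits the line on any scored library with
experimental values; `kfold_cv()` cross-validates it;
`ligand_baseline_logp()` provides the classical ligand-only baseline (copy-
number-weighted mean of ligand logP values) the surface method is compared
against.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| grid spacing `h` | 0.8 | Å | resolves atomic features (vdW radii 1.2–2 Å) at desk-scale cost; halving `h` multiplies surface nodes by ~4 |
| probe radius | 1.4 | Å | water molecule |
| kernel | exponential, λ = 1.5 | Å | Fauchère-type MLP weighting; the hyperbolic Audry kernel `1/(1+d)` is selectable |
| kernel cutoff | 10 | Å | see "Numerical choices" |
| min. anchor separation | 2.0 | Å arc | prevents coincident grafting sites; well below the ~5 Å footprint of a thiol at realistic densities |
| S–Au bond offset | 2.4 | Å | typical thiolate–gold bond length |
| vdW radii | Bondi-type | Å | single documented table, overridable per call |
| Au radius / contribution | 1.66 / 0 | Å / – | gold occludes but is chemically passivated |

All of these live in `vgnp_config()`, can be loaded from a YAML file
(`read_config()`), and are echoed into every output file's provenance
header together with the seeds, so any output is regenerable from its own
header.

## Numerical choices

**Kernel cutoff and locality.** Weights are exactly zero at and beyond the
cutoff, so far atoms can never contribute. The truncation error of the
default 10 Å cutoff is not negligible in an absolute sense — on a coated
particle many atoms sit 10–20 Å from a surface point, and their pooled
tail shifts logG/R at the $10^{-2}$ level — but it decays exponentially
with the cutoff and, being systematic across particles, is absorbed by the
linear calibration. The test suite asserts the decay and that doubling the
cutoff from 20 Å moves logG/R by less than $10^{-3}$.

**Exact antisymmetry.** `log_g_over_r()` computes
$\log_{10} I_G - \log_{10} I_R$ rather than the log of the quotient, which
makes the channel-swap law (negating every $f_i$ flips the sign of logG/R)
exact in floating point, not merely approximate.

**Degenerate surfaces.** A shell made purely of alkanethiol has no
negative contribution anywhere, so $I_R = 0$ and the ratio is undefined.
By default this is a classed error carrying both sums. With
`clamp = TRUE` the empty channel is replaced by
$\varepsilon = 10^{-6}(I_G + I_R)$ (a logG/R magnitude of ~6) and a
warning is emitted. Ratio-series runs that include monofunctional
endpoints use the clamp; everything else defaults to the hard error.

**Grid anchoring and determinism.** The grid is anchored at the padded
bounding-box minimum, so a fixed particle always yields identical nodes;
the candidate node ranges in the accelerated SAS are widened by one node
per axis so floating-point rounding at the box boundary can never make the
fast path disagree with the brute-force reference. Placement, identity
assignment and rolls are governed by one placement seed; ligand embedding
by a separate embedding seed; fold assignment and fixture noise by their
own seeds. All package randomness runs under restored RNG state, leaving
the caller's random stream untouched.

**Tie-breaks.** When the attachment pattern matches several atoms
(e.g. a dithiol) the first match in the canonical atom order (input heavy
atoms, then appended hydrogens) is used and a warning names the choice.

## Chemistry backend

Ligand parsing, the seeded ETKDGv3 conformer embedding and the
Wildman–Crippen per-atom contributions are obtained from RDKit through a
bundled Python bridge (`inst/python/ligand_bridge.py`), invoked per unique
(structure, seed) and cached for the session. The contribution-sum
identity — per-atom values summing to the scheme's whole-molecule logP —
is asserted in the tests against independently computed frozen reference
values. Contributions are topological, so re-embedding never changes them;
the tests assert that too.

## What the synthetic libraries emulate — and what they do not

`generate_ratio_series()` builds the two-ligand ratio series: particles
sharing a hydrophilic thiol-PEG-ol (`SCCOCCOCCO`) and a hydrophobic
dodecanethiol (`SCCCCCCCCCCCC`), with the hydrophobic fraction $\varphi$
evenly spaced over $[0, 1]$ at 38 total ligands on a 2 nm core (~3
thiols/nm², a realistic grafting density). Its acceptance property is
strict monotonicity of seed-averaged logG/R in $\varphi$ (Spearman
correlation 1 over 8 particles × 5 placement seeds).

`generate_calibration_library()` emulates a modeling set: `n` two-ligand
particles with $\varphi$ spanning $[0, 0.9]$ (capped so both surface
channels stay populated without clamping artefacts), core diameters
cycling through 2–3 nm, and synthetic experimental logP generated from
each particle's *own* computed logG/R:
$\mathrm{elogP} = a\,\log G/R + b + \mathcal N(0, \sigma^2)$ with
$\sigma = 0.8$ by default, a realistic shake-flask scatter. When $a, b$
are not given they are auto-derived so the noiseless elogP spans exactly
$[-3, 3]$, the range a well-designed modeling library covers; explicit
values are honoured for parameter-recovery tests. Structure and noise have
separate seeds, so the same structures can carry independent noise draws.

What passing these tests shows: the geometry, surface extraction, scoring
and calibration machinery are self-consistent, deterministic under seeds,
and able to recover known generating parameters. What they do not show:
agreement with wet-lab logP of real GNP libraries. The synthetic elogP is
generated from the method's own descriptor, so calibration accuracy on the
fixtures says nothing about the descriptor's real-world validity; only
measured data can. `run_pipeline()` accepts any user library CSV with
measured `elogp` and refits/cross-validates on it, which is the intended
route for users holding real composition tables (the published coefficient
pair ships as the default model for prediction without refitting).

## Problem sizes

The test and acceptance runs use 2–3 nm cores with 10–40 ligands
(roughly 250–1900 atoms, 15,000–25,000 surface nodes at `h = 0.8`),
8-particle ratio series averaged over 5 placement seeds, 41-particle
calibration libraries, and brute-force SAS cross-checks on particles of up
to 50 atoms — sizes chosen so a full verification pass completes in
minutes on one CPU while exercising every code path at realistic grafting
densities.

## Known limitations

* Single static conformer per ligand; no conformational sampling, no
  protonation-state or charge enumeration. Strongly charged or zwitterionic
  ligands are outside the supported chemistry (unsupported elements raise a
  typing error naming the atoms).
* No ligand–ligand packing optimisation; at very high grafting densities
  the random-pose shell overestimates overlaps, though only the outer
  surface enters the score.
* Spherical cores only; faceted or anisotropic particles (rods, tubes) are
  not representable.
* The absolute logG/R value depends on the chosen contribution table,
  kernel and grid spacing; comparisons across configurations require
  refitting the calibration. Exact numeric parity with other
  implementations of the same idea is therefore not claimed — the shipped
  published coefficients are meaningful for the configuration they were
  fitted under.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates every headline
quantity from scratch with the installed package: the worked-example
predictions of the published line, the ratio-series Spearman correlation,
the SAS fast-path/brute-force agreement, and calibration/CV accuracy on
the synthetic modeling library. The README shows a worked example with the
numbers it prints.
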