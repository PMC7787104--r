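---
title: "Reflection triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflection triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(refltriage)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters with their defaults and units, what the
synthetic-data generators do and do not emulate, the numerical choices, and
the places where the design was genuinely open and a choice had to be made.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The problem

Maximum-likelihood phasing is only as good as the preparation of the merged
intensities it consumes. Three pathologies systematically distort Wilson
intensity statistics and, uncorrected, degrade every downstream likelihood:

* **anisotropy** — direction-dependent falloff of the diffraction;
* **translational NCS (TNCS)** — several copies of the molecule related by
  a near-pure translation, which modulates expected intensities
  reflection-by-reflection;
* **twinning** — overlapped diffraction from multiple crystal domains,
  which mixes intensities and can make data merge in too high a symmetry.

These interact: TNCS masks twinning in intensity statistics, and perfect
twinning can hide the true crystal symmetry. The triage pipeline therefore
orders its stages as anisotropy → TNCS → twinning → subgroup expansion, and
because several TNCS orders (and, later, several subgroups) may remain
plausible, every decision is recorded as a hypothesis node in a DAG rather
than a single forced choice. Leaves are phasing-ready datasets; edges add
information; restarting from a halted run is a no-op for completed nodes.

## 2. Normalization model

All statistics operate on normalized intensities

$$z = \frac{I}{\varepsilon_{\mathrm{sym}}\,\varepsilon_{\mathrm{tncs}}\,A(\mathbf h)\,\Sigma(s)}$$

* $\varepsilon_{\mathrm{sym}}$: number of point-group rotations fixing
  $\mathbf h$ (exact integer, from the group algebra).
* $A(\mathbf h) = \exp(-\tfrac12 \mathbf s^\top B \mathbf s)$ with
  $\mathbf s = M\mathbf h$ the reciprocal vector in Å⁻¹ and $B$ a symmetric
  **traceless** tensor in Å². Interpretation: an isotropic $B$ would be the
  ordinary Debye–Waller intensity factor; the trace is deliberately absorbed
  into $\Sigma(s)$ so the tensor refines only genuine directionality. The
  intensity-scale convention (the $\tfrac12$) is ours; nothing upstream
  fixes it.
* $\Sigma(s)$: per-bin mean of $I$ over the applied factors, estimated on
  20 equal-count bins in $s^2$ (bins are merged upward until each holds at
  least 50 reflections), iterated jointly with outlier masking to a fixed
  point ($|\Delta\Sigma|/\Sigma < 10^{-6}$, at most 20 iterations).
* Outliers: acentric $z > -\ln p$, centric $z > \Phi^{-1}(1-p/2)^2$ with
  $p = 10^{-6}$ by default (the classical Wilson tail bounds).

Second moments $\langle z^2\rangle/\langle z\rangle^2$ are computed per
class as count-weighted means over bins, with a jackknife-over-bins standard
error. The jackknife was chosen because it is distribution-free and honest
for the bin-correlated estimator; a closed-form moment variance would
understate the error in the presence of residual resolution structure.

**French–Wilson handling.** Likelihood targets want raw intensities, not
posterior expectations. Detection uses two signatures of prior posterior
treatment: no negative intensities at all, and a depleted low tail
(posterior shrinkage pulls weak acentrics up toward the prior mean). The
flag fires when the fraction of acentric $z<0.05$ is below half its Wilson
expectation $1-e^{-0.05}$ *and* no negatives exist. The exact criterion used
by production software is unpublished; ours is a documented surrogate, and
`french_wilson_posterior()` (exponential prior × Gaussian likelihood, a
truncated normal in intensity with closed-form moments) provides the forward
model used to test it.

## 3. Anisotropy refinement

The coefficient space is the nullspace of the symmetry-invariance system:
orthonormal traceless symmetric tensors $B_j$ with $QB_jQ^\top = B_j$ for
every Laue rotation $Q$ in the orthogonal frame — 5 parameters for Laue
$\bar1$, 3 for $2/m$, 2 for $mmm$, 1 for the tetragonal/trigonal/hexagonal
classes, 0 for cubic. Refinement maximizes the Wilson log-likelihood
(exponential acentric, half-Gaussian centric) by BFGS over these
coefficients, alternating with re-estimation of $\Sigma(s)$, declaring
convergence on a scaled gradient norm or coefficient stagnation (cap 100
alternations). Measurement sigmas are folded into the Wilson mean only — a
documented approximation; the exact per-reflection error treatment of the
production likelihood is not public.

**Low-resolution restraint.** With sparse low-resolution data the tensor is
poorly anchored, so a harmonic restraint with weight
$w = 0.01 \cdot \max(0, 100 - n_{\mathrm{lowres}})$ per Å⁴ (reflections
with $s < 0.1$ Å⁻¹) pulls coefficients to zero. Two consequences worth
knowing: on small datasets mild anisotropy is deliberately under-fitted,
and because the weight depends on the unique-reflection count it relaxes
slightly when data are expanded to a subgroup — the expansion-invariance
test bounds the resulting tensor difference at 25 %.

Anisotropy is refined once, in the parent symmetry, and inherited by
subgroup expansions: expanded intensities retain the higher symmetry, so
repeating the correction with fewer constraints could only chase noise.

## 4. TNCS: detection and correction

**Detection.** The Patterson synthesis uses coefficients $z-1$ from
symmetry- and anisotropy-normalized intensities in a 10–4 Å window
(defaults; TNCS modulations are strong there, atomic-scale vectors are
suppressed), evaluated by FFT on a grid of target spacing $d_{\min}/3$.
With mean-one coefficients the origin of the $z-1$ synthesis is near zero,
yet peak heights are conventionally quoted relative to the origin; the
origin value is therefore *defined* as $\sum z$ — the self-vector term the
$z-1$ coefficients remove — restoring the convention and making the origin
the global maximum by construction. Peaks are 26-neighbourhood local maxima
above 20 % of that origin, outside a 5 Å exclusion sphere, parabolically
refined to sub-grid positions and deduplicated under the map symmetry.

**Order inference.** For each strong peak $\mathbf u$, the smallest order
$m \le m_{\max}$ (default 8) with $m\mathbf u$ integral within two grid
steps is proposed with $\mathbf t = \mathrm{round}(m\mathbf u)/m$; a peak
closing no commensurate family still proposes $m=2$ with
$\mathbf t=\mathbf u$ (a molecular pair needs no closure). Hypotheses
predicting the same peak family are duplicates (e.g. generators $1/7$ and
$3/7$ along c) and are merged. The no-TNCS hypothesis is *always* retained:
large Patterson peaks have causes other than TNCS.

**Correction.** Expected-intensity factors follow the pairwise-correlation
model given in the README, normalized to unit mean per resolution shell.
The defining equations of the production parameterization live in cited
literature rather than in any single public source, so the concrete form
here is the package's own instantiation with the required limits: $\rho=0$
gives flat factors, $\rho=1$ the interference function of an $m$-fold
translation lattice. The resolution-dependent related fraction
$f(s) = f_0 e^{-\beta s^2}$ is likewise a flagged surrogate. Refinement is
L-BFGS-B with bounds $r_{\mathrm{eff}} \in [5,100]$ Å,
$\sigma_{\mathrm{rmsd}} \in [0,3]$ Å, $f_0 \in [0,1]$, $\beta \in [0,50]$ Å²,
translation free within one grid step (components that are exactly zero in
the Patterson-derived vector are treated as structural and held). For
order 2 the rotational difference between copies is refined from five
starting states — exact alignment and $\pm2°$ about each of two axes
orthogonal to $\mathbf t$; the perturbation magnitude and axis geometry are
our choice (five starts are prescribed, their geometry is not). Small-angle
axis-angle composition parameterizes the rotation.

**Model comparison.** Because $f_0$ is free, a forced TNCS fit on clean data
degenerates to the no-TNCS model with *equal* likelihood; "fits worse" is
therefore judged with an AIC-style margin — the refined model must beat the
no-TNCS likelihood by at least one unit per added parameter, else the
`tncs_not_supported` flag is set.

## 5. Twinning

The L-test runs on fully corrected normalized intensities: pairs of
distinct acentric reflections with all index differences $\le 2$, never
symmetry-related (automatic, since canonical unique indices are distinct
orbits), each reflection in at most 4 pairs to keep dependence weak.
Centric reflections are excluded — their wider intensity distribution
inflates $|L|$ and the reference distributions assume acentric statistics.
$\langle|L|\rangle$ references for twin fraction $\alpha$ come from a
cached, internally seeded $10^6$-sample Monte Carlo of
$(1-\alpha)E_1+\alpha E_2$ mixtures (exact value $1/2$ substituted at
$\alpha=0$). The reported `p_untwinned` is
$\Phi\big((\overline{|L|}-\tfrac12)/(\mathrm{sd}_0/\sqrt n)\big)$: near 1
for untwinned data, tiny for twinned data, matching the convention in which
clean datasets print 1 and pathological ones print vanishing values; the
statistic behind the analogous published column is not defined there, so
the orientation is our documented choice, as is reading the "twin fraction
below 5 %" column as the same construction against the $\alpha=0.05$
reference. The verdict threshold `p_untwinned < 1e-6` (config-exposed)
triggers subgroup expansion.

## 6. Symmetry and expansion

Merged intensities only feel the rotation group of the Laue class, so
groups are integer matrix groups acting on Miller indices; space-group
translations enter only through the axial-absence screen (`"unmeasured"`
below 3 screened axials, `"absent"` below mean I/σ of 2). The canonical
asymmetric-unit representative is the lexicographically greatest orbit
member under rotations plus Friedel — deterministic and group-agnostic,
since no convention is imposed from outside. Subgroups are enumerated by
closing all generator subsets of size ≤ 3 (every subgroup of these groups
is 2-generated; 3 is margin) and reduced to one representative per
conjugacy class: conjugate subgroups are the same hypothesis up to axis
relabelling, and this reduction is exactly what makes the worked
pathological example yield 7 proper subgroups of 422 and hence 8 leaves.
Expansion maps each parent orbit into the subgroup's ASU with intensities
copied unchanged; re-merging reproduces the parent data exactly, which the
tests assert.

Supported point groups: 1, 2, 222, 4, 422, 3, 32, 6, 622, 23, 432 and
their Laue/space-group symbol aliases. Rhombohedral settings are deferred —
lattice bookkeeping, not algorithm, would change.

## 7. The DAG

Nodes are typed (crystal, data, anisotropy, tncs_order, tncs_correction,
twinning, spacegroup, spacegroup_expansion) with a stage partial order
enforced at insertion; edges are acyclic by construction and checked.
Node ids are `kind-` plus a 32-bit FNV-1a hash of the kind, the *defining*
payload entries and the parent ids. The defining subset deliberately
excludes computed results: an id must be known before the stage runs, or
resume could never recognize completed work. (A hash over the full payload,
results included, was considered and rejected for exactly that reason.)
Stage nodes carry their configuration inputs in the defining set, so
changing, say, the twin threshold regenerates the twinning node and its
descendants while reusing everything upstream. Serialization is JSON with
type-tagged payload entries (scalars, vectors, matrices, TNCS models);
`NA` serializes as JSON null. Graphviz DOT export is provided for
inspection.

## 8. What the simulators emulate — and what they do not

`simulate_wilson_data()` draws normalized intensities directly from the
Wilson distributions with a smooth $\Sigma(s)=K e^{-B_{\mathrm{iso}}s^2/2}$
($B_{\mathrm{iso}} = 25$ Å², a typical protein Wilson B), twin mixing with
a same-class same-resolution partner, and Gaussian noise at 5 % of
$\Sigma$ — the stated world for the moment-calibration targets (2.0/3.0
clean, 1.5/2.0 perfect twin).

`simulate_dataset()` is atomistic: uniform point scatterers, TNCS copies at
$k\mathbf t$ with Cartesian scatter of total r.m.s. $\sigma$, a fraction
$1-f_0$ of atoms independently repositioned per copy, optional order-2
rotation, direct structure-factor summation over the symmetry-expanded atom
list, anisotropic attenuation, permutation-based twin mixing, and noise at
2 % of the shell mean. Defaults (45×55×65 ų cell, 50 atoms, 2.5 Å) are a
mid-size protein-like stated world chosen once.

Not emulated: atomic form factors, solvent, measurement-error profiles,
radiation damage, partial twin-domain structure. A green test therefore
establishes the *statistical* machinery — distributions, modulations,
symmetry bookkeeping — not detector physics. One honest consequence seen in
the tests: in the synthetic sevenfold-TNCS-plus-perfect-twin preset the
*uncorrected* branch also trips the twin verdict (the TNCS masking is only
partial in our world, where it was complete in the historical dataset), so
the end-to-end DAG has 14 leaves while the stated logical scenario — twin
detected only under order 7 — has the canonical 8.

`scenario_4n3e()` emulates tetartohedral twinning by simulating the true
twofold crystal and re-merging into the 422 ASU, which averages the four
twin-domain intensities exactly (perfect twinning, α = 0.25 per domain) —
a merge, not a coset operation, consistent with keeping twin-law algebra
out of scope.

## 9. Numerical choices

* Cell algebra: $M = \mathrm{chol}(G^{-1})$ so $|M\mathbf h| = 1/d$ exactly;
  positive-definiteness of the metric is checked at construction.
* Patterson FFT grids take the larger of the $d_{\min}/3$ target and the
  aliasing bound $2h_{\max}+2$ per axis.
* `interference_G` switches to a series below $x=10^{-3}$ (the closed form
  loses digits to cancellation there).
* Normalized TNCS factors are floored at $10^{-6}$: raw factors may be
  exactly zero under perfect destructive interference, but they serve as
  likelihood means and divisors.
* Ties everywhere (topological sort, shortest path, leaf ordering, subgroup
  ordering) break lexicographically by id/label, making every output
  deterministic; the `threads` configuration field is an advisory contract
  that results are independent of parallelism degree, trivially satisfied
  by the vectorised implementation and asserted by test.

## 10. Known limitations

* One independent TNCS vector; non-commensurate rotation families and
  doubled-cell pathologies are logged, not modelled.
* No twin-fraction estimation (H-test/Britton) and no twin-law coset
  enumeration; expansion is by subgroups only.
* The anisotropy likelihood ignores per-reflection sigmas beyond the Wilson
  mean; at very low multiplicity this under-weights noisy reflections.
* MTZ I/O is a minimal self-contained implementation of the standard binary
  layout (no suitable library exists in the target environment): it
  round-trips its own files exactly and reads well-formed merged files with
  H/K/L plus I/SIGI or F/SIGF columns, but does not attempt batch headers,
  multi-dataset hierarchies or anomalous pairs.
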