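---
title: "Community metabolic modeling of the gut microbiome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolic modeling of the gut microbiome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfba)
```

This vignette is the package's account of its science: the community
model and its assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, and the numerical and design
choices that were genuinely open.

## 1. The community model

Constraint-based metabolic modeling treats an organism as a
stoichiometric matrix `S` (metabolites in rows, reactions in columns)
whose flux vector `v` (mmol per gram dry weight per hour) is assumed at
steady state, `S v = 0`, within thermodynamic and environmental bounds
`lb <= v <= ub`. The biomass reaction is normalized so that unit flux
corresponds to a growth rate of 1/h. Flux balance analysis (FBA)
maximizes biomass flux by linear programming.

A gut community embeds each taxon in a private compartment and couples
all of them through a shared lumen. We use the abundance-weighted
convention: for lumen metabolite `m`,

$$\sum_i a_i\, v_{i,\mathrm{ex}}(m) \;-\; v_{\mathrm{env}}(m) \;=\; 0,$$

where `a_i` is the relative abundance of taxon `i` (mass fraction),
`v_i,ex` its per-gDW exchange flux with the lumen (positive = export),
and `v_env` the environment exchange of the lumen (positive = export out
of the community; imports are bounded by the diet). Because taxon fluxes
are per gram of that taxon, weighting by `a_i` makes the lumen balance a
whole-community mass balance, and community growth is
$\mu_c = \sum_i a_i \mu_i$. A one-taxon community at abundance 1 reduces
exactly to single-model FBA, which the tests exploit.

Taxa with relative abundance below `1e-4` are removed before assembly
and the remainder renormalized; this cutoff is applied to the raw
relative abundances, and the filtering is idempotent.

Sign convention throughout: exchange flux > 0 is export, < 0 import.
Identifier scheme: `<taxon>__<met>` for taxon-internal metabolites,
`<met>_lu` for lumen metabolites, `EX_<met>_lu` for environment
exchanges.

## 2. Growth allocation: the cooperative trade-off

Maximizing $\mu_c$ alone lets the single most efficient taxon absorb all
growth, which contradicts the observed coexistence of gut communities.
The cooperative trade-off solves two stages:

1. maximize $\mu_c$, giving $\mu_c^*$;
2. minimize $\sum_i \mu_i^2$ subject to $\mu_c \ge \tau\,\mu_c^*$ and
   all flux constraints.

The default $\tau = 0.7$ sacrifices 30% of the community optimum to
spread growth. Stage 2 is strictly convex in the growth rates, so the
$\mu_i$ are unique even though other fluxes may not be; a tiny ridge
(1e-8) on non-growth fluxes pins those to the minimum-norm optimum, and
reports that depend on flux identity use the parsimony solve below. With
$\tau < 1$ and any slack to trade, the growth constraint binds, so the
achieved $\mu_c$ equals $\tau \mu_c^*$ to solver tolerance — the package
verifies a ratio of 0.7 to within 1e-4.

`minimize_intake(community, growth_floor)` selects, at a required
growth, the solution with the lowest total lumen import
($\sum_m \max(0, -v_{\mathrm{env}}(m))$) — the scarce-resource
assumption that a gut community draws as little from the diet as its
growth requires. Each environment exchange is split into nonnegative
export and import parts so the objective is linear over equalities and
bounds.

## 3. Numerical core

No dedicated LP solver is assumed; all programs are solved through the
dual active-set quadratic solver in `quadprog`:

* **LPs** by proximal-point iteration: repeatedly maximize
  $c'v - \tfrac{r}{2}\lVert v - v_{k}\rVert^2$, posed with unit quadratic
  matrix and the linear term scaled by $1/r$ (well-conditioned for the
  solver). For polyhedral objectives the iteration reaches the exact LP
  optimum after finitely many steps; against a brute-force
  vertex-enumeration oracle on random small instances, objectives agree
  to better than 1e-8.
* **QPs** (trade-off stage 2) directly, with the ridge above.

Stoichiometric matrices routinely carry linearly dependent rows; these
are removed by QR factorization before each solve (with a consistency
check on the right-hand side). Two failure modes of the active-set
method are handled: spurious "inconsistent constraints" reports on
ill-conditioned instances trigger an escalating-ridge retry, and stalls
on heavily degenerate vertices (many bounds active at the start point)
trigger a retry with every inequality relaxed by a deterministic offset
below 1e-9, which splits the degenerate vertex while perturbing the
optimum by less than the reporting tolerance. Bounds at infinity are
clamped to 1e6 and a solution pinned at the clamp is reported as
unbounded, never silently. All solves are deterministic: rerunning any
pipeline stage with the same seed reproduces artifacts checksum-exactly.

## 4. Elasticities and pair labels

The elasticity of an exchange flux `v` with respect to a parameter `p`
(a taxon's abundance, or a diet uptake bound) is the log-derivative
$\varepsilon = \partial \ln v / \partial \ln p$, estimated by a
one-sided forward difference with step `h = 0.1` on the log scale — a
10.5% native-scale increase ($e^{0.1}-1$). A one-sided difference is
used because the procedure is defined by a single stated step; the
discretization error is first-order in `h`, which the tests confirm by
Richardson ratio. The perturbed community is re-solved by the full
cooperative trade-off. Direction (the sign of the baseline flux) is
recorded separately, and the elasticity is undefined — never infinite —
whenever the baseline or perturbed flux magnitude falls below the flux
epsilon of 1e-6 mmol/gDW/h. Abundance perturbations are applied before
renormalization: one taxon is bumped, the vector rescaled.

Matched pairs are compared per taxon by the *variance of defined
elasticities across the flux panel* for that taxon's abundance
parameter, computed separately in each member. How to take this variance
was genuinely open (across parameters, metabolites, or repeated solves);
we fix "across the flux panel" and document it. A pair is labeled
`ADHD` when the case member's variance exceeds the control's by more
than the relative threshold `theta` (default 0.2, i.e. 20% wider),
`Control` for the reverse, `Same` within the band, and `NA` when the
taxon is absent from either member or fewer than two elasticities are
defined. The threshold is a tunable: the notion of a "wider range" is
qualitative in the source analyses, and 20% separates solver-level
jitter from real asymmetry at the default panel sizes.

## 5. Diversity

Alpha indices per sample (on counts): richness `S`; Chao1
`S + F1^2/(2 F2)` with the bias-corrected `S + F1(F1-1)/2` when no
doubletons exist; Shannon `-sum p ln p`; Simpson `D = sum p^2`; Simpson
evenness `(1/D)/S`. Chao1 needs singleton and doubleton counts, which
relative abundances cannot supply, so the generators also emit integer
counts by multinomial draw at a documented pseudo-depth (default
10,000), and `to_counts()` converts compositional data the same way.

Beta diversity: Bray-Curtis on counts,
$BC_{ij} = 1 - 2 C_{ij} / (S_i + S_j)$ with $C_{ij}$ the sum over shared
species of the lesser count — 0 for identical samples, 1 for disjoint
support, always within [0, 1]. UniFrac on a phylogeny: unweighted is
unique-branch length over observed-branch length; weighted uses the
normalized variant
$\sum_e b_e |p_A(e) - p_B(e)| \,/\, \sum_e b_e (p_A(e) + p_B(e))$
(bounded in [0, 1]; the variant choice was open and the normalized form
is taken so both UniFrac flavors share a scale). The implementation is
first-principles; the test suite cross-checks it against an independent
reference implementation on a fixture tree.

Group comparisons: the Mann-Whitney U test uses the exact null
distribution (standard counting recursion) when `n_A * n_B <= 400` and
the pooled sample is tie-free, otherwise the normal approximation with
tie and continuity corrections; the F test compares variances with a
two-sided p from the F distribution. Both are validated against their
stats-package counterparts.

## 6. The synthetic-data layer

The generators define the study conditions; their defaults are fixed
constants of the package, not knobs.

**Taxon models.** An archetype lists what a taxon consumes and secretes
(molar yields per mol substrate) and its growth yield (gDW/mmol). The
generated network has one uptake exchange per substrate, a linear
conversion chain on the primary substrate (padding to the requested
size), one conversion per substrate yielding biomass precursor plus the
secreted products, secretion exchanges, and one biomass reaction; every
internal metabolite participates in at least two reactions. Uptake caps
default to 10 mmol/gDW/h. The default roster names 12 gut taxa with
literature-motivated roles — e.g. *S. variabile* as a butyrate producer
that also converts lumen acetate, *R. bromii* as a starch specialist,
Bacteroides as propionate producers, amino-acid (tryptophan, tyrosine,
phenylalanine) importers among them, and *L. rhamnosus* as the probiotic
acetate producer whose cross-feeding can raise butyrate export.

**Calibration.** The secretion yields are the generator's calibration
constants: under the healthy baseline composition and the western-style
diet, the community lumen SCFA exports sit at approximately the
physiological 3:1:1 acetate:butyrate:propionate ratio (achieved
3.06 : 1 : 0.97). They were set once, by scaling initial
literature-guessed yields against a single measurement of the preset,
and frozen.

**Paired studies.** Each pair shares an age (normal around 19.5 y, sd
2.5, floored at 12), a gender (60% male), and a baseline log-abundance
profile (roster baseline plus pair-level lognormal variation, sd 0.5);
the case member additionally receives planted log-fold shifts.
Multiplicative lognormal noise (default sd 0.3) is applied per member
before renormalization — the noise model is a design choice, since only
relative abundances are observable. With zero noise and zero shifts the
two members are identical, and every downstream pair comparison returns
`Same`.

**Diets.** A diet is a table of per-nutrient exchange bounds with
nutrient class and energy density (Atwater factors — 9 kcal/g lipid,
4 kcal/g carbohydrate and protein, 2 kcal/g fermentable fiber — times
molar mass). Styles realize prescribed macro-energy splits exactly:
Atkins-style 1.7% carbohydrate / 70% lipid / 24% protein with the
remaining 4.3% as fermentable fiber (the printed macro percentages sum
to 95.7%, so a small non-macro energy carrier is required for the
fractions to be shares of total energy); vegan-style 63.35 / 20.99 /
15.66 (which sums to 100); western-style 50 / 35 / 15, a typical
US-diet estimate, chosen here because no printed split was available.
How to realize percentage targets as flux bounds was open — the
Atwater-factor realization with fixed intra-class shares is this
package's convention.

**Trees.** Random coalescent topologies with exponential branch lengths
(`ape::rcoal`), deterministic under the seed; nothing about the real
taxa's phylogeny is emulated beyond leaf labels.

**Planted elasticity effects.** Guaranteeing a calibrated
elasticity-variance inflation through actual community physics is not
controllable, so group effects on elasticity are planted at the profile
level: both members share per-cell baseline elasticities (spread sd
0.5 around a per-taxon mean), the case member's deviations for
designated taxa are scaled by $\sqrt{\text{inflation}}$, and
independent observation noise is added per member. The default
observation noise (0.05 of the baseline spread) is derived, not tuned:
under the null the log variance-ratio of the two members fluctuates
with standard deviation about
$\sqrt{2}\cdot 2\,\sigma_\varepsilon/(\sigma_b\sqrt{n_f - 1})$, so 0.05
keeps spurious labels below 1% for the default 8-flux panel at
`theta = 0.2`, while a 3x inflation moves the ratio far outside the
band. With 50 pairs the package recovers over 80% of designated taxa as
`ADHD` and over 95% `Same` under the null.

**What the generators do not emulate.** Real strain reconstructions
(hundreds to thousands of reactions, realistic stoichiometry and
cofactors), real diet composition, compositional correlation structure
between taxa, sequencing noise, or any real phylogeny. Passing tests
demonstrate that the pipeline's logic and numerics are correct under
controlled conditions — not that its predictions transfer to clinical
data.

## 7. The intervention

The probiotic dose is fitted by least squares on compositions:
$m^* = \arg\min_{m \ge 0} \lVert (x + m e_k)/(1+m) - c \rVert^2$ for
sample `x`, reference `c`, probiotic `k`. The objective is a smooth
rational function of `m`, unimodal on the search bracket `[0, 5]`
(doses of interest are an order of magnitude smaller); it is minimized
by golden-section search and verified in the tests against both a 1e-4
grid and the closed-form stationary point
$m^* = (A - B)/(C - B)$ where, with $d = x - c$ and $g = e_k - c$,
$A = d'd$, $B = d'g$, $C = g'g$. The reference sample is an explicit
argument with a seeded random default: reproducibility is preferred
over fidelity to an unspecified random choice. After addition the
sample is renormalized, the community rebuilt and re-solved, and
per-metabolite flux shifts reported as percent change with a
direction-flip flag; shifts are undefined when the pre-intervention
flux is below the flux epsilon.

## 8. Pipeline scale and reproducibility

The default pipeline (10 pairs, 12 taxa, 3 diets, 4-flux elasticity
panel) performs roughly a thousand community solves and completes in
about 40 s on one CPU; the test suite solves smaller configurations
throughout and finishes in about half a minute. One global seed fans
out to per-stage seeds by stable integer hashing, every artifact is
checksummed into a manifest, and a failed stage aborts by name after
persisting the partial manifest.

## 9. Known limitations

* Toy stoichiometry: yields are phenomenological, not mass- or
  electron-balanced; quantitative fluxes have no physiological units
  beyond their construction.
* The LP path relies on a dense active-set QP solver; it is exact at
  this problem scale but would not scale to genome-scale models with
  tens of thousands of reactions.
* Non-growth fluxes at the trade-off optimum are only pinned by the
  minimum-norm ridge; flux-identity claims should use
  `minimize_intake`.
* The pair-label threshold `theta` is a convention; real analyses
  should report sensitivity to it.
* Chao1 on pseudo-counts inherits the pseudo-depth: singleton counts at
  depth 10,000 are not sequencing-read singletons.
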