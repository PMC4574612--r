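---
title: "Ensemble modeling of the monolignol pathway: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modeling of the monolignol pathway: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligninGMA)
```

## The modeling problem

Lignin is the main determinant of cell-wall recalcitrance in bioenergy
grasses, and its monomer composition (H, G and S units, from
p-coumaryl, coniferyl and sinapyl alcohol) responds in sometimes
counterintuitive ways to transgenic down-regulation of the pathway
enzymes. The most striking case in switchgrass is a roughly twofold
*increase* of H lignin when 4CL — an enzyme *upstream* of the H branch
point — is down-regulated. `ligninGMA` implements an
ensemble-modeling workflow for the monolignol pathway that uses such
knockdown observations to discriminate between candidate pathway
structures and regulatory mechanisms:

1. encode the pathway (16 metabolites, up to 26 fluxes, 2 influxes)
   under three configurations of a hypothesized CCR1/CAD channel;
2. anchor the wild type to a steady-state flux distribution obtained by
   linear programming;
3. sample kinetic orders by constrained Monte Carlo;
4. simulate knockdown scenarios for every sampled model and accept the
   models that reproduce the experimental fold changes;
5. analyze the accepted ensemble (PCA) and validate the surviving
   configuration under a multi-enzyme perturbation.

## The normalized GMA model

Each flux follows a generalized mass action (power-law) rate law

$$V_j = \alpha_j \prod_r Z_r^{g_{r,j}} \cdot E_j,$$

where the $Z_r$ are metabolite concentrations, $g_{r,j}$ are real
kinetic orders (positive for the substrate, negative for inhibitors)
and $E_j$ is the activity of the catalysing enzyme, entering linearly
(exponent 1), consistent with Michaelis–Menten-style kinetics where
$V_{max} = k_{cat} \cdot E$. Because absolute in-vivo concentrations
are unknown, every state is normalized to its wild-type steady state
and rebased at 100; enzymes are normalized to 1. Knockdowns are then
simple multipliers on enzyme activities (a 40 % down-regulation of 4CL
is activity 0.6).

The normalization has a major computational advantage: at the
wild-type steady state every steady-state flux satisfies
$V_j = \alpha_j\,100^{\sum_r g_{r,j}}$, so once a steady-state flux
distribution $V$ is fixed, the rate constants follow analytically as
$\alpha_j = V_j / 100^{\sum_r g_{r,j}}$ for *any* sampled kinetic-order
set. Every sampled model therefore has the all-100 state as an exact
wild-type fixed point by construction — no per-model calibration is
needed, which is what makes screening of thousands of models feasible.
`compute_rate_constants()` implements this inversion and
`simulate_steady_state()` verifies the fixed point (acceptance test:
residual at machine precision, and return to all-100 from randomly
perturbed starts).

### Regulation structure

Three regulatory mechanisms are switchable per model:

* **Universal product inhibition.** Every flux whose immediate product
  is a model state carries that product with a negative kinetic order.
  Linearization of a product-inhibited Michaelis–Menten law bounds the
  ratio of inhibitor to substrate order: $-1 < g_I/g_S < 0$. The
  sampler enforces this by drawing the *ratio* (default uniform on
  $(-0.99, -0.01)$; a fixed $-1/2$ mode reproduces the shipped example
  set, in which every inhibitor order is exactly half its partner
  substrate order with opposite sign).
* **CCR1 substrate competition.** p-Coumaroyl-CoA and feruloyl-CoA
  compete for CCR1, so each substrate appears with a negative order in
  the other's CCR1 flux (and in the channel flux). Competition orders
  are tied to the competitor's own substrate order by the same ratio
  rule — the pattern exhibited by the example set.
* **4CL inhibition in COMT knockdowns.** COMT transgenics accumulate
  4CL substrates while coniferaldehyde falls, which is only consistent
  with an inhibition of the 4CL-catalysed steps. It is implemented
  generically by scaling the 4CL activity (equivalently the rate
  constants of its three fluxes) with a factor
  $\phi \sim U(0.1, 0.9)$, sampled because no measured value exists.
  $\phi$ is a nuisance parameter of the COMT *scenario*, not a
  property of the wild-type model, so the screen asks an existence
  question: a kinetic-order set matches the COMT data if *some*
  admissible inhibition strength reproduces them. `screen_ensemble()`
  tries the set's sampled $\phi$ first and then a fixed grid
  (0.15–0.90 in steps of 0.15), deterministically; requiring the
  random $\phi$ draw itself to land in the admissible window
  (`phi_grid = NULL`) gates acceptance on sampling luck instead and
  starves the ensemble several-fold.

## The flux anchor

The wild-type flux distribution is the solution of a linear program:
maximize total lignin flux ($V_7 + V_{17} + V_{25}$) subject to
steady-state mass balance and bounds. The published problem leaves the
bound magnitudes open, so the package's defaults are calibrated once to
the flux distribution implied by the shipped example parameter set
(through $V_j = \alpha_j 100^{\sum g}$): influx $I_1 = 1$, secondary
influx $I_2 \in [0, 0.1]$ (implied value ≈ 0.08), lower bounds on the
five non-lignin effluxes at their implied values (0.155, 0.082, 0.046,
0.050, 0.010), each capped at 30 % of total influx, H pinned at 3 % of
lignin flux (the reported H share), and a wild-type S/G flux ratio
window of $[0.5, 1]$. All of these live in `default_bounds()` /
`default_config()`, not in code.

Alternate optima are genuinely present (the split between the free
CCR1/CAD route and the channel is objective-neutral, as is the S/G
split inside its window), so the optimum is tie-broken by minimizing
the Euclidean norm of the flux vector among optima — a deterministic,
reproducible anchor. With the default bounds the tie-break routes about
61 % of the feruloyl-CoA→coniferyl-alcohol conversion through the
channel and puts the wild-type S/G flux ratio at the lower edge of its
window.

In Configuration 3 the free route is absent, so the coniferaldehyde
sub-branch (F5H → 5-OH-coniferaldehyde → sinapaldehyde) has no supply;
its fluxes are structurally zero, their rate constants are set to zero,
and the affected nodes simply hold their initial value. This is the
mass-consistent reading of "channel only", and it is one reason that
configuration cannot reproduce the COMT metabolite signature.

## Reading out lignin

The model has no lignin pools; lignin production is read out as the
steady-state values of the three terminal monolignol fluxes $V_7$ (H),
$V_{17}$ (G) and $V_{25}$ (S); the minor 5-OH-coniferyl alcohol efflux
is excluded from totals. Fold changes are taken relative to the
wild-type fluxes, which are known analytically.

A structural consequence of constant influxes deserves emphasis: at a
*true* steady state, total efflux equals total influx, so total lignin
flux can only decrease to the extent that mass is diverted into the
non-lignin effluxes. Large knockdown-induced lignin reductions
therefore require substantial accumulation of efflux-carrying
intermediates (p-coumaric acid, ferulic acid, the CoA esters), driven
by sufficiently strong product-inhibition cascades and efflux kinetic
orders. This is exactly the regime the screening selects, and it is why
acceptance is a rare event under uniform sampling: the data demand a
specific, strongly regulated corner of the kinetic-order space. A
quasi-steady (finite-horizon) readout was evaluated during design and
rejected: it produces lignin decreases easily but cannot produce the
4CL H-lignin increase, whose underlying relief-of-competition wave
develops on slow timescales.

## The channel coupling

How CCR1 and CAD knockdowns propagate to the channel complex `Z34` is
not specified by the biology available to the model, so it is a
configurable rule. The default couples the channel to CCR1 alone
(`ccr1`): the complex's throughput is controlled by its committed
reductase step, and CAD down-regulation leaves channel flux intact.
This is the only rule among the three shipped (`ccr1`, `product`,
`min`) that reproduces the observed S/G directions — S/G *increases*
in CCR1 knockdowns (G is hit through both the free route and the
channel) but *decreases* in CAD knockdowns (the channel shields G
while the S branch loses its CAD step). Multiplicative and min
couplings make the channel track CAD as well, which forces S/G up
under CAD knockdown, contradicting the data.

## Screening criteria

The experimental table mixes point values, ranges and directions, and
no numeric matching tolerance is published. Two readings are shipped.

`default_criteria()` encodes the four match conditions the screening
protocol states, quantitatively where the data are quantitative and
directionally elsewhere: under the 4CL knockdown the H-lignin fold must
reach the reported accumulation (1.82 within ±20 %), G and total lignin
must decrease and S/G increase; under CCR1, total lignin must decrease
and S/G increase; under COMT, the metabolite signature must match
(ferulic acid +30 %, coniferaldehyde −20 %, each within ±20 %) and
total lignin decrease; under CAD, total lignin and S/G must decrease.

`table_criteria()` is the strict entry-by-entry reading: every printed
point within ±20 %, printed ranges by containment. It is provided for
sensitivity analyses but admits (almost) no parameter sets, for a
structural reason worth understanding: with constant influxes, the
steady-state total efflux equals the total influx, so total lignin
flux can fall only by diverting mass into the five non-lignin
effluxes. Knockdowns downstream of the efflux-carrying nodes (CCR1,
CAD) can drive that diversion only through chains of product-inhibition
links, each sub-proportional by the ratio bound $-1 < g_I/g_S < 0$, so
the printed 15–25 % total-lignin reductions in those columns are
unreachable at a true steady state for *any* kinetic-order set. In a
screen of 20,000 Configuration-1 sets under the strict reading, ten
sets reproduced the full quantitative 4CL column and none survived the
CCR1/CAD containment bands. The default reading keeps the
quantitative anchors that are realizable (the headline H accumulation
and the COMT signature) and the directional content of the rest.

The tolerance is a configuration knob; absolute acceptance counts are
not comparable to the (unreported) published counts — only the
contrasts between configurations and regulation variants are.

Scenario simulations integrate from the wild-type state with a
stiff-capable solver (`lsoda` with root-triggered termination when
$\max_i |dZ_i/dt| < 10^{-6}$ on the normalized scale, relative
tolerance $10^{-8}$, concentration floor $10^{-9}$), followed by a
damped log-space Newton polish with the analytic Jacobian whenever slow
final relaxation keeps the integrator from reaching the residual
threshold within the horizon; the polished root is accepted only if it
lies within a factor of 3 of the integrated state, so the solver cannot
jump to a foreign root. Converged states with any metabolite outside
$[1, 10^4]$ on the normalized scale (two orders of magnitude around
wild type) are classed out-of-bounds and the parameter set is
inadmissible for that scenario; divergence and non-convergence are
flagged separately and never silently returned.

## Sampling design

The sampling space is the unit hypercube over the free coordinates
(one substrate order per flux, one ratio per inhibition/competition
pair when sampled, plus $\phi$). A configurable fraction (default
10 %) is drawn by Latin hypercube sampling for even coverage, the rest
uniformly, mirroring the published 10,000 + 90,000 split. All
randomness descends from one master seed; each configuration × variant
cell derives a fixed sub-seed, so any cell can be reproduced in
isolation.

## PCA of the accepted ensemble

PCA is fitted to the centered kinetic-order vectors of accepted sets
(rate constants are excluded — they are deterministic functions of the
anchor and carry no sampling information). Axis signs are fixed by
making each axis's dominant loading positive. Resampling in the
reduced space draws scores uniformly within the accepted ensemble's
per-axis score ranges on the leading axes, holds the remaining axes at
the mean, back-transforms, and *rejects* (rather than clips) draws
violating the sign/ratio constraints, preserving the constraint
geometry. At small accepted-ensemble sizes the spectrum is dominated
by few directions, so cumulative variance figures at reduced scale are
only loosely comparable to large-ensemble values.

## Synthetic data and what passing tests mean

`generate_truth_instance()` + `generate_observations()` emulate the
experimental fold-change table from a known ground-truth model:
multiplicative lognormal noise (default σ = 0.05) on strictly positive
fold changes, with S/G directions derived from the noisy folds so
tables stay internally consistent. These tables drive the recovery
tests (a Configuration-1 truth is accepted under Configuration 1 and
rejected under Configurations 2/3). The generator reproduces the
*structure* of the experimental data, not its biology: real
measurements are thioacidolysis yields and metabolite pools with
correlated, non-lognormal errors, biological line-to-line variation,
and incomplete coverage. Passing recovery tests therefore demonstrates
that the pipeline's inference machinery works, not that the biological
conclusions are certain.

## Problem sizes and numerical choices

The package's own test and reproduction runs use reduced ensembles
(thousands of sets per configuration rather than 100,000), chosen as
the smallest sizes at which the qualitative contrasts (configuration
discrimination, regulation necessity) are stable across seeds.
Integration tolerances, the steady-state threshold, the state bounds,
the concentration floor, and the screening tolerance are all
configurable; the defaults above were fixed during design and are the
ones used everywhere in the package's tests and scripts.

## Known limitations

* The published parameter sample leaves one node (cinnamic acid)
  unbalanced, so it cannot serve as a balance oracle; it is used as a
  flux-law fixture, and `example_model(balanced = TRUE)` ships the
  minimal one-parameter repair.
* The transcription-factor (PvMYB4-style) validation uses a generic
  global-reduction activity vector (all catalytic enzymes × 0.4)
  because the per-enzyme activities are not published; results are
  compared by direction, not magnitude. With the shipped example model
  this perturbation lands the total-lignin fold change inside the
  experimentally reported 40–70 % decrease window (asserted by the
  test suite).
* Acceptance under the default criteria is a rare event (a few sets
  per 10,000) by the mass-balance argument above; small screening
  budgets can return empty accepted sets for the valid configuration
  as well.
* Topology discrimination is only partially reproducible.
  Configuration 3 (channel replacing the free route) is excluded
  structurally: its coniferaldehyde node carries no flux, so the COMT
  metabolite signature can never match. Configuration 2 (no channel),
  however, accepts parameter sets at a rate comparable to
  Configuration 1 under every realizable reading of the criteria we
  tested, and under the strict entry-by-entry reading *no*
  configuration accepts anything. The absolute channel/no-channel
  discrimination therefore could not be reproduced from the printed
  model class and data alone; the channel hypothesis remains supported
  only through the S/G-direction coupling argument (see "The channel
  coupling"), not through ensemble counts.
* Absolute acceptance counts depend on the unpublished matching
  tolerance and are not comparable across studies.
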