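---
title: "Constraint-based and kinetic ensemble analysis of monolignol biosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based and kinetic ensemble analysis of monolignol biosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignoflux)
```

## The biological problem

Lignin is assembled from three monomers — p-hydroxyphenyl (H), guaiacyl (G)
and syringyl (S) units — produced by the monolignol pathway from
phenylalanine. In alfalfa (*Medicago sativa*) stems, successive internodes
represent successive developmental stages: the H share of the monomer pool
falls from about 7% in the youngest (pooled) internodes 1–2 to about 1% in
internode 8, while the S/G ratio climbs from roughly 0.09 to 0.64.
Transgenic lines in which single pathway enzymes (PAL, C4H, HCT, C3H,
CCoAOMT, COMT) are down-regulated shift this composition in enzyme-specific
ways, some of which are hard to reconcile with the textbook pathway — most
prominently, CCoAOMT down-regulation depresses G lignin while leaving S
lignin largely intact, although both descend from the same precursor.

`lignoflux` implements the computational side of this analysis: per-internode
flux balance analysis (FBA) of wild-type stems, prediction of transgenic flux
redistributions by minimization of metabolic adjustment (MOMA), developmental
trend classification of branch-point flux partitioning, and a Monte Carlo
ensemble of reduced kinetic models that asks whether enzyme saturation
kinetics alone could reproduce the observed S/G shifts.

## The stoichiometric model

The pathway is encoded as 24 irreversible reactions over 16 internal
metabolites (`build_reference_network("extended")`). Reactions v1–v21 form
the core routes from phenylalanine to the three cell-wall transport steps
(v6 for H, v15 for G, v19 for S), including the parallel pair of routes from
caffeoyl-CoA to coniferyl aldehyde (CCoAOMT–CCR1 via feruloyl-CoA, v11/v13,
versus CCR2–COMT via caffeyl aldehyde, v10/v12) and the two F5H-controlled
committed steps towards S lignin (v16 at the aldehyde level, v20 at the
alcohol level). Three overflow fluxes complete the extended variant: v22
drains cinnamic acid (towards salicylate), v23 drains p-coumaroyl-CoA
(towards flavonoids), and v24 drains 5-hydroxyconiferyl alcohol,
representing 5H incorporation into the polymer. Shikimate and CoA are
treated as perfectly recycled cofactors, so both HCT steps appear as simple
conversions. The 21-reaction `"unextended"` variant omits the overflows.

One structural choice deserves mention: v23 is attached to p-coumaroyl-CoA
rather than p-coumaraldehyde. Chalcone synthase — the biological
justification for this efflux — consumes p-coumaroyl-CoA, and the
branch-point accounting of the transgenic trends places the efflux there;
the network table is plain data, so the alternative placement is a one-line
change.

## Wild-type FBA

For each internode the flux polytope is

* mass balance \(N v = 0\) over the internal metabolites,
* normalization \(v_1 = 1\) (all fluxes are expressed relative to the PAL
  step; maximal rates for the pathway enzymes are unavailable),
* bounds \(0 \le v_i \le 1\), except the overflows with lower bound 0.01 so
  they cannot vanish during optimization,
* proportionality constraints tying the transports to the measured monomer
  composition: \(v_6 = h\,(v_6+v_{15}+v_{19})\) and
  \(v_{15} = g\,(v_6+v_{15}+v_{19})\) (the S constraint is implied).

The objective maximizes total monomer production \(v_6+v_{15}+v_{19}\).
Since every unit of v1 ends in exactly one of the six sinks, the optimum
pins the overflows at their lower bounds and equals \(1 - 3 \times 0.01 =
0.97\) whenever the problem is feasible — a closed-form fact the test suite
uses as an independent oracle for the LP solver.

### Alternate optima and the unique reference

The optimum is a face, not a point: the caffeoyl-CoA split between the two
parallel routes and the aldehyde- versus alcohol-level F5H routing are both
left free by the objective. `enumerate_alternate_optima()` computes flux
ranges restricted to the optimal face, pins the constant coordinates and
enumerates all vertices of the remaining (typically two-dimensional) face;
the result is checked in the tests against exhaustive simplex-basis
enumeration. Two selection policies reduce the face to a unique reference:

* `"min-norm"` — the minimum-Euclidean-norm point of the face (unique by
  strict convexity). It splits the parallel routes evenly (v10 = v11).
* `"main-route"` — lexicographically minimizes v10, then v20, then the norm.
  This routes all wild-type G/S flux through CCoAOMT–CCR1 and the
  aldehyde-level F5H step.

`select_reference_distribution()` defaults to `"min-norm"` as the neutral
mathematical rule, but `run_pipeline()` defaults to `"main-route"`: the
CCR2–COMT shunt is dispensable in wild-type plants, and an even split would
assign half of the wild-type G/S flux to a route that only becomes relevant
under CCoAOMT knockdown. Both policies agree on the transports and on the
objective; downstream conclusions that depend on the v10/v11 split are
policy-sensitive and the configuration exposes that.

## MOMA for the transgenic lines

A knockdown of enzyme E to residual activity \(\alpha\) adds one cap
\(v_j \le \alpha v^*_j\) for every reaction j catalyzed by E (COMT and CAD
each cap three reactions). The mutant's measured composition enters as the
same proportionality constraints, with its own H/G/S values. The predicted
mutant state is the Euclidean projection of the wild-type reference \(v^*\)
onto this polytope — a strictly convex QP with a unique solution
(`solve_moma()`), cross-checked in the tests against Dykstra alternating
projections.

Two structural facts matter here:

* On the unextended network, fixing \(v_1 = 1\) makes four of the six lines
  infeasible; the canonical case is C4H at \(\alpha = 0.45\), where the
  cinnamic-acid balance forces \(v_2 = 1 > 0.45\). `check_feasibility()`
  returns this certificate from a least-violation QP. The overflow-extended
  network is feasible for every line because the overflows decouple total
  monomer output from the fixed v1.
* A PAL knockdown caps v1 itself, which would contradict the normalization
  \(v_1 = 1\). For PAL lines the package therefore replaces the
  normalization equality by the knockdown cap and leaves v1 free below it —
  the only reading under which all lines admit solutions, and consistent
  with the strong lignin reduction observed in PAL transgenics.
* F5H knockdowns are structurally infeasible on the extended network: the
  mandatory 5H efflux (v24 ≥ 0.01) forces v20 ≥ 0.01 while the cap demands
  v20 ≤ α·v20*. The F5H line is excluded from the study design (its
  activity could not be assayed in the underlying experiments either).

## Trend classification

Branch-point partitioning divides each diverging flux by the total flux
entering its branch point, so the shares at a branch sum to one. Ordered
over the seven internodes, each share series is classified into five
categories (`classify_trend()`): strictly monotone series are `MONO_UP` /
`MONO_DOWN`; series whose total range is below 5% of their mean level are
`UNCHANGED`; otherwise the sign of the Spearman rank correlation with the
maturity order decides (`UP_MINOR` / `DOWN_MINOR`) when its magnitude
reaches 0.6, and `UNCHANGED` otherwise. The published trend table gives
arrows without numeric thresholds; these defaults are documented package
choices, exposed in `trend_config()`, and the classifier is scale-free by
construction.

## The reduced kinetic model

The kinetic question is whether saturation kinetics alone could explain an
S/G increase under CCoAOMT or CCR1 knockdown. The reduced model keeps five
pools (caffeoyl-CoA fed by a constant influx J, feruloyl-CoA, caffeyl
aldehyde, coniferyl aldehyde, coniferyl alcohol) and eight reactions — the
two parallel routes plus the two branch points where G and S diverge, with
everything downstream of v16/v20 lumped into the S sink and v15 the G sink.
Each reaction carries Michaelis–Menten kinetics
\(v_{\max} c / (K_m + c)\), or Hill kinetics
\(v_{\max} c^n / (K_m^n + c^n)\); MM mode therefore has exactly 16 free
parameters. COMT's three activities are treated as independent reactions
(no shared capacity), the simplest reading of the reduced model.

Steady states are computed exactly by walking the feedforward cascade:
monotone one-dimensional balances for the three shared pools (solved with
`uniroot` at tolerance `.Machine$double.eps^0.75`) and closed-form rate-law
inversions for the linear steps. When total downstream capacity falls short
of the influx at any pool, the substrate grows without bound and no steady
state exists; this is reported as non-convergence with the saturated pool
named. `integrate_branch_model()` provides the dynamic route to the same
state via `deSolve::lsoda` and serves as the independent cross-check in the
tests (agreement to 1e-6 or better).

## The Monte Carlo ensemble

`run_ensemble()` draws all \(v_{\max}\) and \(K_m\) values independently
log-uniformly from [0.1, 10] (Hill exponents uniformly from [1, 4] in Hill
mode) and screens draws for admissibility: a converged, positive baseline
steady state whose S/G ratio lies in the wild-type window [0.09, 0.64]. The
influx is fixed at J = 0.5, chosen once so that roughly half of the
unconstrained draws possess a steady state. The published admissibility
rule and sampling ranges are not in the main text of the study this package
models, so all of these are explicit, configurable stand-ins.

An important structural result emerges: at any *re-converged* steady state,
the feedforward cascade conserves the influx, so the coniferyl-aldehyde
pool — and with it the S/G ratio — is invariant to knockdowns of the
upstream \(v_{\max}\) values (v11 or v13). Every admissible draw whose
perturbed model still has a steady state therefore shows a relative S/G
change of exactly zero, and draws whose perturbed model loses its steady
state are flagged and excluded. The ensembles consequently bound the
steady-state S/G response at zero — consistent with, and stronger than, the
reported sub-0.5% bound for CCR1 — while nonzero response *fractions* of a
few percent can only arise from finite-horizon readouts of systems that
have not re-converged, a regime this package deliberately does not report
as a steady-state response. The scientific conclusion is unchanged: purely
kinetic control of the S/G ratio is not a robust explanation.

## The synthetic study generator

No public accession exists for the per-line, per-internode observation
table, so `generate_synthetic_study()` emulates it: the wild-type
trajectory interpolates the anchor composition of internodes 1–2
(7/85.5/7.4, renormalized) linearly in H share and in S/G ratio to the
printed endpoints (1% H, S/G 0.64) at internode 8; each transgenic line
applies multiplicative shifts (S/G up for PAL and CCoAOMT, down for C4H and
COMT, H share up for HCT and C3H) and carries a residual activity fraction
(C4H 0.45 as reported; the others 0.2–0.4). Noise is a truncated Gaussian
(3 sd) on the logit of each monomer fraction, renormalized afterwards; the
default sd of 0.1 yields a replicate S/G standard deviation of about 0.03
at mid-stem wild-type compositions, matching the reported control-line
spread. Total lignin rises linearly from 50 to 140 mg/g cell wall in the
wild type with line-specific reduction factors.

What the generator does *not* emulate: per-internode variation in residual
enzyme activity (real activities were measured per internode; the synthetic
alpha is constant within a line), correlated measurement error across
internodes, and 5H monomers (thioacidolysis reports H/G/S; v24 absorbs 5H
in the model). Consequences follow for one published quantity: the pooled
v13–v14 Pearson correlation across non-CCoAOMT transgenic MOMA solutions is
about 0.975 on synthetic tables, below the ~0.995 computed from the real
data, because the synthetic pool lacks the per-internode activity variance
that dominates the real common-mode signal, while the S/G-driven v16 efflux
(v14 − v13 = v12 − v16) decorrelates the pair within each line. Tests of
pipeline behaviour on synthetic data are tests of the machinery, not
evidence about real stems.

## Numerical choices

No linear-programming package is part of this package's dependency
footprint; all LPs and QPs are solved by the dual active-set method of
`quadprog`. LPs use the exact regularization path: for \(\varepsilon\)
below a finite threshold the minimizer of
\(\varepsilon\|v\|^2/2 - c^\top v\) over a polytope is exactly the
least-norm point of the LP's optimal face, so the solver certifies
optimality by agreement between two \(\varepsilon\) values (a ladder of six
values guards against active-set degeneracies) and returns the least-norm
optimizer — which is precisely the `"min-norm"` selection rule.
Infeasibility is decided by a least-violation QP (minimal squared residual
of the balance equalities subject to bounds and caps, ridge 1e-7 on the
fluxes), whose residual names the violated balances; the feasibility
threshold is 1e-6 on the residual, and flux-distribution invariants are
checked at 1e-8. Vertex enumeration pins face-constant coordinates at
tolerance 1e-7 and deduplicates vertices at 8 decimals. Degenerate
composition entries of exactly zero are kept as hard equalities.

Problem sizes used by the test and acceptance suites: 100 random
compositions for the LP oracle, 50 random knockdowns for the MOMA oracle,
exhaustive basis enumeration over all 10,626 bases of the internode 1–2
face, and ensembles of 1,000–2,000 draws (the `sampling_config()` default
remains 10,000).

## Known limitations

* Reversibility of HCT and C3H — discussed verbally in the underlying study
  — is not modeled; all reactions are irreversible.
* The exact selection rule, kinetic rate laws and admissibility definition
  of the study's supplement were not published in the main text; this
  package's documented defaults stand in for them, and every one is
  configurable.
* The trend-category thresholds are package choices, not the original
  authors'.
* MOMA results inherit the reference-policy choice; analyses that depend on
  the wild-type v10/v11 split should be run under both policies.
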