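---
title: "Transient diel metabolic modeling from time-series transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient diel metabolic modeling from time-series transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Photosynthetic microbes grown under day/night cycles are never at steady
state: transcript abundances, enzyme capacities and the biomass composition
itself all cycle with the light. Classical flux balance analysis (FBA)
assumes a fixed biomass equation and time-invariant bounds, so it cannot
represent a cell that banks starch by day and burns it at night, or a
mutant that dies only because the night exists. `dielflux` implements a
transient constraint-based framework for this setting. The pipeline has
four stages, each usable on its own:

1. **Continuous transcriptome.** Each gene's diel FPKM series is fitted by
   eight candidate parametric curve families; families are ranked by the
   small-sample-corrected Akaike information criterion (AICc) and combined
   into Akaike-weighted ensembles queryable at any time of day.
2. **Transcript-driven bounds.** Gene-protein-reaction (GPR) Boolean rules
   convert normalized expression fractions into time-varying reaction
   bounds: AND (enzyme complex) takes the minimum subunit fraction, OR
   (isozymes) the sum, and the combined fraction — capped at 1 — scales a
   global flux ceiling calibrated against light availability.
3. **Decoupled biomass with PI control.** The biomass equation is split
   into ten independently producible component pools; dual
   proportional-integral controllers per component track diel composition
   setpoints and set production ratios and catabolic priorities.
4. **Diel simulation.** Fixed-timestep marching: rebound, control update,
   maintenance-ATP satisfaction (catabolizing stored components at night),
   an iterative ratio-constrained production LP, and forward-Euler mass
   update. Genome-wide single-knockout scans rerun this loop with one
   gene's curve zeroed.

## Curve families and model selection

The eight families, all on a fixed 24-h period with time taken modulo 24
(hours since light onset), are:

| family | form | free parameters |
|---|---|---|
| constant | $c$ | 1 |
| one-term cosine | $c + A\cos(2\pi(t-\varphi)/24)$ | 3 |
| two-term cosine | adds $A_2\cos(4\pi(t-\varphi_2)/24)$ | 5 |
| hat | baseline plus plateau on $[t_\text{on}, t_\text{off})$, wrap-around allowed | 4 |
| fixed decay | $c + A e^{-t/\tau_0}$, $\tau_0 = 4$ h | 2 |
| variable decay | as above with $\tau$ fitted in $(0.1, 24]$ | 3 |
| Kronecker delta | baseline plus a spike on one sampling interval | 3 |
| cosine multiplicative | $(c + A\cos(2\pi(t-\varphi)/24))\,e^{g t}$ | 4 |

These functional forms are this package's declared choices for the named
shape classes; alternates can be swapped by editing one table without
touching the pipeline. Fitting is least squares on raw FPKM. Families that
are linear in their parameters (possibly after profiling one nonlinear
parameter — the decay constant, or the envelope rate $g$) are solved in
closed form; the profiled parameter is additionally multi-started from
`n_restarts` random draws inside family-specific boxes derived from the
data range, with the lowest-AICc restart kept, so results are deterministic
under a fixed seed and more restarts can only improve the selected fit.

Model comparison uses
$\mathrm{AICc} = n\log(\mathrm{rss}/n) + 2k + 2k(k+1)/(n-k-1)$, with an
`Inf` sentinel when $n \le k+1$. The residual sum of squares is floored at
$10^{-30}$ so that exact interpolation on noise-free data leaves the
parameter penalty as the deciding term; consequently, on noise-free data
nested families tie on fit and the fewest-parameter family wins, which is
the behaviour the selection-consistency test pins down. Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_r e^{-\Delta_r/2}$ are invariant to shifting
all AICc values and always sum to 1. Exact AICc ties break to the fewest
parameters, then canonical family order, for determinism.

Two numerical caveats worth knowing: the Kronecker-delta spike width is the
sampling-grid interval (stored alongside the fitted parameters so curve
databases round-trip), and negative raw curve values are clamped to zero
only when curves are queried — fitting sees the raw model.

## Similarity and clustering

The *score* method turns each gene's ensemble into a fixed-layout vector
(per family, Akaike weight × fitted parameters, concatenated in canonical
order) and combines Euclidean distance $d$ and angle:
$S = \cos\theta \cdot \min(1 - \log d / \log d_m,\, 1)$, with $d_m$ the
dataset's maximum pairwise distance. Natural logarithms are fixed here by
convention; any common base changes nothing as long as both logs share
it. $d \le 1$ (including identical vectors) maps to
distance value 1; $d = d_m$ maps to 0. If a dataset's $d_m \le 1$ the
mapping loses monotonicity, so distances are rescaled by $e/d_m$ and the
result flagged. Raw (weight-scaled) parameter slots are used without
per-slot normalization; since slot scales differ, score distances are
dominated by large-magnitude parameters — a documented sensitivity of the
method.

The *integral* method — the one used for clustering — samples both
best-fit curves on a $dt = 0.1$ h grid, min–max normalizes each
independently (so any positive affine transform of a curve is a no-op),
and takes the mean absolute difference, a symmetric dissimilarity in
$[0,1]$. A flat curve has no shape and is mapped to the constant 0.5 with
a degeneracy flag. Clustering applies Ward linkage to the rows of the
square dissimilarity matrix treated as feature vectors — deliberately
matching the behaviour of the reference hierarchical-clustering
implementation when handed a square matrix rather than a condensed one —
and the heat map is assembled blockwise, one truncated-dendrogram leaf at
a time, with a stacked per-gene bar of the eight Akaike weights as a
sidebar.

## Transcript bounds and the flux ceiling

For gene $a$, $v_a(t) = a(t)/\max_{t'\in[0,24)} a(t')$ is the normalized
expression fraction (an all-zero curve yields fraction 0, flagged). Rule
fractions combine by min (AND) and sum (OR); sums are *not* capped inside
the tree — only the final bound applies $u_A(t) = u_\max \min(1, v_A(t))$,
with $-u_A(t)$ as the lower bound for reversible reactions and 0
otherwise. Genes present in GPRs but absent from the curve set contribute
fraction 1 with a warning: penalizing unmeasured genes would fabricate
constraints. Reactions with no GPR keep their model-default bounds. The
ceiling $u_\max$ is calibrated so that the transcript-capped light uptake
peaks exactly at the environment's light availability:
$u_\max = L / \max_t \min(1, v_\text{light}(t))$. Knockouts replace a
gene's curve by the zero function, so every referencing rule recomputes.

## Decoupled biomass and PI control

`split_biomass()` disables the biomass reaction and adds, per component,
a synthesis pseudo-reaction scaled so that unit flux forms exactly 1 g of
component per gDW per hour (coefficients are the biomass coefficients
divided by the component's mass fraction), and a degradation
pseudo-reaction that is its exact reverse. Summing the syntheses at the
original mass fractions reproduces the original biomass equation
identically — a construction invariant the tests assert. Degraded species
that no catabolic pathway can consume leave through per-metabolite dump
sinks; dumped mass is tracked as lost. Lipids are partitioned into a
lipid-droplet pool (TAGs with measured tails) and a bulk pool that
contains the nitrogen-bearing lipids, which is what couples lipid
composition to nitrogen limitation.

Each component carries a pair of PI controllers against its diel setpoint
trajectory (piecewise-linear, periodic interpolation of a composition
table; fractions must sum to ≤ 1 at tabulated times, and sums of 1 at the
table's breakpoints stay 1 under interpolation). With error
$e = \mathrm{sp} - x$: the integral accumulates $e\,dt$ clamped to
±10× setpoint (anti-windup), the production error is $K_p e + K_i I$, and
the consumption error is its negative. Gains default to $K_p = 1$,
$K_i = 0.1$ — values of this package's choosing, exposed as configuration,
since regulation is deliberately abstracted into a small parameter space.
Production weights are the normalized positive production errors over the
currently producible components. When no producible component has positive
error, components sitting essentially at their setpoints (|error| ≤ 1e-9)
share uniform weights so an on-target cell keeps growing, but components
clearly above setpoint get nothing — during early development the looser
rule (uniform whenever nothing is positive) made the simulated night cell
convert its starch reserve into surplus pools it could not later burn, and
starve before dawn. Consumption priority is descending positive
consumption error (canonical-order tie-break); when maintenance is still
unmet the remaining components are appended in descending order with
starch promoted among ties, flagged as an emergency.

## The simulation step

Per timestep (default $dt = 0.1$ h, ten steps per simulated hour; the
step is freely adjustable):

1. **Rebound** every GPR-mapped reaction from the curves at $t \bmod 24$;
   set the light exchange from the square-wave schedule and the
   maintenance-ATP (NGAM) demand as a fixed lower bound.
2. **Update controllers** from the current mass fractions.
3. **Maintenance.** If the medium alone cannot meet NGAM, open component
   degradation in priority order, one component at a time, until feasible;
   then solve for minimal total degradation and cap the components opened
   only for survival at exactly that level, so production cannot raid
   below-setpoint pools. If NGAM is unreachable with everything open, the
   cell dies: the trajectory is truncated with status `"died"` (death is a
   result, not an exception).
4. **Production.** Components are produced at the controller-set ratios:
   maximize a common scale $s$ subject to
   $\mathrm{net}_k \equiv \mathrm{syn}_k - \mathrm{deg}_k = b_k + w_k s$.
   Constraining *net* production is essential — each component's
   synthesis/degradation pair is a stoichiometric futile cycle, and an LP
   constrained on gross synthesis will happily satisfy any ratio by
   cycling. When expansion stalls, each unexpanded component is probed
   (can its net rise with the others pinned? tolerance $10^{-6}$
   relative); limiting components are frozen at their achieved flux and
   the rest re-expanded, iterating until nothing improves. A final solve
   pins all nets and minimizes degradation plus (at weight $10^{-3}$)
   dumping, removing futile catabolism from the reported solution.
5. **Advance.** Forward Euler:
   $\Delta m_k = (\mathrm{syn}_k - \mathrm{deg}_k)\, M\, dt$ (synthesis
   fluxes are g component/gDW/h by construction). The ledger identity
   $\Delta M = \text{produced} - \text{consumed} - \text{dumped}$ holds to
   machine precision each step, where *consumed* counts catabolized or
   recycled mass and *dumped* counts mass that left through dump sinks.
   Masses clamp at zero, erroring if the overshoot exceeds $10^{-6}$ g.

Production possibilities — which components can be made at which times
from the medium or from each single component as substrate (energy
exchanges closed) — are precomputed on an hourly grid and looked up per
step; a component trivially "re-produced" from its own degradation does
not count. The hourly grid (rather than one entry per 6-min step) keeps
the precomputation to a few hundred LPs; producibility patterns on the
fixture change on hour scales, not minutes.

A genotype that can never produce some component (the starchless knockout
and starch) starts with zero mass in that pool, and its setpoints are
renormalized over the achievable components. Without this, the mutant's
composition is permanently "above target" and it refuses to grow — while
the real starchless mutant grows happily on acetate.

## The LP core

No linear-programming package is available in this package's dependency
footprint, and the general-purpose tableau implementations we evaluated
fail on exactly the degenerate inputs FBA produces (zero right-hand
sides, reactions pinned to zero, redundant conservation rows). `dielflux`
therefore ships a dense bounded-variable two-phase revised simplex
(`lp_solve()`): Dantzig pricing with a Bland's-rule fallback after 500
iterations for anti-cycling, bound-flip ratio tests, explicit artificial
variables kept pinned at zero in phase 2 so redundant stoichiometric rows
are harmless, and a requirement of finite variable bounds (always true
for flux models). It is validated in the test suite against an
independent brute-force vertex enumerator on random degenerate LPs.
Optimal *vertices* are solver-dependent where the optimum is degenerate;
trajectories are deterministic because the pivoting rule is, but
individual flux values on alternative optima are reported as-is and
should be read with the usual constraint-based-modeling caution.

## The synthetic fixture and what passing tests mean

The toy photoautotroph (~27 reactions, 25 metabolites, 25 genes) is a test
harness, not a biological claim. It contains light capture into a plastid
ATP/NADPH pool, carbon fixation to a generic sugar unit (CH2O),
mitochondrial respiration behind an ATP translocator, acetate
assimilation, starch synthesis gated by a single designated gene, a
starch-to-sugar catabolic route (the only catabolic route — all other
components dump on degradation, which keeps the starchless-mutant
phenotype sharp), and synthesis routes to all ten component pools under
AND/OR GPRs. All internal reactions are elementally balanced by
construction: component units are integer combinations of CH2O and NH3,
and the cofactor formulas are chosen so ATP hydrolysis and NADPH redox
balance exactly. Default conditions: 12:12 light, NGAM
1.2 mmol ATP/gDW/h, CO2 10 and ammonium 5 mmol/gDW/h uptake ceilings, and
light availability 15.6 mmol photons/gDW/h — the value the package's own
bisection returns for one wild-type doubling per 24 h, which is the
fixture's stated design point. The setpoint table ramps starch from 0.15
at dawn to 0.30 at dusk and back, with protein and carbohydrate making
room, summing to exactly 1 at every breakpoint. Under these conditions
the night maintenance demand (~0.22 g starch-equivalent per gDW) sits
between the wild type's dusk reserve and anything the starchless mutant
can bank, so the mutant's minimal-medium death and acetate rescue are
decisive rather than marginal.

The synthetic transcriptome generator emulates 2-h diel sampling with
multiplicative lognormal noise (mean-1, specified coefficient of
variation) and clamping at zero. Its default shape mix is weighted the
way diel transcriptomes of photosynthetic microbes are reported to look —
roughly 60% cyclic shapes, 10% cyclic with an exponential envelope, 8%
light-onset spikes, 22% non-periodic — and planted parameters keep an
identifiability margin between nested siblings (the variable decay
constant is drawn away from the fixed-decay value of 4 h; the
multiplicative-cosine envelope rate is drawn in |g| ∈ [0.04, 0.1], enough
to change the envelope ≥ 2.5× per day). These margins are what make
"recover the planted family" a well-posed benchmark: with 13 points and
5% noise, AICc flips between *nested* families at an irreducible rate
when the planted parameters make the families nearly identical. What the
generator does not emulate: replicate structure, count-level
overdispersion, unequal sampling grids, missing data, or any coupling
between genes. Passing the recovery and clustering tests therefore shows
the estimator and the selection machinery work under the stated noise
model, not that real RNA-seq data will be this clean.

Problem sizes in the shipped tests are chosen for single-CPU desk runs:
100-gene recovery benchmarks, 60-gene clustering, 24-h simulations at
$dt = 0.1$ h, and a timestep-refinement check at $dt = 0.05$ h. The
knockout survey's full-week (168-h) mode is exposed as configuration; the
tests exercise the 24-h quick mode.

## Known limitations

- Biomass composition ratios are *not* hard constraints; as in the source
  framework, knockouts unable to make a costly minor component (the
  FAD-style case) can appear as overperformers. This behaviour is
  reproduced deliberately and should be filtered by inspection, not
  trusted blindly.
- Photorespiration and photoinhibition carry no enforced flux, so the
  model allocates none; high-light or low-CO2 regimes are outside the
  framework's validated envelope.
- Forward Euler is first-order; the shipped timestep keeps the
  halving-consistency error under 1% on the fixture, but stiff custom
  models may need smaller steps.
- The dense simplex is sized for reduced networks (up to a few thousand
  reactions); genome-scale matrices with tens of thousands of reactions
  would want a sparse factorized implementation.
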