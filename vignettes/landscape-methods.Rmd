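---
title: "Landscape and kinetic-path methods for regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape and kinetic-path methods for regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnland)
```

This vignette explains the models and numerical choices behind the
package: what is being computed, under which assumptions, and where the
approximations end. Nothing here reports a number that the test suite
or `scripts/acceptance.R` does not itself recompute.

## The rate law and its consequences

Every analysis starts from the additive Hill rate law

$$\frac{dx_i}{dt} \;=\; -k\,x_i \;+\; \sum_{j \in \mathrm{act}(i)} a_{ji}\,
\frac{x_j^{\,n}}{S^n + x_j^{\,n}} \;+\; \sum_{j \in \mathrm{rep}(i)} b_{ji}\,
\frac{S^n}{S^n + x_j^{\,n}},$$

with a single global activation strength $a$ and repression strength
$b$ unless a link carries its own value. There is **no basal
production**, and regulators combine **additively** — no AND-gates.
Defaults $k = 1$, $S = 0.5$, $n = 4$ are the canonical constants for
bistable fate circuits of this type.

Two structural consequences of this parameterization matter for
interpreting every result:

* **Repression acts by withholding production.** The repression term
  equals $b$ when the repressor is absent and $\to 0$ when it is high.
  A gene therefore *gains* production $b$ per incoming repression link
  whose source is silent. Strengthening a repression link deepens the
  **target's** high state (which lives where the repressor is low) —
  the direction our sensitivity tests assert, verified by direct
  barrier recomputation at $\pm 20\%$.
* **A high state needs a production source.** With $n = 4$ a gene at
  zero has zero activation input slope, so silent genes stay silent
  deterministically; fates are reignited only through released
  repression or noise.

### The two-gene motif is tristable at the textbook constants

For the classic two-gene mutual-antagonism motif (self-activation $a$,
cross-repression $b = 1$), multi-start root finding shows that at
$a = 1$ the symmetric co-expression state $(1, 1)$ is an **exact,
stable** fixed point (because the activation and repression Hill terms
sum to 1 there), alongside the two asymmetric fates — three attractors,
not two. Strict bistability holds for $a \lesssim 0.6$. All
experiments that require a clean two-fate switch therefore run the
motif at $a = 0.5$, where the two mirror attractors
$(1.4938, 0.0124)/(0.0124, 1.4938)$ split the sampling box almost
evenly.

## Attractors and basin weights

`find_attractors()` integrates the ODEs (compiled RK4, default
$dt = 0.1$, horizon $t = 200$ with up to three extensions for endpoints
still moving) from `n_starts` uniform draws in $[0, 3]^N$, polishes
endpoints by Newton iteration, deduplicates at max-norm tolerance 0.05
and keeps only linearly stable fixed points. The basin weight of an
attractor is the fraction of starts reaching it — the stationary
weights used by the mean-field mixture.

## The packaged 52-gene network

The stem-cell network ships as a reconstruction: the 22 marker genes
(11 pluripotency, ids 1–11; 11 differentiation, ids 12–22), the
OCT4/SOX2/NANOG/OCT4SOX2 core with its 14 key activation links, the
NANOG–GATA6 and OCT4–CDX2 antagonisms, the self-activations of NANOG,
GATA6 and CDX2 and the six key repressions of the published sensitivity
analysis are wired verbatim (`provenance == "text"` in the edge
table); the remaining links follow the described architecture — mutual
activation among ES markers, stem-activated satellites, a
GATA6/CDX2-driven differentiation cascade — and are generated to the
published totals of 123 links (84 activation, 39 repression)
(`provenance == "figure"`). It is a faithful *architecture*, not the
published adjacency, and conclusions should be read at that level.

**The balanced working point.** With uniform strengths the network is
bistable for $a \in [\sim0.32, \sim0.42]$ at $b = 0.5$; larger $a$
leaves only the stem fate — falling activation strength is the
direction of differentiation, which is also what the annealing
experiment exploits. `stemcell_params()` fixes the balanced default at
$a = 0.34$, $b = 0.5$, chosen once as the point in that band where the
differentiated basin is widest. Even there the differentiated basin
captures only $\sim 0.15\%$ of uniform random starts: the mandated
activation wiring of the pluripotency core ignites it from almost any
initial condition. Bistability checks therefore use thousands of
starts; the two fates themselves show the canonical marker patterns
(high NANOG/low GATA6 vs the reverse, binary codes
`1111111111100000000000` / `0000000000011111111111`).

## Gaussian mean-field landscape

`propagate_moments()` integrates, per basin,

$$\dot{\bar x} = F(\bar x), \qquad
\dot\sigma_i = 2 A_{ii}(\bar x)\,\sigma_i + 2D,$$

the diagonal moment closure under the mean-field factorization of the
probability (cross-covariances dropped; the full
$\sigma A^{T} + A \sigma + 2D$ form reduces to this under the diagonal
restriction). At a stable fixed point $\sigma_i = -D / A_{ii}$, which
for an unregulated gene is the exact Ornstein–Uhlenbeck variance
$D/k$ under the noise convention
$\langle \eta_i(t)\eta_j(t')\rangle = 2 D \delta_{ij}\delta(t-t')$ used
throughout. `mixture_probability()` then mixes the per-basin diagonal
Gaussians with the basin weights; because the covariance is diagonal,
marginalizing onto two displayed genes is exact (drop the other
factors). `potential_from_probability()` applies
$U = -\ln \max(P, \text{floor})$ with a floor of $10^{-12}$ of the grid
maximum.

The closure is an approximation with known failure modes: it ignores
the reflecting boundary at zero expression (benchmarks against
simulation therefore disable the clamp via
`sim_config(lower = -Inf)`); it is blind to within-basin
non-Gaussianity; and its mixture is **not** a steady state of the
Fokker–Planck equation, so the flux computed from it retains an
appreciable divergence. On the two-gene motif the mean-field and
Langevin-histogram landscapes agree globally (rank correlation
$\ge 0.7$ over well-sampled cells), which is the level of fidelity one
should expect.

## Langevin route, flux, barriers, MFPT

`simulate_network()` is Euler–Maruyama,
$x \leftarrow x + F\,dt + \sqrt{2 D\, dt}\,\xi$, clamped at zero
(expression levels are concentrations; the boundary treatment is our
own choice). `histogram_landscape()` bins long
trajectories on two gene axes or on RMSD coordinates
($\mathrm{RMSD}_r(x) = \sqrt{\tfrac1N \sum_i (x_i - r_i)^2}$ to the two
attractor states) and takes $U = -\ln P$.

`flux_2d()` evaluates $J = F P - D \nabla P$ by central differences.
At a detailed-balance steady state $J \equiv 0$; for the motif the
steady-state flux is divergence-free to discretization accuracy but
decidedly nonzero — the curl component that bends kinetic paths. The
test suite verifies this against a steady state computed by an
independent finite-volume Fokker–Planck marcher, since the mixture
approximation cannot supply one.

`barrier_heights()` defines the saddle between the two deepest grid
minima as the **minimax** cell over 8-connected paths (computed by a
threshold flood fill, exactly equal to the spanning-tree bottleneck),
and barriers as $U_{\text{saddle}} - U_{\text{min}}$. Because $U$ is
$-\ln P_{ss}$, barriers are dimensionless and *do* change with noise —
both barriers and both mean first passage times shrink as $D$ grows.

`estimate_mfpt()` launches independent restarts from the source
attractor and times the first entry into a max-norm ball (default
radius 10% of the attractor separation) around the target, reporting
mean and standard error. The estimator is validated against the exact
1-D double-quadrature MFPT on the quartic double well
(`make_double_well_oracle()`), agreeing within a few percent at the
tested $(h, D)$.

## Dominant paths and irreversibility

`path_action()` discretizes the zeroth-order Onsager–Machlup action
$S = \int \sum_i (\dot x_i - F_i)^2/(4D)\,dt$ with segment-midpoint
velocities and forces; the $\nabla \cdot F / 2$ correction is omitted
(recorded in the output metadata) — at small $D$ it does not change
the path ranking. `optimize_path()` minimizes over the interior points
(endpoints pinned at the attractors) with L-BFGS-B and an analytic
gradient, from a straight-line initialization plus seeded noisy
restarts; ties break to the lowest action, then lexicographically.
Defaults of 50 points over a duration of 12 (in units of $1/k$) were
chosen because longer durations let the midpoint discretization alias
a cheap overshoot past the target well, degrading the gradient-field
symmetry benchmark; at these settings forward and reverse paths of a
gradient double well coincide to a normalized Fréchet distance of
$\sim 10^{-4}$.

`irreversibility_index()` compares a forward path with the reversed
backward path by discrete Fréchet distance after resampling both
curves uniformly in arc length (vertex clustering would otherwise
masquerade as geometric difference), normalized by the endpoint
separation. For the motif the index is $\approx 0.12$ — the
differentiation and reprogramming routes genuinely differ, the
signature of curl flux. Note that the dominant path is *not* the
lowest-potential corridor for non-gradient systems: its ceiling on the
sampled landscape can slightly exceed the straight line's. That is
expected physics, not an optimizer failure; the corridor property is
asserted only for gradient benchmarks.

## Discretized dynamics and the state graph

`binarize()` thresholds each gene at (max − min)/2 + min over the
trajectory (ties code high; constant genes code low with a warning),
`project_markers()` keeps the 22 marker columns, and
`build_state_graph()` turns code occupancies into state probabilities
and consecutive differing code pairs into transition probabilities
(self-transitions excluded; joint fractions by default, per-source
conditionals optional). A probability cutoff (0.0002 in the published
analysis) prunes rare states. Exports: GraphML (lossless round trip),
SIF, TSV.

## Sensitivity and annealing

`sensitivity_scan()` perturbs one link at a time by a signed fraction
(default $\pm 20\%$; the global constant is the base for unset
strengths) or knocks down a gene (removing all its production terms),
then recomputes barriers (from a seeded Langevin histogram over the
marker axes) and MFPTs under the *same* seeds as the cached baseline.
A zero perturbation reproduces the baseline bit-for-bit. Barrier-based
and MFPT-based deltas agree in sign across the scanned links;
`rank_links()` orders by total absolute barrier impact. Whole-gene
knockdowns on the 52-gene network behave as marker logic dictates:
silencing GATA6+CDX2 leaves only the stem fate, silencing NANOG only
the differentiated fate.

`anneal_activation()` ramps the strength of selected activation links
(linear by default; exponential available) during a Langevin run and
detects fate jumps as the first time the projected marker code matches
the destination code for 10 consecutive recorded samples (debouncing).
The forward and reversed sweeps give the two critical activations
$a_{c1} < a_{c2}$ — hysteresis. A caveat discovered during
construction: for the *symmetric* motif no global-$a$ ramp can ever
flip the state, because each asymmetric fate is maintained by released
repression from its silent partner independently of $a$. The
hysteresis experiment therefore uses the motif as an asymmetric switch
(cross-repression onto the stem gene weakened to 0.3) and ramps the
stem gene's self-activation between 1.4 and 0.1 at rate
$5\times10^{-4}$ with $D = 0.01$: the downward jump occurs a little
above the deterministic fold (noise-assisted, $a_{c1} \approx 0.7$
against a fold near 0.5 located by numerical continuation) while the
upward jump needs much stronger noise assistance
($a_{c2} \approx 1.1$–1.3). At very low noise, slowing the ramp moves
$a_{c1}$ monotonically toward the fold.

## Problem sizes and reproducibility

Simulations in the tests and the acceptance script use trajectories of
$10^6$–$6\times10^6$ steps, 100–250 passages per MFPT estimate,
40–100-cell grids and up to 8000 attractor-search starts — sizes at
which every stochastic assertion is stable under its fixed seed while
a full run stays comfortably interactive. Every random number in the
package flows through R's RNG, so any seed reproduces any result
bit-for-bit.

## Known limitations

* The 52-gene edge list beyond the text-mandated links is a synthetic
  reconstruction; per-edge provenance is shipped, and analyses that
  depend on the exact published adjacency (e.g. identities of the
  top-20 sensitive links) are out of scope.
* The uniform-strength parameterization leaves the differentiated
  basin small under uniform random starts; basin *weights* on the
  packaged network should not be over-interpreted.
* Diagonal moment closure only; no covariances, no non-Gaussian
  closures, no discrete-molecule (Gillespie) noise, no cell division.
* MFPT and histogram landscapes need noise levels at which transitions
  actually occur on simulable timescales ($D \gtrsim 0.03$ for the
  motif at $a = 0.5$).
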