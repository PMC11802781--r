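---
title: "Energy-optimal mRNA localisation in dendrites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-optimal mRNA localisation in dendrites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrocost)
```

## The model

A neuron must keep every dendritic spine stocked with a prescribed number of
copies of each protein species, and it can do so in two ways: keep all
transcripts in the soma and export the protein, or traffic transcripts into
the dendrite and translate locally. `dendrocost` quantifies the ATP cost of
both strategies per molecular species and picks the cheaper one.

The dendrite is a one-dimensional segment of length $L$ with the soma at
$x = 0$ and a sealed tip at $x = L$. Three fields evolve on it: the dendritic
mRNA density $m(x,t)$, the shaft protein density $p(x,t)$ and the spine
protein density $p_\mathrm{spine}(x,t)$ (all per micrometre):

$$\partial_t m = \tilde D_m \, m'' - \lambda_m m,$$
$$\partial_t p = \tau m + D_p\, p'' -
  u_p\, p \left(1 - \frac{p_\mathrm{spine}}{\rho \eta_p}\right)
  + \nu_p\, p_\mathrm{spine} - \lambda_p\, p,$$
$$\partial_t p_\mathrm{spine} =
  u_p\, p \left(1 - \frac{p_\mathrm{spine}}{\rho \eta_p}\right)
  - \nu_p\, p_\mathrm{spine} - \lambda_p\, p_\mathrm{spine}.$$

Here $\lambda_{m,p} = \ln 2 / t_{1/2}$ are degradation rates, $\tau$ the
per-transcript translation rate, $u_p$ and $\nu_p$ the spine entry/exit
rates, $\eta_p$ the maximal protein copy number per spine and $\rho$ the
spine density (1 per $\mu$m throughout). Both ends are sealed
($m'(L) = p'(L) = 0$); a somatic transcript pool $m_\mathrm{soma}$ holds a
share $r_\mathrm{soma}$ of all transcripts and its translation output enters
the dendrite as a protein flux at $x = 0$. The overall amplitude is set by a
proteostatic demand constraint: every spine must hold at least a fraction
$\phi$ (default 0.95) of its capacity at equilibrium.

### Steady-state solution

At equilibrium the mRNA field is the closed-form diffusion–decay profile
$m(x) = A \cosh((L-x)/\ell_m)/\cosh(L/\ell_m)$ with
$\ell_m = \sqrt{\tilde D_m/\lambda_m}$ (an optional anterograde drift term
adds an advective correction with two exponentials). The spine equation is
eliminated exactly by its quasi-steady solution

$$p_\mathrm{spine}(p) = \frac{u_p\, p\, \rho\eta_p}
 {u_p\, p + (\nu_p + \lambda_p)\, \rho\eta_p},$$

which saturates below capacity; substituting it makes the shaft equation a
single nonlinear two-point boundary-value problem. `solve_steady()`
discretises it with second-order finite volumes (default $dx = 1\,\mu$m,
matching one spine per node) and solves shaft profile *and* source amplitude
simultaneously with a bordered Newton system, the extra equation being the
distal filling condition
$p(L) = \pi_p^{-1} \phi/(1-\phi)\, \rho\eta_p$ with spine permeability
$\pi_p = u_p/(\nu_p + \lambda_p)$. If the occupancy minimum falls away from
the tip (possible with drift), the constraint is moved to the minimising
node and the solve repeated, so the filling requirement binds at the true
minimum rather than being silently violated.

Numerical choices: Newton with backtracking line search (positivity
preserved), convergence at relative residual $10^{-8}$ against the dominant
reaction-term magnitude (the attainable floor for profiles spanning many
orders of magnitude), at most 80 iterations, and explicit errors — never
silent clipping — when the filling constraint is infeasible. The
finite-volume stencil makes the discrete synthesis–degradation balance exact
to rounding, which the test suite asserts at 0.1%.

Two properties follow analytically and are exploited internally. First, the
equations are homogeneous of degree one in $\rho\eta_p$: scaling the spine
capacity rescales every density and cost linearly and therefore can never
change the preferred localisation strategy. The solver works in
capacity-normalised variables, so factorial populations that differ only in
$\eta_p$ share one solve (a cache keyed on shape parameters makes the
2187-species grid cost a few hundred solves per dendrite length). Second,
the somatic boundary condition routes exactly $\tau\, m_\mathrm{soma}$ of
protein flux into the dendrite, which forces the somatic protein pool to
zero at equilibrium; we adopt this closure ($p_\mathrm{soma} = 0$) and note
it as a modelling choice where a finite somatic volume would retain a pool.

### Active transport and the effective diffusion constant

Motor-driven transcript movement follows a three-state run-and-pause model:
anterograde and retrograde populations run at speed $v$, stop with rate
$\beta$, and resting (diffusing, decaying) molecules re-enter each moving
state with rate $\alpha$. The transported fraction is
$\theta_m = 2\alpha/(2\alpha+\beta)$. Because the stationary system is
linear with constant coefficients, `solve_three_state()` evaluates it in
closed form from the quartic characteristic exponents, with moving molecules
reversing at both ends and a point source at the soma.
`effective_diffusion()` then summarises the mixed motion by the single
constant $\tilde D_m$ whose one-state profile best matches the three-state
total density — by least squares on unit-normalised profiles (default) or by
matching the mean molecule position (`strategy = "length"`); the fit
residual is attached for inspection. A stochastic particle simulation of the
same rules serves as an independent oracle in the tests.

### ATP accounting

Maintaining a steady state costs, per second and species,

* transcription: $2.17 \cdot N_{nt} \cdot \lambda_m (m_\mathrm{soma} + \int m)$ ATP
  (chain elongation plus post-transcriptional processing per nucleotide);
* translation and degradation, folded into one constant:
  $5 \cdot N_{aa} \cdot \tau (m_\mathrm{soma} + \int m)$ ATP — at steady state
  synthesis equals degradation, so a single per-residue constant covers both;
* transport: $125 \cdot \theta_m \cdot \int m / g$ ATP for granules of $g$
  transcripts, scaled linearly with run speed relative to the
  1 $\mu$m/s reference.

Infrastructure costs (ribosome or mitochondrion biogenesis, tRNA charging)
are deliberately excluded: they are not specific to a transcript's
localisation choice. The somatic scenario pays no transport.
`decide()` evaluates the somatic scenario against the dendritic scenario
minimised over a grid of somatic shares $r_\mathrm{soma} \in
\{0.1,\dots,0.9\}$ — the framework looks for minimal-energy solutions, so
the dendritic budget is itself an optimum, not a fixed split — and ties
break toward somatic, which needs no transport machinery.

## The synthetic species grid

Population statements are made over a full factorial of three values (low /
medium / high) in seven dimensions: mRNA half-life, non-coding/coding length
ratio, protein half-life, protein length, spine capacity, protein diffusion
constant, and transport intensity (the instantaneous transported fraction,
which sets $\tilde D_m$). The $3^7 = 2187$ combinations are built by
`grid_sample()` from `inst/extdata/grid_levels.yaml`.

The bundled levels are one-time choices from literature-typical ranges for
hippocampal pyramidal neurons — mRNA half-lives 2 h / 10 h / 30 h,
non-coding ratios 0.25 / 1 / 4, protein half-lives 2 d / 8 d / 32 d, protein
lengths 100 / 450 / 1500 aa, spine capacities 100 / 1000 / 10000 copies,
protein diffusion 0.01 / 0.1 / 1 $\mu$m$^2$/s, transported fractions
0.02 / 0.05 / 0.15 (live imaging consistently finds only a small share of
transcript granules in directed motion at any instant). Fixed across the
grid: $\tau = 0.01$ proteins per mRNA per second, $u_p = 10^{-3}$/s,
$\nu_p = 2\times 10^{-4}$/s (spine residence ~80 min), resting mRNA
diffusion $5\times10^{-3}\,\mu$m$^2$/s, runs of 2 s at 1 $\mu$m/s. These are
configuration, not code; headline fractions (the share of species preferring
dendritic mRNA) are sensitive to them, while the *directional* results below
are not, which is why the test suite asserts the directions unconditionally
and treats the fractions as reproduction targets of the bundled
configuration.

With the bundled configuration the qualitative population structure is
stable: the preference for dendritic mRNA strengthens with mRNA half-life,
non-coding length and protein length, weakens with protein half-life and
protein diffusion, and is exactly flat in spine capacity (a theorem in this
model, see homogeneity above); the dendritic-preferring group carries higher
mRNA and protein counts; and all directions persist across dendrite lengths
250–1000 $\mu$m and filling ratios 0.7–0.95.

## Synthetic screens

`synthetic_screen()` emulates compartment-resolved enrichment screens as
used for validation: two latent groups (soma- vs. neurite-destined) with
lognormal molecular properties whose medians differ by configurable effect
sizes (defaults follow the model's predicted directions), and lognormal
enrichment scores around group fold levels 0.35 and 3.2. What it does *not*
emulate: measurement error correlated across properties, detection dropout,
batch structure, or the heavy right tails of real abundance data — so
passing screen-pipeline tests demonstrates calibration and sign recovery,
not robustness to real-data artefacts. Group comparisons use a two-sided
Wilcoxon rank-sum test (exact permutation enumeration, tie-safe, up to
pooled $n = 12$; tie-corrected normal approximation beyond), 10,000-fold
group bootstrap for interval summaries, a 2-fold enrichment threshold with
an excluded middle band (1-fold variant available for small datasets), and
reciprocal detection-probability rescaling of counts (25% detection
multiplies counts by 4, 20% by 5; where a source states a different
convention we keep reciprocal scaling and flag the difference rather than
guess). No multiple-testing correction is applied: panels are reported as
individual pairwise comparisons.

## Photoactivation dynamics

`simulate_labeling()` rides a labelled protein subpopulation on a solved
steady state: from $t = 0$ the somatic pool is fully and continuously
photoactivated, implemented as a Dirichlet condition pinning the labelled
shaft concentration at $x = 0$ to its steady value (unlabelled protein
diffusing somatically joins the labelled pool there). With the spine entry
factor frozen at the equilibrium occupancy the labelled dynamics are linear;
the total pool is an exact fixed point, so labelled + unlabelled reproduces
the steady state to solver precision at all times. Time stepping is implicit
Euler (unconditionally stable) with one sparse LU factorisation, default
$dt = 10$ s.

Two timescales matter when comparing with pulse-chase experiments. The
*onset* of spine labelling at a position $x$ is set by buffered diffusion
($\sim x^2/2D_p$, retarded by spine uptake) plus the spine exchange time
$1/(\nu_p+\lambda_p)$; with the bundled Shank3 preset the spine 25 $\mu$m
from the soma crosses half of its labelling fixed point at about 4 h while
the spine at 105 $\mu$m remains far from it after 8 h. *Completion* (95% of
the fixed point) is much slower everywhere — order $10^2$ h proximally —
because the distal dendrite acts as an unlabelled reservoir that keeps
back-feeding the proximal shaft (for pure diffusion the unlabelled fraction
at $x$ decays only as $\mathrm{erf}(x/\sqrt{4 D_p t})$). Experimental
descriptions of a spine "starting to saturate" within an imaging session
therefore correspond to the onset knee, not to 95% completion;
`saturation_time()` defaults to level 0.95 of the analytic fixed point for
generic use, and the reproduction checks of the Shank3 paradigm use the 0.5
onset level, for the reason above.

The Shank3 preset itself (diffusion 0.1 $\mu$m$^2$/s, spine exit
$2.5\times10^{-4}$/s, ~9.8 d protein half-life, 300 copies per spine) is
provisional: half-lives and copy numbers are published values, the mobility
and exchange entries are literature-range choices documented in
`defaults.yaml` and exposed as configuration.

## Worked example

```{r camkii, eval = FALSE}
species <- camkii_preset()
geom <- dendrite_geometry(L = 500)
decide(species, geom)
```

With the bundled provisional mobility defaults the CaMKII-alpha example
sits close to cost parity between the two strategies (cost ratio ~1.0);
the published parameterisation reports a clear dendritic advantage, which
in this model requires slower protein spread or cheaper transport than our
bundled defaults assume — see the sensitivity note below.

## Known limitations

* Absolute population fractions (e.g. the share of grid species preferring
  dendritic mRNA) depend on the bundled parameter levels; with our one-time
  literature choices they come out lower (~23–29% across lengths) than the
  ~34–42% reported for the original parameterisation, whose exact level
  values were not available to us. The directional structure is insensitive
  to this.
* Linear, unbranched dendrite; no synaptic plasticity, no stochastic
  reaction noise, no time-varying demand.
* The somatic compartment is a boundary condition, not a volume: somatic
  protein pools are not modelled beyond the flux closure described above.
* Granule aggregation dynamics are reduced to a fixed transcripts-per-
  granule divisor in the transport cost.

## Problem sizes used in the checks

The bundled test suite solves the full 2187-species grid at four dendrite
lengths (a few hundred cached Newton solves per length at $dx = 1\,\mu$m),
runs the particle-simulation oracle with 5000 particles on a 20 $\mu$m
domain, 1000-seed calibration sweeps for the rank-sum pipeline, and a 16 h
labelled-transport simulation at $dt = 60$ s; the acceptance script repeats
the grid at all four lengths and a 300 h labelling horizon at
$dt = 120$ s.
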