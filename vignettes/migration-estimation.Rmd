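---
title: "Estimating migration in neutral metacommunities: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating migration in neutral metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutralmig)
```

## The problem

Under the unified neutral theory of biodiversity (Hubbell 2001), a local
community of `J` trees changes by zero-sum death/replacement events: each
recruit's parent is either a local individual (probability `1 - m`) or an
individual from a large regional pool, the metacommunity (probability `m`).
The migration parameter `m` controls how strongly local communities are
coupled to the regional pool, and hence how much compositional
differentiation (beta diversity) ecological drift can build up among plots.

Several estimator families infer `m` from plot-by-species count matrices:

* the **Gst statistic** adapted from population genetics (Munoz, Couteron
  & Ramesh 2007), based on within-plot vs pooled probabilities of
  conspecific identity;
* a per-plot **compound-multinomial ("Inference") likelihood** conditioned
  on a regional relative-abundance estimate (Jabot, Etienne & Chave 2008);
* **Etienne's sampling formula**, fit jointly over `(theta, I)` in one
  stage (Etienne 2005) or with `theta` first fixed from the pooled sample
  by the Ewens relation (two-stage; Munoz et al. 2007, Etienne 2009);
* a **plot-geometry method** that ignores composition entirely and derives
  `m` from the plot's edge length and the species' absolute dispersal
  distances (Chisholm & Lichstein 2009).

All composition-based methods assume a spatially implicit world: every plot
exchanges migrants with the pool only. Real landscapes are spatially
structured — most seed dispersal is short-range, so most immigration into a
1-ha plot comes from its immediate surroundings, not from a regional pool.
This package provides both a spatially implicit simulator and a spatially
*semi-explicit* lattice simulator in which recruitment is split between a
Moore-adjacent plot (`m_adj`), the metacommunity (`m_meta`) and local
recruitment, so that the behaviour of the estimators can be studied when
their generating assumptions are violated. The headline phenomena the
experiment pipeline reproduces are: the estimators recover `m` well on the
implicit model; on the lattice they can only estimate the *joint* migration
`m_adj + m_meta`, accurately when metacommunity migration dominates and as
an underestimate when adjacent-plot migration dominates; and implicit
simulations run at field-estimated `m` under-produce species and singletons
relative to real inventories.

## The regional pool: Fisher's logseries

Amazonian tree inventories are very close to Fisher's logseries, so the
metacommunity is a fixed, ranked abundance vector derived from it. The
expected number of species with abundance `n` is `phi_n = alpha x^n / n`
with `x = N/(N + alpha)`; summing over `n` gives the familiar
`S = alpha log(1 + N/alpha)`, which `fishers_alpha()` inverts for `alpha`.

`logseries_metacommunity()` builds the pool deterministically from the most
dominant species downwards. The abundance at rank `r` is the largest
integer `a` such that the expected number of species with abundance at
least `a`,

\[ T(a) = \sum_{k \ge a} \alpha x^k / k, \]

still satisfies `T(a) >= r - 0.5`. The midpoint rule is symmetric and
deterministic; the construction itself only prescribes "most dominant
first", so the rounding convention is a design choice of this package. Any
residual difference between the distributed individuals and `N` is absorbed
starting at rank 1 (never violating monotonicity), so totals are exact.

**Numerics.** For realistic pools `x` is extremely close to 1 (for a pool
of 2 x 10^10 trees, `1 - x` is about 1.2 x 10^-8) and `T(a)` has on the
order of 10^9 significant terms, so direct summation is impossible. The
package sums the first 500 terms exactly and closes the tail with an
exponential-integral expression plus Euler–Maclaurin corrections,

\[ \sum_{k \ge b} e^{-\epsilon k}/k \approx E_1(b\epsilon) +
   \frac{x^b}{2b} + \frac{x^b}{12}\left(\frac{\epsilon}{b} +
   \frac{1}{b^2}\right), \qquad \epsilon = -\log x, \]

which at `b = a + 500` is accurate far beyond the half-species resolution
the rank inversion needs. The tests verify it against brute-force summation
in regimes where that is feasible.

Three pool shapes recur in the experiments: a low-diversity pool
(2.0192 x 10^10 individuals, 4,582 species; Guiana-Shield-like), a
high-diversity pool (5.611 x 10^9, 6,834; Ecuador-like), and a smaller pool
for the lattice work (5.5 x 10^6 individuals, Fisher's alpha 272, giving
2,697 species).

## Simulators

`run_implicit()` initializes every plot as a multinomial metacommunity
sample of size `J` and then applies kill-and-replace events: the dead
individual's replacement descends from the metacommunity with probability
`m`, otherwise from a parent drawn uniformly from the `J - 1` survivors
(the standard zero-sum Moran convention; at `J = 500` the distinction from
including the dead individual is negligible, but it must be fixed for the
exact two-individual test chain). Plots evolve independently.

`run_lattice()` places plots on a `rows x cols` lattice (default 20 x 20,
`J = 500`). Events are scheduled in sweeps — one death per plot per sweep —
and the recruitment source is drawn from the PMF
`{local: 1 - m_adj - m_meta, adjacent: m_adj, metacommunity: m_meta}`.
An adjacent recruitment first picks one of the Moore neighbors uniformly,
then a parent in proportion to that plot's abundances. The lattice edge is
a torus by default, which keeps every plot statistically identical and
matches pooled reporting; a truncated edge mode is available for
sensitivity checks. No within-plot space is modelled, and no local
speciation occurs: species identities always refer back to the pool.

**Run length.** One generation is `J` events per plot; the default is 200
generations. Published descriptions of comparable simulation studies are
ambiguous about run length (per-sweep counts and total-event counts an
order of magnitude apart can be found for the same design), so the package
treats it as an explicit parameter and provides `stationarity_trace()` to
verify plateaus. At the scales used here, pooled richness, pooled
singletons, within-plot identity and the Gst/likelihood estimates all
plateau well before 200 generations (the identity plateau also matches the
moment relation `E[F] = (I F_meta + 1)/(I + 1)` used by the Gst inversion).
Per-plot richness relaxes on a slower time scale than pooled richness,
which matters for interpretation: see "Reporting Fisher's alpha" below.

Both engines are implemented in C++ (Rcpp) — runs of 10^7–10^8 events are
routine — and draw all randomness from R's RNG, so `set.seed()` makes every
simulation bit-reproducible.

## Estimators

**Gst.** `simpson_identity()` is the unbiased within-sample identity
`F = sum n_i(n_i - 1) / (J(J - 1))`. With `F_T` the same quantity on the
pooled counts, the equilibrium compound-multinomial moment relation
`E[F_k] = (I F_T + 1)/(I + 1)` inverts to `I_k = (1 - F_k)/(F_k - F_T)` and
`m_k = I_k/(I_k + J_k - 1)`. Plots with `F_k <= F_T` carry no detectable
differentiation; they are flagged and capped at `m = 1`, while the raw
transform is kept as a diagnostic (`m_raw`). Raw per-plot values slightly
above 1 are expected for undifferentiated data and their mean is the
quantity comparable with published tables, which themselves print values
like 1.011. Unbiased (rather than plug-in) identities matter because plot
sizes are only 500–625 individuals.

**Inference (compound multinomial).** `dm_loglik()` is the
Dirichlet-multinomial likelihood with concentration `I * p`, the stationary
distribution of a local Moran community receiving immigrants from a fixed
pool `p`. `inference_migration()` estimates `p` from the pooled sample
(optionally leave-one-plot-out) and maximizes over `log I` per plot. With
few plots, including the focal plot in `p` inflates `I` slightly; with the
20+ plots used in the experiments the effect is well inside the acceptance
tolerances.

**Etienne sampling formula.** `etienne_loglik()` implements the full
sampling formula for one local community,

\[ P[D \mid \theta, I] = \frac{J!}{\prod_i n_i \prod_j \Phi_j!}
   \frac{\theta^S}{(I)_J} \sum_{A=S}^{J} K(D, A) \frac{I^A}{(\theta)_A}, \]

where the ancestry coefficients `K(D, A)` combine, per species, unsigned
Stirling numbers of the first kind, `c_n(a) = s(n, a) (a-1)!/(n-1)!`, and
are convolved across species. All coefficient arithmetic is done in log
space with log-sum-exp accumulation; the coefficients overflow double
precision near `J` in the low hundreds, but their logarithms are stable up
to `J` in the thousands, which covers every scale used here. The
coefficients are computed once per abundance vector and reused across
likelihood evaluations during optimization. Exhaustive enumeration over all
partitions at small `J` confirms normalization to machine precision, and at
`I -> Inf` the formula reproduces the Ewens sampling formula.

`etienne_onestage()` fits `(log theta, log I)` jointly by Nelder–Mead. The
known pathology near `m -> 1` — as `I -> Inf` the formula degenerates until
all `J` individuals are immigrant ancestors and the likelihood ridge
flattens — is detected and flagged rather than hidden. One-stage estimates
on simulated data show exactly the overestimation/instability at high `m`
that motivates the two-stage variant.

`twostage_migration()` first solves `S = theta (psi(theta + N) -
psi(theta))` on the pooled sample (`ewens_theta()`), then fits only `log I`
per plot. Fixing `theta` removes the ridge but imports a bias: the pooled
sample of drift-affected plots is poorer in species than a true
metacommunity sample, so pooled `theta_hat` is biased low and `m_hat`
correspondingly high. The effect is visible at `J = 625` (about +0.05 at
`m = 0.2`) and shrinks at smaller `J`; the recovery tests therefore hold
the two-stage method to a wider tolerance than Gst/Inference. A scalar
optimizer with explicit ridge handling (`scalar_mle`) reports boundary
solutions as such: when the likelihood toward an interval endpoint ties the
interior optimum, the endpoint wins and the plot is flagged.

**Plot geometry.** `plot_geometry_migration()` computes the probability
that the parent of a uniformly placed recruit inside a `w x w` plot lies
outside the plot, for an isotropic dispersal kernel with mean displacement
distance `d`, by nested numeric integration in polar coordinates. The
default kernel is the two-dimensional Gaussian displacement (radial
distance Rayleigh with `sigma = d sqrt(2/pi)`); an exponential-distance
kernel is available, and the linearized perimeter form `4wd/(pi w^2)` is
exposed both as a kernel option and as the small-`d/w` limit the exact
integral must approach (the tests require agreement within 2% at
`d/w = 0.02`). Published applications of this method include a "corrected"
variant whose derivation rescales the estimate by roughly 0.30; since only
the uncorrected computation is fully specified, the correction is exposed
as a multiplicative constant `correction` (default 1) rather than
hard-coded. A `d` range yields the estimate at the midpoint and an interval
at the endpoints; `d >= w` is flagged as outside the approximation regime.

**Singleton diagnostic.** `singleton_ratio()` compares the pooled observed
singleton count with the logseries expectation `alpha_hat N/(N +
alpha_hat)` at the pooled `(N, S)`. Well-mixed systems sit near 1;
dispersal-limited systems accumulate locally common but regionally
unshared species and fall below 1.

## Experiments and the synthetic field data

`recovery_experiment()` simulates the implicit model over a migration grid
and reports `delta_m`, the mean absolute difference between given and
estimated migration per estimator (the acceptance suite runs 20 plots of
`J = 625` over `m` in {.05, .1, .2, .4, .8} with 3 replicates and requires
`delta_m <= .03` for Gst and Inference, and `<= .05` for the two-stage
method at `J = 100`).

`additivity_experiment()` runs one lattice simulation per `(m_adj, m_meta)`
scenario. The estimators see only the joint migration: at
`(m_adj, m_meta) = (.01, .20)` both Gst and Inference return about 0.21;
at the mirrored `(.20, .01)` both return about 0.14–0.16, a strict
underestimate of the same joint 0.21 — on small lattices the Moore
neighborhood is a sizable fraction of the whole system and the
underestimate weakens, so the experiment defaults to 20 x 20.

`field_emulation()` doubles as the synthetic-data generator: it produces
plot-by-species matrices with the shape of large Amazonian inventory
networks (e.g. 67 plots x 625 trees from the low-diversity pool). It
emulates the statistical structure those analyses assume — equal plot
sizes, a single shared pool, neutral dynamics at a given `m` — and *not*
features of real inventories such as unequal stem counts per hectare,
habitat heterogeneity, non-neutral dynamics or spatial distance decay.
Passing tests therefore validate the estimation machinery on its own
assumptions; they say nothing about whether real forests satisfy them.

**Reporting Fisher's alpha.** For a simulated dataset the pipeline emits
both the pooled alpha (solved from pooled `(N, S)`) and the mean of
per-plot alphas. These differ strongly away from `m = 1`: at `m = .046`,
`J = 625` the stationary per-plot richness is about 80 species (immigration
number `I` near 30), giving per-plot alphas near 24, while the pooled alpha
sits near 143. Published field summaries described as "alpha averaged over
plots" are numerically consistent with the *pooled* computation for these
data shapes, so comparisons against such summaries use the pooled value.

## Degenerate inputs and edge behaviour

* `fishers_alpha()` requires `N >= S >= 2`; plots with `S = 1` or `S = J`
  have no finite alpha and are excluded (flagged `NA`) from per-plot means.
* `ewens_theta()` returns `Inf` with a warning at `S = N` and 0 at `S = 1`.
* Monocultures yield `m_hat = 0` (boundary-flagged) in the one-stage fit.
* `m_adj + m_meta > 1` and out-of-range lattice coordinates are errors.
* Moore neighborhoods never include the focal plot, even on lattices
  narrower than 3 cells where the torus wrap would fold onto it.
* All `m_hat` are clamped to `[0, 1]` with the raw transform preserved in
  diagnostics rather than erroring.

## Limitations

* The metacommunity is static: no speciation, no pool dynamics.
* The lattice is semi-explicit only — no within-plot positions and no
  continuous dispersal kernels between plots; recruitment sources follow
  the three-way PMF.
* The two-stage estimator inherits the pooled-Ewens `theta` bias described
  above; no finite-`theta` correction to the Gst moment inversion is
  attempted.
* Smoothed given-vs-estimated curves are deliberately replaced by plain
  binned tables; plotting is left to the user.

## References

Chisholm, R.A. & Lichstein, J.W. (2009) Linking dispersal, immigration and
scale in the neutral theory of biodiversity. *Ecology Letters* 12, 1385–93.

Etienne, R.S. (2005) A new sampling formula for neutral biodiversity.
*Ecology Letters* 8, 253–260.

Etienne, R.S. (2009) Improved estimation of neutral model parameters for
multiple samples with different degrees of dispersal limitation. *Ecology*
90, 847–852.

Fisher, R.A., Corbet, A.S. & Williams, C.B. (1943) The relation between the
number of species and the number of individuals in a random sample of an
animal population. *Journal of Animal Ecology* 12, 42–58.

Hubbell, S.P. (2001) *The Unified Neutral Theory of Biodiversity and
Biogeography.* Princeton University Press.

Jabot, F., Etienne, R.S. & Chave, J. (2008) Reconciling neutral community
models and environmental filtering: theory and an empirical test. *Oikos*
117, 1308–1320.

Munoz, F., Couteron, P. & Ramesh, B.R. (2007) Beta diversity in spatially
implicit neutral models: a new way to assess species migration. *The
American Naturalist* 172, 116–127.
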