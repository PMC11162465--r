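---
title: "Divide-and-conquer CME solving, filtering and identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer CME solving, filtering and identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rbcme)
```

# The model class

`rbcme` works with stochastic reaction networks: `n` chemical species
$S_1,\dots,S_n$ undergoing `r` reactions
$\nu_{1,j}S_1+\cdots+\nu_{n,j}S_n \to \nu'_{1,j}S_1+\cdots+\nu'_{n,j}S_n$,
modeled as a continuous-time Markov chain on copy-number vectors
$X(t)\in\mathbb{Z}_{\ge0}^n$.  Reaction $j$ fires at the state-dependent
propensity $\lambda_j(x)$ and displaces the state by
$\zeta_j = \nu'_{\cdot j}-\nu_{\cdot j}$.  The probability law $p(t,x)$
solves the chemical master equation (CME)

$$\frac{d\,p(t,x)}{dt} \;=\; \sum_{j=1}^r \lambda_j(x-\zeta_j)\,p(t,x-\zeta_j)
\;-\; \sum_{j=1}^r \lambda_j(x)\,p(t,x),$$

a linear ODE system with (in general) infinitely many states.  The package
supports stochastic mass-action kinetics (with falling-factorial counting),
Hill activation/repression, and state-switched linear combinations such as a
transcription propensity $k_{p1}G_1 + (k_{p1}+k_{p2})G_2$.  Propensities are
pure functions of the state and the parameters; time-varying inputs are out
of scope.  Unknown rate parameters live on finite, strictly increasing value
grids with prior probability vectors, which keeps Bayesian identification a
finite linear-algebra problem.

Two classical solvers anchor everything else:

* **Stochastic simulation** (`ssa_simulate`, direct method, compiled):
  statistically exact trajectories; the empirical distribution of `N` runs
  (`mc_cme_solve`, `empirical_distribution`) is the plain Monte Carlo CME
  estimate.  Its expected L1 error decays as $c/\sqrt N$ with
  $c \in \sqrt{2/\pi}\,[\Sigma-1, \Sigma+1]$, $\Sigma=\sum_x\sqrt{p(t,x)}$
  (`mc_l1_prefactor`).  $\Sigma$ grows exponentially with the dimension —
  the Monte Carlo face of the curse of dimensionality.
* **Finite state projection** (`fsp_solve`): direct integration of the CME
  restricted to a truncation, with transitions leaving the truncation routed
  to an absorbing sink whose accumulated mass bounds the L1 truncation error.
  Exact but exponentially expensive in the dimension.

# The Rao-Blackwellized solver

The package's core splits the species into a **leader** system $\tilde X$ and
follower subsystems $Z_1,\dots,Z_l$ such that, *given the whole leader
trajectory*, the follower subsystems are conditionally independent.  The
sufficient topological conditions checked by `check_conditions` are:

* **C1** — every reaction involves at most one follower subsystem (through
  its stoichiometry or its propensity);
* **C2** — reactions sharing the same non-zero leader net change jointly
  involve at most one follower subsystem;
* **C3** — each observation channel depends on at most one follower
  subsystem (filtering problems);
* **C4** — all parameter pseudo-species are follower-side (identification).

Each follower subsystem's conditional law $\pi_{Z_i\mid\tilde X}(t, z_i)$
solves a *filtered CME*: a jump-ODE system that the package integrates on the
subsystem truncation ("filtered FSP").  Between leader jumps the filter
evolves by

* a *prediction* term: the sub-CME over the reactions internal to the
  subsystem, at the frozen leader state; and
* a *correction* for the information carried by the absence of leader jumps:
  an exponential reweighting $\exp(-\int \Lambda_i(z_i)\,ds)$ with
  $\Lambda_i(z_i) = \sum_{j:\ \zeta_j^{\tilde X}\neq 0,\ \lambda_j \text{
  depends on } z_i} \lambda_j(\tilde x, z_i)$, folded into the generator
  diagonal (the evolution stays linear, so no operator splitting is needed).

At an observed leader jump with net change $\Delta$, Bayes' rule gives

$$\pi'(z) \;\propto\; \sum_{j:\ \zeta_j^{\tilde X}=\Delta}
\lambda_j\!\big(\tilde x(t^-),\, z-\zeta_j^{Z_i}\big)\,
\pi\big(t^-, z-\zeta_j^{Z_i}\big),$$

i.e. a reweighting by the firing propensity plus a support shift when the
jump reaction also moves the follower.  Condition C2 guarantees at most one
subsystem is updated per jump; for all others the update is proportional to
the identity and drops out after normalization.  The detailed form of these
correction terms is not uniquely pinned down by a high-level description, so
the package treats their validation as part of the test contract: the
implementation is required to agree with two independent oracles — a
conditioning filter run on the *joint* (unfactorized) state space, and
rejection sampling of $10^6$ exact simulations sharing the leader's no-jump
event.  Both agree to well below the stated tolerances (about $10^{-11}$ in
L1 for the joint-space oracle on a miniature toggle switch).

The **RB-CME solver** (`rb_cme_solve`) then estimates

$$\hat p_{\mathrm{RB}}(t, \tilde x, z_1,\dots,z_l) = \frac1N \sum_{j=1}^N
\mathbf 1\{\tilde x_j(t)=\tilde x\}\prod_{i=1}^l q_j^i(t,z_i),$$

where the $\tilde x_j$ are leader paths of `N` full-system simulations
(followers discarded) and $q_j^i$ the filtered-FSP conditionals along path
$j$.  With every species a leader this is plain Monte Carlo; with everything
a follower it reproduces the FSP solution exactly (verified to $10^{-12}$).
In between, sampling is confined to the low-dimensional leader while the
followers are integrated exactly — a Rao-Blackwellization, so at equal `N`
the estimator is never less accurate than plain Monte Carlo.

An alternative, follower-free route to sampling leader paths — thinning
against the conditional leader-jump intensity implied by the filters — is
exact too; the package keeps it as a cross-validation oracle in the test
suite and uses the simulate-and-discard route in `rb_cme_solve`, which is
the simpler and cheaper of the two.

# Automated decomposition

`optimal_decomposition` searches leader subsets exhaustively (up to 22
components; a greedy fallback warns beyond that).  For a fixed leader set
the follower partition is forced to the *finest* partition satisfying C1-C3,
computed by a union-find closure (`induced_follower_partition`); since the
product of subsystem sizes over any exact partition equals the product of
the follower component sizes, coarser partitions cannot increase the
follower size, and the finest one minimizes the largest subsystem.  A leader
set is feasible when every induced subsystem has at most
`max_subsystem_size` states; among feasible sets the search maximizes the
whole-follower size $\prod_i \mathtt{SS}_i$ (equivalently, minimizes the
leader state-space size).

Ties are real: on the six-species chain several leader sets achieve the same
follower size.  They are broken deterministically by (1) fewest leader
species, then (2) preferring the lexicographically *greatest* sorted leader
index set, i.e. the most downstream species become leaders.  Downstream
species act as conduits that receive flux from the upstream blocks, so this
convention keeps each follower block a contiguous upstream unit; on linear
chains of any length it selects every third species ($S_3, S_6, \dots$), and
on the repressilator, toggle switch and transcription fixtures the optimum
is unique anyway.  (A plain lexicographically-smallest rule would pick
$\{S_1, S_4\}$ on the six-species chain — equally sized but a different
convention than the one this package standardizes on.)

# Filtering and identification

Observations follow $Y(t_i) = h(X(t_i)) + \Sigma W_i$ with independent
standard Gaussian noise and diagonal $\Sigma$; channels may read a species
directly, through a background-censoring threshold ($x\,\mathbf 1\{x>c\}$, as
on microscopy platforms that cannot resolve low counts), or as a linear
combination.  A channel with zero noise becomes an exact-match indicator.

Three filters share the recursive prediction/correction structure:

* `exact_fsp_filter` — FSP prediction plus pointwise Bayes correction; the
  reference on tractable truncations (about $10^5$ states).
* `bootstrap_pf` — SSA proposals, Gaussian weighting, systematic resampling
  when the effective sample size drops below `N/2`.
* `rb_particle_filter` — the RB-CME solver in the prediction step.  Each
  particle carries a leader path and one conditional filter per follower
  subsystem.  Between observations the leader path is advanced by drawing
  one follower/parameter configuration from the particle's current
  conditionals, simulating the whole system, keeping the leader path and
  discarding the sampled configuration — an exact draw from the leader
  path's conditional law by the law of total probability.  At an
  observation, each channel's likelihood is marginalized over the touched
  subsystem's filter for the weight update, and that filter is reweighted by
  the state likelihood (exact under C3).  Resampling is systematic at
  `ESS < N/2`.  If every weight underflows, the step is retried once with a
  tempered likelihood (power 1/2) and a warning — a pragmatic guard, not a
  statistical claim.

**Identification** treats the gridded parameters as additional species that
never change (`augment_with_parameters`): the admissible states of a
pseudo-species are its grid indices, its value enters propensities wherever
the parameter was referenced, and its prior becomes its initial law.
`rb_identify` augments, decomposes under C1-C4, filters, and marginalizes
the final-time posterior onto the parameter coordinates.  C4 matters:
parameters inside follower filters are updated by exact conditional
arithmetic, so no artificial parameter jitter is ever needed and the sample
degeneracy that plagues particle-based estimation of static states never
arises.  The MAP estimate is the argmax of the joint final-time parameter
posterior (a weighted mixture of products across parameter blocks),
maximized exactly when the full grid has at most $10^6$ cells and otherwise
over the Cartesian product of the top 8 values of each block marginal
(posteriors concentrate, so the restriction is effectively exact); ties
break toward lower grid indices, and the per-marginal argmax is reported
alongside.

Identified models are validated without ground truth by comparing the FSP
stationary law of the MAP model against the *occupation-time distribution*
of the rounded measurements (ergodicity makes the latter a consistent
estimate of the cell's stationary law), after binning states in groups of
ten; the discrepancy is summarized by KL(data ‖ model) with model bins
floored at $10^{-12}$.  The KL direction is configurable; data-given-model
is the default because the question asked is whether the *inferred model*
explains the *measured cell*.

# Noise decomposition

For a population of cells whose parameters $\theta$ vary, the stationary
variance of a species splits by the law of total variance into intrinsic
(mean conditional variance; randomness of reaction firing at fixed
parameters) and extrinsic (variance of conditional means; parameter
heterogeneity) components.  Two estimation routes are provided:

* `decompose_from_trajectories` — dual-reporter-free: under ergodicity the
  conditional moments are approximated by per-cell time averages, so the
  extrinsic noise is the across-cell variance of time-averaged means and the
  intrinsic noise the across-cell mean of time-averaged variances.  Exact
  event integrals are used for simulated trajectories; sampled readouts are
  rounded to integers and integrated by the trapezoid rule.  Cells whose
  readout never leaves zero are excluded (configurable minimal-activity
  filter) with a reported count.
* `decompose_from_models` — from per-cell (e.g. MAP-identified) models:
  conditional moments from each model's FSP stationary law; the additivity
  total = intrinsic + extrinsic is then an algebraic identity.

Finite records bias the trajectory route in a known direction: time-averaged
means fluctuate around the true conditional means by roughly
$2\tau/T \times$ (intrinsic variance), with $\tau$ the autocorrelation time,
which inflates the extrinsic estimate; thresholded readouts additionally
censor low counts, so decompositions are reported on the readout scale.
The route-concordance tests therefore use tolerances scaled to the record
length: about 10% for intrinsic/total at long horizons.  For the extrinsic
component at the 130-cell, 4-hour protocol scale the inflation itself is of
order half the extrinsic noise, so the tests assert the exact statements
instead: the raw trajectory-route extrinsic exceeds the model value
(positive inflation), and after subtracting the within-group variance of
time-averaged means across cells sharing the same generating parameters
(available because the synthetic generator retains the truth), the debiased
extrinsic agrees with the model route within a few percent of the total
variance.

Model validation by binned KL is resolution-limited: on the in-silico
truncation \{0..20\} a bin width of ten leaves only about three occupied
bins, which any reasonable fit matches; discriminating gene-state
structures (the two-state-versus-three-state question) additionally needs a
cell whose stationary law actually has several expression modes.  The
misspecification test therefore simulates a three-state cell with modes
near 0, 3 and 10 and slow switching, where forcing a two-state refit
degrades the binned KL several-fold at every bin width.

# Numerical choices

* **Exponential action.** All linear propagation (FSP, filtered FSP,
  stationary iteration) uses the action of the matrix exponential computed by
  uniformization: with $\Lambda \ge \max_x |Q_{xx}|$,
  $e^{Qt}v = e^{-\Lambda t}\sum_k \frac{(\Lambda t)^k}{k!}(I+Q/\Lambda)^k v$,
  truncated when the nonnegative tail falls below a tolerance.  Every term
  is nonnegative, so the scheme cannot produce negative probabilities and is
  robust for stiff generators; since CME generators are time-constant this
  is preferred over a general-purpose stiff ODE integrator, which is kept as
  an independent cross-check (`deSolve::lsoda`) in the tests.  Long
  intervals are split so the per-step $\Lambda\,\Delta t$ stays at or below
  40.  Default tolerances: $10^{-12}$ for one-shot FSP solves, $10^{-7}$ per
  segment inside particle ensembles (`filter_tol`), where the per-segment
  truncation — a pure, renormalized tail drop — accumulates to orders of
  magnitude below the Monte Carlo error.
* **Block-diagonal exploitation.** A follower subsystem whose trailing
  members are parameter pseudo-species has a generator that is block
  diagonal over the (static) parameter configurations; each block is
  propagated with its own uniformization rate, which spares low-rate blocks
  the series length that the globally stiffest block would force.
* **Filter normalization.** Filters are renormalized after every
  propagation and jump, accumulating the log-normalizer, rather than
  evolving unnormalized — numerically essential over hundreds of segments.
  A zero normalizer (a jump impossible under the current filter, or total
  annihilation) raises a recoverable condition; ensemble callers zero the
  particle's weight instead of aborting.
* **Stationary distributions** integrate the boundary-conserving generator
  (outflow across the truncation removed) in doubling time chunks until
  $\|Qp\|_1$ falls below `tol` (default $10^{-9}$), then renormalize — the
  "solve to a large time" convention, robust to transient states, rather
  than an eigenproblem.
* **Reproducibility.** All randomness runs through R's RNG; `seed`
  arguments make every solver deterministic.  Execution is serial; ensemble
  members consume one sequential stream, so results are bit-reproducible
  for a fixed seed.
* **Degenerate inputs.** Zero total propensity ends a simulation at the
  horizon; empty leader sets (pure filtering) and empty follower sets
  (pure Monte Carlo) are first-class limits; single-state subsystems remain
  point masses.

# The fixtures and what the tests do (and do not) show

Four benchmark networks ship as both constructors and JSON model files: the
expandable linear chain (whose CME solution stays product-Poisson with
ODE-evolving means — the analytic oracle for all error-law tests), the
repressilator (Hill repression, oscillatory), the genetic toggle switch
(mutual repression, bistable switching), and a three-gene-state
light-induced transcription model with one inactive and two active gene
states, encoded as three binary species whose stoichiometry preserves
$G_0+G_1+G_2=1$.  Chain rate constants and initial laws follow a fixed
scheme (production 2.4 into $S_1$, 0.9 elsewhere; degradation 0.6, 1.6 for
the last species; conversion 1; independent Poisson(0.5) starts).
Repressilator and toggle rate constants are representative package defaults
chosen to produce the qualitative regimes (oscillation; double-well
occupancy above 10% per mode) on the standard truncations — they are
representative defaults, and no quantitative accuracy claim rests on them.

`generate_cell_population` emulates a single-cell microscopy experiment:
cell-specific parameters drawn from the grids, exact trajectories from the
inactive zero-mRNA initial condition, and noisy readouts on a regular grid
(2-minute spacing over 4 hours for the 130-cell protocol).  What it does
*not* emulate: cell division and lineage effects, photobleaching or drift,
segmentation errors, non-Gaussian or multiplicative measurement noise, and
any slow drift of "constant" parameters.  Tests passing on these
populations validate the estimators' mathematics at matched model
assumptions — not the biology of any particular dataset.

Problem sizes used by the test suite and the acceptance script are chosen as
desk-scale study conditions: chain comparisons run at $N=2000$ samples with
20 replicates (where the plain-MC estimator is still pre-asymptotic — its
effective support is roughly $2.8\times10^4$ states, so the fold-improvement
of the RB solver measured there is smaller than its asymptotic value);
identification runs use 240 one-minute observations and 500 particles
(the full-scale protocol uses $10^4$); the toggle filtering comparison uses
$10^3$ RB particles against $10^4$ bootstrap particles.

# Known limitations

* Exhaustive decomposition search is exponential in the component count;
  beyond 22 components a greedy heuristic takes over (with a warning).
* Truncations are static; no adaptive or moving state spaces.
* The filtered FSP is the only follower filter implemented (no moment
  closure / entropic matching backends).
* Gridded priors only; continuous-parameter samplers and grid refinement
  are out of scope, so posterior resolution is limited by the grid pitch.
* Observation likelihoods are Gaussian per channel (or exact at zero noise).
* No smoothing (backward) passes; posteriors are filtering posteriors.
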