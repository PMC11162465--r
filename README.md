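# rbcme — Rao-Blackwellized solvers for chemical master equations

Stochastic models of gene expression and other intracellular reaction
networks are continuous-time Markov chains whose probability law solves the
chemical master equation (CME).  Both standard solvers hit the curse of
dimensionality: the error of Monte Carlo simulation grows with the effective
state-space size, and direct finite-state-projection (FSP) integration costs
exponentially many states.  `rbcme` implements a divide-and-conquer
alternative for systems-biology modelers: it automatically splits a network
into a small **leader** system and several **follower** subsystems that are
conditionally independent given the leader's trajectory, simulates only the
leader, and integrates each follower subsystem's conditional law exactly
with a filtered FSP.  The combined estimator

> p̂(t, x̃, z₁, …, z_l) = (1/N) Σⱼ 1{x̃ⱼ(t) = x̃} Πᵢ qⱼⁱ(t, zᵢ)

is a Rao-Blackwellization of plain Monte Carlo: never less accurate at equal
sample size, and dramatically better when the followers carry most of the
probability spread.

On top of the solver the package provides:

* exact (Gillespie) simulation, FSP with sink-mass error bounds, and
  stationary distributions;
* the automated leader–follower decomposition (topological conditions
  C1–C4, exhaustive optimality search);
* stochastic filtering from noisy time courses: exact FSP filter, bootstrap
  particle filter, and the Rao-Blackwellized particle filter (RB-PF);
* cell-specific Bayesian parameter identification on discrete grids, with
  MAP extraction and stationary-distribution validation (binned KL);
* a dual-reporter-free intrinsic/extrinsic noise decomposition for
  single-cell time-course data, plus the model-based law-of-total-variance
  route;
* benchmark fixtures (linear chains with an analytic product-Poisson
  solution, repressilator, toggle switch, a three-gene-state yeast
  transcription model) and a synthetic cell-population generator.

## Worked example

Solve the three-species linear chain at `t = 10` and compare against its
analytic product-Poisson law:

```r
library(rbcme)

net <- make_linear_chain(3)          # 8 reactions, Poisson(0.5) start
dec <- optimal_decomposition(net, max_subsystem_size = 100)
dec
#> Leader-follower decomposition
#>   leaders: S3
#>   subsystem 1: S1, S2  (100 states)
#>   whole follower size: 100

est <- rb_cme_solve(net, dec, t = 10, N = 1000, seed = 1)
mc  <- mc_cme_solve(net, t = 10, N = 1000, seed = 1)

m <- linear_chain_means(3, 10)       # analytic means: 1.5 1.5 1.5
chain_l1_error(est, m)               # 0.02443031
chain_l1_error(mc,  m)               # 0.3120836

head(marginalize(est, "S1"), 4)
#>   S1      prob
#> 1  1 0.3347164
#> 2  2 0.2510289
#> 3  0 0.2231488
#> 4  3 0.1255063
```

At the same 1000 samples the RB estimate's L1 error against the exact
solution (0.024) is more than an order of magnitude below plain Monte
Carlo's (0.31): the solver samples only the leader species `S3` and
integrates the `(S1, S2)` block exactly along every sampled path.

Identification works the same way on the parameter-augmented system:

```r
y   <- make_yeast_model("insilico")              # gridded k1..k4, kp1, kp2
md  <- obs_model(channel_identity("mRNA"), 0.1)
tr  <- ssa_simulate(y, theta = c(k1=.3, k2=.4, k3=.3, k4=.3, kp1=3, kp2=5),
                    t_end = 240, seed = 42)
obs <- generate_observations(tr, md, 1:240, y)
post <- rb_identify(y, obs, N = 500, seed = 7)   # ~3 min
post$map                                         # MAP on the grids
validate_stationary(y, post$map, obs)            # binned-KL model check
```

A thin command-line wrapper over the same functions ships in
`exec/rbcme` (subcommands `simulate`, `solve-fsp`, `decompose`, `solve-rb`,
`filter`, `identify`, `noise`, `fixtures`), reading the JSON model files in
`inst/extdata/`.

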