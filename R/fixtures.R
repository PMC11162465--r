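## ---------------------------------------------------------------------------
## Benchmark networks: an expandable linear chain with an analytic
## product-Poisson solution, a repressilator, a genetic toggle switch, and a
## three-gene-state yeast transcription model.
## ---------------------------------------------------------------------------

#' Expandable linear reaction chain
#'
#' `n` species with production, degradation, and conversion
#' \eqn{S_i \to S_{i+1}} reactions under mass-action kinetics: rate constants
#' 2.4 (production of S1), 0.9 (production of each later species), 0.6
#' (degradation of S1..S(n-1)), 1.6 (degradation of Sn) and 1 (each
#' conversion), so the chain has `3n - 1` reactions.  All species start
#' independently Poisson with mean 0.5.  Because the system is linear, the
#' CME solution stays product-Poisson with means following the linear rate
#' ODE ([linear_chain_means()]).
#'
#' @param n Number of species (>= 2).
#' @param size Per-species truncation size (default 10: states 0..9).
#' @return A [reaction_network()].
#' @export
make_linear_chain <- function(n, size = 10L) {
  stopifnot(n >= 2)
  sp <- lapply(seq_len(n), function(i) species(paste0("S", i), size = size))
  nm <- function(i) paste0("S", i)
  rx <- list(reaction(products = stats::setNames(1L, nm(1)),
                      propensity = mass_action(2.4)))
  for (i in seq_len(n - 1L)) {
    rx <- c(rx, list(
      reaction(reactants = stats::setNames(1L, nm(i)),
               propensity = mass_action(0.6)),                       # degradation
      reaction(reactants = stats::setNames(1L, nm(i)),
               products = stats::setNames(1L, nm(i + 1L)),
               propensity = mass_action(1)),                          # conversion
      reaction(products = stats::setNames(1L, nm(i + 1L)),
               propensity = mass_action(0.9))))                       # production
  }
  rx <- c(rx, list(reaction(reactants = stats::setNames(1L, nm(n)),
                            propensity = mass_action(1.6))))
  reaction_network(sp, rx, init = init_poisson(rep(0.5, n)))
}

#' Analytic means of the linear chain
#'
#' The mean vector solves \eqn{dm/dt = A m + b} with the chain's rate
#' constants; the closed form uses the matrix exponential
#' \eqn{m(t) = e^{At}(m_0 + A^{-1}b) - A^{-1}b}.  The joint law is the
#' product of independent Poissons with these means.
#'
#' @param n Chain length.
#' @param t Time (>= 0).
#' @param m0 Initial mean (default 0.5 per species).
#' @return Numeric vector of per-species Poisson means at `t`.
#' @export
linear_chain_means <- function(n, t, m0 = 0.5) {
  deg <- c(rep(0.6, n - 1L), 1.6)
  conv <- c(rep(1, n - 1L), 0)
  A <- diag(-(deg + conv), n)
  for (i in seq_len(n - 1L)) A[i + 1L, i] <- 1
  b <- c(2.4, rep(0.9, n - 1L))
  mst <- -solve(A, b)
  m0v <- rep(m0, n)
  as.numeric(Matrix::expm(A * t) %*% (m0v - mst) + mst)
}

#' L1 error of a CME estimate against the chain's product-Poisson law
#'
#' Works on an empirical probability table (plain Monte Carlo) or on an
#' `rbcme_rb_estimate` (grouping particles by leader state and expanding the
#' conditional-independence product over the follower truncations; mass the
#' reference law puts outside the truncation or on unobserved leader states
#' is counted in full).
#'
#' @param x Probability table or `rbcme_rb_estimate`.
#' @param means Per-species Poisson means (e.g. [linear_chain_means()]).
#' @return The L1 distance (in [0, 2]).
#' @export
chain_l1_error <- function(x, means) {
  if (is.data.frame(x)) {
    st <- as.matrix(x[setdiff(names(x), "prob")])
    p <- rep(1, nrow(st))
    for (i in seq_len(ncol(st))) p <- p * stats::dpois(st[, i], means[i])
    return(sum(abs(x$prob - p)) + (1 - sum(p)))
  }
  stopifnot(inherits(x, "rbcme_rb_estimate"))
  dec <- x$decomp
  nsub <- length(dec$subsystems)
  if (nsub == 0L)
    return(chain_l1_error(empirical_distribution(
      x$leader_states, species = x$species[dec$leaders]), means[dec$leaders]))
  ## reference follower factors on each subsystem truncation
  qstar <- lapply(seq_len(nsub), function(i) {
    st <- space_states(x$spaces[[i]])
    p <- rep(1, nrow(st))
    mem <- dec$subsystems[[i]]
    for (k in seq_along(mem)) p <- p * stats::dpois(st[, k], means[mem[k]])
    p
  })
  m_in <- vapply(qstar, sum, 0)
  ref <- Reduce(function(a, b) as.numeric(outer(a, b)), qstar)
  lk <- if (length(dec$leaders))
    do.call(paste, c(as.data.frame(x$leader_states), sep = ",")) else rep("", x$N)
  lmeans <- means[dec$leaders]
  total <- 0; p_lead_seen <- 0
  for (u in unique(lk)) {
    grp <- which(lk == u)
    M <- 0
    for (p in grp) {
      v <- x$filters[[p]][[1L]]
      if (nsub > 1L)
        for (i in seq.int(2L, nsub)) v <- as.numeric(outer(v, x$filters[[p]][[i]]))
      M <- M + x$weights[p] * v
    }
    pl <- if (length(dec$leaders)) {
      uv <- as.integer(strsplit(u, ",", fixed = TRUE)[[1L]])
      prod(stats::dpois(uv, lmeans))
    } else 1
    p_lead_seen <- p_lead_seen + pl
    total <- total + sum(abs(M - pl * ref)) + pl * (1 - prod(m_in))
  }
  total + (1 - p_lead_seen)
}

#' Genetic repressilator
#'
#' Three gene-expression units whose proteins cyclically repress the next
#' unit's transcription through Hill kinetics.  The default rate constants
#' are representative values chosen to produce sustained stochastic
#' oscillations on the truncations mRNA {0..19} and protein {0..199}; they
#' are representative fixture defaults.
#'
#' @param vmax,K,n_h Transcription Hill parameters (repression by the
#'   upstream protein).
#' @param gamma_m,k_t,gamma_p mRNA degradation, translation and protein
#'   degradation rate constants.
#' @param mrna_size,protein_size Truncation sizes.
#' @return A [reaction_network()].
#' @export
make_repressilator <- function(vmax = 2, K = 40, n_h = 3, gamma_m = 0.2,
                               k_t = 0.8, gamma_p = 0.05,
                               mrna_size = 20L, protein_size = 200L) {
  sp <- list()
  rx <- list()
  for (i in 1:3) {
    M <- paste0("M", i); P <- paste0("P", i)
    Prev <- paste0("P", ((i - 2) %% 3) + 1)   # upstream repressor
    sp <- c(sp, list(species(M, size = mrna_size), species(P, size = protein_size)))
    rx <- c(rx, list(
      reaction(products = stats::setNames(1L, M),
               propensity = hill_kinetics(vmax, K, n_h, Prev, "repressor")),
      reaction(reactants = stats::setNames(1L, M), propensity = mass_action(gamma_m)),
      reaction(reactants = stats::setNames(1L, M),
               products = stats::setNames(c(1L, 1L), c(M, P)),
               propensity = mass_action(k_t)),
      reaction(reactants = stats::setNames(1L, P), propensity = mass_action(gamma_p))))
  }
  reaction_network(sp, rx,
                   init = init_point(stats::setNames(c(10L, 0L, 0L, 0L, 0L, 0L),
                                                     c("M1", "P1", "M2", "P2", "M3", "P3"))))
}

#' Genetic toggle switch
#'
#' Two gene-expression units whose proteins repress each other's gene: each
#' gene activates spontaneously and is switched off at a rate proportional
#' to the abundance of the opposing protein.  Default rate constants are
#' representative values producing bistable switching on the truncations
#' gene {0,1} and protein {0..199}; they are representative fixture
#' defaults.
#'
#' @param k_on Spontaneous gene activation rate.
#' @param k_rep Per-repressor-molecule gene inactivation rate.
#' @param k_p Protein production rate while the gene is on.
#' @param gamma_p Protein degradation rate constant.
#' @param protein_size Protein truncation size.
#' @return A [reaction_network()].
#' @export
make_toggle <- function(k_on = 0.05, k_rep = 0.005, k_p = 8, gamma_p = 0.08,
                        protein_size = 200L) {
  sp <- list(species("Ga", states = 0:1), species("Gb", states = 0:1),
             species("Pa", size = protein_size), species("Pb", size = protein_size))
  on_prop <- function(g) lin_comb(coef = list(k_on, -k_on), species = c(NA, g))
  rx <- list(
    reaction(products = c(Ga = 1L), propensity = on_prop("Ga")),
    reaction(reactants = c(Ga = 1L, Pb = 1L), products = c(Pb = 1L),
             propensity = mass_action(k_rep)),
    reaction(reactants = c(Ga = 1L), products = c(Ga = 1L, Pa = 1L),
             propensity = mass_action(k_p)),
    reaction(reactants = c(Pa = 1L), propensity = mass_action(gamma_p)),
    reaction(products = c(Gb = 1L), propensity = on_prop("Gb")),
    reaction(reactants = c(Gb = 1L, Pa = 1L), products = c(Pa = 1L),
             propensity = mass_action(k_rep)),
    reaction(reactants = c(Gb = 1L), products = c(Gb = 1L, Pb = 1L),
             propensity = mass_action(k_p)),
    reaction(reactants = c(Pb = 1L), propensity = mass_action(gamma_p)))
  reaction_network(sp, rx,
                   init = init_point(c(Ga = 1L, Gb = 0L, Pa = 0L, Pb = 0L)))
}

#' Three-gene-state yeast transcription model
#'
#' A light-inducible transcription system with one inactive gene state `G0`
#' and two active states `G1`, `G2`, encoded as three binary species with
#' `G0 + G1 + G2 = 1` preserved by the stoichiometry.  Switching
#' `G0 <-> G1 <-> G2` has rates `k1..k4`; mRNA is transcribed at rate
#' `kp1` in `G1` and `kp1 + kp2` in `G2` and degrades with rate constant 1.
#' `k3 = 0` collapses the model to the two-state telegraph model.  Two
#' parameter-grid regimes are shipped: `"insilico"` (k1..k4 on
#' {0, 0.05, ..., 1}; kp1, kp2 on {1, ..., 10}; mRNA truncated to {0..20})
#' and `"experimental"` (k1..k3 on {0, 0.05, ..., 1}; k4 on {0, 0.1, ..., 2};
#' kp1 on {0, 8, ..., 80}; kp2 on {20, 30, ..., 120}; mRNA {0..150}).  In
#' both, half of k3's prior mass sits at zero (one vs two active states),
#' the rest uniform; all other priors are uniform.  The cell starts inactive
#' (`G0 = 1`) with zero mRNA.
#'
#' @param regime `"insilico"` or `"experimental"`.
#' @param mrna_size Optional mRNA truncation-size override.
#' @return A [reaction_network()] with six [param_spec()]s.
#' @export
make_yeast_model <- function(regime = c("insilico", "experimental"),
                             mrna_size = NULL) {
  regime <- match.arg(regime)
  if (is.null(mrna_size)) mrna_size <- if (regime == "insilico") 21L else 151L
  sp <- list(species("G0", states = 0:1), species("G1", states = 0:1),
             species("G2", states = 0:1), species("mRNA", size = mrna_size))
  rx <- list(
    reaction(reactants = c(G0 = 1L), products = c(G1 = 1L),
             propensity = mass_action(param("k1"))),
    reaction(reactants = c(G1 = 1L), products = c(G0 = 1L),
             propensity = mass_action(param("k2"))),
    reaction(reactants = c(G1 = 1L), products = c(G2 = 1L),
             propensity = mass_action(param("k3"))),
    reaction(reactants = c(G2 = 1L), products = c(G1 = 1L),
             propensity = mass_action(param("k4"))),
    reaction(products = c(mRNA = 1L),
             propensity = lin_comb(coef = list(param("kp1"), param("kp1"), param("kp2")),
                                   species = c("G1", "G2", "G2"))),
    reaction(reactants = c(mRNA = 1L), propensity = mass_action(1)))
  half_zero <- function(grid) c(0.5, rep(0.5 / (length(grid) - 1L), length(grid) - 1L))
  if (regime == "insilico") {
    g01 <- seq(0, 1, by = 0.05)
    pars <- list(param_spec("k1", g01), param_spec("k2", g01),
                 param_spec("k3", g01, prior = half_zero(g01)),
                 param_spec("k4", g01),
                 param_spec("kp1", 1:10), param_spec("kp2", 1:10))
  } else {
    g01 <- seq(0, 1, by = 0.05)
    pars <- list(param_spec("k1", g01), param_spec("k2", g01),
                 param_spec("k3", g01, prior = half_zero(g01)),
                 param_spec("k4", seq(0, 2, by = 0.1)),
                 param_spec("kp1", seq(0, 80, by = 8)),
                 param_spec("kp2", seq(20, 120, by = 10)))
  }
  reaction_network(sp, rx, params = pars,
                   init = init_point(c(G0 = 1L, G1 = 0L, G2 = 0L, mRNA = 0L)))
}

#' Synthetic single-cell population
#'
#' Draws cell-specific parameters, simulates each cell's trajectory from the
#' network's initial condition over `[0, T]`, and records noisy observations
#' every `dt` through the observation model.  The generating parameters are
#' retained for recovery tests.  With the defaults of the yeast experimental
#' protocol (`n_cells = 130`, `dt = 2`, `T = 240`) the output is
#' schema-identical to a microscopy time-course dataset.
#'
#' @param network A [reaction_network()] with parameters.
#' @param theta_sampler Function `n -> matrix` (rows = cells, named columns)
#'   drawing parameters from the grids.
#' @param n_cells Number of cells.
#' @param T Horizon.
#' @param dt Sampling interval.
#' @param model [obs_model()] applied to each cell.
#' @param seed Integer master seed.
#' @return An `rbcme_cell_population`: `series` (list of [obs_series()]),
#'   `trajectories`, and the true `theta` matrix.
#' @export
generate_cell_population <- function(network, theta_sampler, n_cells, T, dt,
                                     model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- theta_sampler(n_cells)
  stopifnot(nrow(theta) == n_cells)
  times <- seq(dt, T, by = dt)
  trajectories <- vector("list", n_cells)
  series <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    tr <- ssa_simulate(network, theta = theta[c, ], t_end = T)
    trajectories[[c]] <- tr
    series[[c]] <- generate_observations(tr, model, times, network)
  }
  structure(list(series = series, trajectories = trajectories, theta = theta,
                 T = T, dt = dt),
            class = "rbcme_cell_population")
}
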