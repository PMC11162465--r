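## a follower birth-death X alongside an independent leader Y: the filtered
## CME for X has no correction terms, so it must equal the plain sub-CME
make_independent_pair <- function() {
  reaction_network(
    list(species("X", 15), species("Y", 15)),
    list(reaction(products = c(X = 1L), propensity = mass_action(2)),
         reaction(reactants = c(X = 1L), propensity = mass_action(1)),
         reaction(products = c(Y = 1L), propensity = mass_action(1.5)),
         reaction(reactants = c(Y = 1L), propensity = mass_action(0.8))),
    init = init_point(c(X = 0L, Y = 0L)))
}

test_that("with no leader coupling the filtered propagation is the sub-CME", {
  net <- make_independent_pair()
  d <- decomposition(net, leaders = "Y")
  f0 <- follower_filter(d, 1, c(1, rep(0, 14)))
  f1 <- filtered_propagate(f0, net, d, leader_state = 3L, dt = 4)
  expect_equal(sum(f1$prob), 1, tolerance = 1e-12)

  subx <- make_birth_death(k = 2, gamma = 1, size = 15L)
  fs <- fsp_solve(subx, t = 4)
  expect_lt(sum(abs(f1$prob - fs$prob / sum(fs$prob))), 1e-7)
})

test_that("the no-jump correction matches a rejection-sampling oracle", {
  ## two-state gene follower driving a leader birth process
  net <- reaction_network(
    list(species("g", states = 0:1), species("X", size = 30L)),
    list(reaction(products = c(g = 1L),
                  propensity = lin_comb(list(1, -1), c(NA, "g"))),
         reaction(reactants = c(g = 1L), propensity = mass_action(0.7)),
         reaction(reactants = c(g = 1L), products = c(g = 1L, X = 1L),
                  propensity = mass_action(2))),
    init = init_point(c(g = 0L, X = 0L)))
  d <- decomposition(net, leaders = "X")
  dt <- 0.8
  set.seed(9)
  N <- 1e6
  Xf <- rbcme:::cpp_ssa_final(net$enc, matrix(0L, N, 2), numeric(0), 0, dt, 1e6L)
  keep <- Xf[, 2] == 0                      # no leader (birth) jump occurred
  p_rej <- mean(Xf[keep, 1])
  f0 <- follower_filter(d, 1, c(1, 0))
  f1 <- filtered_propagate(f0, net, d, leader_state = 0L, dt = dt)
  se <- sqrt(p_rej * (1 - p_rej) / sum(keep))
  expect_lt(abs(f1$prob[2] - p_rej), 4 * se)
  ## survival mass accumulates in the log-normalizer
  expect_equal(exp(f1$log_norm), mean(keep), tolerance = 4 * 1e-3)
})

test_that("jump updates apply Bayes' rule with propensity weights and shifts", {
  ## leader birth at rate k*z on a follower holding z in {0, 2}:
  ## observing a birth reweights by z, killing z = 0
  net <- reaction_network(
    list(species("z", size = 3L), species("X", size = 10L)),
    list(reaction(products = c(X = 1L),
                  propensity = lin_comb(list(1.5), "z"))),
    init = init_point(c(z = 0L, X = 0L)))
  d <- decomposition(net, leaders = "X")
  f0 <- follower_filter(d, 1, c(0.5, 0, 0.5))
  f1 <- filtered_jump_update(f0, net, d, pre_jump_leader_state = 0L,
                             leader_net_change = 1L)
  expect_equal(f1$prob, c(0, 0, 1))

  ## a jump whose matching propensities do not involve the subsystem leaves
  ## the filter unchanged
  net2 <- make_independent_pair()
  d2 <- decomposition(net2, leaders = "Y")
  f0 <- follower_filter(d2, 1, dpois(0:14, 2) / sum(dpois(0:14, 2)))
  f1 <- filtered_jump_update(f0, net2, d2, pre_jump_leader_state = 4L,
                             leader_net_change = 1L)
  expect_equal(f1$prob, f0$prob)

  ## a jump reaction that moves the follower shifts the support
  chain <- make_linear_chain(2)
  dch <- decomposition(chain, leaders = "S2")
  f0 <- follower_filter(dch, 1, c(0, 0, 1, rep(0, 7)))   # S1 = 2 surely
  f1 <- filtered_jump_update(f0, chain, dch, pre_jump_leader_state = 0L,
                             leader_net_change = 1L)
  ## +S2 matches both the conversion (shift, weight x1) and production (0.9)
  expect_equal(f1$prob[2], 2 / 2.9, tolerance = 1e-12)
  expect_equal(f1$prob[3], 0.9 / 2.9, tolerance = 1e-12)

  ## impossible jumps signal a recoverable zero-mass condition
  f0 <- follower_filter(d, 1, c(1, 0, 0))   # z = 0 surely, birth rate 0
  expect_error(filtered_jump_update(f0, net, d, 0L, 1L),
               class = "rbcme_zero_mass")
})

test_that("filtering along a trajectory matches the joint-space conditioning oracle", {
  tg <- make_mini_toggle()
  d <- decomposition(tg, leaders = c("Ga", "Gb"))
  leaders <- d$leaders
  set.seed(21)
  for (rep in 1:3) {
    tr <- ssa_simulate(tg, t_end = 30)
    orc <- full_conditioning_oracle(tg, leaders, tr)
    fl <- filter_along_trajectory(tg, d, tr)
    qa <- fl[[1]][[1]]$prob
    qb <- fl[[2]][[1]]$prob
    expect_lt(sum(abs(qa - oracle_marginal(orc, "Pa"))), 1e-6)
    expect_lt(sum(abs(qb - oracle_marginal(orc, "Pb"))), 1e-6)
    ## conditional independence: the joint factorizes given the leader path
    expect_lt(sum(abs(as.numeric(outer(qa, qb)) -
                      oracle_marginal(orc, c("Pa", "Pb")))), 1e-6)
  }
})

test_that("degenerate paths and subsystems behave as limits", {
  net <- make_independent_pair()
  d <- decomposition(net, leaders = "Y")
  ## a trajectory with no leader jumps equals one long propagation
  tr <- structure(list(times = numeric(0), states = matrix(0L, 0, 2),
                       rxn = integer(0), x0 = c(0L, 3L), t0 = 0, t_end = 4,
                       species = net$species_names),
                  class = "rbcme_trajectory")
  fl <- filter_along_trajectory(net, d, tr)
  f0 <- follower_filter(d, 1, c(1, rep(0, 14)))
  f1 <- filtered_propagate(f0, net, d, 3L, 4)
  expect_equal(fl[[1]][[1]]$prob, f1$prob, tolerance = 1e-10)

  ## a single-state subsystem stays a point mass
  net1 <- reaction_network(
    list(species("c", size = 1L), species("Y", 10)),
    list(reaction(products = c(Y = 1L), propensity = mass_action(1)),
         reaction(reactants = c(Y = 1L), propensity = mass_action(0.5))),
    init = init_point(c(c = 0L, Y = 0L)))
  d1 <- decomposition(net1, leaders = "Y")
  tr1 <- ssa_simulate(net1, t_end = 6, seed = 11)
  fl1 <- filter_along_trajectory(net1, d1, tr1)
  expect_equal(fl1[[1]][[1]]$prob, 1)
})
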