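test_that("SSA is exact for analytically solvable systems", {
  ## absorbing system: all propensities zero at the initial state
  dead <- reaction_network(list(species("X", 5)),
                           list(reaction(reactants = c(X = 1L),
                                         propensity = mass_action(1))),
                           init = init_point(c(X = 0L)))
  tr <- ssa_simulate(dead, t_end = 5, seed = 1)
  expect_equal(length(tr$times), 0L)
  expect_equal(as.integer(trajectory_states(tr, 5)), 0L)

  ## pure production: X(t) ~ Poisson(k t)
  prod <- reaction_network(list(species("X", 100)),
                           list(reaction(products = c(X = 1L),
                                         propensity = mass_action(2.4))),
                           init = init_point(c(X = 0L)))
  set.seed(2)
  X0 <- matrix(0L, 10000, 1)
  Xf <- rbcme:::cpp_ssa_final(prod$enc, X0, numeric(0), 0, 10, 1e6L)
  expect_lt(abs(mean(Xf) - 24), 3 * sqrt(24) / sqrt(10000))
  expect_lt(abs(var(Xf[, 1]) - 24), 4 * 24 * sqrt(2 / 9999))

  ## birth-death stationary mean k/gamma
  bd <- make_birth_death(k = 2, gamma = 1)
  set.seed(3)
  Xf <- rbcme:::cpp_ssa_final(bd$enc, matrix(0L, 4000, 1), numeric(0), 0, 15, 1e6L)
  expect_lt(abs(mean(Xf) - 2), 3 * sqrt(2) / sqrt(4000))
})

test_that("inter-jump waiting times are exponential with the total propensity rate", {
  prod <- reaction_network(list(species("X", 2000)),
                           list(reaction(products = c(X = 1L),
                                         propensity = mass_action(3))),
                           init = init_point(c(X = 0L)))
  tr <- ssa_simulate(prod, t_end = 400, seed = 4)
  gaps <- diff(c(0, tr$times))
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical distributions are normalized sparse tables", {
  bd <- make_birth_death()
  tr <- ssa_simulate(bd, t_end = 3, seed = 5)
  one <- empirical_distribution(list(tr), t = 3)
  expect_equal(nrow(one), 1L)
  expect_equal(one$prob, 1)
  expect_equal(one$X, as.integer(trajectory_states(tr, 3)))

  trs <- lapply(1:50, function(i) ssa_simulate(bd, t_end = 3, seed = 100 + i))
  df <- empirical_distribution(trs, t = 3)
  expect_equal(sum(df$prob), 1)
  expect_true(all(df$prob > 0))
})

test_that("observation generation applies h and Gaussian noise per channel", {
  y <- make_yeast_model("insilico")
  th <- c(k1 = 0.3, k2 = 0.4, k3 = 0.3, k4 = 0.3, kp1 = 3, kp2 = 5)
  tr <- ssa_simulate(y, theta = th, t_end = 30, seed = 6)
  md0 <- obs_model(channel_identity("mRNA"), 0)
  s0 <- generate_observations(tr, md0, 1:30, y)
  expect_equal(s0$values[, 1], as.numeric(trajectory_states(tr, 1:30)[, "mRNA"]))

  ## background-censored readout: counts at or below 7 read as zero
  thr <- obs_model(channel_threshold("mRNA", 7), 0)
  X <- trajectory_states(tr, 1:30)[, "mRNA"]
  sthr <- generate_observations(tr, thr, 1:30, y)
  expect_equal(sthr$values[, 1], as.numeric(X * (X > 7)))
  fake <- structure(list(times = c(1, 2), states = matrix(c(0L,0L,1L,0L, 0L,0L,1L,0L),
                                                          2, 4, byrow = TRUE),
                         x0 = c(0L, 0L, 0L, 5L), t0 = 0, t_end = 3,
                         species = y$species_names),
                    class = "rbcme_trajectory")
  ## mRNA = 5 reads 0; mRNA = 9 reads 9
  fake$x0 <- c(0L, 0L, 0L, 5L); fake$states[, 4] <- c(5L, 9L)
  s <- generate_observations(fake, thr, c(1.5, 2.5), y)
  expect_equal(s$values[, 1], c(0, 9))

  set.seed(7)
  md1 <- obs_model(channel_identity("mRNA"), 1)
  s1 <- generate_observations(tr, md1, 1:30, y)
  expect_false(all(s1$values[, 1] == round(s1$values[, 1])))
})

test_that("the Monte Carlo L1 prefactor matches its closed forms", {
  unif <- rep(1 / 100, 100)
  pf <- mc_l1_prefactor(unif)
  expect_equal(pf$sqrt_sum, 10)                  # sqrt(S) for uniform on S
  expect_equal(pf$center, sqrt(2 / pi) * 10)
  expect_equal(pf$upper - pf$lower, 2 * sqrt(2 / pi))

  expect_equal(mc_l1_prefactor(c(1, 0, 0))$sqrt_sum, 1)   # point mass

  ## product law: the sum factorizes over marginals
  p1 <- dpois(0:40, 1.3); p1 <- p1 / sum(p1)
  p2 <- dpois(0:40, 2.6); p2 <- p2 / sum(p2)
  joint <- as.numeric(outer(p1, p2))
  expect_equal(mc_l1_prefactor(joint)$sqrt_sum,
               sum(sqrt(p1)) * sum(sqrt(p2)), tolerance = 1e-12)

  expect_error(mc_l1_prefactor(c(0.5, 0.4)), "not normalized")
})

test_that("empirical-distribution error decays like 1/sqrt(N) in the sampled regime", {
  net <- make_linear_chain(3)
  m <- linear_chain_means(3, 10)
  err <- sapply(c(1000, 16000), function(N) {
    mean(sapply(1:3, function(r) {
      chain_l1_error(mc_cme_solve(net, 10, N, seed = 1000 * r + N), m)
    }))
  })
  slope <- log(err[2] / err[1]) / log(16)
  expect_lt(abs(slope + 0.5), 0.1)
})
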