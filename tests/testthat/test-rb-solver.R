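test_that("the RB solver reduces to its two limits", {
  net <- make_linear_chain(2)
  ## all-leader decomposition with a shared seed is plain Monte Carlo
  dall <- decomposition(net, leaders = c("S1", "S2"), subsystems = list())
  est <- rb_cme_solve(net, dall, t = 5, N = 300, seed = 42)
  mc <- mc_cme_solve(net, t = 5, N = 300, seed = 42)
  emp <- empirical_distribution(est$leader_states, species = net$species_names)
  expect_equal(l1_error(emp, mc), 0)

  ## all-follower decomposition equals the FSP solution for any N
  dfol <- decomposition(net, leaders = integer(0))
  f <- fsp_solve(net, t = 10)
  for (N in c(1, 4)) {
    est <- rb_cme_solve(net, dfol, t = 10, N = N, seed = N)
    expect_lt(max(abs(est$filters[[1]][[1]] - f$prob / sum(f$prob))), 1e-12)
  }
})

test_that("averaging follower filters over leader paths reproduces the joint law", {
  tg <- make_mini_toggle()
  d <- decomposition(tg, leaders = c("Ga", "Gb"))
  truth <- fsp_solve(tg, t = 12)
  ptrue <- truth$prob
  est <- rb_cme_solve(tg, d, t = 12, N = 1500, seed = 5)
  l1 <- sum(abs(rb_joint_dense(est, tg) - ptrue))
  expect_lt(l1, truth$sink_mass + 0.06)   # Monte Carlo error of the leader part
})

test_that("SSA keep-leader and conditional-intensity thinning give equivalent estimates", {
  tg <- make_mini_toggle()
  d <- decomposition(tg, leaders = c("Ga", "Gb"))
  truth <- fsp_solve(tg, t = 10)$prob
  nrep <- 4
  l1_ssa <- sapply(seq_len(nrep), function(r) {
    est <- rb_cme_solve(tg, d, t = 10, N = 250, seed = 300 + r)
    sum(abs(rb_joint_dense(est, tg) - truth))
  })
  l1_thin <- sapply(seq_len(nrep), function(r) {
    est <- rb_thinning_solve(tg, d, t = 10, N = 250, seed = 400 + r)
    sum(abs(rb_joint_dense(est, tg) - truth))
  })
  tt <- t.test(l1_ssa, l1_thin)
  expect_gt(tt$p.value, 0.01)
  expect_lt(abs(mean(l1_ssa) - mean(l1_thin)) / mean(l1_ssa), 0.5)
})

test_that("marginalization respects blocks and conditional independence", {
  tg <- make_mini_toggle()
  d <- decomposition(tg, leaders = c("Ga", "Gb"))
  est <- rb_cme_solve(tg, d, t = 12, N = 1200, seed = 9)
  ## every marginal sums to 1
  for (comp in list("Ga", "Pa", c("Ga", "Pa"), c("Pa", "Pb"))) {
    m <- marginalize(est, comp)
    expect_equal(sum(m$prob), 1, tolerance = 1e-9)
  }
  ## leader marginal is the empirical law of the kept paths
  ml <- marginalize(est, c("Ga", "Gb"))
  emp <- empirical_distribution(est$leader_states, species = c("Ga", "Gb"))
  expect_equal(l1_error(ml, emp), 0, tolerance = 1e-12)

  ## cross-subsystem joint: E[q_a (x) q_b], not the product of marginals
  truth <- fsp_solve(tg, t = 12)
  sp <- truth$space
  tj <- rbcme:::space_marginalize(sp, truth$prob / sum(truth$prob),
                                  match(c("Pa", "Pb"), sp$names))
  mj <- marginalize(est, c("Pa", "Pb"))
  jl <- matrix(0, 8, 8)
  jl[cbind(mj$Pa + 1L, mj$Pb + 1L)] <- mj$prob
  l1_joint <- sum(abs(jl - tj))
  ma <- marginalize(est, "Pa"); mb <- marginalize(est, "Pb")
  l1_prod <- sum(abs(outer(ma$prob, mb$prob) - tj))
  expect_lt(l1_joint, l1_prod)            # correlations are retained
  expect_lt(l1_joint, 0.08)
})

test_that("L1 distance behaves as a metric on probability tables", {
  a <- data.frame(X = 0:2, prob = c(0.2, 0.3, 0.5))
  expect_equal(l1_error(a, a), 0)
  b <- data.frame(X = 5, prob = 1)
  expect_equal(l1_error(a, b), 2)
  expect_equal(l1_error(c(0.5, 0.5), c(0.25, 0.75)), 0.5)

  ## Monte Carlo replicate-mean error sits in the pre-convergence band of
  ## the three-species chain (well-sampled regime at N = 1e5)
  net <- make_linear_chain(3)
  m <- linear_chain_means(3, 10)
  pref <- prod(sapply(m, function(mm) sum(sqrt(dpois(0:40, mm)))))
  errs <- sapply(1:10, function(r)
    chain_l1_error(mc_cme_solve(net, 10, 1e5, seed = 500 + r), m))
  band <- sqrt(2 / pi) * c(pref - 1, pref + 1) / sqrt(1e5)
  expect_gt(mean(errs), band[1])
  expect_lt(mean(errs), band[2])
})

test_that("RB dominates plain MC at equal sample size; leader marginals match", {
  net <- make_linear_chain(3)
  d <- optimal_decomposition(net, 100)
  m <- linear_chain_means(3, 10)
  nrep <- 6
  l1_mc <- sapply(seq_len(nrep), function(r)
    chain_l1_error(mc_cme_solve(net, 10, 800, seed = 600 + r), m))
  ests <- lapply(seq_len(nrep), function(r)
    rb_cme_solve(net, d, t = 10, N = 800, seed = 700 + r))
  l1_rb <- sapply(ests, chain_l1_error, means = m)
  expect_lt(mean(l1_rb), mean(l1_mc))

  ## the leader (S3) marginal is estimated by the same protocol in both
  l1_lead_rb <- sapply(ests, function(e) {
    ml <- marginalize(e, "S3")
    sum(abs(ml$prob - dpois(ml$S3, m[3]))) + (1 - sum(dpois(ml$S3, m[3])))
  })
  l1_lead_mc <- sapply(seq_len(nrep), function(r) {
    mc <- mc_cme_solve(net, 10, 800, seed = 800 + r)
    agg <- rowsum(mc$prob, mc$S3)
    v <- as.integer(rownames(agg))
    sum(abs(as.numeric(agg) - dpois(v, m[3]))) + (1 - sum(dpois(v, m[3])))
  })
  expect_lt(abs(mean(l1_lead_rb) - mean(l1_lead_mc)),
            3 * sd(c(l1_lead_rb, l1_lead_mc)))
})
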