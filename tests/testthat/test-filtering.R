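test_that("the Gaussian likelihood follows the observation model", {
  y <- make_yeast_model("insilico")
  md <- obs_model(channel_identity("mRNA"), 1)
  x5 <- c(1L, 0L, 0L, 5L)
  ## maximal at y = h(x); ratio e^{-1/2} one sigma away
  l0 <- gaussian_likelihood(md, 5, x5, y)
  l1 <- gaussian_likelihood(md, 6, x5, y)
  expect_equal(l1 / l0, exp(-0.5))
  expect_true(all(gaussian_likelihood(md, 5, rbind(x5, c(1L, 0L, 0L, 4L)), y)
                  <= l0 + 1e-15))

  ## censored readout: counts 5 and 3 are indistinguishable (both read 0)
  thr <- obs_model(channel_threshold("mRNA", 7), 1)
  for (yv in c(0, 2.3, 9)) {
    expect_equal(gaussian_likelihood(thr, yv, c(1L, 0L, 0L, 5L), y),
                 gaussian_likelihood(thr, yv, c(1L, 0L, 0L, 3L), y))
  }

  ## sigma = 0 channels are exact-match indicators
  md0 <- obs_model(channel_identity("mRNA"), 0)
  expect_equal(gaussian_likelihood(md0, 5, x5, y), 1)
  expect_equal(gaussian_likelihood(md0, 4, x5, y), 0)
})

test_that("the exact FSP filter reduces to the plain FSP without information", {
  bd <- make_birth_death(k = 2, gamma = 0.5, size = 30L)
  md <- obs_model(channel_identity("X"), 1e7)     # effectively flat likelihood
  set.seed(31)
  tr <- ssa_simulate(bd, t_end = 8)
  series <- generate_observations(tr, md, c(3, 6, 8), bd)
  ef <- exact_fsp_filter(bd, state_space(bd), series)
  f <- fsp_solve(bd, t = 8)
  expect_lt(sum(abs(ef$posteriors[[3]] - f$prob / sum(f$prob))), 1e-4)
})

test_that("the bootstrap filter converges to the exact filter", {
  bd <- make_birth_death(k = 3, gamma = 0.5, size = 60L)
  md <- obs_model(channel_identity("X"), 1)
  set.seed(32)
  tr <- ssa_simulate(bd, t_end = 10)
  series <- generate_observations(tr, md, seq(2, 10, by = 2), bd)
  ef <- exact_fsp_filter(bd, state_space(bd), series)
  final_l1 <- function(post) {
    m <- posterior_marginal(post, 5, "X")
    v <- numeric(60); v[m$value + 1] <- m$prob
    sum(abs(v - ef$posteriors[[5]]))
  }
  errs <- sapply(c(200, 3200), function(N) {
    mean(sapply(1:4, function(r)
      final_l1(bootstrap_pf(bd, series, N, seed = 50 * r + N))))
  })
  expect_lt(errs[2], errs[1] / 2)        # ~1/sqrt(N): factor 4 expected
  expect_lt(errs[2], 0.06)
})

test_that("flat likelihoods leave particle weights uniform", {
  tg <- make_mini_toggle()
  md <- obs_model(channel_identity("Pa"), 1e7)
  set.seed(33)
  tr <- ssa_simulate(tg, t_end = 10)
  series <- generate_observations(tr, md, c(5, 10), tg)
  d <- decomposition(tg, leaders = c("Ga", "Gb"), obs_model = md)
  rp <- rb_particle_filter(tg, d, series, N = 100, seed = 1, keep = "all")
  expect_equal(rp$ess, c(100, 100), tolerance = 1e-6)
  ## and the posterior matches the unconditional RB solution statistically
  est <- rb_cme_solve(tg, d, t = 10, N = 4000, seed = 2)
  mu_uncond <- sum(marginalize(est, "Pb")$prob * 0:7)
  mp <- posterior_marginal(rp, 2, "Pb")
  expect_lt(abs(sum(mp$value * mp$prob) - mu_uncond), 0.35)
})

test_that("the RB particle filter tracks the exact filter on the mini toggle", {
  tg <- make_mini_toggle()
  md <- obs_model(channel_identity("Pa"), 1)
  set.seed(34)
  tr <- ssa_simulate(tg, t_end = 20)
  series <- generate_observations(tr, md, seq(4, 20, by = 4), tg)
  ef <- exact_fsp_filter(tg, state_space(tg), series)
  d <- decomposition(tg, leaders = c("Ga", "Gb"), obs_model = md)
  rp <- rb_particle_filter(tg, d, series, N = 800, seed = 3, keep = "all")
  for (k in seq_along(series$times)) {
    me <- posterior_marginal(ef, k, "Pb")
    mr <- posterior_marginal(rp, k, "Pb")
    v <- numeric(8); v[mr$value + 1] <- mr$prob
    expect_lt(sum(abs(v - me$prob)), 0.2)
  }
  ## log marginal likelihood is finite
  expect_true(all(is.finite(rp$log_lik)))

  ## filtering (RB-PF) and CME solving (RB-CME) achieve comparable accuracy
  ## at matched sample size on the same system
  truth_fsp <- fsp_solve(tg, t = 20)
  est <- rb_cme_solve(tg, d, t = 20, N = 800, seed = 4)
  l1_cme <- sum(abs(rb_joint_dense(est, tg) -
                    truth_fsp$prob / sum(truth_fsp$prob)))
  l1_filt <- local({
    ps <- rp$posteriors[[length(series$times)]]
    estf <- structure(list(leader_states = ps$leader_states,
                           filters = ps$filters, weights = ps$weights,
                           N = length(ps$weights), decomp = d, t = 20,
                           species = tg$species_names, spaces = est$spaces),
                      class = "rbcme_rb_estimate")
    sum(abs(rb_joint_dense(estf, tg) - ef$posteriors[[5]]))
  })
  expect_lt(l1_filt / l1_cme, 4)
  expect_lt(l1_cme / l1_filt, 4)
})
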