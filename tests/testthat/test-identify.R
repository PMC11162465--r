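## small-grid transcription model whose augmented space is exactly
## enumerable, so the RB identification can be checked against the exact
## filter on the joint (state, parameter) space
make_small_grid_model <- function() {
  sp <- list(species("G0", states = 0:1), species("G1", states = 0:1),
             species("G2", states = 0:1), species("mRNA", size = 15L))
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
             propensity = lin_comb(coef = list(param("kp1"), param("kp1"),
                                               param("kp2")),
                                   species = c("G1", "G2", "G2"))),
    reaction(reactants = c(mRNA = 1L), propensity = mass_action(1)))
  pars <- list(param_spec("k1", 0.3), param_spec("k2", 0.4),
               param_spec("k3", c(0, 0.3)), param_spec("k4", 0.3),
               param_spec("kp1", c(2, 3)), param_spec("kp2", 5))
  reaction_network(sp, rx, params = pars,
                   init = init_point(c(G0 = 1L, G1 = 0L, G2 = 0L, mRNA = 0L)))
}

test_that("RB identification agrees with the exact augmented-space filter", {
  net <- make_small_grid_model()
  truth <- c(k1 = 0.3, k2 = 0.4, k3 = 0.3, k4 = 0.3, kp1 = 3, kp2 = 5)
  set.seed(5)
  tr <- ssa_simulate(net, theta = truth, t_end = 100)
  md <- obs_model(channel_identity("mRNA"), 0.1)
  series <- generate_observations(tr, md, seq(1, 100), net)
  aug <- augment_with_parameters(net)
  ef <- exact_fsp_filter(aug, state_space(aug), series)
  spA <- ef$space
  pk3 <- as.numeric(rbcme:::space_marginalize(spA, ef$posteriors[[100]],
                                              match("k3", spA$names)))
  pkp1 <- as.numeric(rbcme:::space_marginalize(spA, ef$posteriors[[100]],
                                               match("kp1", spA$names)))
  post <- rb_identify(net, series, N = 200, seed = 3)
  expect_equal(post$marginals$k3$prob, pk3, tolerance = 1e-4)
  expect_equal(post$marginals$kp1$prob, pkp1, tolerance = 1e-4)
})

test_that("point-mass priors pass through identification unchanged", {
  net <- make_small_grid_model()
  ## collapse every grid to a point: posterior must equal the prior
  net2 <- reaction_network(net$species, net$reactions,
                           params = list(param_spec("k1", 0.3), param_spec("k2", 0.4),
                                         param_spec("k3", 0.3), param_spec("k4", 0.3),
                                         param_spec("kp1", 3), param_spec("kp2", 5)),
                           init = net$init)
  set.seed(6)
  tr <- ssa_simulate(net2, theta = c(k1 = 0.3, k2 = 0.4, k3 = 0.3, k4 = 0.3,
                                     kp1 = 3, kp2 = 5), t_end = 40)
  md <- obs_model(channel_identity("mRNA"), 0.1)
  series <- generate_observations(tr, md, seq(1, 40), net2)
  post <- rb_identify(net2, series, N = 100, seed = 2)
  for (pn in names(post$marginals)) expect_equal(post$marginals[[pn]]$prob, 1)
  expect_equal(post$map, c(k1 = 0.3, k2 = 0.4, k3 = 0.3, k4 = 0.3,
                           kp1 = 3, kp2 = 5))
})

test_that("prior support is preserved exactly", {
  net <- make_small_grid_model()
  ## zero prior mass on k3 = 0.3 must stay zero
  pars <- net$params
  pars[[3]] <- param_spec("k3", c(0, 0.3), prior = c(1, 0))
  net3 <- reaction_network(net$species, net$reactions, params = pars,
                           init = net$init)
  set.seed(8)
  tr <- ssa_simulate(net3, theta = c(k1 = 0.3, k2 = 0.4, k3 = 0, k4 = 0.3,
                                     kp1 = 3, kp2 = 5), t_end = 40)
  md <- obs_model(channel_identity("mRNA"), 0.1)
  series <- generate_observations(tr, md, seq(1, 40), net3)
  post <- rb_identify(net3, series, N = 100, seed = 4)
  expect_equal(post$marginals$k3$prob[2], 0)
})

test_that("MAP extraction maximizes the joint grid posterior deterministically", {
  blocks <- list(list(params = "a", dims = 3L,
                      M = rbind(c(0.1, 0.2, 0.7), c(0.6, 0.3, 0.1))),
                 list(params = "b", dims = 2L,
                      M = rbind(c(0.9, 0.1), c(0.2, 0.8))))
  post <- structure(list(blocks = blocks, weights = c(0.5, 0.5),
                         grids = list(a = c(1, 2, 3), b = c(10, 20))),
                    class = "rbcme_param_posterior")
  ## joint = 0.5 * outer products summed; brute force the argmax
  joint <- 0.5 * outer(blocks[[1]]$M[1, ], blocks[[2]]$M[1, ]) +
           0.5 * outer(blocks[[1]]$M[2, ], blocks[[2]]$M[2, ])
  ix <- which(joint == max(joint), arr.ind = TRUE)[1, ]
  expect_equal(unname(map_estimate(post)),
               c(c(1, 2, 3)[ix[1]], c(10, 20)[ix[2]]))

  ## exact ties break toward the lowest grid value
  post$blocks <- list(list(params = "a", dims = 2L, M = rbind(c(0.5, 0.5))))
  post$weights <- 1
  post$grids <- list(a = c(1, 2))
  expect_equal(unname(map_estimate(post)), 1)
})

test_that("occupation-time distributions approximate the stationary law", {
  s <- obs_series(1:10, rep(5.4, 10))
  occ <- occupation_distribution(s)
  expect_equal(occ, data.frame(value = 5, prob = 1))

  bd <- make_birth_death(k = 4, gamma = 1, size = 40L)
  tr <- ssa_simulate(bd, t_end = 3000, seed = 10)
  md <- obs_model(channel_identity("X"), 0)
  series <- generate_observations(tr, md, seq(10, 3000, by = 1), bd)
  occ <- occupation_distribution(series)
  expect_equal(sum(occ$prob), 1)
  pois <- dpois(occ$value, 4)
  expect_lt(sum(abs(occ$prob - pois)) + (1 - sum(pois)), 0.08)
})

test_that("stationary validation measures model-data agreement via binned KL", {
  bdp <- reaction_network(
    list(species("X", 40)),
    list(reaction(products = c(X = 1L), propensity = mass_action(param("k"))),
         reaction(reactants = c(X = 1L), propensity = mass_action(1))),
    params = list(param_spec("k", c(2, 4, 6))),
    init = init_point(c(X = 0L)))
  tr <- ssa_simulate(bdp, theta = c(k = 4), t_end = 4000, seed = 11)
  md <- obs_model(channel_identity("X"), 0)
  series <- generate_observations(tr, md, seq(20, 4000, by = 1), bdp)
  rep1 <- validate_stationary(bdp, c(k = 4), series, bin_width = 1)
  expect_gte(rep1$kl, 0)
  expect_lt(rep1$kl, 0.01)                  # matched model, long horizon
  rep2 <- validate_stationary(bdp, c(k = 2), series, bin_width = 1)
  expect_gt(rep2$kl, 10 * rep1$kl)          # misspecified rate stands out
  ## identical binned tables give exactly zero
  expect_equal(rbcme:::bin_distribution(0:9, rep(0.1, 10), 10, 1), 1)
})
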