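test_that("network construction validates components and reports structure", {
  net <- make_linear_chain(3)
  expect_equal(net$n, 3L)
  expect_equal(net$r, 8L)                       # 3n - 1 reactions
  expect_equal(dim(net$zeta), c(3L, 8L))

  conv <- reaction(reactants = c(S1 = 1L), products = c(S2 = 1L),
                   propensity = mass_action(1))
  net2 <- reaction_network(list(species("S1", 5), species("S2", 5), species("S3", 5)),
                           list(conv))
  expect_equal(as.integer(net2$zeta[, 1]), c(-1L, 1L, 0L))

  expect_error(reaction_network(list(species("S1", 5), species("S1", 5)), list()),
               "duplicate species")
  expect_error(reaction_network(list(species("S1", 5)),
                                list(reaction(reactants = c(S9 = 1L),
                                              propensity = mass_action(1)))),
               "unknown species")
  expect_error(mass_action(-0.5), "nonnegative")
})

test_that("propensity evaluation follows mass action, state-switched and Hill kinetics", {
  net <- make_linear_chain(3)
  lam <- propensity_eval(net, c(4L, 0L, 0L))
  expect_equal(lam[1], 2.4)                     # pure production
  expect_equal(lam[2], 0.6 * 4)                 # degradation at x1 = 4
  expect_equal(lam[3], 1 * 4)                   # conversion
  expect_equal(lam[5], 0)                       # insufficient reactant => 0

  y <- make_yeast_model("insilico")
  th <- c(k1 = 0.3, k2 = 0.4, k3 = 0.3, k4 = 0.3, kp1 = 3, kp2 = 5)
  lam <- propensity_eval(y, c(0L, 0L, 1L, 0L), th)   # state G2
  expect_equal(lam[5], 3 + 5)                   # transcription kp1 + kp2 in G2
  lam <- propensity_eval(y, c(0L, 1L, 0L, 0L), th)
  expect_equal(lam[5], 3)                       # kp1 in G1
  expect_error(propensity_eval(y, c(0L, 1L, 0L, 0L),
                               replace(th, 1, 0.31)), "off its grid")
  expect_error(propensity_eval(y, c(2L, 0L, 0L, 0L), th), "admissible")

  hillnet <- reaction_network(
    list(species("P", 50), species("M", 10)),
    list(reaction(products = c(M = 1L),
                  propensity = hill_kinetics(2, 10, 2, "P", "repressor"))))
  expect_equal(propensity_eval(hillnet, c(10L, 0L))[1], 1)   # half saturation
  expect_equal(propensity_eval(hillnet, c(0L, 0L))[1], 2)    # unrepressed
})

test_that("propensities are nonnegative and finite on whole truncations", {
  for (net in list(make_linear_chain(3), make_toggle(protein_size = 12L))) {
    sp <- state_space(net)
    st <- rbcme:::space_states(sp)
    L <- rbcme:::propensities_from_values(net$enc,
                                          rbcme:::state_values(net, st))
    expect_true(all(is.finite(L)))
    expect_true(all(L >= 0))
  }
  y <- make_yeast_model("insilico", mrna_size = 6L)
  aug <- augment_with_parameters(y)
  sp <- state_space(aug, c("G0", "G1", "G2", "mRNA", "k1", "kp1"))
  st <- rbcme:::space_states(sp)
  X <- matrix(0L, nrow(st), aug$n)
  X[, sp$members] <- st
  L <- rbcme:::propensities_from_values(aug$enc, rbcme:::state_values(aug, X))
  expect_true(all(is.finite(L)) && all(L >= 0))
})

test_that("parameter augmentation yields static pseudo-species with grid encoding", {
  y <- make_yeast_model("insilico")
  aug <- augment_with_parameters(y)
  expect_equal(aug$n, 10L)                      # 4 species + 6 parameters
  pidx <- aug$param_pseudo
  expect_true(all(aug$zeta[pidx, ] == 0L))      # parameters never change
  ## propensity uses the grid VALUE at the encoded index
  x <- c(0L, 1L, 0L, 0L,                        # G1 active
         6L, 8L, 6L, 6L, 2L, 4L)                # grid indices
  lam <- propensity_eval(aug, x)
  expect_equal(lam[5], 3)                 # kp1 grid index 2 -> value 3
  expect_equal(lam[2], seq(0, 1, 0.05)[9])      # k2 index 8 -> 0.4

  expect_error(augment_with_parameters(make_linear_chain(2)), "no gridded")
})

test_that("augmentation with point-mass priors preserves the chemical law", {
  bd <- reaction_network(
    list(species("X", 25)),
    list(reaction(products = c(X = 1L), propensity = mass_action(param("k"))),
         reaction(reactants = c(X = 1L), propensity = mass_action(1))),
    params = list(param_spec("k", grid = 2)),
    init = init_point(c(X = 0L)))
  aug <- augment_with_parameters(bd)
  f1 <- fsp_solve(bd, t = 6, theta = c(k = 2))
  f2 <- fsp_solve(aug, t = 6)
  m2 <- rbcme:::space_marginalize(f2$space, f2$prob, 1L)
  expect_lt(sum(abs(f1$prob - as.numeric(m2))), 1e-9)
})
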