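## Independent oracles used across the test suite.  These deliberately avoid
## the package's filtered-CME code path: the conditioning oracle works on the
## *joint* truncated space with dense/sparse linear algebra built directly
## from propensity evaluations.

## Full-space conditioning oracle: the conditional law of all follower
## species given a leader path, computed on the joint truncation by evolving
## an unnormalized measure restricted to the leader's current slice.
## Between jumps: follower-only reactions move mass; every leader-changing
## reaction drains mass at its full-state rate (conditioning on "no leader
## jump").  At a recorded jump of reaction r: mass is pushed by every
## reaction sharing r's leader net change, shifted by its full net change.
full_conditioning_oracle <- function(net, leaders, traj, t_end = traj$t_end) {
  sp <- state_space(net)
  st <- rbcme:::space_states(sp)
  W <- rbcme:::state_values(net, st)
  L <- rbcme:::propensities_from_values(net$enc, W)
  S <- sp$size
  lead_chg <- apply(net$zeta[leaders, , drop = FALSE], 2, function(z) any(z != 0))
  drain <- rowSums(L[, lead_chg, drop = FALSE])
  shift_mat <- function(j) {
    lam <- L[, j]
    act <- which(lam > 0)
    to <- sweep(st[act, , drop = FALSE], 2, -net$zeta[, j])
    ti <- rbcme:::space_index(sp, to)
    ok <- !is.na(ti)
    Matrix::sparseMatrix(i = ti[ok], j = act[ok], x = lam[act][ok], dims = c(S, S))
  }
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(S, S))
  outflow <- numeric(S)
  for (j in which(!lead_chg)) {
    if (all(net$zeta[, j] == 0)) next
    A <- A + shift_mat(j)
    outflow <- outflow + L[, j]
  }
  G <- methods::as(A - Matrix::Diagonal(S, outflow + drain), "CsparseMatrix")
  keys <- apply(net$zeta[leaders, , drop = FALSE], 2, paste, collapse = ",")
  mu <- rbcme:::init_vector(net, sp)
  lead0 <- traj$x0[leaders]
  slice <- apply(st[, leaders, drop = FALSE], 1, function(rw) all(rw == lead0))
  mu[!slice] <- 0
  mu <- mu / sum(mu)
  lp <- rbcme:::leader_path(traj, leaders)
  bounds <- c(lp$t0, lp$times[lp$times <= t_end], t_end)
  for (s in seq_len(length(bounds) - 1L)) {
    mu <- as.numeric(rbcme:::cpp_expatv(G, mu, bounds[s + 1L] - bounds[s], 1e-13))
    if (s < length(bounds) - 1L) {
      r <- lp$rxn[s]
      Jm <- Reduce(`+`, lapply(which(keys == keys[r] & lead_chg), shift_mat))
      mu <- as.numeric(Jm %*% mu)
    }
    mu <- mu / sum(mu)
  }
  list(space = sp, prob = mu)
}

## marginal of an oracle joint onto a set of species names
oracle_marginal <- function(oracle, keep) {
  i <- match(keep, oracle$space$names)
  as.numeric(rbcme:::space_marginalize(oracle$space, oracle$prob, i))
}

## Miniature toggle switch on small protein truncations (joint space is
## enumerable, so the conditioning oracle and exact filters are exact).
make_mini_toggle <- function(protein_size = 8L, k_on = 0.3, k_rep = 0.1,
                             k_p = 1.5, gamma_p = 0.3) {
  make_toggle(k_on = k_on, k_rep = k_rep, k_p = k_p, gamma_p = gamma_p,
              protein_size = protein_size)
}

## Poisson product table on the full nonnegative orthant restricted to the
## states present in `df` is never needed: chain_l1_error handles tails.

## brute-force decomposition search: enumerate every leader subset, build the
## finest partition by direct condition checking, maximize follower size
brute_force_best_follower_size <- function(net, threshold, obs_model = NULL) {
  n <- net$n
  sizes <- vapply(net$species, `[[`, 0L, "size")
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    leaders <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
    subs <- induced_follower_partition(net, leaders, obs_model)
    ss <- vapply(subs, function(s) prod(sizes[s]), 0)
    if (length(ss) && max(ss) > threshold) next
    d <- decomposition(net, leaders, subs, obs_model)
    if (!check_conditions(net, d, obs_model)$ok) next
    obj <- prod(sizes[setdiff(seq_len(n), leaders)])
    if (obj > best) best <- obj
  }
  best
}

## Conditional-intensity thinning sampler: draws a leader path from its exact
## marginal law WITHOUT simulating the followers, by Ogata thinning against
## the follower filters' expected leader-jump intensities.  An alternative,
## equally exact route to the SSA keep-leader sampler; used only as a
## cross-validation oracle.
rb_thinning_particle <- function(net, decomp, t_end) {
  ctx <- rbcme:::filter_context(net, decomp, NULL)
  lead0 <- rbcme:::init_sample(net, 1L)[, decomp$leaders, drop = FALSE]
  lead <- as.integer(lead0)
  q <- lapply(seq_len(ctx$nsub), function(i) rbcme:::follower_init(ctx, i, lead))
  gkeys <- names(ctx$groups)
  ## per-group rate as a function of the filters at a frozen leader state
  group_rate <- function(gkey, lead) {
    i <- ctx$grp_sub[[gkey]]
    if (i == 0L) {
      ## leader-only propensities: evaluate at an arbitrary follower state
      X <- matrix(0L, 1, net$n)
      X[, decomp$leaders] <- lead
      lam <- rbcme:::propensities_from_values(net$enc,
                                              rbcme:::state_values(net, X))
      list(rate = sum(lam[ctx$groups[[gkey]]]),
           bound = sum(lam[ctx$groups[[gkey]]]), J = NULL, i = 0L)
    } else {
      jm <- rbcme:::ctx_jump(ctx, gkey, lead)
      J <- ctx$jump_list[[jm$pos]]
      cs <- Matrix::colSums(J)
      list(rate = sum(cs * q[[jm$i]]), bound = max(cs), J = J, i = jm$i)
    }
  }
  t <- 0
  repeat {
    info <- lapply(gkeys, group_rate, lead = lead)
    M <- sum(vapply(info, `[[`, 0, "bound"))
    if (M <= 0) break
    dt <- rexp(1, M)
    if (t + dt >= t_end) dt <- t_end - t
    ## propagate all filters under the no-jump condition over (t, t+dt]
    for (i in seq_len(ctx$nsub)) {
      g <- rbcme:::ctx_gen(ctx, i, lead)
      res <- rbcme:::cpp_filter_path(q[[i]], ctx$gen_list, g, dt,
                                     list(), 0L, 1e-10, ctx$block[i])
      q[[i]] <- res$v
    }
    t <- t + dt
    if (t >= t_end) break
    rates <- vapply(gkeys, function(k) group_rate(k, lead)$rate, 0)
    if (runif(1) * M > sum(rates)) next          # thinned proposal
    gk <- sample(gkeys, 1L, prob = rates)
    info_g <- group_rate(gk, lead)
    if (info_g$i > 0L) {
      v <- as.numeric(info_g$J %*% q[[info_g$i]])
      q[[info_g$i]] <- v / sum(v)
    }
    lead <- lead + as.integer(strsplit(gk, ",", fixed = TRUE)[[1L]])
  }
  list(leader_state = lead, filters = q)
}

## assemble thinning particles into an rbcme_rb_estimate-compatible object
rb_thinning_solve <- function(net, decomp, t, N, seed) {
  set.seed(seed)
  parts <- lapply(seq_len(N), function(p) rb_thinning_particle(net, decomp, t))
  ctx <- rbcme:::filter_context(net, decomp, NULL)
  structure(list(
    leader_states = do.call(rbind, lapply(parts, `[[`, "leader_state")),
    filters = lapply(parts, `[[`, "filters"),
    weights = rep(1 / N, N), N = N, decomp = decomp, t = t,
    species = net$species_names, spaces = ctx$spaces),
    class = "rbcme_rb_estimate")
}

## dense joint probability vector (on the full truncation) of an RB estimate
## for small systems: groups particles by leader state and expands the
## conditional-independence product
rb_joint_dense <- function(est, net) {
  sp <- state_space(net)
  dec <- est$decomp
  p <- numeric(sp$size)
  st_idx <- function(x) rbcme:::space_index(sp, matrix(x, 1))
  for (j in seq_len(est$N)) {
    v <- est$filters[[j]][[1L]]
    if (length(dec$subsystems) > 1L)
      for (i in seq.int(2L, length(dec$subsystems)))
        v <- as.numeric(outer(v, est$filters[[j]][[i]]))
    ## v is over follower coords in subsystem order (fastest first); embed
    full <- numeric(sp$size)
    ford <- unlist(dec$subsystems)
    stf <- do.call(expand.grid, lapply(ford, function(i)
      0:(net$species[[i]]$size - 1L)))
    X <- matrix(0L, nrow(stf), net$n)
    X[, ford] <- as.matrix(stf)
    if (length(dec$leaders))
      X[, dec$leaders] <- rep(est$leader_states[j, ], each = nrow(stf))
    idx <- rbcme:::space_index(sp, X)
    ok <- !is.na(idx)
    full[idx[ok]] <- v[ok]
    p <- p + est$weights[j] * full
  }
  p
}

## L1 distance between an exact filter posterior on the full toggle space
## (species order Ga, Gb, Pa, Pb) and a particle representation
toggle_joint_l1 <- function(exact_vec, space, ps, method, protein_size = 200L) {
  arr <- array(exact_vec, dim = space$sizes)
  total <- 0
  if (method == "rbpf") {
    lk <- paste(ps$leader_states[, 1], ps$leader_states[, 2])
    for (ga in 0:1) for (gb in 0:1) {
      grp <- which(lk == paste(ga, gb))
      truth <- arr[ga + 1, gb + 1, , ]
      if (!length(grp)) { total <- total + sum(truth); next }
      QA <- do.call(cbind, lapply(grp, function(j) ps$filters[[j]][[1]]))
      QB <- do.call(cbind, lapply(grp, function(j) ps$filters[[j]][[2]]))
      M <- QA %*% (ps$weights[grp] * t(QB))
      total <- total + sum(abs(M - truth))
    }
  } else {
    for (ga in 0:1) for (gb in 0:1) {
      sel <- ps$states[, "Ga"] == ga & ps$states[, "Gb"] == gb
      truth <- arr[ga + 1, gb + 1, , ]
      M <- matrix(0, protein_size, protein_size)
      if (any(sel)) {
        idx <- cbind(pmin(ps$states[sel, "Pa"], protein_size - 1L) + 1L,
                     pmin(ps$states[sel, "Pb"], protein_size - 1L) + 1L)
        for (k in seq_len(nrow(idx)))
          M[idx[k, 1], idx[k, 2]] <- M[idx[k, 1], idx[k, 2]] + ps$weights[sel][k]
      }
      total <- total + sum(abs(M - truth))
    }
  }
  total
}

## deterministic little birth-death network: 0 -> X (k), X -> 0 (gamma)
make_birth_death <- function(k = 2, gamma = 1, size = 30L, x0 = 0L) {
  reaction_network(
    list(species("X", size = size)),
    list(reaction(products = c(X = 1L), propensity = mass_action(k)),
         reaction(reactants = c(X = 1L), propensity = mass_action(gamma))),
    init = init_point(c(X = x0)))
}
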