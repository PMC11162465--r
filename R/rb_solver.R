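#' Rao-Blackwellized CME solver
#'
#' Solves the CME by the divide-and-conquer estimator: simulate `N` full
#' trajectories, keep only the leader paths, solve each follower subsystem's
#' filtered CME along every path, and combine
#' \deqn{\hat p(t, \tilde x, z_1,\dots,z_l) = \frac1N \sum_j
#'   1(\tilde x_j(t)=\tilde x)\prod_i q_j^i(t, z_i).}
#' With an all-leader decomposition this reduces to plain Monte Carlo; with a
#' single all-follower subsystem it reduces to the (renormalized) FSP
#' solution.
#'
#' @param network A [reaction_network()].
#' @param decomp An `rbcme_decomposition` satisfying C1-C2.
#' @param t Solution time.
#' @param N Number of simulated leader paths (particles).
#' @param seed Integer master seed.
#' @param theta Named parameter vector if needed.
#' @param filter_tol Per-segment series tolerance of the filtered-FSP
#'   exponential action; the truncation drops only nonnegative tail mass
#'   that renormalization absorbs, and accumulates far below the Monte
#'   Carlo error at the default.
#' @return An `rbcme_rb_estimate`: `leader_states` (N x n_leaders),
#'   `filters` (per particle, per subsystem probability vectors at `t`),
#'   `weights`, `decomp`, `t`.
#' @export
rb_cme_solve <- function(network, decomp, t, N, seed = NULL, theta = NULL,
                         filter_tol = 1e-7) {
  chk <- check_conditions(network, decomp)
  if (!chk$C1$ok || !chk$C2$ok)
    stop("decomposition violates C1/C2; RB solver would be biased")
  if (!is.null(seed)) set.seed(seed)
  ctx <- filter_context(network, decomp, theta)
  th <- ctx$theta
  nl <- length(decomp$leaders)
  X0 <- init_sample(network, N)
  leader_states <- matrix(0L, N, nl)
  filters <- vector("list", N)
  nfail <- 0L
  for (p in seq_len(N)) {
    sim <- cpp_ssa(network$enc, as.integer(X0[p, ]), th, 0, t, 1e7L)
    traj <- list(times = sim$times, states = sim$states, rxn = sim$rxn,
                 x0 = as.integer(X0[p, ]), t0 = 0, t_end = t)
    lpath <- leader_path(traj, decomp$leaders)
    leader_states[p, ] <- if (nl) lpath$seg_states[nrow(lpath$seg_states), ]
                          else integer(0)
    fl <- vector("list", ctx$nsub)
    ok <- TRUE
    for (i in seq_len(ctx$nsub)) {
      v0 <- follower_init(ctx, i, traj$x0[decomp$leaders])
      res <- tryCatch(filter_path_run(ctx, lpath, i, v0, tol = filter_tol),
                      rbcme_zero_mass = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      fl[[i]] <- res[[length(res)]]$prob
    }
    if (!ok) { nfail <- nfail + 1L; filters[p] <- list(NULL); next }
    filters[[p]] <- fl
  }
  if (nfail > N / 2) stop("follower filters failed on more than half the particles")
  keep <- !vapply(filters, is.null, TRUE)
  structure(list(leader_states = leader_states[keep, , drop = FALSE],
                 filters = filters[keep],
                 weights = rep(1 / sum(keep), sum(keep)),
                 N = sum(keep), decomp = decomp, t = t,
                 species = network$species_names,
                 spaces = ctx$spaces),
            class = "rbcme_rb_estimate")
}

#' Plain Monte Carlo CME estimate
#'
#' Simulates `N` full SSA trajectories and returns the empirical distribution
#' at time `t`: the baseline the RB-CME solver is compared against (and the
#' limit of [rb_cme_solve()] under the all-leader decomposition).
#'
#' @inheritParams rb_cme_solve
#' @return A probability table (`data.frame`), as [empirical_distribution()].
#' @export
mc_cme_solve <- function(network, t, N, seed = NULL, theta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- resolve_theta(network, theta)
  X0 <- init_sample(network, N)
  Xf <- cpp_ssa_final(network$enc, X0, th, 0, t, 1e7L)
  colnames(Xf) <- network$species_names
  empirical_distribution(Xf)
}

#' @export
print.rbcme_rb_estimate <- function(x, ...) {
  cat("RB-CME estimate at t =", x$t, "from", x$N, "leader paths;",
      length(x$decomp$subsystems), "follower subsystem(s)\n")
  invisible(x)
}

#' Marginal probability tables from an RB estimate
#'
#' Leader marginals are weighted empirical distributions of the kept paths;
#' follower-subsystem marginals are weighted averages of the conditional
#' filters; joints across blocks use the conditional-independence product
#' within each particle (so cross-subsystem correlations induced by the
#' leader path are retained).
#'
#' @param estimate An `rbcme_rb_estimate`.
#' @param components Species names (or indices) to marginalize onto.  Each
#'   component must be a leader or a follower; follower components may span
#'   several subsystems.
#' @return A probability table (`data.frame` with one column per component
#'   plus `prob`).
#' @export
marginalize <- function(estimate, components) {
  if (is.character(components)) components <- match(components, estimate$species)
  stopifnot(!anyNA(components))
  dec <- estimate$decomp
  lead_sel <- intersect(components, dec$leaders)
  subs_sel <- lapply(seq_along(dec$subsystems), function(i)
    intersect(components, dec$subsystems[[i]]))
  active <- which(vapply(subs_sel, length, 0L) > 0L)
  N <- estimate$N
  w <- estimate$weights
  ## leader part: observed value rows per particle
  lead_cols <- match(lead_sel, dec$leaders)
  if (length(active) == 0L) {
    df <- empirical_distribution(estimate$leader_states[, lead_cols, drop = FALSE],
                                 species = estimate$species[lead_sel])
    return(df)
  }
  ## follower part: per-particle marginal vectors per active subsystem
  margs <- lapply(active, function(i) {
    keep <- match(subs_sel[[i]], dec$subsystems[[i]])
    lapply(seq_len(N), function(p)
      as.numeric(space_marginalize(estimate$spaces[[i]],
                                   estimate$filters[[p]][[i]], keep)))
  })
  sub_dims <- lapply(active, function(i) {
    keep <- match(subs_sel[[i]], dec$subsystems[[i]])
    estimate$spaces[[i]]$sizes[keep]
  })
  ## group particles by the selected leader values
  lk <- if (length(lead_sel))
    do.call(paste, c(as.data.frame(estimate$leader_states[, lead_cols, drop = FALSE]),
                     sep = ",")) else rep("", N)
  out <- list()
  for (u in unique(lk)) {
    grp <- which(lk == u)
    acc <- 0
    for (p in grp) {
      v <- margs[[1L]][[p]]
      if (length(active) > 1L)
        for (a in seq.int(2L, length(active))) v <- as.numeric(outer(v, margs[[a]][[p]]))
      acc <- acc + w[p] * v
    }
    g <- do.call(expand.grid, lapply(unlist(sub_dims), function(s) seq.int(0L, s - 1L)))
    df <- as.data.frame(g)
    names(df) <- estimate$species[unlist(subs_sel[active])]
    if (length(lead_sel)) {
      lv <- as.integer(strsplit(u, ",", fixed = TRUE)[[1L]])
      for (k in seq_along(lead_sel))
        df[[estimate$species[lead_sel[k]]]] <- lv[k]
    }
    df$prob <- acc
    out[[length(out) + 1L]] <- df
  }
  df <- do.call(rbind, out)
  df <- df[df$prob > 0, c(estimate$species[sort(components)], "prob"), drop = FALSE]
  ## collapse duplicated states (possible when leader groups share rows)
  key <- do.call(paste, c(df[setdiff(names(df), "prob")], sep = ","))
  agg <- rowsum(df$prob, key)
  first <- match(rownames(agg), key)
  res <- df[first, , drop = FALSE]
  res$prob <- as.numeric(agg)
  res <- res[order(-res$prob), , drop = FALSE]
  rownames(res) <- NULL
  res
}
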