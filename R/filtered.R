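## ---------------------------------------------------------------------------
## Filtered CME: conditional distributions of follower subsystems given a
## leader trajectory, solved by the filtered FSP.  Between leader jumps each
## subsystem's conditional evolves by its own sub-CME at the frozen leader
## state, corrected by conditioning on "no leader jump occurred" (a decay
## term Lambda_i(z) = sum of leader-jump propensities that depend on z_i,
## folded into the generator diagonal).  At a leader jump with net change
## Delta, Bayes' rule reweights (and possibly shifts) the conditional by the
## propensities of the reactions matching Delta.
## ---------------------------------------------------------------------------

## Precomputed filtering context for a (network, decomposition, theta) triple.
filter_context <- function(network, decomp, theta = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$net <- network
  ctx$decomp <- decomp
  ctx$theta <- resolve_theta(network, theta)
  n <- network$n
  ctx$nsub <- length(decomp$subsystems)
  ctx$comps <- reaction_components(network)
  ctx$keys <- leader_change_key(network, decomp$leaders)
  ctx$nz <- vapply(seq_len(network$r), function(j)
    any(network$zeta[decomp$leaders, j] != 0L), TRUE)
  ctx$spaces <- lapply(decomp$subsystems, function(m) state_space(network, m))
  ctx$states <- lapply(ctx$spaces, space_states)
  ## parameter pseudo-species are static, so a subsystem whose trailing
  ## members are all parameters has a block-diagonal generator: record the
  ## dynamic-block size for the blocked exponential action
  ctx$block <- vapply(decomp$subsystems, function(mem) {
    is_par <- vapply(network$species[mem], function(s) isTRUE(s$is_param), TRUE)
    if (!any(is_par)) return(0L)
    if (is.unsorted(is_par)) return(0L)      # a dynamic member after a static one
    sizes <- vapply(network$species[mem], `[[`, 0L, "size")
    as.integer(prod(sizes[!is_par]))
  }, 0L)
  dep_leaders <- function(j)
    intersect(ctx$comps[[j]], decomp$leaders)
  ctx$internal <- vector("list", ctx$nsub)
  ctx$lam_rxns <- vector("list", ctx$nsub)
  ctx$rel_gen <- vector("list", ctx$nsub)
  for (i in seq_len(ctx$nsub)) {
    mem <- decomp$subsystems[[i]]
    chg_mem <- vapply(seq_len(network$r), function(j)
      any(network$zeta[mem, j] != 0L), TRUE)
    dep_mem <- vapply(seq_len(network$r), function(j) {
      d <- network$enc$dep[[j]]
      any(mem %in% d[d <= n])
    }, TRUE)
    ctx$internal[[i]] <- which(chg_mem & !ctx$nz)
    ctx$lam_rxns[[i]] <- which(ctx$nz & dep_mem)
    rel <- unique(unlist(lapply(c(ctx$internal[[i]], ctx$lam_rxns[[i]]), function(j) {
      d <- network$enc$dep[[j]]
      intersect(d[d <= n], decomp$leaders)
    })))
    ctx$rel_gen[[i]] <- sort(as.integer(rel %||% integer(0)))
  }
  ## leader-jump groups keyed by the leader net-change
  grp_keys <- unique(ctx$keys[ctx$nz])
  ctx$groups <- lapply(grp_keys, function(key) which(ctx$keys == key & ctx$nz))
  names(ctx$groups) <- grp_keys
  sub_of <- integer(n)
  for (i in seq_len(ctx$nsub)) sub_of[decomp$subsystems[[i]]] <- i
  ctx$sub_of <- sub_of
  ctx$grp_sub <- vapply(ctx$groups, function(grp) {
    tt <- unique(unlist(lapply(grp, function(j) {
      cc <- ctx$comps[[j]]; unique(sub_of[cc][sub_of[cc] > 0L])
    })))
    if (length(tt) > 1L) stop("decomposition violates C2")
    if (length(tt)) tt else 0L
  }, 0L)
  ctx$grp_rel <- lapply(ctx$groups, function(grp)
    sort(unique(unlist(lapply(grp, dep_leaders)))))
  ctx$rxn_key <- ctx$keys                     # per reaction
  ctx$gen_list <- list(); ctx$gen_pos <- new.env(parent = emptyenv())
  ctx$jump_list <- list(); ctx$jump_pos <- new.env(parent = emptyenv())
  ctx
}

## full-state template: members vary over the subsystem space, leaders frozen
ctx_values <- function(ctx, i, leader_state) {
  net <- ctx$net
  Si <- ctx$spaces[[i]]$size
  X <- matrix(0L, Si, net$n)
  X[, ctx$decomp$subsystems[[i]]] <- ctx$states[[i]]
  if (length(ctx$decomp$leaders))
    X[, ctx$decomp$leaders] <- rep(as.integer(leader_state), each = Si)
  W <- state_values(net, X, if (net$enc$ntheta) ctx$theta else NULL)
  W
}

## generator (with no-jump correction on the diagonal) for subsystem i at a
## frozen leader state; cached on the relevant leader coordinates
ctx_gen <- function(ctx, i, leader_state) {
  rel <- ctx$rel_gen[[i]]
  lv <- leader_state[match(rel, ctx$decomp$leaders)]
  key <- paste(i, paste(lv, collapse = ","), sep = "|")
  pos <- ctx$gen_pos[[key]]
  if (!is.null(pos)) return(pos)
  net <- ctx$net
  sp <- ctx$spaces[[i]]
  Si <- sp$size
  W <- ctx_values(ctx, i, leader_state)
  L <- propensities_from_values(net$enc, W)
  mem <- ctx$decomp$subsystems[[i]]
  src <- list(); dst <- list(); val <- list()
  outflow <- numeric(Si)
  for (j in ctx$internal[[i]]) {
    lam <- L[, j]
    act <- which(lam > 0)
    if (!length(act)) next
    z <- net$zeta[mem, j]
    to <- sweep(ctx$states[[i]][act, , drop = FALSE], 2L, -z)
    ti <- space_index(sp, to)
    inside <- !is.na(ti)
    src[[length(src) + 1L]] <- act[inside]
    dst[[length(dst) + 1L]] <- ti[inside]
    val[[length(val) + 1L]] <- lam[act][inside]
    outflow[act] <- outflow[act] + lam[act]     # boundary leak is lost mass
  }
  corr <- numeric(Si)
  for (j in ctx$lam_rxns[[i]]) corr <- corr + L[, j]
  Q <- Matrix::sparseMatrix(i = c(unlist(dst), seq_len(Si)),
                            j = c(unlist(src), seq_len(Si)),
                            x = c(unlist(val), -(outflow + corr)),
                            dims = c(Si, Si))
  Q <- methods::as(Q, "CsparseMatrix")
  ctx$gen_list[[length(ctx$gen_list) + 1L]] <- Q
  ctx$gen_pos[[key]] <- length(ctx$gen_list)
  length(ctx$gen_list)
}

## Bayes jump-update matrix for subsystem i and leader net-change group
## `gkey`, evaluated at the pre-jump leader state; NULL when the update is
## proportional to the identity (subsystem untouched)
ctx_jump <- function(ctx, gkey, leader_state_pre) {
  i <- ctx$grp_sub[[gkey]]
  if (i == 0L) return(NULL)
  rel <- ctx$grp_rel[[gkey]]
  lv <- leader_state_pre[match(rel, ctx$decomp$leaders)]
  key <- paste(gkey, paste(lv, collapse = ","), sep = "|")
  pos <- ctx$jump_pos[[key]]
  if (!is.null(pos)) return(list(i = i, pos = pos))
  net <- ctx$net
  sp <- ctx$spaces[[i]]
  Si <- sp$size
  W <- ctx_values(ctx, i, leader_state_pre)
  L <- propensities_from_values(net$enc, W)
  mem <- ctx$decomp$subsystems[[i]]
  J <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(Si, Si))
  for (j in ctx$groups[[gkey]]) {
    lam <- L[, j]
    z <- net$zeta[mem, j]
    if (all(z == 0L)) {
      J <- J + Matrix::Diagonal(Si, lam)
    } else {
      act <- which(lam > 0)
      if (!length(act)) next
      to <- sweep(ctx$states[[i]][act, , drop = FALSE], 2L, -z)
      ti <- space_index(sp, to)
      inside <- !is.na(ti)
      J <- J + Matrix::sparseMatrix(i = ti[inside], j = act[inside],
                                    x = lam[act][inside], dims = c(Si, Si))
    }
  }
  J <- methods::as(J, "CsparseMatrix")
  ctx$jump_list[[length(ctx$jump_list) + 1L]] <- J
  ctx$jump_pos[[key]] <- length(ctx$jump_list)
  list(i = i, pos = length(ctx$jump_list))
}

## initial conditional of subsystem i given the leader initial state
follower_init <- function(ctx, i, leader_state0) {
  net <- ctx$net
  sp <- ctx$spaces[[i]]
  if (net$init$kind == "product") {
    p <- init_vector(net, sp)
  } else {
    keep <- rep(TRUE, nrow(net$init$states))
    if (length(ctx$decomp$leaders))
      keep <- apply(net$init$states[, ctx$decomp$leaders, drop = FALSE], 1L,
                    function(rw) all(rw == leader_state0))
    p <- numeric(sp$size)
    idx <- space_index(sp, net$init$states[keep, sp$members, drop = FALSE])
    pr <- net$init$prob[keep]
    ok <- !is.na(idx)
    for (k in which(ok)) p[idx[k]] <- p[idx[k]] + pr[k]
  }
  if (sum(p) <= 0) stop("initial distribution has no mass on the subsystem truncation")
  p / sum(p)
}

## extract the leader path from a full-system SSA trajectory
leader_path <- function(traj, leaders, keys = NULL) {
  L <- length(leaders)
  if (L == 0L) {
    return(list(t0 = traj$t0, t_end = traj$t_end, times = numeric(0),
                rxn = integer(0), seg_states = matrix(integer(0), 1L, 0L)))
  }
  lead0 <- traj$x0[leaders]
  if (length(traj$times) == 0L) {
    return(list(t0 = traj$t0, t_end = traj$t_end, times = numeric(0),
                rxn = integer(0),
                seg_states = matrix(lead0, 1L, L, byrow = TRUE)))
  }
  lst <- traj$states[, leaders, drop = FALSE]
  prev <- rbind(lead0, lst[-nrow(lst), , drop = FALSE])
  jump <- rowSums(lst != prev) > 0
  seg_states <- rbind(lead0, lst[jump, , drop = FALSE])
  list(t0 = traj$t0, t_end = traj$t_end,
       times = traj$times[jump], rxn = traj$rxn[jump],
       seg_states = seg_states)
}

## run subsystem i's filter along a leader path; returns snapshots at
## query_times (plus the final time) as probability vectors + log-normalizer
filter_path_run <- function(ctx, lpath, i, v0, query_times = numeric(0),
                            tol = 1e-10) {
  nseg <- length(lpath$times) + 1L
  bounds <- c(lpath$t0, lpath$times, lpath$t_end)
  gidx <- integer(nseg); jidx <- integer(nseg)
  for (s in seq_len(nseg)) {
    gidx[s] <- ctx_gen(ctx, i, lpath$seg_states[s, ])
    if (s < nseg) {
      gkey <- ctx$rxn_key[lpath$rxn[s]]
      jm <- ctx_jump(ctx, gkey, lpath$seg_states[s, ])
      jidx[s] <- if (!is.null(jm) && jm$i == i) jm$pos else 0L
    }
  }
  qt <- sort(unique(query_times))
  v <- v0; logw <- 0
  out <- vector("list", length(qt) + 1L)
  cut_prev <- lpath$t0
  seg_ptr <- 1L
  run_until <- function(tcut) {
    ## advance through segments until tcut, splitting the current segment
    g <- integer(0); d <- numeric(0); jj <- integer(0)
    t_here <- cut_prev
    while (seg_ptr <= nseg && bounds[seg_ptr + 1L] <= tcut + 1e-12) {
      g <- c(g, gidx[seg_ptr]); d <- c(d, bounds[seg_ptr + 1L] - t_here)
      jj <- c(jj, jidx[seg_ptr])
      t_here <- bounds[seg_ptr + 1L]
      seg_ptr <<- seg_ptr + 1L
    }
    if (seg_ptr <= nseg && tcut > t_here + 1e-12) {
      g <- c(g, gidx[seg_ptr]); d <- c(d, tcut - t_here); jj <- c(jj, 0L)
    }
    cut_prev <<- tcut
    if (!length(g)) return(invisible())
    ## merge consecutive segments sharing a generator when no jump matrix
    ## applies to this subsystem in between (identity updates drop out)
    if (length(g) > 1L) {
      len <- 1L
      for (s in seq.int(2L, length(g))) {
        if (jj[len] == 0L && g[len] == g[s]) {
          d[len] <- d[len] + d[s]; jj[len] <- jj[s]
        } else {
          len <- len + 1L
          g[len] <- g[s]; d[len] <- d[s]; jj[len] <- jj[s]
        }
      }
      g <- g[seq_len(len)]; d <- d[seq_len(len)]; jj <- jj[seq_len(len)]
    }
    res <- cpp_filter_path(v, ctx$gen_list, g, d, ctx$jump_list, jj, tol,
                           ctx$block[i])
    if (!isTRUE(res$ok))
      stop(structure(class = c("rbcme_zero_mass", "error", "condition"),
                     list(message = "follower filter mass annihilated",
                          call = sys.call(-1))))
    v <<- res$v; logw <<- logw + res$logw
    invisible()
  }
  for (k in seq_along(qt)) {
    run_until(qt[k])
    out[[k]] <- list(t = qt[k], prob = v, log_norm = logw)
  }
  run_until(lpath$t_end)
  out[[length(qt) + 1L]] <- list(t = lpath$t_end, prob = v, log_norm = logw)
  out
}

#' Follower filter: the conditional law of one subsystem
#'
#' @param decomp An `rbcme_decomposition`.
#' @param i Subsystem index.
#' @param prob Probability vector on the subsystem truncation.
#' @param time Current time.
#' @param log_norm Accumulated log-normalizer (survival/jump mass).
#' @export
follower_filter <- function(decomp, i, prob, time = 0, log_norm = 0) {
  stopifnot(i >= 1L, i <= length(decomp$subsystems),
            abs(sum(prob) - 1) < 1e-6, all(prob >= 0))
  structure(list(subsystem = i, prob = prob / sum(prob), time = time,
                 log_norm = log_norm),
            class = "rbcme_follower_filter")
}

#' Propagate a follower filter over a jump-free leader interval
#'
#' Integrates the subsystem's conditional distribution over `(t, t+dt]` while
#' the leader stays at `leader_state`: the sub-CME prediction over reactions
#' internal to the subsystem, combined with the correction for the event that
#' no leader jump occurred (exponential reweighting by the z-dependent leader
#' jump intensity), then renormalized.  The log of the surviving mass is
#' accumulated in the filter's `log_norm`.
#'
#' @param filter An [follower_filter()].
#' @param network,decomp The network and decomposition.
#' @param leader_state Integer leader state (constant over the interval).
#' @param dt Interval length.
#' @param theta Parameters, if the network has free parameters.
#' @export
filtered_propagate <- function(filter, network, decomp, leader_state, dt,
                               theta = NULL) {
  ctx <- filter_context(network, decomp, theta)
  g <- ctx_gen(ctx, filter$subsystem, leader_state)
  res <- cpp_filter_path(filter$prob, ctx$gen_list, g, dt, list(), 0L, 1e-10)
  if (!isTRUE(res$ok)) stop("follower filter mass annihilated")
  follower_filter(decomp, filter$subsystem, res$v, filter$time + dt,
                  filter$log_norm + res$logw)
}

#' Bayes update of a follower filter at a leader jump
#'
#' Applies the jump correction for an observed leader net change:
#' \eqn{\pi'(z) \propto \sum_j \lambda_j(\tilde x^-, z-\zeta_j^{Z_i})
#' \pi(z-\zeta_j^{Z_i})} over the reactions matching the leader net change.
#' Subsystems not involved in the matching reactions are unchanged.
#'
#' @inheritParams filtered_propagate
#' @param pre_jump_leader_state Leader state just before the jump.
#' @param leader_net_change Integer net change of the leader coordinates.
#' @export
filtered_jump_update <- function(filter, network, decomp,
                                 pre_jump_leader_state, leader_net_change,
                                 theta = NULL) {
  ctx <- filter_context(network, decomp, theta)
  gkey <- paste(as.integer(leader_net_change), collapse = ",")
  if (!gkey %in% names(ctx$groups))
    stop("leader_net_change matches no reaction's leader net change")
  jm <- ctx_jump(ctx, gkey, pre_jump_leader_state)
  if (is.null(jm) || jm$i != filter$subsystem) return(filter)
  J <- ctx$jump_list[[jm$pos]]
  v <- as.numeric(J %*% filter$prob)
  m <- sum(v)
  if (m <= 1e-300)
    stop(structure(class = c("rbcme_zero_mass", "error", "condition"),
                   list(message = "jump impossible under the current filter",
                        call = sys.call())))
  follower_filter(decomp, filter$subsystem, v / m, filter$time,
                  filter$log_norm + log(m))
}

#' Solve all follower filters along a leader trajectory
#'
#' Alternates [filtered_propagate()] and [filtered_jump_update()] along a
#' piecewise-constant leader path extracted from a full-system trajectory,
#' returning per-subsystem conditional distributions at the query times.
#'
#' @param network,decomp Network and decomposition (C1-C2 must hold).
#' @param traj A full-system `rbcme_trajectory` (its leader coordinates
#'   define the path).
#' @param query_times Times at which snapshots are requested (default: the
#'   trajectory end time).
#' @param theta Parameters, if needed.
#' @return A list over subsystems; each element is a list over query times of
#'   [follower_filter()] snapshots.
#' @export
filter_along_trajectory <- function(network, decomp, traj,
                                    query_times = NULL, theta = NULL) {
  ctx <- filter_context(network, decomp, theta)
  lpath <- leader_path(traj, decomp$leaders)
  if (is.null(query_times)) query_times <- numeric(0)
  lapply(seq_len(ctx$nsub), function(i) {
    v0 <- follower_init(ctx, i, if (length(decomp$leaders)) traj$x0[decomp$leaders]
                                 else integer(0))
    snaps <- filter_path_run(ctx, lpath, i, v0, query_times)
    lapply(snaps, function(s)
      follower_filter(decomp, i, s$prob, s$t, s$log_norm))
  })
}
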