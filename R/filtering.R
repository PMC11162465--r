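## systematic resampling: lowest-variance standard scheme, deterministic
## given the RNG state; ties broken by particle index
systematic_resample <- function(w, N = length(w)) {
  u <- (stats::runif(1) + seq_len(N) - 1) / N
  findInterval(u, cumsum(w / sum(w))) + 1L
}

ess <- function(w) { w <- w / sum(w); 1 / sum(w^2) }

#' Exact stochastic filter by finite state projection
#'
#' Reference filter on a tractable truncation: alternates FSP prediction of
#' the CME between observation times with pointwise Bayes corrections by the
#' Gaussian observation likelihood.
#'
#' @param network A [reaction_network()].
#' @param space A [state_space()] over all species.
#' @param series An [obs_series()] carrying its [obs_model()].
#' @param theta Parameters if needed.
#' @param tol Exponential-action tolerance.
#' @return An `rbcme_filter_posterior` with `times`, per-time probability
#'   vectors (`posteriors`), `space` and per-step log marginal likelihood.
#' @export
exact_fsp_filter <- function(network, space = state_space(network), series,
                             theta = NULL, tol = 1e-10) {
  model <- series$model
  if (is.null(model)) stop("series must carry its observation model")
  gen <- build_generator(network, space, theta)
  Qs <- generator_with_sink(gen)
  st <- space_states(space)
  if (!identical(space$members, seq_len(network$n)))
    st <- st[, match(seq_len(network$n), space$members), drop = FALSE]
  colnames(st) <- network$species_names
  p <- init_vector(network, space)
  p <- p / sum(p)
  t_prev <- 0
  posteriors <- vector("list", length(series$times))
  loglik <- numeric(length(series$times))
  for (k in seq_along(series$times)) {
    dt <- series$times[k] - t_prev
    v <- cpp_expatv(Qs, c(p, 0), dt, tol)
    rho <- pmax(v[seq_len(space$size)], 0)
    lik <- gaussian_likelihood(model, series$values[k, ], st, network)
    post <- rho * lik
    m <- sum(post)
    if (m <= 0) stop("zero posterior mass after correction at t = ", series$times[k])
    loglik[k] <- log(m)
    p <- post / m
    posteriors[[k]] <- p
    t_prev <- series$times[k]
  }
  structure(list(times = series$times, posteriors = posteriors, space = space,
                 log_lik = loglik, method = "exact"),
            class = "rbcme_filter_posterior")
}

#' Bootstrap particle filter
#'
#' Sequential Monte Carlo with the SSA as proposal between observations,
#' Gaussian likelihood weighting, and systematic resampling when the
#' effective sample size drops below `N/2`.
#'
#' @inheritParams exact_fsp_filter
#' @param N Number of particles (>= 2).
#' @param seed Integer master seed.
#' @return An `rbcme_filter_posterior` whose per-time entries hold particle
#'   states and weights.
#' @export
bootstrap_pf <- function(network, series, N, seed = NULL, theta = NULL) {
  stopifnot(N >= 2)
  model <- series$model
  if (is.null(model)) stop("series must carry its observation model")
  if (!is.null(seed)) set.seed(seed)
  th <- resolve_theta(network, theta)
  X <- init_sample(network, N)
  colnames(X) <- network$species_names
  w <- rep(1 / N, N)
  t_prev <- 0
  posteriors <- vector("list", length(series$times))
  loglik <- numeric(length(series$times))
  for (k in seq_along(series$times)) {
    X <- cpp_ssa_final(network$enc, X, th, t_prev, series$times[k], 1e7L)
    colnames(X) <- network$species_names
    lik <- gaussian_likelihood(model, series$values[k, ], X, network)
    w2 <- w * lik
    if (sum(w2) <= 0) {                       # tempering fallback
      warning("all particle weights vanished at t = ", series$times[k],
              "; tempering the likelihood (power 1/2)")
      w2 <- w * sqrt(lik)
      if (sum(w2) <= 0) w2 <- w
    }
    loglik[k] <- log(sum(w2))
    w <- w2 / sum(w2)
    if (ess(w) < N / 2) {
      idx <- systematic_resample(w, N)
      X <- X[idx, , drop = FALSE]
      w <- rep(1 / N, N)
    }
    posteriors[[k]] <- list(states = X, weights = w)
    t_prev <- series$times[k]
  }
  structure(list(times = series$times, posteriors = posteriors,
                 log_lik = loglik, method = "pf",
                 species = network$species_names),
            class = "rbcme_filter_posterior")
}

## channel dependence analysis under a decomposition: leader-only or one
## follower subsystem (C3)
channel_blocks <- function(network, decomp, model) {
  lapply(model$channels, function(ch) {
    ii <- match(channel_species(ch), network$species_names)
    subs <- vapply(ii, function(i) {
      hit <- which(vapply(seq_along(decomp$subsystems), function(s)
        i %in% decomp$subsystems[[s]], TRUE))
      if (length(hit)) hit else 0L
    }, 0L)
    usub <- unique(subs[subs > 0L])
    if (length(usub) > 1L) stop("observation channel touches several follower subsystems (C3)")
    list(leaders = ii[subs == 0L],
         subsystem = if (length(usub)) usub else 0L,
         members = ii[subs > 0L])
  })
}

#' Rao-Blackwellized particle filter
#'
#' Particle filter whose prediction step is the RB-CME solver: each particle
#' carries a leader path and exact conditional filters for every follower
#' subsystem.  Between observations the leader path is advanced by simulating
#' the full system from a configuration drawn from the particle's current
#' conditionals (an exact draw of the leader path's conditional law; the
#' sampled follower configuration is discarded).  At an observation, each
#' channel's Gaussian likelihood is marginalized over the particle's follower
#' filters for the weight update, and the touched filters are reweighted by
#' the state likelihood (exact per-subsystem factorization under C3).
#'
#' @inheritParams bootstrap_pf
#' @param decomp An `rbcme_decomposition` satisfying C1-C3.
#' @param keep Either `"last"` (store the full particle representation only
#'   at the final time) or `"all"`.
#' @param filter_tol Per-segment series tolerance of the filtered-FSP
#'   exponential action (see [rb_cme_solve()]).
#' @return An `rbcme_filter_posterior`; entries hold leader states, follower
#'   filters and weights.
#' @export
rb_particle_filter <- function(network, decomp, series, N, seed = NULL,
                               theta = NULL, keep = c("last", "all"),
                               filter_tol = 1e-7) {
  keep <- match.arg(keep)
  model <- series$model
  if (is.null(model)) stop("series must carry its observation model")
  chk <- check_conditions(network, decomp, model)
  if (!chk$ok) stop("decomposition violates C1-C3")
  if (!is.null(seed)) set.seed(seed)
  ctx <- filter_context(network, decomp, theta)
  th <- ctx$theta
  nsub <- ctx$nsub
  nl <- length(decomp$leaders)
  blocks <- channel_blocks(network, decomp, model)
  X0 <- init_sample(network, N)
  Z <- X0[, decomp$leaders, drop = FALSE]
  filters <- lapply(seq_len(N), function(p)
    lapply(seq_len(nsub), function(i) follower_init(ctx, i, Z[p, ])))
  w <- rep(1 / N, N)
  t_prev <- 0
  nT <- length(series$times)
  posteriors <- vector("list", nT)
  loglik <- numeric(nT); ess_trace <- numeric(nT)
  ## per-channel likelihood vector over a subsystem's states at a frozen
  ## leader state (cached per observation time)
  lik_cache <- new.env(parent = emptyenv())
  chan_lik_vec <- function(kch, i, leader_state, y) {
    key <- paste(kch, paste(leader_state, collapse = ","), sep = "|")
    v <- lik_cache[[key]]
    if (!is.null(v)) return(v)
    Si <- ctx$spaces[[i]]$size
    X <- matrix(0L, Si, network$n)
    X[, decomp$subsystems[[i]]] <- ctx$states[[i]]
    if (nl) X[, decomp$leaders] <- rep(as.integer(leader_state), each = Si)
    colnames(X) <- network$species_names
    mdl <- obs_model(model$channels[kch], model$sigma[kch])
    v <- gaussian_likelihood(mdl, y[kch], X, network)
    lik_cache[[key]] <- v
    v
  }
  for (k in seq_len(nT)) {
    tk <- series$times[k]
    y <- series$values[k, ]
    rm(list = ls(lik_cache), envir = lik_cache)
    pre_filters <- filters; pre_w <- w
    lik_all <- numeric(N)
    for (p in seq_len(N)) {
      ## draw a follower configuration from the particle's conditionals
      x <- integer(network$n)
      x[decomp$leaders] <- Z[p, ]
      for (i in seq_len(nsub)) {
        q <- filters[[p]][[i]]
        idx <- sample.int(length(q), 1L, prob = q)
        x[decomp$subsystems[[i]]] <- ctx$states[[i]][idx, ]
      }
      sim <- cpp_ssa(network$enc, x, th, t_prev, tk, 1e7L)
      traj <- list(times = sim$times, states = sim$states, rxn = sim$rxn,
                   x0 = x, t0 = t_prev, t_end = tk)
      lpath <- leader_path(traj, decomp$leaders)
      ok <- TRUE
      newf <- vector("list", nsub)
      for (i in seq_len(nsub)) {
        res <- tryCatch(filter_path_run(ctx, lpath, i, filters[[p]][[i]],
                                        tol = filter_tol),
                        rbcme_zero_mass = function(e) NULL)
        if (is.null(res)) { ok <- FALSE; break }
        newf[[i]] <- res[[length(res)]]$prob
      }
      if (!ok) { lik_all[p] <- 0; next }
      if (nl) Z[p, ] <- lpath$seg_states[nrow(lpath$seg_states), ]
      ## correction
      lk <- 1
      for (kch in seq_along(blocks)) {
        b <- blocks[[kch]]
        if (b$subsystem == 0L) {
          xs <- matrix(0L, 1L, network$n,
                       dimnames = list(NULL, network$species_names))
          xs[, decomp$leaders] <- Z[p, ]
          mdl <- obs_model(model$channels[kch], model$sigma[kch])
          lk <- lk * gaussian_likelihood(mdl, y[kch], xs, network)
        } else {
          i <- b$subsystem
          lv <- chan_lik_vec(kch, i, if (nl) Z[p, ] else integer(0), y)
          num <- sum(newf[[i]] * lv)
          lk <- lk * num
          if (num > 0) newf[[i]] <- newf[[i]] * lv / num
        }
      }
      lik_all[p] <- lk
      filters[[p]] <- newf
    }
    w2 <- w * lik_all
    if (sum(w2) <= 0) {
      warning("all RB-PF weights vanished at t = ", tk,
              "; tempering the likelihood (power 1/2)")
      w2 <- pre_w * sqrt(lik_all)
      if (sum(w2) <= 0) w2 <- pre_w
    }
    loglik[k] <- log(sum(w2))
    w <- w2 / sum(w2)
    ess_trace[k] <- ess(w)
    if (ess(w) < N / 2) {
      idx <- systematic_resample(w, N)
      Z <- Z[idx, , drop = FALSE]
      filters <- filters[idx]
      w <- rep(1 / N, N)
    }
    if (keep == "all" || k == nT)
      posteriors[[k]] <- list(leader_states = Z, filters = filters, weights = w)
    t_prev <- tk
  }
  structure(list(times = series$times, posteriors = posteriors,
                 log_lik = loglik, ess = ess_trace, method = "rbpf",
                 decomp = decomp, species = network$species_names,
                 spaces = ctx$spaces),
            class = "rbcme_filter_posterior")
}

#' @export
print.rbcme_filter_posterior <- function(x, ...) {
  cat("Filter posterior (", x$method, "): ", length(x$times),
      " observation times\n", sep = "")
  invisible(x)
}

#' Marginal posterior of one species at an observation time
#'
#' @param posterior An `rbcme_filter_posterior`.
#' @param k Observation-time index.
#' @param species Species name.
#' @return Probability table `data.frame` (`value`, `prob`).
#' @export
posterior_marginal <- function(posterior, k, species) {
  ps <- posterior$posteriors[[k]]
  if (is.null(ps)) stop("posterior at time index ", k, " was not stored")
  if (posterior$method == "exact") {
    sp <- posterior$space
    i <- match(species, sp$names)
    m <- as.numeric(space_marginalize(sp, ps, i))
    return(data.frame(value = seq.int(0L, sp$sizes[i] - 1L), prob = m))
  }
  if (posterior$method == "pf") {
    x <- ps$states[, species]
    agg <- rowsum(ps$weights, x)
    return(data.frame(value = as.integer(rownames(agg)),
                      prob = as.numeric(agg) / sum(ps$weights)))
  }
  ## rbpf
  dec <- posterior$decomp
  i <- match(species, posterior$species)
  if (i %in% dec$leaders) {
    x <- ps$leader_states[, match(i, dec$leaders)]
    agg <- rowsum(ps$weights, x)
    return(data.frame(value = as.integer(rownames(agg)),
                      prob = as.numeric(agg) / sum(ps$weights)))
  }
  s <- which(vapply(dec$subsystems, function(m) i %in% m, TRUE))
  keep <- match(i, dec$subsystems[[s]])
  acc <- 0
  for (p in seq_along(ps$weights))
    acc <- acc + ps$weights[p] *
      as.numeric(space_marginalize(posterior$spaces[[s]], ps$filters[[p]][[s]], keep))
  data.frame(value = seq.int(0L, posterior$spaces[[s]]$sizes[keep] - 1L),
             prob = acc / sum(ps$weights))
}
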