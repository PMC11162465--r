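#' Exact stochastic simulation (Gillespie direct method)
#'
#' Draws one statistically exact trajectory of the continuous-time Markov
#' chain defined by the network, using cumulative-sum channel selection.
#' Trajectories are stored event-sparse (jump times and post-jump states);
#' values on a time grid are obtained with [trajectory_states()].
#'
#' @param network A [reaction_network()].
#' @param theta Named parameter vector (if the network declares parameters).
#' @param x0 Initial state (default: one draw from the network's initial
#'   distribution).
#' @param t0,t_end Simulation interval.
#' @param seed Integer seed; each call derives its own RNG stream.
#' @param max_events Safety cap on the number of reaction firings.
#' @return An `rbcme_trajectory`: `times`, `states` (events x n, state after
#'   each jump), `x0`, `t0`, `t_end`, `seed`.
#' @export
ssa_simulate <- function(network, theta = NULL, x0 = NULL, t0 = 0, t_end,
                         seed = NULL, max_events = 1e7L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- as.integer(init_sample(network, 1L))
  stopifnot(length(x0) == network$n, all(x0 >= 0))
  th <- resolve_theta(network, theta)
  sim <- cpp_ssa(network$enc, as.integer(x0), th, t0, t_end, as.integer(max_events))
  structure(list(times = sim$times, states = sim$states, rxn = sim$rxn,
                 x0 = as.integer(x0), x_final = sim$x_final,
                 t0 = t0, t_end = t_end, seed = seed,
                 species = network$species_names),
            class = "rbcme_trajectory")
}

#' @export
print.rbcme_trajectory <- function(x, ...) {
  cat("SSA trajectory:", length(x$times), "events on [", x$t0, ",", x$t_end, "]\n")
  invisible(x)
}

#' States of a trajectory at given times
#'
#' @param traj An `rbcme_trajectory`.
#' @param times Query times within the trajectory span.
#' @return Integer matrix (length(times) x n); the trajectory is
#'   right-continuous and piecewise constant.
#' @export
trajectory_states <- function(traj, times) {
  stopifnot(all(times >= traj$t0 - 1e-12), all(times <= traj$t_end + 1e-12))
  k <- findInterval(times, traj$times)
  out <- matrix(traj$x0, length(times), length(traj$x0), byrow = TRUE)
  nz <- k > 0
  if (any(nz)) out[nz, ] <- traj$states[k[nz], , drop = FALSE]
  colnames(out) <- traj$species
  out
}

#' Empirical distribution of an ensemble at a time
#'
#' Tabulates the states of many trajectories (or a matrix of sampled states)
#' at time `t` into a sparse probability table; the plain Monte Carlo CME
#' estimate.
#'
#' @param trajectories List of `rbcme_trajectory`, or an integer state matrix
#'   (samples x species).
#' @param t Query time (ignored for a state matrix).
#' @param species Column names when a matrix is supplied.
#' @return A `data.frame` probability table: one column per species plus
#'   `prob`; probabilities sum to exactly 1.
#' @export
empirical_distribution <- function(trajectories, t = NULL, species = NULL) {
  if (is.matrix(trajectories)) {
    X <- trajectories
    if (!is.null(species)) colnames(X) <- species
  } else {
    if (length(trajectories) == 0L) stop("empty trajectory list")
    X <- do.call(rbind, lapply(trajectories, trajectory_states, times = t))
  }
  key <- do.call(paste, c(as.data.frame(X), sep = ","))
  tab <- table(key)
  uk <- names(tab)
  first <- match(uk, key)
  df <- as.data.frame(X[first, , drop = FALSE])
  df$prob <- as.numeric(tab) / nrow(X)
  df <- df[order(-df$prob), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate noisy observations from a trajectory
#'
#' Evaluates the observation model's ideal readout \eqn{h(X(t_i))} along the
#' trajectory and adds independent Gaussian noise per channel.
#'
#' @param traj An `rbcme_trajectory`.
#' @param model An [obs_model()].
#' @param times Observation times within the trajectory span.
#' @param network The network the trajectory was simulated from.
#' @param seed Optional integer seed.
#' @return An [obs_series()].
#' @export
generate_observations <- function(traj, model, times, network, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- trajectory_states(traj, times)
  V <- state_values(network, X)
  colnames(V) <- c(network$species_names, network$param_names)
  Y <- matrix(0, length(times), length(model$channels))
  for (k in seq_along(model$channels)) {
    h <- channel_h(model$channels[[k]], V)
    Y[, k] <- h + model$sigma[k] * stats::rnorm(length(times))
  }
  obs_series(times, Y, model)
}

#' Monte Carlo L1 pre-convergence factor
#'
#' For the empirical-distribution estimator with N samples, the expected L1
#' error converges as \eqn{c/\sqrt{N}} where the pre-convergence factor c lies
#' in \eqn{\sqrt{2/\pi}\,[\sum_x \sqrt{p(x)} - 1,\ \sum_x \sqrt{p(x)} + 1]}.
#' For a uniform law on S states \eqn{\sum\sqrt p = \sqrt S}; for a product
#' law it factorizes over the marginals.
#'
#' @param distribution Probability table (`data.frame` with a `prob` column)
#'   or a plain probability vector.
#' @param tol Normalization tolerance.
#' @return List with `center`, `lower`, `upper` and `sqrt_sum`
#'   (\eqn{\sum_x\sqrt{p(x)}}).
#' @export
mc_l1_prefactor <- function(distribution, tol = 1e-9) {
  p <- if (is.data.frame(distribution)) distribution$prob else as.numeric(distribution)
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > tol) stop("distribution is not normalized (sum = ", sum(p), ")")
  s <- sum(sqrt(p))
  f <- sqrt(2 / pi)
  list(center = f * s, lower = f * (s - 1), upper = f * (s + 1), sqrt_sum = s)
}

#' L1 distance between two probability tables
#'
#' \eqn{\sum_x |\hat p(x) - p(x)|} over the union of supports (missing states
#' count as probability zero); lies in [0, 2].
#'
#' @param estimate,reference Probability tables (`data.frame`s whose
#'   non-`prob` columns index states) or plain vectors on a shared space.
#' @export
l1_error <- function(estimate, reference) {
  if (!is.data.frame(estimate) && !is.data.frame(reference)) {
    if (length(estimate) != length(reference))
      stop("vector tables must share a state space")
    return(sum(abs(estimate - reference)))
  }
  stopifnot(is.data.frame(estimate), is.data.frame(reference))
  cols <- setdiff(names(estimate), "prob")
  if (!setequal(cols, setdiff(names(reference), "prob")))
    stop("mismatched state columns between tables")
  ka <- do.call(paste, c(estimate[cols], sep = ","))
  kb <- do.call(paste, c(reference[cols], sep = ","))
  allk <- union(ka, kb)
  pa <- numeric(length(allk)); pa[match(ka, allk)] <- estimate$prob
  pb <- numeric(length(allk)); pb[match(kb, allk)] <- reference$prob
  sum(abs(pa - pb))
}
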