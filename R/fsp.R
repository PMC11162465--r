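#' Build the truncated CME generator with a sink column
#'
#' Assembles the sparse transition-rate matrix of the chemical master
#' equation on a truncated state space.  Transitions leaving the truncation
#' are routed to a single absorbing sink; the sink inflow rates are returned
#' separately so that `colSums(Q) == -sink_rates`.
#'
#' @param network A [reaction_network()].
#' @param space A [state_space()] covering all network species.
#' @param theta Named parameter vector (if the network declares parameters).
#' @return List with `Q` (sparse `dgCMatrix`, `dp/dt = Q p`), `sink_rates`
#'   (inflow rate into the sink from each state) and `space`.
#' @export
build_generator <- function(network, space = state_space(network), theta = NULL) {
  if (length(space$members) != network$n)
    stop("build_generator needs a space over all network species")
  st <- space_states(space)
  stn <- st
  if (!identical(space$members, seq_len(network$n)))
    stn <- st[, match(seq_len(network$n), space$members), drop = FALSE]
  W <- state_values(network, stn, theta)
  L <- propensities_from_values(network$enc, W)
  if (any(!is.finite(L))) stop("state with non-finite propensity on the truncation")
  S <- space$size
  src <- list(); dst <- list(); val <- list()
  sink <- numeric(S)
  outflow <- numeric(S)
  for (j in seq_len(network$r)) {
    lam <- L[, j]
    act <- lam > 0
    if (!any(act)) next
    z <- network$zeta[space$members, j]
    if (all(z == 0L)) next                       # no net change: no-op
    to <- sweep(st[act, , drop = FALSE], 2L, -z)
    ti <- space_index(space, to)
    inside <- !is.na(ti)
    ii <- which(act)
    src[[length(src) + 1L]] <- ii[inside]
    dst[[length(dst) + 1L]] <- ti[inside]
    val[[length(val) + 1L]] <- lam[act][inside]
    sink[ii[!inside]] <- sink[ii[!inside]] + lam[act][!inside]
    outflow[ii] <- outflow[ii] + lam[act]
  }
  i <- c(unlist(dst), seq_len(S))
  jj <- c(unlist(src), seq_len(S))
  x <- c(unlist(val), -outflow)
  Q <- Matrix::sparseMatrix(i = i, j = jj, x = x, dims = c(S, S))
  list(Q = methods::as(Q, "CsparseMatrix"), sink_rates = sink, space = space)
}

## extend Q with the absorbing sink state as the (S+1)-th coordinate
generator_with_sink <- function(gen) {
  S <- gen$space$size
  Tq <- methods::as(gen$Q, "TsparseMatrix")
  nz <- which(gen$sink_rates > 0)
  Qs <- Matrix::sparseMatrix(i = c(Tq@i + 1L, rep(S + 1L, length(nz))),
                             j = c(Tq@j + 1L, nz),
                             x = c(Tq@x, gen$sink_rates[nz]),
                             dims = c(S + 1L, S + 1L))
  methods::as(Qs, "CsparseMatrix")
}

#' Solve a truncated CME by finite state projection
#'
#' Integrates `dp/dt = Q p` on the truncation from `p0` to time `t` by the
#' action of the matrix exponential (uniformization, error-controlled,
#' nonnegativity- and mass-preserving).  The probability mass absorbed by the
#' sink bounds the L1 distance to the untruncated CME solution.
#'
#' @param network A [reaction_network()].
#' @param space A [state_space()] over all species.
#' @param p0 Initial probability vector on `space` (default: the network's
#'   initial distribution restricted to the truncation), or an `rbcme_init`.
#' @param t Solution time (>= 0).
#' @param theta Named parameter vector if needed.
#' @param tol Series tolerance of the exponential action.
#' @return An `rbcme_fsp` object: `prob` (vector on the truncation),
#'   `sink_mass`, `t`, `space`.
#' @export
fsp_solve <- function(network, space = state_space(network), p0 = NULL, t,
                      theta = NULL, tol = 1e-12) {
  gen <- build_generator(network, space, theta)
  if (is.null(p0)) p0 <- init_vector(network, space)
  stopifnot(length(p0) == space$size, all(p0 >= 0))
  sink0 <- 1 - sum(p0)
  if (sink0 < -1e-9) stop("p0 has mass > 1")
  Qs <- generator_with_sink(gen)
  v <- cpp_expatv(Qs, c(p0, max(sink0, 0)), t, tol)
  structure(list(prob = v[seq_len(space$size)],
                 sink_mass = v[space$size + 1L],
                 t = t, space = space),
            class = "rbcme_fsp")
}

#' @export
print.rbcme_fsp <- function(x, ...) {
  cat("FSP solution at t =", x$t, "on", x$space$size, "states; sink mass",
      format(x$sink_mass, digits = 4), "\n")
  invisible(x)
}

#' Stationary distribution on a truncation
#'
#' Integrates the truncated CME (with outflow across the truncation boundary
#' removed, so probability is conserved on the truncation) in doubling time
#' chunks until the residual `||Q p||_1` falls below `tol`, then renormalizes.
#' This mirrors solving the CME "at a large time point" rather than an
#' eigenproblem, and is robust for reducible truncations with transient
#' states.
#'
#' @inheritParams fsp_solve
#' @param tol Residual tolerance per unit time (L1 norm of `dp/dt`).
#' @param t_max Maximum integration horizon before giving up.
#' @return Probability vector on `space`.
#' @export
stationary_distribution <- function(network, space = state_space(network),
                                    theta = NULL, p0 = NULL,
                                    tol = 1e-9, t_max = 1e7) {
  gen <- build_generator(network, space, theta)
  Q <- gen$Q + Matrix::Diagonal(space$size, gen$sink_rates)  # conserve mass
  if (is.null(p0)) p0 <- init_vector(network, space)
  p <- p0 / sum(p0)
  dt <- 1
  t_acc <- 0
  repeat {
    p <- cpp_expatv(Q, p, dt, 1e-12)
    p <- pmax(p, 0); p <- p / sum(p)
    res <- sum(abs(Q %*% p))
    t_acc <- t_acc + dt
    if (res < tol) break
    if (t_acc >= t_max)
      stop("stationary_distribution did not converge within t_max (residual ",
           format(res, digits = 3), ")")
    dt <- min(2 * dt, t_max - t_acc)
  }
  p
}
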