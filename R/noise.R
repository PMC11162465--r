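#' Time averages of a single-cell record
#'
#' Computes \eqn{\frac1T\int_0^T x\,dt}, \eqn{\frac1T\int_0^T x^2\,dt} and
#' the time-averaged variance (second moment minus squared mean).  For an
#' event-sparse SSA trajectory the piecewise-constant integrals are exact;
#' for a sampled observation series the readouts are rounded to the nearest
#' integer and integrated by the trapezoid rule.
#'
#' @param x An `rbcme_trajectory` or an [obs_series()] (one channel).
#' @param T Averaging horizon (must be covered by the record); defaults to
#'   the record's end time.
#' @param species For a trajectory: which species to average.
#' @return Named vector `c(mean, second_moment, variance)`.
#' @export
trajectory_time_averages <- function(x, T = NULL, species = NULL) {
  if (inherits(x, "rbcme_trajectory")) {
    if (is.null(species)) {
      if (length(x$species) > 1L) stop("give `species` for a multi-species trajectory")
      species <- x$species
    }
    i <- match(species, x$species)
    if (is.null(T)) T <- x$t_end
    if (T > x$t_end + 1e-9) stop("T exceeds the trajectory span")
    tt <- c(x$t0, x$times[x$times < T], T)
    vals <- c(x$x0[i], x$states[x$times < T, i])
    dur <- diff(tt)
    span <- T - x$t0
    m1 <- sum(vals * dur) / span
    m2 <- sum(vals^2 * dur) / span
  } else if (inherits(x, "rbcme_obs_series")) {
    if (ncol(x$values) != 1L) stop("time averages need a single channel")
    if (is.null(T)) T <- max(x$times)
    if (T > max(x$times) + 1e-9) stop("T exceeds the series span")
    keep <- x$times <= T + 1e-12
    tt <- x$times[keep]
    if (length(tt) < 2L) stop("need at least two observations within [0, T]")
    v <- pmax(round(x$values[keep, 1L]), 0)
    dt <- diff(tt)
    m1 <- sum((v[-1L] + v[-length(v)]) / 2 * dt) / (max(tt) - min(tt))
    m2 <- sum((v[-1L]^2 + v[-length(v)]^2) / 2 * dt) / (max(tt) - min(tt))
  } else stop("x must be a trajectory or an observation series")
  c(mean = m1, second_moment = m2, variance = m2 - m1^2)
}

#' Intrinsic/extrinsic noise decomposition from time-course records
#'
#' Dual-reporter-free decomposition for an ergodic population: the extrinsic
#' noise is the across-cell variance of the per-cell time-averaged means,
#' and the intrinsic noise is the across-cell mean of the per-cell
#' time-averaged variances; the total is their sum (the law of total
#' variance with time averages standing in for conditional moments).
#'
#' @param cells List of single-cell records (`rbcme_trajectory` or
#'   [obs_series()]).
#' @param T Common averaging horizon (default: each record's span).
#' @param species Species to average, for trajectory input.
#' @param min_active Minimal number of nonzero readings for a cell to be
#'   included (mirrors selecting cells with sufficiently active
#'   transcription); excluded cells are counted and reported.
#' @return An `rbcme_noise_decomposition` with `total`, `intrinsic`,
#'   `extrinsic`, `n_cells`, `n_excluded` and the per-cell table.
#' @export
decompose_from_trajectories <- function(cells, T = NULL, species = NULL,
                                        min_active = 1L) {
  active <- vapply(cells, function(x) {
    v <- if (inherits(x, "rbcme_obs_series")) round(x$values[, 1L])
         else {
           i <- if (is.null(species)) 1L else match(species, x$species)
           c(x$x0[i], x$states[, i])
         }
    sum(v != 0) >= min_active
  }, TRUE)
  n_excluded <- sum(!active)
  if (n_excluded > 0L)
    message(n_excluded, " cell(s) excluded by the minimal-activity filter")
  cells <- cells[active]
  if (length(cells) < 2L) stop("extrinsic noise needs at least two active cells")
  per <- t(vapply(cells, trajectory_time_averages, numeric(3), T = T,
                  species = species))
  extrinsic <- stats::var(per[, "mean"])
  intrinsic <- mean(per[, "variance"])
  structure(list(total = extrinsic + intrinsic, intrinsic = intrinsic,
                 extrinsic = extrinsic, n_cells = length(cells),
                 n_excluded = n_excluded,
                 per_cell = data.frame(mean = per[, "mean"],
                                       variance = per[, "variance"]),
                 route = "trajectories"),
            class = "rbcme_noise_decomposition")
}

#' Intrinsic/extrinsic noise decomposition from per-cell models
#'
#' Given cell-specific parameter estimates (e.g. MAP values from
#' [rb_identify()]), computes each cell's stationary conditional mean and
#' variance of the species of interest from the FSP stationary law, and
#' applies the law of total variance exactly: intrinsic = mean of
#' conditional variances, extrinsic = variance of conditional means,
#' total = their sum.
#'
#' @param network The shared [reaction_network()] (with parameters).
#' @param thetas Matrix or data.frame of per-cell parameter values (rows =
#'   cells, named columns).
#' @param species Species of interest.
#' @param space Optional [state_space()] (default: the network truncation).
#' @return An `rbcme_noise_decomposition` (route `"models"`).
#' @export
decompose_from_models <- function(network, thetas, species,
                                  space = state_space(network)) {
  thetas <- as.matrix(thetas)
  stopifnot(nrow(thetas) >= 1L)
  i <- match(species, space$names)
  vals <- seq.int(0L, space$sizes[i] - 1L)
  per <- t(apply(thetas, 1L, function(th) {
    stat <- stationary_distribution(network, space, theta = th)
    m <- as.numeric(space_marginalize(space, stat, i))
    mu <- sum(vals * m)
    c(mean = mu, variance = sum(vals^2 * m) - mu^2)
  }))
  extrinsic <- if (nrow(per) > 1L) stats::var(per[, "mean"]) else 0
  intrinsic <- mean(per[, "variance"])
  structure(list(total = extrinsic + intrinsic, intrinsic = intrinsic,
                 extrinsic = extrinsic, n_cells = nrow(per), n_excluded = 0L,
                 per_cell = data.frame(mean = per[, "mean"],
                                       variance = per[, "variance"]),
                 route = "models"),
            class = "rbcme_noise_decomposition")
}

#' @export
print.rbcme_noise_decomposition <- function(x, ...) {
  cat("Noise decomposition (", x$route, ", ", x$n_cells, " cells)\n",
      "  total     ", format(x$total, digits = 5), "\n",
      "  intrinsic ", format(x$intrinsic, digits = 5),
      " (", round(100 * x$intrinsic / x$total, 1), "%)\n",
      "  extrinsic ", format(x$extrinsic, digits = 5),
      " (", round(100 * x$extrinsic / x$total, 1), "%)\n", sep = "")
  invisible(x)
}
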