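#' Observation models
#'
#' An observation model maps a state to a vector of ideal readouts
#' \eqn{h(x)} and adds independent Gaussian noise per channel:
#' \eqn{Y(t_i) = h(X(t_i)) + \Sigma W_i} with diagonal \eqn{\Sigma}.
#' Channels are built with [channel_identity()] (direct copy-number readout),
#' [channel_threshold()] (background-censored readout \eqn{x\,1(x>c)}, e.g. a
#' microscopy platform that cannot resolve low counts), or
#' [channel_lincomb()] (a weighted sum of species).
#'
#' @param channels List of channel specifications.
#' @param sigma Per-channel observation noise intensities (>= 0; 0 means the
#'   channel is noise-free and filtering matches it exactly).
#' @return An object of class `rbcme_obs_model`.
#' @export
obs_model <- function(channels, sigma) {
  if (inherits(channels, "rbcme_channel")) channels <- list(channels)
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(channels))
  stopifnot(length(sigma) == length(channels), all(sigma >= 0))
  for (ch in channels) stopifnot(inherits(ch, "rbcme_channel"))
  structure(list(channels = channels, sigma = sigma), class = "rbcme_obs_model")
}

#' @rdname obs_model
#' @param species Observed species name.
#' @export
channel_identity <- function(species) {
  structure(list(kind = "identity", species = species),
            class = "rbcme_channel")
}

#' @rdname obs_model
#' @param threshold Counts at or below `threshold` read as 0.
#' @export
channel_threshold <- function(species, threshold) {
  structure(list(kind = "threshold", species = species,
                 threshold = as.numeric(threshold)),
            class = "rbcme_channel")
}

#' @rdname obs_model
#' @param coefs Named numeric vector of per-species weights.
#' @export
channel_lincomb <- function(coefs) {
  stopifnot(!is.null(names(coefs)))
  structure(list(kind = "lincomb", coefs = coefs), class = "rbcme_channel")
}

channel_species <- function(ch) {
  switch(ch$kind, identity = ch$species, threshold = ch$species,
         lincomb = names(ch$coefs))
}

## evaluate one channel's h on a matrix of state VALUES with named columns
channel_h <- function(ch, V) {
  switch(ch$kind,
    identity = V[, ch$species],
    threshold = { x <- V[, ch$species]; x * (x > ch$threshold) },
    lincomb = as.numeric(V[, names(ch$coefs), drop = FALSE] %*% ch$coefs))
}

#' Gaussian observation likelihood
#'
#' Density of an observation vector `y` given a state `x`: the product over
#' channels of normal densities centered at \eqn{h(x)} with the channel's
#' noise intensity.  A channel with `sigma = 0` contributes an exact-match
#' indicator (unit mass at \eqn{y = h(x)}).
#'
#' @param model An [obs_model()].
#' @param y Observation vector (one value per channel).
#' @param x State vector, or a matrix of states (one per row).
#' @param network The network defining species names/values.
#' @return Likelihood value(s), one per state row.
#' @export
gaussian_likelihood <- function(model, y, x, network) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L,
                                       dimnames = list(NULL, network$species_names))
  V <- state_values(network, X)
  colnames(V) <- c(network$species_names, network$param_names)
  lik <- rep(1, nrow(V))
  for (k in seq_along(model$channels)) {
    h <- channel_h(model$channels[[k]], V)
    s <- model$sigma[k]
    lik <- lik * if (s > 0) stats::dnorm(y[k], mean = h, sd = s)
                 else as.numeric(abs(y[k] - h) < 1e-9)
  }
  lik
}

#' Single-cell observation series
#'
#' @param times Strictly increasing observation times.
#' @param values Numeric matrix (times x channels) or vector for one channel.
#' @param model The generating [obs_model()] (optional but recommended).
#' @export
obs_series <- function(times, values, model = NULL) {
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  stopifnot(length(times) == nrow(values), !is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), values = values, model = model),
            class = "rbcme_obs_series")
}

#' @export
print.rbcme_obs_series <- function(x, ...) {
  cat("Observation series:", length(x$times), "time points,",
      ncol(x$values), "channel(s), span [",
      min(x$times), ",", max(x$times), "]\n")
  invisible(x)
}
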