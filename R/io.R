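## ---------------------------------------------------------------------------
## Declarative model files: JSON with sections `species`, `reactions`
## (each: reactants, products, kinetics), `parameters` (grid + prior) and
## `initial`.  Round-trips losslessly through read_model()/write_model().
## ---------------------------------------------------------------------------

coef_to_json <- function(a) if (is_param_ref(a)) list(param = a$name) else a
coef_from_json <- function(a) {
  if (is.list(a) && !is.null(a$param)) param(a$param) else as.numeric(a)
}

#' Write a reaction network to a JSON model file
#'
#' @param network A [reaction_network()].
#' @param path Output file path.
#' @export
write_model <- function(network, path) {
  sp <- lapply(network$species, function(s) {
    out <- list(name = s$name, size = s$size)
    if (!identical(s$values, as.numeric(seq.int(0L, s$size - 1L))))
      out$values <- s$values
    out
  })
  rx <- lapply(network$reactions, function(r) {
    kin <- r$propensity
    k <- switch(kin$kind,
      mass_action = list(kind = "mass_action", rate = coef_to_json(kin$rate)),
      hill = list(kind = "hill", vmax = coef_to_json(kin$vmax), K = kin$K,
                  n = kin$n, regulator = kin$regulator, type = kin$type),
      lin_comb = list(kind = "lin_comb",
                      coef = lapply(kin$coef, coef_to_json),
                      species = as.list(kin$species)))
    list(reactants = as.list(r$reactants), products = as.list(r$products),
         kinetics = k)
  })
  pars <- lapply(network$params, function(p)
    list(name = p$name, grid = p$grid, prior = p$prior))
  init <- network$init
  ini <- if (init$kind == "product") {
    list(kind = "product",
         dists = lapply(init$dists, function(d) d),
         names = as.list(init$names))
  } else {
    list(kind = "explicit", states = init$states, prob = init$prob)
  }
  obj <- list(species = sp, reactions = rx, parameters = pars, initial = ini)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a reaction network from a JSON model file
#'
#' @param path Model file written by [write_model()] (or by hand in the same
#'   schema).
#' @return A [reaction_network()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- lapply(obj$species, function(s)
    species(s$name, size = as.integer(s$size),
            values = if (!is.null(s$values)) as.numeric(unlist(s$values))))
  rx <- lapply(obj$reactions, function(r) {
    k <- r$kinetics
    kin <- switch(k$kind,
      mass_action = mass_action(coef_from_json(k$rate)),
      hill = hill_kinetics(coef_from_json(k$vmax), k$K, k$n, k$regulator, k$type),
      lin_comb = lin_comb(lapply(k$coef, coef_from_json),
                          vapply(k$species, function(s)
                            if (is.null(s)) NA_character_ else s, "")))
    tovec <- function(x) if (length(x)) unlist(x) else integer(0)
    reaction(reactants = tovec(r$reactants), products = tovec(r$products),
             propensity = kin)
  })
  pars <- lapply(obj$parameters, function(p)
    param_spec(p$name, as.numeric(unlist(p$grid)), as.numeric(unlist(p$prior))))
  ini <- obj$initial
  init <- if (identical(ini$kind, "product")) {
    structure(list(kind = "product",
                   dists = lapply(ini$dists, function(d) {
                     d$kind <- as.character(d$kind)
                     if (!is.null(d$prob)) d$prob <- as.numeric(unlist(d$prob))
                     d
                   }),
                   names = unlist(ini$names)),
              class = "rbcme_init")
  } else {
    init_explicit(do.call(rbind, lapply(ini$states, unlist)),
                  as.numeric(unlist(ini$prob)))
  }
  reaction_network(sp, rx, params = pars, init = init)
}

#' Write a probability table or observation series as delimited text
#'
#' @param x A probability table (`data.frame`) or [obs_series()].
#' @param path Output CSV path.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "rbcme_obs_series")) {
    df <- data.frame(time = x$times)
    for (k in seq_len(ncol(x$values))) df[[paste0("channel_", k)]] <- x$values[, k]
    x <- df
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read an observation series from delimited text
#'
#' Expects a `time` column followed by one column per channel.
#'
#' @param path CSV path.
#' @param model Optional [obs_model()] to attach.
#' @export
read_obs_series <- function(path, model = NULL) {
  df <- utils::read.csv(path)
  stopifnot("time" %in% names(df))
  obs_series(df$time, as.matrix(df[setdiff(names(df), "time")]), model)
}
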