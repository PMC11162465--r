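#' Declare a chemical species
#'
#' @param name Species name (unique within a network).
#' @param size Number of admissible copy-number states used by truncation-based
#'   solvers; the admissible states are `0:(size-1)` unless `states` is given.
#'   Exact simulation is not truncated by `size`.
#' @param states Optional explicit admissible state list (e.g. `0:1` for a
#'   binary gene state).  Must be `0:(length(states)-1)`-indexable, i.e. the
#'   internal encoding is the position in this list.
#' @param values Optional numeric value attached to each state, used when a
#'   propensity references the species (defaults to the states themselves;
#'   parameter pseudo-species map grid indices to grid values).
#' @return An object of class `rbcme_species`.
#' @export
species <- function(name, size = NULL, states = NULL, values = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(size) && is.null(states)) stop("give `size` or `states`")
  if (is.null(states)) states <- seq.int(0L, size - 1L)
  states <- as.integer(states)
  size <- length(states)
  if (size < 1L) stop("truncation size must be >= 1")
  if (!identical(states, seq.int(0L, size - 1L)) && is.null(values))
    values <- as.numeric(states)
  if (is.null(values)) values <- as.numeric(states)
  stopifnot(length(values) == size)
  structure(list(name = name, size = size, values = as.numeric(values),
                 is_param = FALSE),
            class = "rbcme_species")
}

#' Declare a gridded parameter with a discrete prior
#'
#' Unknown rate parameters take values on a finite ordered grid with a prior
#' probability vector; identification computes their posterior on that grid.
#'
#' @param name Parameter name.
#' @param grid Strictly increasing numeric grid of admissible values.
#' @param prior Prior probabilities over `grid` (default uniform); must be
#'   nonnegative and sum to 1 within 1e-12.
#' @export
param_spec <- function(name, grid, prior = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(grid), length(grid) >= 1L)
  if (any(diff(grid) <= 0)) stop("parameter grid must be strictly increasing")
  if (is.null(prior)) prior <- rep(1 / length(grid), length(grid))
  stopifnot(length(prior) == length(grid))
  if (any(prior < 0)) stop("prior must be nonnegative")
  if (abs(sum(prior) - 1) > 1e-12) stop("prior must sum to 1")
  structure(list(name = name, grid = as.numeric(grid), prior = as.numeric(prior)),
            class = "rbcme_param_spec")
}

#' Declare a reaction
#'
#' @param reactants Named integer vector of reactant stoichiometries
#'   (species name -> count); may be empty for pure production.
#' @param products Named integer vector of product stoichiometries.
#' @param propensity A kinetics object ([mass_action()], [hill_kinetics()],
#'   [lin_comb()]).
#' @export
reaction <- function(reactants = integer(0), products = integer(0), propensity) {
  norm <- function(v) {
    if (length(v) == 0L) return(stats::setNames(integer(0), character(0)))
    stopifnot(!is.null(names(v)), all(nzchar(names(v))))
    v <- v[v != 0]
    storage.mode(v) <- "integer"
    if (any(v < 0)) stop("stoichiometric coefficients must be nonnegative")
    v
  }
  stopifnot(inherits(propensity, "rbcme_kinetics"))
  structure(list(reactants = norm(reactants), products = norm(products),
                 propensity = propensity),
            class = "rbcme_reaction")
}

#' Initial-distribution specifications
#'
#' A network's initial distribution is either a product over species of
#' per-species laws (point mass, Poisson, or explicit categorical over the
#' admissible states) or an explicit joint table.
#'
#' @param x0 Named (or positional) integer vector of initial copy numbers.
#' @name initial-distributions
NULL

#' @rdname initial-distributions
#' @export
init_point <- function(x0) {
  structure(list(kind = "product",
                 dists = lapply(as.numeric(x0), function(v)
                   list(kind = "point", value = v)),
                 names = names(x0)),
            class = "rbcme_init")
}

#' @rdname initial-distributions
#' @param means Per-species Poisson means (recycled if scalar).
#' @export
init_poisson <- function(means) {
  structure(list(kind = "product",
                 dists = lapply(as.numeric(means), function(m)
                   list(kind = "poisson", mean = m)),
                 names = names(means)),
            class = "rbcme_init")
}

#' @rdname initial-distributions
#' @param states Integer matrix (rows = joint states, columns = species).
#' @param prob Probabilities for the rows of `states`.
#' @export
init_explicit <- function(states, prob) {
  states <- as.matrix(states)
  stopifnot(nrow(states) == length(prob), all(prob >= 0),
            abs(sum(prob) - 1) < 1e-9)
  structure(list(kind = "explicit", states = states, prob = as.numeric(prob) / sum(prob)),
            class = "rbcme_init")
}

#' Build and validate a reaction network
#'
#' Assembles species, reactions, gridded parameters and an initial
#' distribution into a validated network object; reports the dimension `n`,
#' the reaction count `r` and the net-change (stoichiometry) matrix.
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param params Optional list of [param_spec()] objects.
#' @param init An initial distribution ([init_point()], [init_poisson()],
#'   [init_explicit()]); defaults to all species at 0 (lowest state).
#' @return An object of class `rbcme_network` with elements `species`,
#'   `reactions`, `params`, `init`, `n`, `r` and `zeta` (n x r net-change
#'   matrix).
#' @export
reaction_network <- function(species, reactions, params = list(), init = NULL) {
  stopifnot(is.list(species), length(species) >= 1L, is.list(reactions))
  for (s in species) stopifnot(inherits(s, "rbcme_species"))
  for (rx in reactions) stopifnot(inherits(rx, "rbcme_reaction"))
  for (p in params) stopifnot(inherits(p, "rbcme_param_spec"))
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names)) stop("duplicate species name: ",
                                    sp_names[duplicated(sp_names)][1L])
  par_names <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(par_names)) stop("duplicate parameter name")
  if (any(par_names %in% sp_names)) stop("parameter name collides with a species name")
  n <- length(species)
  r <- length(reactions)
  zeta <- matrix(0L, n, r, dimnames = list(sp_names, NULL))
  for (j in seq_len(r)) {
    rx <- reactions[[j]]
    for (side in c("reactants", "products")) {
      nm <- names(rx[[side]])
      bad <- setdiff(nm, sp_names)
      if (length(bad)) stop("reaction ", j, " references unknown species: ", bad[1L])
    }
    refs <- kinetics_species_refs(rx$propensity)
    bad <- setdiff(refs, sp_names)
    if (length(bad)) stop("reaction ", j, " propensity references unknown species: ", bad[1L])
    prefs <- kinetics_param_refs(rx$propensity)
    bad <- setdiff(prefs, c(par_names, sp_names))
    if (length(bad)) stop("reaction ", j, " propensity references unknown parameter: ", bad[1L])
    ii <- match(names(rx$products), sp_names)
    zeta[ii, j] <- zeta[ii, j] + rx$products
    ii <- match(names(rx$reactants), sp_names)
    zeta[ii, j] <- zeta[ii, j] - rx$reactants
  }
  if (is.null(init)) init <- init_point(stats::setNames(rep(0L, n), sp_names))
  stopifnot(inherits(init, "rbcme_init"))
  if (init$kind == "product") {
    if (length(init$dists) == 1L && n > 1L)
      init$dists <- rep(init$dists, n)
    if (length(init$dists) != n) stop("initial distribution dimension mismatch")
    if (!is.null(init$names)) init$dists <- init$dists[match(sp_names, init$names)]
    init$names <- sp_names
  } else if (ncol(init$states) != n) stop("initial distribution dimension mismatch")
  net <- structure(list(species = species, reactions = reactions, params = params,
                        init = init, n = n, r = r, zeta = zeta,
                        species_names = sp_names, param_names = par_names),
                   class = "rbcme_network")
  net$enc <- encode_network(net)
  net
}

#' @export
print.rbcme_network <- function(x, ...) {
  cat("Reaction network:", x$n, "species,", x$r, "reactions,",
      length(x$params), "gridded parameters\n")
  cat("  species:", paste(x$species_names, collapse = ", "), "\n")
  invisible(x)
}

## ---- internal numeric encoding shared by the R evaluators and the C++ SSA ----
##
## The "value vector" w for a state has length n + ntheta: species values
## (copy numbers, or grid values for pseudo-species) followed by the entries
## of theta.  Kinetics references are compiled to indices into w.

encode_network <- function(net) {
  n <- net$n; r <- net$r
  sp_names <- net$species_names
  par_names <- net$param_names
  ntheta <- length(par_names)
  wref <- function(a) {           # coefficient -> (literal, w index)
    if (is_param_ref(a)) {
      ks <- match(a$name, sp_names)       # pseudo-species after augmentation
      if (!is.na(ks)) return(c(0, ks))
      c(0, n + match(a$name, par_names))
    } else c(as.numeric(a), 0)
  }
  sref <- function(nm) match(nm, sp_names)
  kind <- integer(r); c_lit <- numeric(r); c_ref <- integer(r)
  hillK <- numeric(r); hilln <- numeric(r); hill_reg <- integer(r); hill_act <- integer(r)
  react_idx <- list(); react_nu <- list()
  lc_alit <- list(); lc_aref <- list(); lc_sref <- list()
  dep <- vector("list", r)
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    kin <- rx$propensity
    react_idx[[j]] <- sref(names(rx$reactants))
    react_nu[[j]] <- as.integer(rx$reactants)
    d <- react_idx[[j]]
    if (kin$kind == "mass_action") {
      kind[j] <- 1L
      cr <- wref(kin$rate); c_lit[j] <- cr[1]; c_ref[j] <- cr[2]
      if (cr[2] > 0) d <- c(d, cr[2])
    } else if (kin$kind == "hill") {
      kind[j] <- 2L
      cr <- wref(kin$vmax); c_lit[j] <- cr[1]; c_ref[j] <- cr[2]
      hillK[j] <- kin$K; hilln[j] <- kin$n
      hill_reg[j] <- sref(kin$regulator)
      hill_act[j] <- if (kin$type == "activator") 1L else 0L
      d <- c(d, hill_reg[j], if (cr[2] > 0) cr[2])
    } else {
      kind[j] <- 3L
      al <- numeric(0); ar <- integer(0); sr <- integer(0)
      for (k in seq_along(kin$coef)) {
        cr <- wref(kin$coef[[k]])
        al <- c(al, cr[1]); ar <- c(ar, cr[2])
        snm <- kin$species[k]
        sr <- c(sr, if (is.na(snm)) 0L else sref(snm))
        d <- c(d, if (cr[2] > 0) cr[2], if (!is.na(snm)) sref(snm))
      }
      lc_alit[[j]] <- al; lc_aref[[j]] <- ar; lc_sref[[j]] <- sr
    }
    dep[[j]] <- sort(unique(as.integer(d)))
  }
  flat <- function(lst, mode) {
    off <- c(0L, cumsum(vapply(lst, length, 0L)))
    list(off = as.integer(off), dat = as.vector(unlist(lst) %||% vector(mode, 0)))
  }
  ri <- flat(react_idx, "integer"); rn <- flat(react_nu, "integer")
  la <- flat(lc_alit, "numeric"); lr <- flat(lc_aref, "integer"); ls <- flat(lc_sref, "integer")
  vdefault <- vapply(net$species, function(s)
    identical(s$values, as.numeric(seq.int(0L, s$size - 1L))), TRUE)
  list(n = n, r = r, ntheta = as.integer(ntheta),
       sizes = vapply(net$species, `[[`, 0L, "size"),
       vdefault = vdefault,
       values = lapply(net$species, `[[`, "values"),
       zeta = net$zeta,
       react_off = ri$off, react_idx = as.integer(ri$dat), react_nu = as.integer(rn$dat),
       kind = kind, c_lit = c_lit, c_ref = c_ref,
       hillK = hillK, hilln = hilln, hill_reg = hill_reg, hill_act = hill_act,
       lc_off = la$off, lc_alit = as.numeric(la$dat),
       lc_aref = as.integer(lr$dat), lc_sref = as.integer(ls$dat),
       dep = dep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## value vector(s) for a matrix of states (rows = states, encoded as indices /
## copy numbers); returns rows x (n + ntheta)
state_values <- function(net, X, theta = NULL) {
  enc <- net$enc
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  W <- matrix(0, nrow(X), enc$n + enc$ntheta)
  for (i in seq_len(enc$n)) {
    if (enc$vdefault[i]) W[, i] <- X[, i]
    else W[, i] <- enc$values[[i]][X[, i] + 1L]
  }
  if (enc$ntheta > 0L) {
    ## theta may be absent when only species-dependent quantities (e.g.
    ## observation readouts) are evaluated; misuse surfaces as NaN rates
    th <- if (is.null(theta)) rep(NA_real_, enc$ntheta) else resolve_theta(net, theta)
    W[, enc$n + seq_len(enc$ntheta)] <- rep(th, each = nrow(X))
  }
  W
}

resolve_theta <- function(net, theta, on_grid = FALSE) {
  if (length(net$param_names) == 0L) return(numeric(0))
  if (is.null(theta)) stop("network has parameters; `theta` is required")
  if (!is.null(names(theta))) theta <- theta[net$param_names]
  if (length(theta) != length(net$param_names) || anyNA(theta))
    stop("`theta` must supply a value for each parameter")
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("parameter values must be finite and nonnegative")
  if (on_grid) for (k in seq_along(theta)) {
    g <- net$params[[k]]$grid
    if (min(abs(g - theta[k])) > 1e-9 * max(1, max(abs(g))))
      stop("theta[", net$param_names[k], "] = ", theta[k], " is off its grid")
  }
  as.numeric(theta)
}

#' Evaluate reaction propensities at a state
#'
#' Computes the propensity \eqn{\lambda_j(\theta, x)} of every reaction at one
#' state (or a matrix of states, one per row).  Mass-action propensities are
#' exactly zero whenever a reactant count is below its stoichiometric
#' requirement.
#'
#' @param network A [reaction_network()].
#' @param state Integer state vector (copy numbers; grid indices for
#'   parameter pseudo-species), or a matrix with one state per row.
#' @param theta Named parameter vector (required iff the network declares
#'   parameters and is not augmented).
#' @return Numeric vector of length `r` (or a states x r matrix).
#' @export
propensity_eval <- function(network, state, theta = NULL) {
  single <- !is.matrix(state)
  X <- if (single) matrix(as.numeric(state), nrow = 1L) else state
  if (ncol(X) != network$n) stop("state dimension mismatch")
  if (any(X < 0)) stop("state outside admissible range (negative copy number)")
  for (i in seq_len(network$n)) {
    if (any(X[, i] > network$species[[i]]$size - 1L))
      stop("state outside admissible range for species ", network$species_names[i])
  }
  if (length(network$param_names)) resolve_theta(network, theta, on_grid = TRUE)
  W <- state_values(network, X, theta)
  L <- propensities_from_values(network$enc, W)
  if (any(!is.finite(L))) stop("non-finite propensity")
  if (any(L < 0)) stop("negative propensity")
  if (single) as.numeric(L) else L
}

## vectorized propensity evaluation on a value matrix W (rows = states)
propensities_from_values <- function(enc, W) {
  m <- nrow(W)
  L <- matrix(0, m, enc$r)
  for (j in seq_len(enc$r)) {
    cj <- if (enc$c_ref[j] > 0L) W[, enc$c_ref[j]] else enc$c_lit[j]
    if (enc$kind[j] == 1L) {
      lam <- if (is.matrix(cj)) cj else rep(cj, length.out = m)
      lo <- enc$react_off[j]; hi <- enc$react_off[j + 1L]
      if (hi > lo) for (k in seq.int(lo + 1L, hi)) {
        xi <- W[, enc$react_idx[k]]
        nu <- enc$react_nu[k]
        f <- xi
        if (nu > 1L) for (d in seq_len(nu - 1L)) f <- f * (xi - d)
        lam <- lam * pmax(f, 0)
      }
      L[, j] <- lam
    } else if (enc$kind[j] == 2L) {
      x <- W[, enc$hill_reg[j]]
      Kn <- enc$hillK[j]^enc$hilln[j]
      xn <- x^enc$hilln[j]
      L[, j] <- cj * (if (enc$hill_act[j] == 1L) xn else Kn) / (Kn + xn)
    } else {
      lo <- enc$lc_off[j]; hi <- enc$lc_off[j + 1L]
      acc <- numeric(m)
      for (k in seq.int(lo + 1L, hi)) {
        a <- if (enc$lc_aref[k] > 0L) W[, enc$lc_aref[k]] else enc$lc_alit[k]
        s <- if (enc$lc_sref[k] > 0L) W[, enc$lc_sref[k]] else 1
        acc <- acc + a * s
      }
      L[, j] <- acc
    }
  }
  L
}

#' Fold gridded parameters into the state as static pseudo-species
#'
#' Each declared parameter becomes an additional species whose admissible
#' states are the indices of its value grid, whose state never changes (zero
#' net change in every reaction), and whose value enters propensities wherever
#' the parameter was referenced.  The initial distribution of a pseudo-species
#' is the parameter's prior.  The augmented network's CME is the
#' parameter-augmented CME used for identification.
#'
#' @param network A [reaction_network()] with at least one [param_spec()].
#' @return A [reaction_network()] of dimension `n + n_params` without free
#'   parameters.
#' @export
augment_with_parameters <- function(network) {
  if (length(network$params) == 0L)
    stop("network has no gridded parameters to augment with")
  pseudo <- lapply(network$params, function(p) {
    s <- species(p$name, size = length(p$grid), values = p$grid)
    s$is_param <- TRUE
    s
  })
  sp <- c(network$species, pseudo)
  ## kinetics are kept verbatim: a param() reference resolves by name to the
  ## pseudo-species value in the augmented network's encoder
  rxs <- network$reactions
  init <- network$init
  if (init$kind != "product")
    stop("augmentation requires a product-form initial distribution")
  init$dists <- c(init$dists, lapply(network$params, function(p)
    list(kind = "categorical", prob = p$prior)))
  init$names <- c(network$species_names, network$param_names)
  net <- reaction_network(sp, rxs, params = list(), init = init)
  net$param_pseudo <- stats::setNames(
    match(network$param_names, net$species_names), network$param_names)
  net$param_specs_source <- network$params
  net
}
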