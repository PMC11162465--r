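#' Reference an unknown rate parameter inside a propensity
#'
#' Creates a symbolic reference to a parameter declared via [param_spec()].
#' During propensity evaluation the reference resolves to the parameter's
#' current value (either a supplied `theta` or, after
#' [augment_with_parameters()], the value encoded by the corresponding
#' pseudo-species grid index).
#'
#' @param name Parameter name (must match a `param_spec`).
#' @return An object of class `rbcme_param_ref`.
#' @export
param <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name), class = "rbcme_param_ref")
}

is_param_ref <- function(x) inherits(x, "rbcme_param_ref")

#' Mass-action kinetics
#'
#' Stochastic mass-action propensity \eqn{\lambda(x) = c \prod_i x_i^{(\nu_i)}}
#' where \eqn{x^{(\nu)}} is the falling factorial \eqn{x(x-1)\cdots(x-\nu+1)}.
#' The propensity is exactly zero whenever a reactant count is below its
#' stoichiometric requirement.
#'
#' @param rate Nonnegative rate constant, or a [param()] reference.
#' @export
mass_action <- function(rate) {
  if (!is_param_ref(rate)) {
    stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
    if (rate < 0) stop("mass-action rate constant must be nonnegative")
  }
  structure(list(kind = "mass_action", rate = rate), class = "rbcme_kinetics")
}

#' Hill kinetics
#'
#' Regulated propensity
#' \eqn{\lambda(x) = v_{max}\, x_R^{n}/(K^{n}+x_R^{n})} (activator) or
#' \eqn{\lambda(x) = v_{max}\, K^{n}/(K^{n}+x_R^{n})} (repressor), with
#' \eqn{x_R} the copy number of the regulator species.
#'
#' @param vmax Maximal rate (numeric or [param()] reference).
#' @param K Half-saturation constant (> 0).
#' @param n Hill coefficient (> 0).
#' @param regulator Name of the regulating species.
#' @param type `"repressor"` or `"activator"`.
#' @export
hill_kinetics <- function(vmax, K, n, regulator, type = c("repressor", "activator")) {
  type <- match.arg(type)
  if (!is_param_ref(vmax)) stopifnot(is.numeric(vmax), vmax >= 0)
  stopifnot(is.numeric(K), K > 0, is.numeric(n), n > 0,
            is.character(regulator), length(regulator) == 1L)
  structure(list(kind = "hill", vmax = vmax, K = K, n = n,
                 regulator = regulator, type = type),
            class = "rbcme_kinetics")
}

#' Linear-combination kinetics
#'
#' Propensity \eqn{\lambda(x) = \sum_k a_k s_k} where each term is a
#' coefficient (numeric or [param()] reference) times either a species copy
#' number or the constant 1.  This covers state-switched rates such as a
#' transcription propensity \eqn{k_{p1} G_1 + (k_{p1}+k_{p2}) G_2} written as
#' `lin_comb(coef = list(param("kp1"), param("kp1"), param("kp2")),
#'           species = c("G1", "G2", "G2"))`.
#'
#' @param coef List of coefficients; each numeric scalar or [param()].
#' @param species Character vector, same length as `coef`; `NA` for a
#'   constant (state-independent) term.
#' @export
lin_comb <- function(coef, species) {
  if (!is.list(coef)) coef <- as.list(coef)
  stopifnot(length(coef) == length(species), length(coef) >= 1L)
  for (a in coef) {
    if (!is_param_ref(a)) stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  }
  structure(list(kind = "lin_comb", coef = coef, species = as.character(species)),
            class = "rbcme_kinetics")
}

## species names referenced by a kinetics object (excludes mass-action
## reactants, which are recorded in the reaction stoichiometry)
kinetics_species_refs <- function(kin) {
  switch(kin$kind,
    mass_action = character(0),
    hill = kin$regulator,
    lin_comb = unique(kin$species[!is.na(kin$species)])
  )
}

kinetics_param_refs <- function(kin) {
  refs <- switch(kin$kind,
    mass_action = list(kin$rate),
    hill = list(kin$vmax),
    lin_comb = kin$coef
  )
  unlist(lapply(refs, function(a) if (is_param_ref(a)) a$name else character(0)))
}
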