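## Components touched by each reaction: species whose state the reaction
## changes, plus species (incl. parameter pseudo-species) its propensity
## depends on.
reaction_components <- function(network) {
  lapply(seq_len(network$r), function(j) {
    dep <- network$enc$dep[[j]]
    sort(unique(c(which(network$zeta[, j] != 0L), dep[dep <= network$n])))
  })
}

## key identifying a reaction's leader net-change vector
leader_change_key <- function(network, leaders) {
  if (length(leaders) == 0L) return(rep("", network$r))
  apply(network$zeta[leaders, , drop = FALSE], 2L, paste, collapse = ",")
}

obs_components <- function(network, obs_model) {
  if (is.null(obs_model)) return(list())
  lapply(obs_model$channels, function(ch)
    match(channel_species(ch), network$species_names))
}

#' Leader-follower decomposition of a reaction network
#'
#' @param network A [reaction_network()] (augmented, for identification).
#' @param leaders Leader species (names or indices).
#' @param subsystems List of follower subsystems (names or indices); must
#'   partition the non-leader components.  If omitted, the finest valid
#'   partition is computed with [induced_follower_partition()].
#' @param obs_model Optional [obs_model()] whose channels constrain the
#'   partition (condition C3).
#' @return An `rbcme_decomposition` with `leaders`, `subsystems`,
#'   `sizes` (SS_i per subsystem) and `whole_follower_size`.
#' @export
decomposition <- function(network, leaders, subsystems = NULL, obs_model = NULL) {
  if (is.character(leaders)) leaders <- match(leaders, network$species_names)
  leaders <- sort(as.integer(leaders))
  stopifnot(!anyNA(leaders))
  if (is.null(subsystems)) {
    subsystems <- induced_follower_partition(network, leaders, obs_model)
  } else {
    subsystems <- lapply(subsystems, function(s) {
      if (is.character(s)) s <- match(s, network$species_names)
      sort(as.integer(s))
    })
    flat <- as.integer(sort(unlist(subsystems)))
    if (!identical(flat, setdiff(seq_len(network$n), leaders)))
      stop("subsystems must exactly partition the non-leader components")
  }
  sizes <- vapply(subsystems, function(s)
    prod(vapply(network$species[s], `[[`, 0L, "size")), 0)
  structure(list(leaders = leaders, subsystems = subsystems, sizes = sizes,
                 whole_follower_size = prod(sizes),
                 leader_names = network$species_names[leaders],
                 subsystem_names = lapply(subsystems, function(s)
                   network$species_names[s])),
            class = "rbcme_decomposition")
}

#' @export
print.rbcme_decomposition <- function(x, ...) {
  cat("Leader-follower decomposition\n  leaders: ",
      if (length(x$leaders)) paste(x$leader_names, collapse = ", ") else "(none)",
      "\n", sep = "")
  for (i in seq_along(x$subsystems))
    cat("  subsystem ", i, ": ", paste(x$subsystem_names[[i]], collapse = ", "),
        "  (", format(x$sizes[i], big.mark = ","), " states)\n", sep = "")
  cat("  whole follower size:", format(x$whole_follower_size, big.mark = ","), "\n")
  invisible(x)
}

#' Finest follower partition induced by a leader set
#'
#' Computes the unique finest partition of the non-leader components that
#' satisfies the topological conditions: followers co-occurring in any
#' reaction are merged (C1); followers occurring across reactions that share
#' the same non-zero leader net-change are merged (C2); followers feeding the
#' same observation channel are merged (C3).
#'
#' @inheritParams decomposition
#' @param leaders Leader component indices or names.
#' @return List of integer vectors (subsystems, ordered by smallest member).
#' @export
induced_follower_partition <- function(network, leaders, obs_model = NULL) {
  if (is.character(leaders)) leaders <- match(leaders, network$species_names)
  leaders <- as.integer(leaders)
  followers <- setdiff(seq_len(network$n), leaders)
  if (length(followers) == 0L) return(list())
  parent <- seq_len(network$n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  merge_all <- function(ii) {
    ii <- ii[ii %in% followers]
    if (length(ii) > 1L) {
      root <- find(ii[1L])
      for (k in ii[-1L]) parent[find(k)] <<- root
    }
  }
  comps <- reaction_components(network)
  for (j in seq_len(network$r)) merge_all(comps[[j]])
  keys <- leader_change_key(network, leaders)
  nz <- vapply(seq_len(network$r), function(j)
    any(network$zeta[leaders, j] != 0L), TRUE)
  for (key in unique(keys[nz])) merge_all(unlist(comps[which(keys == key & nz)]))
  for (oc in obs_components(network, obs_model)) merge_all(oc)
  roots <- vapply(followers, find, 0L)
  subs <- split(followers, roots)
  subs <- lapply(subs, sort)
  names(subs) <- NULL
  subs[order(vapply(subs, min, 0L))]
}

#' Check the decomposition conditions C1-C4
#'
#' C1: every reaction involves (changes the state of, or has its propensity
#' influenced by) at most one follower subsystem.  C2: the reactions sharing
#' each distinct non-zero leader net-change jointly involve at most one
#' follower subsystem.  C3: each observation channel depends on at most one
#' follower subsystem (besides the leader).  C4: every parameter
#' pseudo-species is follower-side.
#'
#' @param network A [reaction_network()].
#' @param decomp An `rbcme_decomposition`.
#' @param obs_model Optional [obs_model()]; enables C3.
#' @return List of per-condition verdicts: `ok` flag plus the violating
#'   reactions/channels/parameters.
#' @export
check_conditions <- function(network, decomp, obs_model = NULL) {
  nsub <- length(decomp$subsystems)
  sub_of <- integer(network$n)                 # 0 = leader
  for (i in seq_len(nsub)) sub_of[decomp$subsystems[[i]]] <- i
  comps <- reaction_components(network)
  subs_touched <- lapply(comps, function(cc) sort(unique(sub_of[cc][sub_of[cc] > 0L])))
  c1_bad <- which(vapply(subs_touched, length, 0L) > 1L)
  keys <- leader_change_key(network, decomp$leaders)
  nz <- vapply(seq_len(network$r), function(j)
    any(network$zeta[decomp$leaders, j] != 0L), length(decomp$leaders) > 0L)
  c2_bad <- character(0)
  for (key in unique(keys[nz])) {
    grp <- which(keys == key & nz)
    if (length(unique(unlist(subs_touched[grp]))) > 1L)
      c2_bad <- c(c2_bad, key)
  }
  res <- list(
    C1 = list(ok = length(c1_bad) == 0L, violating_reactions = c1_bad),
    C2 = list(ok = length(c2_bad) == 0L, violating_changes = c2_bad))
  if (!is.null(obs_model)) {
    oc <- obs_components(network, obs_model)
    c3_bad <- which(vapply(oc, function(cc)
      length(unique(sub_of[cc][sub_of[cc] > 0L])), 0L) > 1L)
    res$C3 <- list(ok = length(c3_bad) == 0L, violating_channels = c3_bad)
  }
  is_par <- vapply(network$species, function(s) isTRUE(s$is_param), TRUE)
  if (any(is_par)) {
    c4_bad <- intersect(which(is_par), decomp$leaders)
    res$C4 <- list(ok = length(c4_bad) == 0L,
                   violating_parameters = network$species_names[c4_bad])
  }
  res$ok <- all(vapply(res[names(res) != "ok"], function(v) v$ok, TRUE))
  res
}

## TRUE if sorted integer vector a is "preferred" over b under the
## downstream-preferring tie-break (lexicographically greatest index set)
prefer_leaders <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (k in seq_len(min(la, lb))) {
    if (a[k] != b[k]) return(a[k] > b[k])
  }
  la > lb
}

#' Search for the optimal leader-follower decomposition
#'
#' Exhaustively searches leader subsets; for each, the follower partition is
#' the finest valid one (the product of follower subsystem sizes depends only
#' on the leader set, so finer partitions lose nothing).  A leader set is
#' feasible when every induced subsystem has at most `max_subsystem_size`
#' states.  Among feasible sets the search maximizes the whole follower
#' system size, breaking ties by fewest leader species and then by preferring
#' the lexicographically greatest (most downstream) leader index set.
#'
#' @param network A [reaction_network()] (augmented for identification).
#' @param max_subsystem_size Per-subsystem state-count threshold.
#' @param obs_model Optional [obs_model()] (activates C3).
#' @param identify_mode Force parameter pseudo-species follower-side (C4).
#' @param sizes Optional per-component size override (defaults to each
#'   species' truncation/grid size).
#' @return The optimal `rbcme_decomposition`; if no proper decomposition is
#'   feasible, the all-leader fallback (plain Monte Carlo) with a warning.
#' @export
optimal_decomposition <- function(network, max_subsystem_size,
                                  obs_model = NULL, identify_mode = FALSE,
                                  sizes = NULL) {
  n <- network$n
  if (is.null(sizes)) sizes <- vapply(network$species, `[[`, 0L, "size")
  is_par <- vapply(network$species, function(s) isTRUE(s$is_param), TRUE)
  cand <- if (identify_mode) which(!is_par) else seq_len(n)
  if (length(cand) > 22L) return(greedy_decomposition(network, max_subsystem_size,
                                                      obs_model, identify_mode, sizes))
  best <- NULL; best_obj <- -Inf; best_leaders <- NULL
  for (mask in 0:(2^length(cand) - 1L)) {
    leaders <- cand[bitwAnd(bitwShiftR(mask, seq_along(cand) - 1L), 1L) == 1L]
    subs <- induced_follower_partition(network, leaders, obs_model)
    ss <- vapply(subs, function(s) prod(sizes[s]), 0)
    if (length(ss) && max(ss) > max_subsystem_size) next
    obj <- sum(log(sizes[setdiff(seq_len(n), leaders)]))
    better <- is.null(best) ||
      obj > best_obj + 1e-9 ||
      (abs(obj - best_obj) <= 1e-9 &&
         (length(leaders) < length(best_leaders) ||
            (length(leaders) == length(best_leaders) &&
               prefer_leaders(leaders, best_leaders))))
    if (better) {
      best <- subs; best_obj <- obj; best_leaders <- leaders
    }
  }
  if (is.null(best_leaders) || length(best_leaders) == n) {
    warning("no feasible proper decomposition under the threshold; ",
            "returning the all-leader fallback (plain Monte Carlo)")
    return(decomposition(network, seq_len(n), list(), obs_model))
  }
  decomposition(network, best_leaders, best, obs_model)
}

## greedy fallback for networks with more than 22 components: grow the leader
## set by the component whose promotion most reduces the largest subsystem
greedy_decomposition <- function(network, max_subsystem_size, obs_model,
                                 identify_mode, sizes) {
  warning("more than 22 components: using greedy decomposition search")
  n <- network$n
  is_par <- vapply(network$species, function(s) isTRUE(s$is_param), TRUE)
  cand <- if (identify_mode) which(!is_par) else seq_len(n)
  leaders <- integer(0)
  repeat {
    subs <- induced_follower_partition(network, leaders, obs_model)
    ss <- vapply(subs, function(s) prod(sizes[s]), 0)
    if (!length(ss) || max(ss) <= max_subsystem_size)
      return(decomposition(network, leaders, subs, obs_model))
    big <- subs[[which.max(ss)]]
    opts <- intersect(big, cand)
    if (!length(opts)) {
      warning("no feasible decomposition; returning all-leader fallback")
      return(decomposition(network, seq_len(n), list(), obs_model))
    }
    score <- vapply(opts, function(i) {
      s2 <- induced_follower_partition(network, c(leaders, i), obs_model)
      if (!length(s2)) return(0)
      max(vapply(s2, function(s) prod(sizes[s]), 0))
    }, 0)
    leaders <- sort(c(leaders, opts[which.min(score)]))
  }
}
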