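#' Truncated state space over a subset of network components
#'
#' Enumerates the product of the admissible state lists of the chosen
#' species, with a bijective mixed-radix index map (first member varies
#' fastest, matching R's array order).
#'
#' @param network A [reaction_network()].
#' @param members Species selection (indices or names); default all species.
#' @return An object of class `rbcme_space` with fields `members`, `sizes`,
#'   `size` and the member names.
#' @export
state_space <- function(network, members = seq_len(network$n)) {
  if (is.character(members)) members <- match(members, network$species_names)
  stopifnot(!anyNA(members), all(members >= 1L), all(members <= network$n))
  members <- as.integer(members)
  sizes <- vapply(network$species[members], `[[`, 0L, "size")
  structure(list(members = members, sizes = sizes,
                 names = network$species_names[members],
                 size = prod(sizes)),
            class = "rbcme_space")
}

#' @export
print.rbcme_space <- function(x, ...) {
  cat("Truncated state space:", paste0(x$names, "{0..", x$sizes - 1L, "}",
                                       collapse = " x "),
      "=", x$size, "states\n")
  invisible(x)
}

## 1-based linear index of states (rows of X give member coordinates)
space_index <- function(space, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  idx <- rep(1, nrow(X))
  mult <- 1
  for (k in seq_along(space$members)) {
    xi <- X[, k]
    out <- xi < 0 | xi >= space$sizes[k]
    idx <- idx + xi * mult
    idx[out] <- NA_real_
    mult <- mult * space$sizes[k]
  }
  idx
}

## enumerate all states: size x n_members integer matrix
space_states <- function(space) {
  g <- do.call(expand.grid, lapply(space$sizes, function(s) seq.int(0L, s - 1L)))
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, space$names)
  storage.mode(m) <- "integer"
  m
}

## marginalize a probability vector on `space` onto a subset of its members
space_marginalize <- function(space, p, keep) {
  if (is.character(keep)) keep <- match(keep, space$names)
  dims <- space$sizes
  arr <- array(p, dim = dims)
  m <- apply(arr, keep, sum)
  array(m, dim = dims[keep])
}

## probability table (data.frame) from a vector on a space
space_table <- function(space, p, drop_zero = TRUE) {
  st <- space_states(space)
  df <- as.data.frame(st)
  df$prob <- as.numeric(p)
  if (drop_zero) df <- df[df$prob != 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

## evaluate a product-form initial distribution on a space; returns vector
init_vector <- function(network, space) {
  init <- network$init
  if (init$kind == "explicit") {
    p <- numeric(space$size)
    idx <- space_index(space, init$states[, space$members, drop = FALSE])
    ok <- !is.na(idx)
    for (k in which(ok)) p[idx[k]] <- p[idx[k]] + init$prob[k]
    return(p)
  }
  marg <- lapply(seq_along(space$members), function(k) {
    i <- space$members[k]
    d <- init$dists[[i]]
    s <- seq.int(0L, space$sizes[k] - 1L)
    switch(d$kind,
      point = as.numeric(s == d$value),
      poisson = stats::dpois(s, d$mean),
      categorical = d$prob[seq_along(s)])
  })
  Reduce(function(a, b) as.numeric(outer(a, b)), marg)
}

## sample joint initial states (matrix N x n) from the initial distribution
init_sample <- function(network, N) {
  init <- network$init
  n <- network$n
  if (init$kind == "explicit") {
    rows <- sample.int(nrow(init$states), N, replace = TRUE, prob = init$prob)
    return(init$states[rows, , drop = FALSE])
  }
  X <- matrix(0L, N, n)
  for (i in seq_len(n)) {
    d <- init$dists[[i]]
    X[, i] <- switch(d$kind,
      point = rep(as.integer(d$value), N),
      poisson = stats::rpois(N, d$mean),
      categorical = sample.int(length(d$prob), N, replace = TRUE, prob = d$prob) - 1L)
  }
  X
}
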