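#' Build the sparse generator of the k-allele Moran process
#'
#' Constructs the continuous-time generator \eqn{Q(\bar{f}^*)} over the
#' state space of tracked mutant counts.  Each state-changing event couples
#' a fecundity-weighted birth with a uniformly chosen death.  Writing
#' \eqn{W = N - \sum_j x_j} for the wild-type count and
#' \eqn{D = W + \sum_j x_j f^*_j} for the total population fitness, the
#' non-zero off-diagonal rates from state \eqn{\bar{x}} are
#' \describe{
#'   \item{\eqn{\bar{x} \to \bar{x} - \bar{e}_l}}{\eqn{(W / D)\,(x_l / N)} —
#'     birth of a wild-type individual, death of a haplotype-l carrier;}
#'   \item{\eqn{\bar{x} \to \bar{x} + \bar{e}_l}}{\eqn{(x_l f^*_l / D)\,(W / N)} —
#'     birth of a haplotype-l carrier, death of a wild-type individual;}
#'   \item{\eqn{\bar{x} \to \bar{x} + \bar{e}_l - \bar{e}_u}}{\eqn{(x_l f^*_l / D)\,(x_u / N)} —
#'     birth of a haplotype-l carrier, death of a haplotype-u carrier.}
#' }
#' Diagonals make every row sum to zero.  Time units: one *expected*
#' birth/death event per unit time, counting self-replacements (an
#' individual replaced by a copy of its own type), which do not change the
#' state and therefore do not appear in the generator; `N` time units
#' correspond roughly to one generation.
#'
#' States in which the population is homogeneous (all wild type, or all
#' carrying haplotype `l`) have zero out-rate and are absorbing.
#'
#' @param space An [enumerate_states()] state space.
#' @param fstar Haplotype fitnesses \eqn{f^*_1, \dots, f^*_k} (see
#'   [haplotype_fitnesses()]); length must equal `space$k`, all > 0.
#'
#' @return An object of class `moran_generator`: list with `space`, `fstar`,
#'   and `rates` (a `dgCMatrix` of dimension `n_states x n_states`).
#'
#' @examples
#' sp <- enumerate_states(1, 2)
#' g <- build_generator(sp, 1)
#' as.matrix(g$rates)
#' @export
build_generator <- function(space, fstar) {
  stopifnot(inherits(space, "allele_state_space"))
  fstar <- as.numeric(fstar)
  if (length(fstar) != space$k) {
    stop("length(fstar) must equal space$k", call. = FALSE)
  }
  if (anyNA(fstar) || any(fstar <= 0)) {
    stop("all haplotype fitnesses must be > 0", call. = FALSE)
  }
  k <- space$k
  N <- space$N
  S <- space$states
  n <- space$n_states

  # per-state totals
  W <- N - rowSums(S)                         # wild-type count
  D <- W + as.vector(S %*% fstar)             # total population fitness

  from <- integer(0)
  to <- integer(0)
  rate <- numeric(0)
  add <- function(i, j, r) {
    keep <- r > 0
    from <<- c(from, i[keep])
    to <<- c(to, j[keep])
    rate <<- c(rate, r[keep])
  }

  for (l in seq_len(k)) {
    el <- integer(k); el[l] <- 1L
    xl <- S[, l]
    # x -> x - e_l : wild-type birth, death of l-carrier
    ok <- xl > 0 & W > 0
    if (any(ok)) {
      y <- S[ok, , drop = FALSE]; y[, l] <- y[, l] - 1L
      add(which(ok), state_index(space, y), (W[ok] / D[ok]) * (xl[ok] / N))
    }
    # x -> x + e_l : birth of l-carrier, wild-type death
    ok <- xl > 0 & W > 0
    if (any(ok)) {
      y <- S[ok, , drop = FALSE]; y[, l] <- y[, l] + 1L
      add(which(ok), state_index(space, y), (xl[ok] * fstar[l] / D[ok]) * (W[ok] / N))
    }
    # x -> x + e_l - e_u : birth of l-carrier, death of u-carrier
    for (u in seq_len(k)) {
      if (u == l) next
      xu <- S[, u]
      ok <- xl > 0 & xu > 0
      if (any(ok)) {
        y <- S[ok, , drop = FALSE]
        y[, l] <- y[, l] + 1L
        y[, u] <- y[, u] - 1L
        add(which(ok), state_index(space, y), (xl[ok] * fstar[l] / D[ok]) * (xu[ok] / N))
      }
    }
  }

  Q <- Matrix::sparseMatrix(
    i = from, j = to, x = rate, dims = c(n, n)
  )
  out_rate <- Matrix::rowSums(Q)
  Q <- Q - Matrix::Diagonal(n, out_rate)
  structure(
    list(space = space, fstar = fstar, rates = methods::as(Q, "CsparseMatrix")),
    class = "moran_generator"
  )
}

#' @export
print.moran_generator <- function(x, ...) {
  cat(sprintf(
    "Moran generator: k = %d, N = %d, %d states, %d non-zero rates\n",
    x$space$k, x$space$N, x$space$n_states, length(x$rates@x)
  ))
  invisible(x)
}

#' Dense copy of a Moran generator
#'
#' Refuses to densify above `max_states` states so that large sparse
#' generators are not accidentally expanded.
#'
#' @param g A `moran_generator`.
#' @param max_states Densification refusal threshold (default `1e4`).
#' @return A base dense matrix.
#' @export
generator_dense <- function(g, max_states = 1e4) {
  stopifnot(inherits(g, "moran_generator"))
  if (g$space$n_states > max_states) {
    stop(sprintf(
      "refusing to densify a %d-state generator (max_states = %g)",
      g$space$n_states, max_states
    ), call. = FALSE)
  }
  as.matrix(g$rates)
}

#' Partition a generator into transient and absorbing blocks
#'
#' Splits the generator as \eqn{Q = [[Q^*, V], [0, 0]]} (up to a state
#' permutation): `Qstar` holds the rates between transient states and `V`
#' the rates from transient into absorbing states.  Absorbing states are
#' those with zero out-rate (the homogeneous-population states).
#'
#' @param g A `moran_generator`.
#' @return List with `Qstar` (sparse, transient x transient), `V` (sparse,
#'   transient x absorbing), `transient` and `absorbing` (integer index
#'   vectors into the full state ordering).
#' @export
transient_partition <- function(g) {
  stopifnot(inherits(g, "moran_generator"))
  out_rate <- -Matrix::diag(g$rates)
  absorbing <- which(out_rate <= 0)
  transient <- which(out_rate > 0)
  list(
    Qstar = g$rates[transient, transient, drop = FALSE],
    V = g$rates[transient, absorbing, drop = FALSE],
    transient = transient,
    absorbing = absorbing
  )
}

#' Long-run absorption probabilities into one absorbing state
#'
#' Solves \eqn{Q^* h = -\bar{v}} for the probability, from every transient
#' state, of eventual absorption into a given absorbing state (one sparse
#' linear solve; no matrix inversion).
#'
#' @param g A `moran_generator`.
#' @param target Absorbing state (count vector), e.g. `c(0, N)` for
#'   fixation of the most-derived haplotype.
#' @return Numeric vector over the *full* state ordering: absorption
#'   probability from each state (1 at `target`, 0 at other absorbing
#'   states).
#' @export
absorption_probabilities <- function(g, target) {
  part <- transient_partition(g)
  ti <- state_index(g$space, target)
  pos <- match(ti, part$absorbing)
  if (is.na(pos)) stop("`target` is not an absorbing state", call. = FALSE)
  v <- part$V[, pos]
  h <- Matrix::solve(part$Qstar, -v)
  out <- numeric(g$space$n_states)
  out[part$transient] <- as.numeric(h)
  out[ti] <- 1
  out
}
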