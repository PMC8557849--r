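#' Enumerate the state space of the k-allele Moran process
#'
#' The k-allele Moran process tracks the counts of `k` *mutant* haplotypes
#' segregating in a population of `N` haploid individuals; the wild type is
#' implicit (its count is `N - sum(x)`).  A state is a count vector
#' \eqn{\bar{x} = (x_1, \dots, x_k)} with non-negative integer entries and
#' \eqn{\sum_j x_j \le N}.
#'
#' Naming convention: `k` here counts *tracked mutant haplotypes*, so the
#' process over `k` mutants plus the implicit wild type is what the
#' population-genetics literature usually calls a (k+1)-allele model.  With
#' `k = 1` this is the classical two-allele Moran model.
#'
#' States are ordered lexicographically on the count vectors, and the
#' state-to-index bijection is precomputed in both directions so that
#' history propagation can remap mass between nested state spaces quickly.
#'
#' @param k Number of tracked mutant haplotypes (integer, >= 1).
#' @param N Population size (integer, >= 2).
#'
#' @return An object of class `allele_state_space` with elements
#'   \describe{
#'     \item{k}{number of tracked mutant haplotypes,}
#'     \item{N}{population size,}
#'     \item{states}{integer matrix, one row per state (lexicographic order),}
#'     \item{n_states}{`choose(N + k, k)`,}
#'     \item{key}{named integer vector mapping the string key
#'       `paste(x, collapse = ",")` to the row index.}
#'   }
#'
#' @examples
#' s <- enumerate_states(k = 2, N = 2)
#' s$n_states # choose(4, 2) = 6
#' @export
enumerate_states <- function(k, N) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  if (length(N) != 1L || is.na(N) || N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  N <- as.integer(N)
  states <- .enumerate_simplex(k, N)
  n <- nrow(states)
  stopifnot(n == choose(N + k, k))
  key <- seq_len(n)
  names(key) <- apply(states, 1L, paste, collapse = ",")
  structure(
    list(k = k, N = N, states = states, n_states = n, key = key),
    class = "allele_state_space"
  )
}

# All non-negative integer vectors of length k with sum <= N, in
# lexicographic order (recursive over the first coordinate).
.enumerate_simplex <- function(k, N) {
  if (k == 1L) {
    return(matrix(0:N, ncol = 1L))
  }
  blocks <- lapply(0:N, function(x1) {
    tail <- .enumerate_simplex(k - 1L, N - x1)
    cbind(x1, tail, deparse.level = 0L)
  })
  do.call(rbind, blocks)
}

#' Map states to indices and back
#'
#' @param space An `allele_state_space`.
#' @param x A state: integer vector of length `space$k` (or a matrix with
#'   one state per row).
#' @return `state_index()` returns integer indices (1-based);
#'   `index_state()` returns the state(s) at the given indices.
#' @export
state_index <- function(space, x) {
  stopifnot(inherits(space, "allele_state_space"))
  if (is.matrix(x)) {
    keys <- apply(x, 1L, paste, collapse = ",")
  } else {
    stopifnot(length(x) == space$k)
    keys <- paste(x, collapse = ",")
  }
  idx <- unname(space$key[keys])
  if (anyNA(idx)) stop("state not in state space", call. = FALSE)
  idx
}

#' @rdname state_index
#' @param i Integer index (1-based) or vector of indices.
#' @export
index_state <- function(space, i) {
  stopifnot(inherits(space, "allele_state_space"))
  space$states[i, , drop = TRUE]
}

#' @export
print.allele_state_space <- function(x, ...) {
  cat(sprintf(
    "k-allele Moran state space: k = %d tracked mutant haplotypes, N = %d, %d states\n",
    x$k, x$N, x$n_states
  ))
  invisible(x)
}

#' Haplotype fitnesses from per-mutation relative fitnesses
#'
#' Under complete linkage the i-th tracked haplotype carries mutations
#' 1..i, and with multiplicative fitness effects its fitness relative to
#' the wild type is the cumulative product \eqn{f^*_i = \prod_{j \le i} f_j},
#' where \eqn{f_j} is the fitness of the j-th mutation relative to the
#' wild-type character at its site.
#'
#' @param f Numeric vector of per-mutation relative fitnesses, all > 0.
#' @return Numeric vector of haplotype fitnesses `cumprod(f)`.
#' @examples
#' haplotype_fitnesses(c(2, 0.5)) # c(2, 1)
#' @export
haplotype_fitnesses <- function(f) {
  if (length(f) < 1L || !is.numeric(f) || anyNA(f) || any(f <= 0)) {
    stop("all mutation fitnesses must be numeric and > 0", call. = FALSE)
  }
  cumprod(as.numeric(f))
}
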