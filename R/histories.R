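#' Branch scenario for K substitutions
#'
#' Parameters of a branch carrying `K` observed substitutions under the
#' tracked (conditioned) infinite-sites model: population size, branch
#' length, per-mutation relative fitnesses, and optionally the fixed
#' arrival times.
#'
#' @param N Population size (>= 2).
#' @param f Numeric vector of per-mutation relative fitnesses (length K,
#'   all > 0), in arrival order.
#' @param tb Branch length (> 0; `Inf` allowed with fixed times).
#' @param times Optional fixed, ordered mutation times
#'   `0 <= t1 <= ... <= tK <= tb`.
#' @return Object of class `branch_scenario`.
#' @export
branch_scenario <- function(N, f, tb, times = NULL) {
  stopifnot(N >= 2, N == round(N), tb > 0, length(f) >= 1, all(f > 0))
  if (!is.null(times)) {
    if (length(times) != length(f)) {
      stop("`times` must have one entry per mutation", call. = FALSE)
    }
    if (is.unsorted(times) || times[1] < 0 || times[length(times)] > tb) {
      stop("need 0 <= t1 <= ... <= tK <= tb", call. = FALSE)
    }
  }
  structure(
    list(N = as.integer(N), f = as.numeric(f), K = length(f),
         tb = tb, times = times),
    class = "branch_scenario"
  )
}

#' Enumerate fixation histories
#'
#' A fixation history for a branch with `K` substitutions is a binary
#' string of length `K - 1` whose i-th digit is 1 when a fixation event
#' separates the i-th and (i+1)-th mutations (the final fixation, between
#' the K-th mutation and the branch end, is implied).  There are
#' `2^(K-1)` histories; for `K = 1` the single history is the empty
#' string.  "0" digits mean the flanking mutations fixed together on one
#' haplotype.
#'
#' @param K Number of substitutions (>= 1).
#' @return Character vector of all `2^(K-1)` histories, lexicographic.
#' @examples
#' enumerate_histories(3) # "00" "01" "10" "11"
#' @export
enumerate_histories <- function(K) {
  if (length(K) != 1L || is.na(K) || K < 1 || K != round(K)) {
    stop("`K` must be a single integer >= 1", call. = FALSE)
  }
  if (K == 1) return("")
  grid <- expand.grid(rep(list(c("0", "1")), K - 1), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_len(K - 1)), drop = FALSE], 1, paste, collapse = ""))
}

# ---- tracked-mass propagation ------------------------------------------

# Cache of state spaces / generators / dimension-growth maps, keyed within
# one propagation run so repeated intervals (MC draws, shared prefixes)
# reuse structure.
.prop_cache <- function(N) {
  env <- new.env(parent = emptyenv())
  env$N <- N
  env
}

.cached_space <- function(cache, k) {
  key <- paste0("s", k)
  if (is.null(cache[[key]])) cache[[key]] <- enumerate_states(k, cache$N)
  cache[[key]]
}

.cached_generator <- function(cache, fstar) {
  key <- paste0("g", length(fstar), ":", paste(signif(fstar, 15), collapse = ","))
  if (is.null(cache[[key]])) {
    cache[[key]] <- build_generator(.cached_space(cache, length(fstar)), fstar)
  }
  cache[[key]]
}

# index remap for dimension growth k -> k+1: rows with 0 < x_k < N of
# space k map to (x - e_k) concatenated with 1 in space k+1, weighted
# x_k/N.  The fully fixed state x_k = N is excluded: a new mutation
# arriving there means a fixation separated the two mutations, which is
# the digit-1 branch — including it here would double-count that mass
# (and for k = 1 would break the equivalence with the pair formula, whose
# same-lineage sum runs over segregating counts i = 1..N-1 only).
.cached_growth_map <- function(cache, k) {
  key <- paste0("m", k)
  if (is.null(cache[[key]])) {
    sp <- .cached_space(cache, k)
    sp2 <- .cached_space(cache, k + 1L)
    src <- which(sp$states[, k] > 0 & sp$states[, k] < cache$N)
    y <- sp$states[src, , drop = FALSE]
    y[, k] <- y[, k] - 1L
    dst <- state_index(sp2, cbind(y, 1L))
    cache[[key]] <- list(src = src, dst = dst,
                         weight = sp$states[src, k] / cache$N)
  }
  cache[[key]]
}

# index of the fully-fixed state (0, ..., 0, N) in the k-tracked space
.fixed_index <- function(cache, k) {
  sp <- .cached_space(cache, k)
  state_index(sp, c(rep(0L, k - 1L), cache$N))
}

#' Apply a mutation-arrival update to a tracked distribution
#'
#' At the arrival of the next tracked mutation, the sub-probability mass of
#' the active process is remapped according to the next history digit:
#' \describe{
#'   \item{digit `"0"` (no intervening fixation)}{the tracked dimension
#'     grows by one: mass at a state with `y` carriers of the most-derived
#'     haplotype sends weight `y/N` to the grown state with one of those
#'     carriers now bearing the new mutation (the new mutation must arise
#'     in a carrier of the full current stack, else not all mutations can
#'     fix under complete linkage — that mass is dropped);}
#'   \item{digit `"1"` (intervening fixation)}{only the mass at the fully
#'     fixed state `(0, ..., 0, N)` survives; the wild type is redefined
#'     and the process restarts as a fresh two-allele process with the new
#'     mutation at one copy.}
#' }
#' Total mass never increases.
#'
#' @param d Tracked distribution: list with `k` (tracked haplotypes) and
#'   `mass` (sub-probability vector over [enumerate_states()]`(k, N)`).
#' @param digit `"0"` or `"1"`.
#' @param N Population size.
#' @return Updated tracked distribution (list with `k`, `mass`).
#' @export
mutation_event_update <- function(d, digit, N) {
  cache <- .prop_cache(N)
  .mutation_update(cache, d, digit)
}

.mutation_update <- function(cache, d, digit) {
  if (digit == "1") {
    m <- d$mass[.fixed_index(cache, d$k)]
    mass <- numeric(.cached_space(cache, 1L)$n_states)
    mass[2L] <- m                       # one copy of the new mutation
    list(k = 1L, mass = mass)
  } else {
    map <- .cached_growth_map(cache, d$k)
    mass <- numeric(.cached_space(cache, d$k + 1L)$n_states)
    contrib <- d$mass[map$src] * map$weight
    mass[map$dst] <- mass[map$dst] + contrib
    list(k = d$k + 1L, mass = mass)
  }
}

# Propagate one interval of length dt under nested fitnesses f[kappa..i].
.interval_propagate <- function(cache, d, f, kappa, i, dt) {
  fstar <- cumprod(f[kappa:i])
  g <- .cached_generator(cache, fstar)
  d$mass <- expm_action(g$rates, d$mass, dt)
  d
}

#' Probability of a fixation history, fixed mutation times
#'
#' Propagates the tracked sub-probability mass through the `K` intervals of
#' the branch.  During the interval following mutation `i` the active
#' process tracks the nested haplotypes of mutations `kappa..i`, where
#' `kappa - 1` is the last mutation fixed before an intervening fixation
#' digit (wild type is redefined at each fixation), with haplotype
#' fitnesses `cumprod(f[kappa:i])`.  At each subsequent arrival the mass is
#' remapped per [mutation_event_update()], and the probability of the
#' history is the terminal mass at the fully fixed state.  Summed over all
#' histories this gives the probability that all `K` tracked mutations fix
#' by `tb`.
#'
#' @param s A [branch_scenario()] with fixed `times`.
#' @param H History string (length `K - 1`, see [enumerate_histories()]).
#' @param k_cap Refuse branches with more than this many substitutions
#'   (state space `choose(N + K, K)` grows combinatorially); default 5.
#' @return Probability of history `H`.
#' @export
history_probability <- function(s, H, k_cap = 5) {
  stopifnot(inherits(s, "branch_scenario"))
  if (is.null(s$times)) stop("`history_probability` needs fixed times", call. = FALSE)
  probs <- .history_probabilities_fixed(s, k_cap = k_cap)
  if (!H %in% names(probs)) stop("invalid history for this K", call. = FALSE)
  unname(probs[H])
}

#' All fixation-history probabilities, fixed mutation times
#'
#' Computes every history's probability in one pass: histories sharing an
#' i-th subhistory have identical tracked mass before the (i+1)-th arrival,
#' so prefixes are propagated once and branched at each arrival.
#'
#' @inheritParams history_probability
#' @return Named numeric vector over [enumerate_histories()]`(K)`.
#' @export
history_probabilities <- function(s, k_cap = 5) {
  stopifnot(inherits(s, "branch_scenario"))
  if (is.null(s$times)) stop("needs fixed times", call. = FALSE)
  .history_probabilities_fixed(s, k_cap = k_cap)
}

.check_k_cap <- function(K, N, k_cap) {
  if (K > k_cap) {
    stop(sprintf(
      paste0("K = %d exceeds the cap of %d tracked substitutions: the largest ",
             "state space would hold choose(N + K, K) = %g states. ",
             "Raise `k_cap` explicitly to proceed."),
      K, k_cap, choose(N + K, K)
    ), call. = FALSE)
  }
}

.history_probabilities_fixed <- function(s, k_cap = 5, cache = NULL) {
  K <- s$K
  .check_k_cap(K, s$N, k_cap)
  if (is.null(cache)) cache <- .prop_cache(s$N)
  t_all <- c(s$times, s$tb)
  final_dt <- t_all[K + 1L] - t_all[K]

  terminal <- function(d, kappa) {
    # mass at the fully-fixed state after the last interval; tb = Inf uses
    # the long-run absorption probabilities instead of a finite action
    fstar <- cumprod(s$f[kappa:K])
    if (is.infinite(final_dt)) {
      g <- .cached_generator(cache, fstar)
      h <- absorption_probabilities(g, c(rep(0L, d$k - 1L), s$N))
      sum(d$mass * h)
    } else {
      g <- .cached_generator(cache, fstar)
      mass <- expm_action(g$rates, d$mass, final_dt)
      mass[.fixed_index(cache, d$k)]
    }
  }

  out <- numeric(0)
  # depth-first over history prefixes; d is the mass at time t_{i}+ after
  # the i-th arrival, kappa the first mutation of the active nested set
  recurse <- function(d, kappa, i, prefix) {
    if (i == K) {
      p <- terminal(d, kappa)
      names(p) <- prefix
      out <<- c(out, p)
      return(invisible())
    }
    dt <- t_all[i + 1L] - t_all[i]
    d <- .interval_propagate(cache, d, s$f, kappa, i, dt)
    for (digit in c("0", "1")) {
      d2 <- .mutation_update(cache, d, digit)
      kappa2 <- if (digit == "1") i + 1L else kappa
      recurse(d2, kappa2, i + 1L, paste0(prefix, digit))
    }
  }

  init <- list(k = 1L, mass = {
    v <- numeric(s$N + 1L); v[2L] <- 1; v
  })
  recurse(init, 1L, 1L, "")
  if (K == 1L) {
    names(out) <- ""
    out
  } else {
    out[enumerate_histories(K)]
  }
}

#' Fixation-history probabilities with random mutation times
#'
#' Integrates [history_probabilities()] over the arrival-time distribution
#' (conditional on `K` Poisson arrivals the times are the order statistics
#' of `K` iid uniforms on `[0, tb]`) by Monte Carlo over sorted-uniform
#' draws.  Shared subhistory prefixes are propagated once per draw, and the
#' state-space/generator caches persist across draws.
#'
#' @inheritParams history_probability
#' @param draws Number of Monte-Carlo time draws (default `1e4`).
#' @param seed Optional integer seed (recorded in the output).
#' @return List with `estimate` (named vector over histories: `P(H | tb)`,
#'   i.e. the probability that all K mutations fix with pattern `H`), `se`
#'   (Monte-Carlo standard errors), `total` and `total_se` (the summed
#'   probability that all K fix), `draws`, `seed`.
#' @export
history_probabilities_random_times <- function(s, draws = 1e4, seed = NULL,
                                               k_cap = 5) {
  stopifnot(inherits(s, "branch_scenario"))
  if (!is.null(s$times)) stop("scenario already has fixed times", call. = FALSE)
  if (is.infinite(s$tb)) stop("random times need a finite branch length", call. = FALSE)
  .check_k_cap(s$K, s$N, k_cap)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cache <- .prop_cache(s$N)
  hs <- enumerate_histories(s$K)
  acc <- matrix(0, nrow = draws, ncol = length(hs), dimnames = list(NULL, hs))
  for (r in seq_len(draws)) {
    tt <- sort(stats::runif(s$K, 0, s$tb))
    sf <- branch_scenario(s$N, s$f, s$tb, times = tt)
    acc[r, ] <- .history_probabilities_fixed(sf, k_cap = k_cap, cache = cache)
  }
  est <- colMeans(acc)
  se <- apply(acc, 2, stats::sd) / sqrt(draws)
  tot <- rowSums(acc)
  list(
    estimate = est, se = se,
    total = mean(tot), total_se = stats::sd(tot) / sqrt(draws),
    draws = draws, seed = seed
  )
}

#' @rdname history_probabilities_random_times
#' @param H History string.
#' @return `history_probability_random_times()`: list with `estimate`,
#'   `se`, `draws`, `seed` for the single history `H`.
#' @export
history_probability_random_times <- function(s, H, draws = 1e4, seed = NULL,
                                             k_cap = 5) {
  all <- history_probabilities_random_times(s, draws = draws, seed = seed,
                                            k_cap = k_cap)
  if (!H %in% names(all$estimate)) stop("invalid history for this K", call. = FALSE)
  list(estimate = unname(all$estimate[H]), se = unname(all$se[H]),
       draws = draws, seed = seed)
}
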