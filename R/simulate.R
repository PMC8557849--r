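#' Canonical amino-acid alphabet
#'
#' Fixed one-letter order used by all fitness tables and mutation matrices
#' in this package.
#' @export
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Finite-sites model configuration
#'
#' Parameters of the exact finite-sites Moran model: a population of `N`
#' genomes of `M` completely linked sites over a character alphabet
#' (default the 20 amino acids), a sitewise fitness table
#' \eqn{f_j(A) > 0}, and a mutation-rate matrix \eqn{\mu(A, B) \ge 0} with
#' zero diagonal.  Individual fitness is multiplicative across sites:
#' \eqn{f(X_k) = \prod_j f_j(X_{kj})}.
#'
#' @param N Population size (>= 2).
#' @param site_fitness `M x A` numeric matrix (or data frame) of sitewise
#'   fitnesses; columns must be named by (and are reordered to) the
#'   alphabet.
#' @param mutation_rate `A x A` numeric matrix of mutation rates, zero
#'   diagonal, rows/columns in alphabet order.
#' @param alphabet Character vector of states (default [AMINO_ACIDS]).
#' @return Object of class `finite_sites_config`.
#' @export
finite_sites_config <- function(N, site_fitness, mutation_rate,
                                alphabet = AMINO_ACIDS) {
  stopifnot(N >= 2, N == round(N))
  A <- length(alphabet)
  site_fitness <- as.matrix(site_fitness)
  if (!is.null(colnames(site_fitness))) {
    if (!setequal(colnames(site_fitness), alphabet)) {
      stop("fitness table columns must match the alphabet", call. = FALSE)
    }
    site_fitness <- site_fitness[, alphabet, drop = FALSE]
  } else if (ncol(site_fitness) != A) {
    stop("fitness table must have one column per alphabet character",
         call. = FALSE)
  }
  if (any(site_fitness <= 0)) stop("all sitewise fitnesses must be > 0", call. = FALSE)
  mutation_rate <- as.matrix(mutation_rate)
  if (!all(dim(mutation_rate) == c(A, A))) {
    stop("mutation matrix must be alphabet-square", call. = FALSE)
  }
  if (any(mutation_rate < 0) || any(diag(mutation_rate) != 0)) {
    stop("mutation rates must be >= 0 with a zero diagonal", call. = FALSE)
  }
  structure(
    list(N = as.integer(N), M = nrow(site_fitness), alphabet = alphabet,
         site_fitness = site_fitness, mutation_rate = mutation_rate),
    class = "finite_sites_config"
  )
}

#' Exact Gillespie simulation of the finite-sites Moran model
#'
#' Realizes the finite-sites process event by event: replacement of
#' individual `i` by a copy of individual `j` at rate
#' \eqn{f(X_j) / (N \sum_k f(X_k))} per ordered pair (so the total
#' replacement rate, self-replacements included, is exactly 1 per unit
#' time), and character mutations \eqn{A \to B} at rate \eqn{\mu(A, B)}
#' per site per individual.  A substitution is logged whenever a site
#' becomes monomorphic for a character differing from its current
#' reference character (the character fixed at `t = 0`, updated after each
#' substitution, so re-substitutions at a site are logged separately).
#'
#' @param cfg A [finite_sites_config()].
#' @param tb Branch length / simulation horizon (> 0).
#' @param init Initial population: `N x M` character matrix, or a vector
#'   of `M` characters for a monomorphic start.  Default: monomorphic for
#'   the fittest character at each site.
#' @param seed Optional integer seed (recorded in the log).
#' @param record_events Keep the full event log (default TRUE); the
#'   substitution log is always kept.
#' @param max_events Cap on logged events (simulation continues beyond it;
#'   `events_truncated` is flagged).
#' @return Object of class `event_log`: list with `population` (final
#'   `N x M` character matrix), `events` (data frame: time, kind
#'   "replacement"/"mutation", individual, parent, site, from, to),
#'   `substitutions` (data frame: time, site, from, to), `n_events`,
#'   `t_end`, `seed`, `config`.
#' @export
simulate_finite_sites <- function(cfg, tb, init = NULL, seed = NULL,
                                  record_events = TRUE, max_events = 1e6) {
  stopifnot(inherits(cfg, "finite_sites_config"), tb > 0)
  if (!is.null(seed)) set.seed(seed)
  pop <- .init_population(cfg, init)
  res <- cpp_finite_sites(pop, cfg$site_fitness, cfg$mutation_rate, tb,
                          record_events, as.integer(max_events))
  al <- cfg$alphabet
  events <- res$events
  events$kind <- c("replacement", "mutation")[events$kind + 1L]
  events$individual <- events$individual + 1L
  events$parent <- events$parent + 1L
  events$site <- events$site + 1L
  events$from <- al[events$from + 1L]
  events$to <- al[events$to + 1L]
  subs <- res$substitutions
  subs$site <- subs$site + 1L
  subs$from <- al[subs$from + 1L]
  subs$to <- al[subs$to + 1L]
  final <- matrix(al[res$population + 1L], nrow = cfg$N)
  structure(
    list(population = final, events = events,
         events_truncated = res$events_truncated,
         substitutions = subs, n_events = res$n_events,
         t_end = res$t_end, tb = tb, seed = seed, config = cfg),
    class = "event_log"
  )
}

.init_population <- function(cfg, init) {
  al <- cfg$alphabet
  if (is.null(init)) {
    best <- al[apply(cfg$site_fitness, 1L, which.max)]
    init <- best
  }
  if (!is.matrix(init)) {
    stopifnot(length(init) == cfg$M)
    init <- matrix(rep(init, each = cfg$N), nrow = cfg$N)
  }
  stopifnot(all(dim(init) == c(cfg$N, cfg$M)), all(init %in% al))
  matrix(match(init, al) - 1L, nrow = cfg$N)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf(
    "Finite-sites Moran realization: N = %d, M = %d, tb = %g\n  %s events, %d substitutions logged\n",
    x$config$N, x$config$M, x$tb, format(x$n_events, big.mark = ","),
    nrow(x$substitutions)
  ))
  invisible(x)
}

#' Conditioned Monte-Carlo replicates of the tracked pair process
#'
#' Simulates the tracked infinite-sites model for `K = 2` exactly as the
#' pair calculus describes it: two mutation times drawn as sorted uniforms
#' on `[0, tb]` (conditioning on exactly two Poisson arrivals), a
#' two-allele jump-chain interval for the first mutation, lineage
#' assignment of the second mutation to a carrier of the first with
#' probability `i/N`, then the appropriate two- or three-allele interval
#' to the branch end.  Replicates are classified as fixed-together
#' (double-mutant haplotype at count `N` at `tb`), fixed-separately (first
#' fixed before the second arrival, second fixed by `tb`), or failed.
#'
#' @inheritParams p_together_random_times
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed (recorded in the output).
#' @return List with `n_together`, `n_separate`, `n_failed`, `n_reps`,
#'   `p_together_given_fix` (the conditioned estimate with its binomial
#'   `se`), and `seed`.
#' @export
tracked_pair_replicates <- function(N, f1, f2, tb, n_reps, seed = NULL) {
  res <- tracked_k_replicates(N, c(f1, f2), tb, n_reps, seed = seed)
  n_tog <- unname(res$counts["0"])
  n_sep <- unname(res$counts["1"])
  n_fix <- n_tog + n_sep
  p <- if (n_fix > 0) n_tog / n_fix else NA_real_
  list(
    n_together = n_tog, n_separate = n_sep, n_failed = res$n_failed,
    n_reps = n_reps,
    p_together_given_fix = p,
    se = if (n_fix > 0) sqrt(p * (1 - p) / n_fix) else NA_real_,
    seed = seed
  )
}

#' Conditioned Monte-Carlo replicates of the tracked process, general K
#'
#' Direct generalization of [tracked_pair_replicates()]: each replicate
#' draws `K` sorted uniform arrival times, simulates the nested k-allele
#' intervals, and is classified into the fixation history it realizes
#' (all `K` mutations fixed) or "failed".  A new mutation must arise in a
#' carrier of the most-derived tracked haplotype (probability `x_k/N`) for
#' all mutations to be able to fix under complete linkage; other
#' placements fail the replicate.
#'
#' @inheritParams branch_scenario
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @return List with `counts` (named by history, see
#'   [enumerate_histories()]), `n_failed`, `n_reps`, `seed`.
#' @export
tracked_k_replicates <- function(N, f, tb, n_reps, seed = NULL) {
  stopifnot(N >= 2, all(f > 0), tb > 0, n_reps >= 1)
  K <- length(f)
  if (K > 5) stop("K > 5 unsupported (combinatorial state growth)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_tracked_k_replicates(as.integer(N), as.numeric(f), tb,
                                  as.integer(n_reps))
  n_hist <- 2^(K - 1)
  hs <- enumerate_histories(K)
  # C++ encodes digit i of the history in bit (K-2-i): binary value order
  val <- if (K == 1) 0L else strtoi(hs, base = 2L)
  counts <- raw[val + 1L]
  names(counts) <- hs
  list(counts = counts, n_failed = raw[n_hist + 1L], n_reps = n_reps,
       seed = seed)
}
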