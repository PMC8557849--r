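#' Pair scenario: two substitutions on one branch
#'
#' Bundles the parameters of the K = 2 calculus: population size `N`,
#' relative fitnesses `f1` (first-arriving mutation) and `f2` (second),
#' branch length `tb`, and optionally the fixed arrival times
#' `0 <= t1 <= t2 <= tb`.  When `t1`/`t2` are omitted the scenario is in
#' random-times mode (mutations arrive as a Poisson process; conditional on
#' two arrivals the times are iid uniform on `[0, tb]`).  All times are in
#' units of expected birth/death events (`N` units ~ 1 generation).
#' `tb = Inf` is allowed with fixed times and uses long-run absorption
#' probabilities for the final interval.
#'
#' @param N Population size (>= 2).
#' @param f1,f2 Relative fitnesses (> 0) of the first and second mutation.
#' @param tb Branch length (> 0, possibly `Inf`).
#' @param t1,t2 Optional fixed mutation times.
#' @return Object of class `pair_scenario`.
#' @export
pair_scenario <- function(N, f1, f2, tb, t1 = NULL, t2 = NULL) {
  stopifnot(N >= 2, N == round(N), f1 > 0, f2 > 0, tb > 0)
  fixed <- !is.null(t1) || !is.null(t2)
  if (fixed) {
    if (is.null(t1) || is.null(t2)) {
      stop("supply both `t1` and `t2`, or neither", call. = FALSE)
    }
    if (!(t1 >= 0 && t1 <= t2 && t2 <= tb)) {
      stop("need 0 <= t1 <= t2 <= tb", call. = FALSE)
    }
  }
  structure(
    list(N = as.integer(N), f1 = f1, f2 = f2, tb = tb,
         t1 = t1, t2 = t2, fixed_times = fixed),
    class = "pair_scenario"
  )
}

# fixation-by-time probability from 1 copy, honouring t = Inf
.pfix_by <- function(N, f, t) {
  if (is.infinite(t)) longrun_fixation_probability(N, f, 1) else fixation_cdf_exact(N, f, t)
}

#' Probability that two substitutions fixed independently
#'
#' For fixed mutation times, the probability that the first mutation fixed
#' in `[t1, t2)` *and* the second then fixed in `[t2, tb]`:
#' the product of two two-allele fixation-by-time probabilities, each from
#' a single copy (after the first fixation the wild type is redefined, so
#' the second sweep is again a fresh two-allele process).
#'
#' @param s A [pair_scenario()] with fixed times.
#' @return Probability `p_I`.
#' @export
p_independent <- function(s) {
  stopifnot(inherits(s, "pair_scenario"))
  if (!s$fixed_times) stop("`p_independent` needs fixed mutation times", call. = FALSE)
  .pfix_by(s$N, s$f1, s$t2 - s$t1) * .pfix_by(s$N, s$f2, s$tb - s$t2)
}

#' Probability that two substitutions fixed together
#'
#' For fixed mutation times: the first mutation is still segregating at
#' `t2` with `i` copies (two-allele transient mass), the second mutation
#' arises in a carrier of the first (probability `i/N` — the same-lineage
#' event), and the double-mutant haplotype, with fitness `f1*f2`, then
#' reaches count `N` by `tb` in the three-allele process started from
#' `(i - 1, 1)` with haplotype fitnesses `(f1, f1*f2)`:
#' \deqn{p_T = \sum_{i=1}^{N-1} a_i(t_2 - t_1)\,\frac{i}{N}\,
#'       [e_{(i-1,1)}\, e^{Q(f_1, f_1 f_2)(t_b - t_2)}]_{(0,N)}.}
#' The three-allele factor for *all* initial states is obtained in one
#' backward pass: a single right-action `exp(Q t) e_{(0,N)}` (finite `tb`)
#' or a single sparse absorption solve (`tb = Inf`) — never `N - 1`
#' separate exponentials.
#'
#' Only mass in which the second mutation is nested inside the first
#' lineage can end with both mutations fixed (complete linkage: two
#' non-nested haplotypes cannot both reach frequency 1), so mass where the
#' second mutation lands on a wild-type background, and three-allele mass
#' that ends with only the first mutation fixed, count toward neither
#' `p_T` nor `p_I`.
#'
#' @param s A [pair_scenario()] with fixed times.
#' @return Probability `p_T`.
#' @export
p_together <- function(s) {
  stopifnot(inherits(s, "pair_scenario"))
  if (!s$fixed_times) stop("`p_together` needs fixed mutation times", call. = FALSE)
  N <- s$N
  a <- transient_distribution(N, s$f1, 1, s$t2 - s$t1)   # mass over 0..N at t2
  g3 <- build_generator(enumerate_states(2L, N), haplotype_fitnesses(c(s$f1, s$f2)))
  w <- .reach_target_by(g3, c(0L, N), s$tb - s$t2)
  i <- seq_len(N - 1)
  idx <- state_index(g3$space, cbind(i - 1L, 1L))
  sum(a[i + 1L] * (i / N) * w[idx])
}

# P(reach absorbing `target` by time t | start state), for every start
# state, via one backward action (or one absorption solve when t = Inf).
.reach_target_by <- function(g, target, t) {
  if (is.infinite(t)) {
    return(absorption_probabilities(g, target))
  }
  e <- numeric(g$space$n_states)
  e[state_index(g$space, target)] <- 1
  w <- expm_action(g$rates, e, t, side = "right")
  pmin(pmax(w, 0), 1)
}

#' Conditional probability of fixing together, fixed times
#'
#' `p_T / (p_T + p_I)`: given both substitutions fixed on the branch, the
#' probability that they fixed together rather than sequentially.  This is
#' also the relative error incurred by an independent-sites model, which
#' accounts only for the sequential history.
#'
#' @param s A [pair_scenario()] with fixed times.
#' @return Probability in \[0, 1\].
#' @export
p_together_given_fix <- function(s) {
  pT <- p_together(s)
  pI <- p_independent(s)
  tot <- pT + pI
  if (tot < 1e-300) {
    stop("P(both fix) is numerically zero; conditional probability undefined",
         call. = FALSE)
  }
  pT / tot
}

#' Probability of fixing together with random mutation times
#'
#' Mutations arrive as a Poisson process; conditional on exactly two
#' arrivals on the branch their times are iid uniform on `[0, tb]` (joint
#' density `1/tb^2`).  The conditional probability that the two mutations
#' fixed together given that both fixed is the ratio of integrated
#' probabilities
#' \deqn{P(E_T \mid E_F) = \frac{\int p_T}{\int (p_T + p_I)},}
#' where the integrals run over both arrival orders (the roles of
#' `(f1, t1)` and `(f2, t2)` swapped in the second term), making the result
#' symmetric in `f1`, `f2` by construction.  Integration uses tensor
#' Gauss–Legendre quadrature on the ordered region parameterized by the
#' time between mutations and the time remaining after the second.
#'
#' The integrand depends on the times only through `v = t2 - t1` and
#' `w = tb - t2`, so the ordered region is the triangle `v + w <= tb`.
#'
#' @inheritParams pair_scenario
#' @param nodes Gauss–Legendre nodes per dimension (default 24; a run at
#'   32 is used as a convergence check by the test suite).
#' @return The conditional probability `P(fix together | both fix)`, with
#'   attributes `p_fix_together`, `p_fix_separate` (unconditional, given
#'   two arrivals) and `mean_conditional` (the unweighted average of
#'   `p_T/(p_T+p_I)` under the prior time density, for reference).
#' @export
p_together_random_times <- function(N, f1, f2, tb, nodes = 24) {
  stopifnot(N >= 2, f1 > 0, f2 > 0, is.finite(tb), tb > 0)
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  one_order <- function(fa, fb) {
    # integrate p_T, p_I over {v >= 0, w >= 0, v + w <= tb}, v = tb*x,
    # w = (tb - v)*y, Jacobian tb*(tb - v); also accumulate the ratio
    # integral for the unweighted average-of-conditionals variant.
    g3 <- build_generator(enumerate_states(2L, N), haplotype_fitnesses(c(fa, fb)))
    idx3 <- state_index(g3$space, cbind(seq_len(N - 1) - 1L, 1L))
    tgt3 <- numeric(g3$space$n_states)
    tgt3[state_index(g3$space, c(0L, N))] <- 1
    g2a <- two_allele_generator(N, fa)
    g2b <- two_allele_generator(N, fb)
    e1 <- numeric(N + 1L); e1[2L] <- 1
    IT <- II <- IR <- 0
    for (ix in seq_len(nodes)) {
      v <- tb * gl$x[ix]
      a <- expm_action(g2a$rates, e1, v)
      p1fix <- a[N + 1L]
      for (iy in seq_len(nodes)) {
        w <- (tb - v) * gl$x[iy]
        jac <- tb * (tb - v)
        wt <- gl$w[ix] * gl$w[iy] * jac
        reach <- expm_action(g3$rates, tgt3, w, side = "right")
        i <- seq_len(N - 1)
        pT <- sum(a[i + 1L] * (i / N) * reach[idx3])
        pI <- p1fix * expm_action(g2b$rates, e1, w)[N + 1L]
        IT <- IT + wt * pT
        II <- II + wt * pI
        if (pT + pI > 0) IR <- IR + wt * pT / (pT + pI)
      }
    }
    c(IT = IT, II = II, IR = IR)
  }
  o1 <- one_order(f1, f2)
  o2 <- if (isTRUE(all.equal(f1, f2))) o1 else one_order(f2, f1)
  IT <- (o1["IT"] + o2["IT"]) / tb^2
  II <- (o1["II"] + o2["II"]) / tb^2
  out <- unname(IT / (IT + II))
  attr(out, "p_fix_together") <- unname(IT)
  attr(out, "p_fix_separate") <- unname(II)
  attr(out, "mean_conditional") <- unname((o1["IR"] + o2["IR"]) / tb^2)
  out
}
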