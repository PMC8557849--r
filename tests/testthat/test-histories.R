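test_that("history enumeration counts 2^(K-1) and matches the K = 3 cases", {
  expect_equal(enumerate_histories(1), "")
  expect_setequal(enumerate_histories(2), c("0", "1"))
  for (K in 1:6) expect_length(enumerate_histories(K), 2^(K - 1))
  # K = 3: all separate (11); first two together (01); last two together
  # (10); all three together (00)
  expect_setequal(enumerate_histories(3), c("00", "01", "10", "11"))
  expect_error(enumerate_histories(0), "K")
})

test_that("mutation-event updates move mass as the model prescribes", {
  N <- 6
  # digit 1: mass at the fully fixed state restarts at one copy
  d <- list(k = 1L, mass = c(rep(0, N), 0.37))
  up <- mutation_event_update(d, "1", N)
  expect_equal(up$k, 1L)
  expect_equal(up$mass[2], 0.37)
  expect_equal(sum(up$mass), 0.37)

  # digit 0 from a pure state with y carriers: weight y/N to (y-1, 1)
  y <- 4
  d0 <- list(k = 1L, mass = replace(numeric(N + 1), y + 1, 1))
  up0 <- mutation_event_update(d0, "0", N)
  expect_equal(up0$k, 2L)
  sp2 <- enumerate_states(2, N)
  expect_equal(up0$mass[state_index(sp2, c(y - 1L, 1L))], y / N)
  expect_equal(sum(up0$mass), y / N)

  # mass never increases under either digit
  set.seed(2)
  m <- runif(N + 1); m <- m / sum(m)
  d1 <- list(k = 1L, mass = m)
  expect_lte(sum(mutation_event_update(d1, "0", N)$mass), sum(m) + 1e-12)
  expect_lte(sum(mutation_event_update(d1, "1", N)$mass), sum(m) + 1e-12)
})

test_that("K = 2 histories reproduce the pair calculus to 1e-10", {
  for (cs in list(c(3, 1, 1, 0, 20, 40), c(3, 1.4, 0.7, 2, 9, 35),
                  c(6, 1.2, 1.2, 1, 12, 50))) {
    s <- pair_scenario(cs[1], cs[2], cs[3], tb = cs[6], t1 = cs[4], t2 = cs[5])
    hp <- history_probabilities(
      branch_scenario(cs[1], c(cs[2], cs[3]), cs[6], times = c(cs[4], cs[5]))
    )
    expect_lt(abs(hp[["0"]] - p_together(s)), 1e-10)
    expect_lt(abs(hp[["1"]] - p_independent(s)), 1e-10)
  }
})

test_that("K = 1 reduces to the two-allele fixation probability", {
  hp <- history_probabilities(branch_scenario(10, 1.5, 30, times = 5))
  expect_equal(unname(hp), fixation_cdf_exact(10, 1.5, 25), tolerance = 1e-12)
})

test_that("histories partition the all-fix event: the total matches
           conditioned Monte Carlo at K = 3", {
  s <- branch_scenario(3, c(1, 1, 1), 60, times = c(0, 20, 40))
  hp <- history_probabilities(s)
  expect_length(hp, 4L)
  expect_true(all(hp >= 0))
  expect_lte(sum(hp), 1)

  # simulation bridge at random times
  tk <- tracked_k_replicates(3, c(1, 1, 1), 30, 2e5, seed = 11)
  hr <- history_probabilities_random_times(
    branch_scenario(3, c(1, 1, 1), 30), draws = 2000, seed = 12
  )
  mc_p <- tk$counts / tk$n_reps
  mc_se <- sqrt(pmax(mc_p * (1 - mc_p), 1e-12) / tk$n_reps)
  z <- (mc_p - hr$estimate) / sqrt(mc_se^2 + hr$se^2)
  expect_true(all(abs(z) < 3))
})

test_that("interval dimension bookkeeping follows 1 + i - kappa", {
  # H = "10" at K = 3: fixation after mutation 1, then 2 and 3 together;
  # the final interval is a two-tracked (three-allele) process.  Compare
  # against an explicit composition of the pieces.
  N <- 4; f <- c(1.2, 0.9, 1.1); tt <- c(0, 8, 16); tb <- 50
  hp <- history_probabilities(branch_scenario(N, f, tb, times = tt))

  a1 <- transient_distribution(N, f[1], 1, tt[2] - tt[1])
  m_fixed <- a1[N + 1]
  a2 <- transient_distribution(N, f[2], 1, tt[3] - tt[2])
  g3 <- build_generator(enumerate_states(2, N), haplotype_fitnesses(f[2:3]))
  reach <- dense_expm(g3$rates, tb - tt[3])[, state_index(g3$space, c(0L, N))]
  idx <- state_index(g3$space, cbind(seq_len(N - 1) - 1L, 1L))
  manual <- m_fixed * sum(a2[2:N] * (seq_len(N - 1) / N) * reach[idx])
  expect_equal(hp[["10"]], manual, tolerance = 1e-10)
})

test_that("random-times Monte Carlo: totals are sub-probabilities, the SE
           shrinks like sqrt(draws), and seeds reproduce", {
  s <- branch_scenario(5, c(1, 1.3), 40)
  h1 <- history_probabilities_random_times(s, draws = 400, seed = 7)
  h2 <- history_probabilities_random_times(s, draws = 1600, seed = 7)
  expect_lte(h1$total, 1)
  expect_equal(h1$total_se / h2$total_se, 2, tolerance = 0.5)
  h1b <- history_probabilities_random_times(s, draws = 400, seed = 7)
  expect_identical(h1$estimate, h1b$estimate)

  single <- history_probability_random_times(s, "0", draws = 400, seed = 7)
  expect_equal(single$estimate, unname(h1$estimate["0"]))
})

test_that("the K cap refuses combinatorial state spaces with a clear error", {
  s <- branch_scenario(10, rep(1, 6), 50, times = seq(0, 25, 5))
  expect_error(history_probability(s, "00000"), "exceeds the cap")
  expect_error(
    tracked_k_replicates(10, rep(1, 6), 50, 10),
    "K > 5"
  )
})
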