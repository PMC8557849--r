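two_char_config <- function(N, f_mut, mu_rate = 0) {
  mu <- matrix(c(0, mu_rate, 0, 0), 2, 2, byrow = TRUE)
  finite_sites_config(
    N,
    matrix(c(1, f_mut), 1, 2, dimnames = list(NULL, c("A", "C"))),
    mu, alphabet = c("A", "C")
  )
}

one_mutant_start <- function(N) {
  init <- matrix("A", N, 1)
  init[1, 1] <- "C"
  init
}

test_that("a monomorphic population with no mutation never changes", {
  cfg <- two_char_config(8, 1.5)
  log <- simulate_finite_sites(cfg, tb = 50, init = matrix("A", 8, 1),
                               seed = 3)
  expect_true(all(log$population == "A"))
  expect_equal(nrow(log$substitutions), 0L)
  ev <- log$events
  expect_equal(nrow(ev[ev$kind == "mutation", ]), 0L)
})

test_that("finite-sites fixation fractions match the two-allele closed form", {
  set.seed(501)
  reps <- 2e4
  cfg <- two_char_config(10, 1)
  nfix <- 0
  for (r in seq_len(reps)) {
    log <- simulate_finite_sites(cfg, tb = 1e9, init = one_mutant_start(10),
                                 record_events = FALSE)
    if (all(log$population == "C")) nfix <- nfix + 1
  }
  p <- closed_form_pfix(10, 1)
  expect_lt(abs(nfix / reps - p), 3 * sqrt(p * (1 - p) / reps))
})

test_that("identical seeds replay identical event logs", {
  cfg <- two_char_config(6, 1.2, mu_rate = 0.02)
  a <- simulate_finite_sites(cfg, tb = 200, init = matrix("A", 6, 1), seed = 42)
  b <- simulate_finite_sites(cfg, tb = 200, init = matrix("A", 6, 1), seed = 42)
  expect_identical(a$events, b$events)
  expect_identical(a$substitutions, b$substitutions)
  expect_identical(a$population, b$population)
  expect_true(nrow(a$events) > 0)
  expect_true(all(diff(a$events$time) > 0))
})

test_that("event-time increments are exponential with total rate
           1 + total mutation rate", {
  # uniform mutation rates keep the total event rate constant:
  # 1 (replacement, self-replacements included) + N*M*mu_out
  N <- 6; mu_rate <- 0.05
  cfg <- two_char_config(N, 1, mu_rate = mu_rate)
  # symmetric mutation so the rate never changes
  cfg$mutation_rate <- matrix(c(0, mu_rate, mu_rate, 0), 2, 2)
  log <- simulate_finite_sites(cfg, tb = 4000, init = matrix("A", N, 1),
                               seed = 2718)
  incr <- diff(c(0, log$events$time))
  rate <- 1 + N * 1 * mu_rate
  ks <- suppressWarnings(stats::ks.test(incr, "pexp", rate))
  expect_gt(ks$p.value, 1e-4)
  expect_gt(length(incr), 2000)
})

test_that("substitutions are logged when a site fixes a new character", {
  cfg <- two_char_config(5, 3, mu_rate = 0.01)
  log <- simulate_finite_sites(cfg, tb = 3000, init = matrix("A", 5, 1),
                               seed = 11)
  expect_gt(nrow(log$substitutions), 0)
  first <- log$substitutions[1, ]
  expect_equal(first$from, "A")
  expect_equal(first$to, "C")
})

test_that("tracked replicates partition into histories plus failures", {
  tk <- tracked_k_replicates(6, c(1.2, 0.9), 30, 5000, seed = 9)
  expect_equal(sum(tk$counts) + tk$n_failed, 5000)
  expect_named(tk$counts, c("0", "1"))

  tp <- tracked_pair_replicates(6, 1.2, 0.9, 30, 5000, seed = 9)
  expect_equal(tp$n_together, unname(tk$counts["0"]))
  expect_equal(tp$n_separate, unname(tk$counts["1"]))
  expect_equal(tp$n_failed, tk$n_failed)
})

test_that("nearly lethal mutations essentially always fail", {
  tk <- tracked_k_replicates(8, c(1e-4, 1e-4), 50, 3000, seed = 13)
  expect_equal(tk$n_failed, 3000)
})

test_that("K = 1 tracked replicates count simple fixations", {
  N <- 8; tb <- 2000
  tk <- tracked_k_replicates(N, 1.5, tb, 2e4, seed = 21)
  # tb long: fixation-by-tb from one copy at a uniform arrival time is
  # close to the long-run probability for most arrival times
  gl <- pracma::gaussLegendre(24, 0, tb)
  pref <- sum(gl$w * fixation_cdf_exact(N, 1.5, tb - gl$x)) / tb
  phat <- tk$counts[[1]] / tk$n_reps
  expect_lt(abs(phat - pref), 3 * sqrt(pref * (1 - pref) / tk$n_reps))
})

test_that("finite-sites multi-site fitness is multiplicative across sites", {
  # two sites, advantageous double mutant; fitness table validated on load
  fit <- matrix(c(1, 2, 1, 3), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "C")))
  cfg <- finite_sites_config(4, fit, matrix(0, 2, 2), alphabet = c("A", "C"))
  init <- matrix("A", 4, 2)
  init[1, ] <- "C"   # one individual carries both derived characters
  set.seed(77)
  nfix <- 0; reps <- 4000
  for (r in seq_len(reps)) {
    log <- simulate_finite_sites(cfg, tb = 1e9, init = init,
                                 record_events = FALSE)
    if (all(log$population == "C")) nfix <- nfix + 1
  }
  p <- closed_form_pfix(4, 6)   # combined relative fitness 2 * 3
  expect_lt(abs(nfix / reps - p), 3 * sqrt(p * (1 - p) / reps))
})

test_that("config validation rejects malformed inputs", {
  expect_error(
    finite_sites_config(10, matrix(-1, 1, 2, dimnames = list(NULL, c("A", "C"))),
                        matrix(0, 2, 2), alphabet = c("A", "C")),
    "> 0"
  )
  mu_bad <- matrix(1, 2, 2)
  expect_error(
    finite_sites_config(10, matrix(1, 1, 2, dimnames = list(NULL, c("A", "C"))),
                        mu_bad, alphabet = c("A", "C")),
    "diagonal"
  )
})
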