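test_that("state enumeration matches direct counts and stated orders", {
  s <- enumerate_states(1, 3)
  expect_equal(s$states[, 1], 0:3)
  expect_equal(s$n_states, 4L)

  s2 <- enumerate_states(2, 2)
  expect_equal(
    s2$states,
    rbind(c(0L, 0L), c(0L, 1L), c(0L, 2L), c(1L, 0L), c(1L, 1L), c(2L, 0L))
  )
  expect_equal(enumerate_states(3, 10)$n_states, 286L)

  expect_error(enumerate_states(0, 5), "k")
  expect_error(enumerate_states(2, 1), "N")
})

test_that("state/index mapping is a bijection and sums stay within N", {
  for (case in list(c(1, 8), c(2, 6), c(3, 4))) {
    sp <- enumerate_states(case[1], case[2])
    expect_equal(sp$n_states, choose(case[2] + case[1], case[1]))
    expect_true(all(rowSums(sp$states) <= case[2]))
    expect_true(all(sp$states >= 0))
    idx <- state_index(sp, sp$states)
    expect_equal(idx, seq_len(sp$n_states))
  }
  sp <- enumerate_states(2, 4)
  expect_error(state_index(sp, c(5L, 5L)), "not in state space")
})

test_that("haplotype fitnesses are cumulative products", {
  expect_equal(haplotype_fitnesses(2), 2)
  expect_equal(haplotype_fitnesses(c(2, 0.5)), c(2, 1))
  expect_equal(haplotype_fitnesses(c(1, 1, 1)), c(1, 1, 1))
  expect_error(haplotype_fitnesses(c(1, -2)), "> 0")
  expect_error(haplotype_fitnesses(c(1, 0)), "> 0")
})

test_that("generator rates match hand-computed values at N = 2", {
  g <- build_generator(enumerate_states(1, 2), 1)
  Q <- as.matrix(g$rates)
  expect_equal(Q[2, 3], 0.25)
  expect_equal(Q[2, 1], 0.25)
  expect_equal(Q[2, 2], -0.5)
  expect_equal(Q[1, ], rep(0, 3))   # all-wild-type absorbing
  expect_equal(Q[3, ], rep(0, 3))   # fixed absorbing

  g2 <- build_generator(enumerate_states(1, 2), 2)
  Q2 <- as.matrix(g2$rates)
  expect_equal(Q2[2, 3], 1 / 3)
  expect_equal(Q2[2, 1], 1 / 6)
})

test_that("generators have zero row sums, non-negative off-diagonals,
           tridiagonal one-mutant structure, and absorbing corners", {
  cases <- list(list(1, 40, 1.3), list(2, 12, c(1.5, 0.9)),
                list(3, 6, c(0.8, 1.2, 2)))
  for (cs in cases) {
    sp <- enumerate_states(cs[[1]], cs[[2]])
    g <- build_generator(sp, cs[[3]])
    Q <- g$rates
    expect_lt(max(abs(Matrix::rowSums(Q))), 1e-12)
    off <- Q - Matrix::Diagonal(sp$n_states, Matrix::diag(Q))
    expect_true(all(off@x >= 0))
    # homogeneous states absorb
    zero <- state_index(sp, rep(0L, cs[[1]]))
    expect_equal(sum(abs(Q[zero, ])), 0)
    for (l in seq_len(cs[[1]])) {
      el <- rep(0L, cs[[1]]); el[l] <- cs[[2]]
      expect_equal(sum(abs(Q[state_index(sp, el), ])), 0)
    }
  }
  # k = 1: tridiagonal
  g1 <- build_generator(enumerate_states(1, 25), 1.4)
  Q1 <- as.matrix(g1$rates)
  expect_true(all(Q1[abs(row(Q1) - col(Q1)) > 1] == 0))
})

test_that("neutral one-mutant rates are symmetric and the birth/death
           ratio equals f (detailed balance)", {
  gN <- build_generator(enumerate_states(1, 15), 1)
  Q <- as.matrix(gN$rates)
  for (x in 1:14) expect_equal(Q[x + 1, x + 2], Q[x + 1, x])

  # per-state birth/death ratio is f at every copy number: the basis of
  # the closed-form fixation probability
  f <- 1.7
  gS <- build_generator(enumerate_states(1, 15), f)
  Qs <- as.matrix(gS$rates)
  ratios <- vapply(1:14, function(x) Qs[x + 1, x + 2] / Qs[x + 1, x],
                   numeric(1))
  expect_equal(ratios, rep(f, 14))
})

test_that("transient partition splits Q = [[Q*, V], [0, 0]] consistently", {
  g <- build_generator(enumerate_states(1, 2), 1)
  part <- transient_partition(g)
  expect_equal(as.matrix(part$Qstar), matrix(-0.5, 1, 1))
  expect_equal(sort(as.numeric(part$V)), c(0.25, 0.25))

  g3 <- build_generator(enumerate_states(1, 3), 1.2)
  p3 <- transient_partition(g3)
  expect_equal(dim(p3$Qstar), c(2L, 2L))
  # conservation: [Q* V] rows sum to zero
  expect_lt(max(abs(Matrix::rowSums(p3$Qstar) + Matrix::rowSums(p3$V))), 1e-14)

  # reassembly up to permutation
  gk <- build_generator(enumerate_states(2, 5), c(1.2, 0.7))
  pk <- transient_partition(gk)
  n <- gk$space$n_states
  R <- matrix(0, n, n)
  R[pk$transient, pk$transient] <- as.matrix(pk$Qstar)
  R[pk$transient, pk$absorbing] <- as.matrix(pk$V)
  expect_equal(R, as.matrix(gk$rates))
})

test_that("dense conversion refuses oversized state spaces", {
  g <- build_generator(enumerate_states(2, 10), c(1, 1))
  expect_true(is.matrix(generator_dense(g)))
  expect_error(generator_dense(g, max_states = 10), "refusing")
})

test_that("build_generator validates inputs", {
  sp <- enumerate_states(2, 5)
  expect_error(build_generator(sp, 1), "length")
  expect_error(build_generator(sp, c(1, -1)), "> 0")
})

test_that("sparse construction scales: 45k-state generator keeps zero row
           sums and bounded per-row fill", {
  g <- build_generator(enumerate_states(2, 300), c(1.2, 0.9))
  expect_equal(g$space$n_states, choose(302, 2))
  expect_lt(max(abs(Matrix::rowSums(g$rates))), 1e-12)
  nnz_per_row <- diff(Matrix::t(g$rates)@p)
  expect_lte(max(nnz_per_row), 2 * (2 + 1) + 1)
})
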