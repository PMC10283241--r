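test_that("state enumeration follows the canonical ordering", {
  sp <- enumerate_states(4)
  expect_equal(sp$n_states, 15)
  expect_equal(unname(sp$states[sp$normal, ]), c(1L, 1L))
  expect_equal(state_index(sp, 1, 1), 4L)   # 0-based convention
  expect_equal(state_index(sp, 4, 0), 14L)

  sp2 <- enumerate_states(2)
  expect_equal(sp2$n_states, 6)
  expect_equal(unname(sp2$states),
               matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 2L, 1L, 1L, 2L, 0L),
                      ncol = 2, byrow = TRUE))
  expect_equal(enumerate_states(6)$n_states, 28)

  # totals sorted, ties by cA; counts per total are c + 1
  for (cm in 2:6) {
    sp <- enumerate_states(cm)
    expect_equal(sp$n_states, (cm + 1) * (cm + 2) / 2)
    expect_true(!is.unsorted(sp$total))
    for (tot in 0:cm) {
      idx <- sp$compat[[tot + 1]]
      expect_length(idx, tot + 1)
      expect_true(all(sp$total[idx] == tot))
      expect_true(!is.unsorted(sp$states[idx, 1]))
    }
  }
  expect_error(enumerate_states(1), "c_max")
  expect_error(enumerate_states(3.5), "c_max")
})

test_that("compatible states cover exactly the matching totals", {
  sp <- enumerate_states(4)
  got <- sp$states[compatible_states(3, sp), , drop = FALSE]
  expect_equal(unname(got),
               matrix(c(0L, 3L, 1L, 2L, 2L, 1L, 3L, 0L), ncol = 2,
                      byrow = TRUE))
  expect_equal(unname(sp$states[compatible_states(0, sp), , drop = FALSE]),
               matrix(c(0L, 0L), ncol = 2))
  expect_equal(unname(sp$states[compatible_states(2, sp), , drop = FALSE]),
               matrix(c(0L, 2L, 1L, 1L, 2L, 0L), ncol = 2, byrow = TRUE))
  expect_error(compatible_states(5, sp), "total_cn")
  expect_error(compatible_states(-1, sp), "total_cn")
})

test_that("rate matrix encodes single-haplotype duplication/deletion moves", {
  sp <- enumerate_states(3)
  u <- 0.7; e <- 0.3
  Q <- build_rate_matrix(u, e, sp)$Q
  expect_equal(rowSums(Q), rep(0, sp$n_states), tolerance = 1e-12)
  expect_true(all(Q[cbind(1:nrow(Q), 1:ncol(Q))] <= 0))
  expect_true(all(Q[upper.tri(Q) | lower.tri(Q)] >= 0))
  expect_equal(Q[1, ], rep(0, sp$n_states))  # (0,0) absorbing

  # independent oracle: enumerate all +-1 single-haplotype moves
  oracle <- matrix(0, sp$n_states, sp$n_states)
  for (i in seq_len(sp$n_states)) {
    cA <- sp$states[i, 1]; cB <- sp$states[i, 2]
    moves <- list(c(cA + 1, cB, u), c(cA, cB + 1, u),
                  c(cA - 1, cB, e), c(cA, cB - 1, e))
    ok_from <- c(cA >= 1, cB >= 1, cA >= 1, cB >= 1)
    for (k in seq_along(moves)) {
      mv <- moves[[k]]
      if (!ok_from[k]) next
      if (mv[1] < 0 || mv[2] < 0 || mv[1] + mv[2] > sp$c_max) next
      j <- state_index(sp, mv[1], mv[2], zero_based = FALSE)
      oracle[i, j] <- oracle[i, j] + mv[3]
    }
  }
  diag(oracle) <- -rowSums(oracle)
  expect_equal(Q, oracle, tolerance = 1e-12)

  # worked row: state (1,1) at c_max=3
  i <- state_index(sp, 1, 1, zero_based = FALSE)
  expect_equal(Q[i, state_index(sp, 2, 1, FALSE)], u)
  expect_equal(Q[i, state_index(sp, 1, 2, FALSE)], u)
  expect_equal(Q[i, state_index(sp, 0, 1, FALSE)], e)
  expect_equal(Q[i, state_index(sp, 1, 0, FALSE)], e)
  expect_equal(Q[i, i], -2 * (u + e))

  expect_equal(build_rate_matrix(0, 0, sp)$Q,
               matrix(0, sp$n_states, sp$n_states))
  expect_error(build_rate_matrix(-0.1, 0.1, sp), "rates")
})

test_that("transition matrices are stochastic and semigroup-consistent", {
  sp <- enumerate_states(4)
  mod <- build_rate_matrix(0.02, 0.05, sp)
  expect_equal(transition_matrix(mod, 0), diag(sp$n_states))
  for (t in c(0, 1e-3, 0.1, 1, 10, 100)) {
    P <- transition_matrix(mod, t)
    expect_equal(rowSums(P), rep(1, sp$n_states), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
  P5 <- transition_matrix(mod, 5)
  expect_equal(transition_matrix(mod, 2) %*% transition_matrix(mod, 3),
               P5, tolerance = 1e-8)
  expect_error(transition_matrix(mod, -1), "non-negative")

  # stiff generators (extreme asymmetric rates, long branches) still give
  # proper stochastic matrices
  sp6 <- enumerate_states(6)
  for (rates in list(c(1e-6, 1), c(1, 1e-6), c(1, 1))) {
    stiff <- build_rate_matrix(rates[1], rates[2], sp6)
    for (t in c(40, 80)) {
      P <- transition_matrix(stiff, t)
      expect_equal(rowSums(P), rep(1, sp6$n_states), tolerance = 1e-9)
      expect_true(all(P >= 0 & P <= 1))
    }
  }
})

test_that("transition probabilities match a truncated series oracle", {
  sp <- enumerate_states(2)
  mod <- build_rate_matrix(0.01, 0.01, sp)
  P <- transition_matrix(mod, 5)
  Qt <- mod$Q * 5
  series <- diag(sp$n_states)
  term <- diag(sp$n_states)
  for (k in 1:50) {
    term <- term %*% Qt / k
    series <- series + term
  }
  expect_equal(P, series, tolerance = 1e-10)
})

test_that("the zero-copy state absorbs and empty haplotypes stay empty", {
  sp <- enumerate_states(4)
  mod <- build_rate_matrix(0.05, 0.08, sp)
  start <- state_index(sp, 1, 1, zero_based = FALSE)
  prev <- 0
  for (t in c(0.5, 1, 2, 5, 20, 80)) {
    mass <- transition_matrix(mod, t)[start, 1]
    expect_gte(mass, prev - 1e-12)
    prev <- mass
  }
  # without deletions no haplotype can be lost from (1,1)
  mod0 <- build_rate_matrix(0.05, 0, sp)
  lost <- sp$states[, 1] == 0 | sp$states[, 2] == 0
  for (t in c(0.1, 1, 10)) {
    expect_equal(sum(transition_matrix(mod0, t)[start, lost]), 0,
                 tolerance = 1e-12)
  }
})
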