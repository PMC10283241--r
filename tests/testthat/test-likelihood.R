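test_that("site patterns compress to distinct columns with counts", {
  sp <- enumerate_states(4)
  v <- rbind(c(2L, 2L, 2L), c(2L, 3L, 3L))
  pat <- compress_patterns(total_matrix(v), sp)
  expect_equal(length(pat$counts), 2)
  expect_equal(pat$counts, c(1L, 2L))
  expect_equal(pat$variant, c(FALSE, TRUE))

  # all-normal matrix: a single invariant pattern carrying all sites
  pat2 <- compress_patterns(total_matrix(matrix(2L, 5, 100)), sp)
  expect_equal(length(pat2$counts), 1)
  expect_equal(pat2$counts, 100L)
  expect_false(any(pat2$variant))

  # counts agree with a naive column-hashing oracle on simulated data
  qs <- quick_sim(301, m = 300)
  pat3 <- compress_patterns(qs$total, qs$space)
  key <- apply(qs$total$values, 2, paste, collapse = "/")
  expect_equal(sort(pat3$counts), sort(unname(table(key))),
               ignore_attr = TRUE)
  expect_equal(sum(pat3$counts[pat3$variant]),
               sum(colSums(qs$total$values != 2) > 0))
})

test_that("tip partials are indicators over compatible states", {
  sp <- enumerate_states(4)
  v <- tip_partial(c(1, 1), "haplotype", sp)
  expect_equal(which(v == 1), 5)  # 0-based state 4
  expect_equal(sum(v), 1)

  v3 <- tip_partial(3, "total", sp)
  expect_equal(sp$states[which(v3 == 1), , drop = FALSE],
               matrix(c(0L, 3L, 1L, 2L, 2L, 1L, 3L, 0L), ncol = 2,
                      byrow = TRUE), ignore_attr = TRUE)
  v0 <- tip_partial(0, "total", sp)
  expect_equal(which(v0 == 1), 1)
  expect_error(tip_partial(9, "total", sp), "total_cn")
})

test_that("a zero-length tree of normal tips has log-likelihood zero", {
  sp <- enumerate_states(4)
  mod <- build_rate_matrix(0.01, 0.02, sp)
  phy <- ape::read.tree(text = "((S1:0,S2:0):0,S3:0);")
  tr <- cnp_tree(phy, luca_len = 0)
  cm <- hap_matrix(A = matrix(1L, 3, 4), B = matrix(1L, 3, 4))
  expect_equal(log_likelihood(tr, mod, cm), 0)
})

test_that("pruning equals exhaustive state-assignment enumeration", {
  sp <- enumerate_states(2)
  mod <- build_rate_matrix(0.03, 0.02, sp)
  phy <- ape::read.tree(text = "((S1:1.5,S2:2.5):1.0,S3:3.0);")
  tr <- cnp_tree(phy, luca_len = 2.0)
  set.seed(5)
  for (rep in 1:5) {
    st <- sample.int(sp$n_states, 3, replace = TRUE)
    A <- matrix(sp$states[st, 1], ncol = 1)
    B <- matrix(sp$states[st, 2], ncol = 1)
    cm <- hap_matrix(A = A, B = B)
    ll <- log_likelihood(tr, mod, cm)
    brute <- brute_site_3tip(mod, c(2.0, 1.0, 1.5, 2.5, 3.0), st)
    expect_equal(ll, log(brute), tolerance = 1e-10)
  }
})

test_that("total-input likelihood sums over compatible haplotype matrices", {
  sp <- enumerate_states(2)
  S <- sp$n_states
  mod <- build_rate_matrix(0.03, 0.02, sp)
  phy <- ape::read.tree(text = "(S1:1.5,S2:2.5);")
  tr <- cnp_tree(phy, luca_len = 2.0)
  Pl <- transition_matrix(mod, 2.0)
  P1 <- transition_matrix(mod, 1.5)
  P2 <- transition_matrix(mod, 2.5)
  site_sum <- function(t1, t2) {
    s <- 0
    for (o1 in sp$compat[[t1 + 1]]) for (o2 in sp$compat[[t2 + 1]]) {
      for (dm in 1:S) {
        s <- s + Pl[sp$normal, dm] * P1[dm, o1] * P2[dm, o2]
      }
    }
    s
  }
  tots <- matrix(c(2L, 1L, 2L, 0L), nrow = 2)  # 2 samples x 2 sites
  ll <- log_likelihood(tr, mod, total_matrix(tots))
  expect_equal(ll, log(site_sum(2, 1)) + log(site_sum(2, 0)),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to pattern order and site duplication", {
  qs <- quick_sim(77, m = 200)
  mod <- qs$model
  ll <- log_likelihood(qs$tree, mod, qs$total)
  perm <- sample(ncol(qs$total$values))
  shuffled <- cn_matrix(qs$total$values[, perm], qs$total$sites[perm, ],
                        qs$total$sample_ids)
  expect_equal(log_likelihood(qs$tree, mod, shuffled), ll,
               tolerance = 1e-10)
  doubled <- cn_matrix(cbind(qs$total$values, qs$total$values),
                       rbind(qs$total$sites, qs$total$sites),
                       qs$total$sample_ids)
  expect_equal(log_likelihood(qs$tree, mod, doubled), 2 * ll,
               tolerance = 1e-8)
})

test_that("per-site probabilities sum to one over all tip observations", {
  sp <- enumerate_states(2)
  mod <- build_rate_matrix(0.04, 0.03, sp)
  phy <- ape::read.tree(text = "(S1:1.2,S2:0.7);")
  tr <- cnp_tree(phy, luca_len = 0.9)
  tot <- 0
  for (s1 in seq_len(sp$n_states)) for (s2 in seq_len(sp$n_states)) {
    cm <- hap_matrix(A = matrix(sp$states[c(s1, s2), 1], ncol = 1),
                     B = matrix(sp$states[c(s1, s2), 2], ncol = 1))
    tot <- tot + exp(log_likelihood(tr, mod, cm))
  }
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("haplotype input never beats total input in likelihood", {
  qs <- quick_sim(88, m = 300)
  ll_hap <- log_likelihood(qs$tree, qs$model, qs$sim$cn)
  ll_tot <- log_likelihood(qs$tree, qs$model, qs$total)
  expect_lte(ll_hap, ll_tot + 1e-9)
})

test_that("impossible data yields -Inf with a diagnostic", {
  sp <- enumerate_states(2)
  mod <- build_rate_matrix(0.01, 0, sp)  # no deletions
  phy <- ape::read.tree(text = "(S1:1,S2:1);")
  tr <- cnp_tree(phy, luca_len = 1)
  cm <- total_matrix(matrix(c(0L, 2L), nrow = 2))  # total 0 unreachable
  expect_warning(ll <- log_likelihood(tr, mod, cm), "impossible")
  expect_identical(ll, -Inf)
})
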