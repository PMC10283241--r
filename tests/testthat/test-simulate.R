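test_that("the default bin layout covers 22 autosomes and 4401 bins", {
  b <- genome_bins()
  expect_length(b, 22)
  expect_equal(sum(b), 4401)
  expect_equal(unname(b[1]), 367)
})

test_that("sample trees respect timing and age constraints", {
  set.seed(2)
  cfg0 <- sim_config(dt = 0)
  for (r in 1:10) {
    tr <- sample_tree(cfg0)
    d <- cnphylo:::.node_depths(tr$tree)
    n <- length(tr$tree$tip.label)
    # same-time sampling: ultrametric tips at the configured MRCA height
    expect_equal(unname(d[1:n]), rep(cfg0$mrca_height, n),
                 tolerance = 1e-9)
    expect_true(all(tr$tree$edge.length > 0))
  }
  cfgdt <- sim_config(dt = 1)
  for (r in 1:10) {
    tr <- sample_tree(cfgdt)
    ages <- node_ages(tr)
    dl <- ages[tr$tree$edge[, 2]] - ages[tr$tree$edge[, 1]]
    expect_true(all(dl > 0))
    expect_lte(attr(ages, "luca_age"), cfgdt$patient_age)
    expect_equal(min(tr$tip_times), 0)
  }
})

test_that("tip staggering multipliers are uniform on 1..n", {
  set.seed(10)
  cfg <- sim_config(dt = 1, n_samples = 5)
  mult <- unlist(lapply(1:500, function(i) {
    tr <- sample_tree(cfg)
    tr$tip_times[tr$tip_times > 0] / cfg$dt
  }))
  expect_true(all(mult %in% 1:5))
  chi <- stats::chisq.test(tabulate(mult, 5), p = rep(0.2, 5))
  expect_gt(chi$p.value, 0.01)
})

test_that("direct simulation follows the transition kernel", {
  sp <- enumerate_states(4)
  cfg <- sim_config(c_max = 4)
  # zero rates: everything stays normal
  mod0 <- build_rate_matrix(0, 0, sp)
  set.seed(1)
  tr <- sample_tree(cfg)
  sim0 <- simulate_direct(tr, mod0, m = 50, config = cfg)
  expect_true(all(sim0$cn$A == 1) && all(sim0$cn$B == 1))
  # empirical transition frequencies on one long branch match P(l)
  mod <- build_rate_matrix(0.01, 0.008, sp)
  phy <- ape::read.tree(text = "(S1:8,S2:0.0001);")
  long <- cnp_tree(phy, luca_len = 1e-4)
  set.seed(2)
  m <- 40000
  sim <- simulate_direct(long, mod, m = m, config = cfg)
  P <- transition_matrix(mod, 8)[sp$normal, ]
  st <- state_index(sp, sim$cn$A[1, ], sim$cn$B[1, ],
                    zero_based = FALSE)
  freq <- tabulate(st, sp$n_states) / m
  tol <- 4 * sqrt(P * (1 - P) / m) + 1e-4
  expect_true(all(abs(freq - P) <= tol))
})

test_that("variant-site counts sit in a plausible band at the defaults", {
  sp <- enumerate_states(6)
  mod <- build_rate_matrix(0.001, 0.001, sp)
  set.seed(33)
  cfg <- sim_config()
  nv <- replicate(8, {
    tr <- sample_tree(cfg)
    sim <- simulate_direct(tr, mod, m = 1000, config = cfg)
    pat <- compress_patterns(as_total(sim$cn), sp)
    sum(pat$counts[pat$variant])
  })
  expect_true(all(nv > 60 & nv < 400))
})

test_that("waiting-time simulation respects its constraints", {
  cfg0 <- sim_config(mode = "waiting_time", u = 0, e = 0, c_max = 4)
  set.seed(3)
  tr <- sample_tree(cfg0)
  sim0 <- simulate_waiting_time(tr, cfg0)
  expect_true(all(sim0$cn$values == 2))
  expect_equal(nrow(sim0$events), 0)
  expect_equal(ncol(sim0$cn$values), 4401)

  cfg <- sim_config(mode = "waiting_time", u = 0.002, e = 0.002,
                    chr_gain = 0.001, chr_loss = 0.001, wgd = 0.02,
                    mean_dup_size = 5, mean_del_size = 5, c_max = 4)
  set.seed(4)
  tr <- sample_tree(cfg)
  sim <- simulate_waiting_time(tr, cfg)
  expect_true(all(sim$cn$values <= cfg$c_max))
  expect_true(all(sim$cn$values >= 0))
  expect_true(all(c("type", "branch", "time", "size") %in%
                    colnames(sim$events)))

  # dup-only, mean size 1: total event count on a long branch is Poisson
  # with rate u * (2 haplotypes) * bins * length
  cfg1 <- sim_config(mode = "waiting_time", u = 5e-4, e = 0, c_max = 6)
  phy <- ape::read.tree(text = "(S1:10,S2:0.001);")
  long <- cnp_tree(phy, luca_len = 1e-3)
  set.seed(5)
  sim1 <- simulate_waiting_time(long, cfg1)
  lam <- 5e-4 * 2 * 4401 * 10
  n_ev <- sum(sim1$events$branch != "luca" & sim1$events$time <= 10)
  expect_lt(abs(n_ev - lam), 5 * sqrt(lam))
})

test_that("error injection perturbs exactly the requested fraction", {
  qs <- quick_sim(44, m = 200)
  expect_equal(inject_errors(qs$total, 0, 6)$values, qs$total$values)
  set.seed(9)
  pert <- inject_errors(qs$total, 0.3, 6)
  changed <- rowSums(pert$values != qs$total$values)
  expect_true(all(changed <= round(200 * 0.3)))
  expect_true(all(pert$values >= 0 & pert$values <= 6))
  # Poisson(0) is 0: all-zero profiles are unchanged even at f_e = 1
  zeros <- total_matrix(matrix(0L, 2, 50))
  expect_equal(inject_errors(zeros, 1, 6)$values, zeros$values)
})

test_that("subclonal mixing takes Dirichlet-weighted rounded means", {
  # single tumour clone at CN 4 mixed half-and-half with the normal clone
  x <- total_matrix(matrix(4L, 1, 10))
  set.seed(6)
  mix <- mix_subclones(x, f_d = 0.5, n_clones = 2, c_max = 6)
  expect_true(all(mix$values == 3))  # 0.5*4 + 0.5*2
  # f_d = 1 keeps the original clone
  qs <- quick_sim(45, m = 100)
  mix1 <- mix_subclones(qs$total, f_d = 1 - 1e-12, n_clones = 3,
                        c_max = 6)
  expect_equal(mix1$values, qs$total$values)
  # identical clones mix to themselves
  same <- total_matrix(matrix(3L, 4, 20))
  # include the normal clone? exclude by using only 3 of 4 tumour clones
  mix2 <- mix_subclones(same, f_d = 0.9, n_clones = 3, c_max = 6)
  expect_true(all(mix2$values %in% c(3L, 2L)))
})

test_that("relative conversion applies baseline, rounding and clamping", {
  # diploid samples map to all-zero relative profiles
  dip <- total_matrix(matrix(2L, 2, 10))
  expect_true(all(make_relative(dip)$values == 0))
  # clonal-WGD tetraploid: baseline cancels the doubling
  tet <- total_matrix(matrix(4L, 1, 10))
  expect_true(all(make_relative(tet)$values == 0))
  # CN 7 against a tetraploid baseline 2: 7/2 -> 4, minus 2 -> 2
  v <- matrix(4L, 1, 20); v[1, 1] <- 7L
  rel <- make_relative(total_matrix(v))
  expect_equal(unname(rel$values[1, 1]), 2)
  expect_true(all(rel$values >= -2 & rel$values <= 2))
  # power-of-two WGD baseline
  rel2 <- make_relative(tet, baseline = "power2_wgd", n_wgd = 1)
  expect_true(all(rel2$values == 0))
  expect_error(make_relative(total_matrix(matrix(0L, 1, 5))),
               "baseline")
})

test_that("seeded simulation runs are bit-reproducible", {
  cfg <- sim_config(m = 100)
  sp <- enumerate_states(cfg$c_max)
  mod <- build_rate_matrix(cfg$u, cfg$e, sp)
  set.seed(77)
  t1 <- sample_tree(cfg); s1 <- simulate_direct(t1, mod, 100, cfg)
  set.seed(77)
  t2 <- sample_tree(cfg); s2 <- simulate_direct(t2, mod, 100, cfg)
  expect_equal(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(s1$cn$values, s2$cn$values)
  expect_identical(s1$node_states, s2$node_states)
})
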