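test_that("normalized RF and branch score behave on known pairs", {
  a <- cnp_tree(ape::read.tree(text = "((((S1:1,S2:1):1,S3:2):1,S4:3):1,S5:4);"),
                luca_len = 1)
  expect_equal(rf_normalized(a, a), 0)
  expect_equal(branch_score(a, a), 0)
  # trees sharing no clades: normalized RF = 1
  b <- cnp_tree(ape::read.tree(text = "(((S1:1,S3:1):1,(S2:1,S5:1):1):1,S4:2);"),
                luca_len = 1)
  expect_equal(rf_normalized(a, b), 1)
  expect_equal(rf_normalized(b, a), rf_normalized(a, b))
  expect_gt(branch_score(a, b), 0)
  expect_equal(branch_score(a, b), branch_score(b, a))
  expect_error(rf_normalized(a, cnp_tree(ape::read.tree(
    text = "((X:1,S2:1):1,S3:1);"), luca_len = 1)), "tip set")
})

test_that("tree distances agree with phangorn via the outgroup trick", {
  # rooted clade RF equals unrooted RF after attaching an outgroup at the
  # root; same for the branch score with a zero-length outgroup pendant
  set.seed(23)
  for (r in 1:25) {
    p1 <- ape::rtree(6)
    p2 <- ape::rtree(6)
    o1 <- ape::read.tree(text = paste0(
      "(", sub(";$", "", ape::write.tree(p1)), ":0,OUT:0);"))
    o2 <- ape::read.tree(text = paste0(
      "(", sub(";$", "", ape::write.tree(p2)), ":0,OUT:0);"))
    rf_ref <- phangorn::RF.dist(ape::unroot(o1), ape::unroot(o2))
    expect_equal(rf_normalized(p1, p2) * (2 * 6 - 4), rf_ref)
    kf_ref <- phangorn::KF.dist(ape::unroot(o1), ape::unroot(o2))
    t1 <- cnp_tree(p1, luca_len = 0)
    t2 <- cnp_tree(p2, luca_len = 0)
    expect_equal(branch_score(t1, t2), kf_ref, tolerance = 1e-9)
  }
})

test_that("branch support counts clade recovery", {
  ref <- ape::read.tree(text = "(((S1,S2),S3),(S4,S5));")
  same <- replicate(10, ref, simplify = FALSE)
  expect_equal(unname(branch_support(ref, same)),
               rep(100, ref$Nnode))
  other <- ape::read.tree(text = "(((S1,S4),S3),(S2,S5));")
  mixed <- c(replicate(5, ref, simplify = FALSE),
             replicate(5, other, simplify = FALSE))
  sup <- branch_support(ref, mixed)
  expect_true(all(sup >= 0 & sup <= 100))
  # naive clade-counting oracle
  refk <- cnphylo:::.clade_keys(ref)
  naive <- vapply(refk, function(k) {
    100 * mean(vapply(mixed, function(b) k %in% cnphylo:::.clade_keys(b),
                      logical(1)))
  }, numeric(1))
  # prop.clades reports the root clade too; compare the non-root clades
  n_tip <- length(ref$tip.label)
  internal <- sort(unique(ref$edge[, 1]))
  nonroot <- internal != n_tip + 1
  expect_equal(unname(sup[nonroot]), unname(naive))
  expect_error(branch_support(ref, list(ape::rtree(4))), "tip set")
})

test_that("degenerate bootstrap data reproduce the original sample", {
  # one repeated column: every resample equals the original matrix
  v <- matrix(rep(c(2L, 3L, 2L, 1L), 30), nrow = 4)
  rownames(v) <- paste0("S", 1:4)
  x <- total_matrix(v)
  sp <- enumerate_states(4)
  set.seed(5)
  boots <- bootstrap_trees(x, sp, B = 2,
                           config = search_config(refine_k = 3,
                                                  screen_iter = 5))
  expect_length(boots, 2)
  expect_true(same_topology(boots[[1]]$tree, boots[[2]]$tree))
})

test_that("bootstrap is reproducible under a fixed seed", {
  qs <- quick_sim(91, u = 0.01, m = 150, n_samples = 4)
  set.seed(123)
  b1 <- bootstrap_trees(qs$total, qs$space, B = 2, u0 = 0.01, e0 = 0.01,
                        config = search_config(screen_iter = 5,
                                               refine_k = 3))
  set.seed(123)
  b2 <- bootstrap_trees(qs$total, qs$space, B = 2, u0 = 0.01, e0 = 0.01,
                        config = search_config(screen_iter = 5,
                                               refine_k = 3))
  expect_equal(vapply(b1, `[[`, numeric(1), "loglik"),
               vapply(b2, `[[`, numeric(1), "loglik"))
  expect_true(same_topology(b1[[1]]$tree, b2[[1]]$tree))
})

test_that("bootstrap intervals are percentile intervals", {
  qs <- quick_sim(92, u = 0.01, m = 300)
  pat <- compress_patterns(qs$total, qs$space)
  fit <- fit_same_time(qs$tree$tree, pat, qs$space, u0 = 0.01, e0 = 0.01)
  set.seed(4)
  ci <- ci_from_bootstrap(fit, qs$total, qs$space, B = 8)
  expect_true(all(ci$lower <= ci$upper))
  # point estimates of the fixed rates have zero-width intervals
  expect_equal(ci$lower[ci$parameter == "u"], ci$upper[ci$parameter == "u"])
  expect_equal(ci$estimate[ci$parameter == "u"], 0.01)
})
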