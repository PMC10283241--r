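# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

fake_sites <- function(m, chrom = "chr1") {
  data.frame(chrom = chrom, start = (seq_len(m) - 1) * 5e5 + 1,
             end = seq_len(m) * 5e5)
}

hap_matrix <- function(A, B, ids = paste0("S", seq_len(nrow(A)))) {
  cn_matrix(sites = fake_sites(ncol(A)), sample_ids = ids,
            kind = "haplotype", A = A, B = B)
}

total_matrix <- function(vals, ids = paste0("S", seq_len(nrow(vals)))) {
  cn_matrix(vals, fake_sites(ncol(vals)), ids, kind = "total")
}

# brute-force site likelihood by enumerating internal-node states on a
# 3-tip tree ((S1,S2),S3) rooted below by the LUCA
brute_site_3tip <- function(model, lens, tip_states) {
  # lens: c(luca, internal, t1, t2, t3); tip_states: 1-based state rows
  sp <- model$space
  S <- sp$n_states
  Pl <- transition_matrix(model, lens[1])
  Pi <- transition_matrix(model, lens[2])
  P1 <- transition_matrix(model, lens[3])
  P2 <- transition_matrix(model, lens[4])
  P3 <- transition_matrix(model, lens[5])
  tot <- 0
  for (dm in 1:S) for (dv in 1:S) {
    tot <- tot + Pl[sp$normal, dm] * P3[dm, tip_states[3]] *
      Pi[dm, dv] * P1[dv, tip_states[1]] * P2[dv, tip_states[2]]
  }
  tot
}

# exhaustive joint probability of internal-state assignments on the
# 4-tip tree ((S1,S2),(S3,S4)) with LUCA above; returns best assignment
brute_joint_4tip <- function(model, lens, tip_sets) {
  # lens: c(luca, left, right, t1..t4); internal nodes: mrca, L, R
  sp <- model$space
  S <- sp$n_states
  Pl <- transition_matrix(model, lens[1])
  PL <- transition_matrix(model, lens[2])
  PR <- transition_matrix(model, lens[3])
  Pt <- lapply(4:7, function(k) transition_matrix(model, lens[k]))
  best <- -Inf; arg <- NULL
  for (dm in 1:S) for (dL in 1:S) for (dR in 1:S) {
    tipmax <- 1
    for (tip in 1:4) {
      par <- if (tip <= 2) dL else dR
      tipmax <- tipmax * max(Pt[[tip]][par, tip_sets[[tip]]])
    }
    pr <- Pl[sp$normal, dm] * PL[dm, dL] * PR[dm, dR] * tipmax
    if (pr > best) { best <- pr; arg <- c(dm, dL, dR) }
  }
  list(prob = best, states = arg)
}

# quick simulated dataset under the default study conditions
quick_sim <- function(seed, u = 0.001, e = u, m = 500, dt = 0,
                      n_samples = 5, c_max = 6) {
  set.seed(seed)
  cfg <- sim_config(n_samples = n_samples, u = u, e = e, m = m, dt = dt,
                    c_max = c_max)
  sp <- enumerate_states(c_max)
  mod <- build_rate_matrix(u, e, sp)
  tr <- sample_tree(cfg)
  sim <- simulate_direct(tr, mod, m = m, config = cfg)
  list(cfg = cfg, space = sp, model = mod, tree = tr, sim = sim,
       total = as_total(sim$cn))
}
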