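#' Default genome bin layout
#'
#' Per-autosome counts of 500-Kbp bins (22 autosomes, 4401 bins in total),
#' as produced by fixed-bin read-count callers on the human reference.
#'
#' @return Named integer vector of bin counts per autosome.
#' @export
genome_bins <- function() {
  counts <- c(367L, 385L, 335L, 316L, 299L, 277L, 251L, 243L, 184L, 210L,
              215L, 213L, 166L, 150L, 134L, 118L, 121L, 127L, 79L, 106L,
              51L, 54L)
  names(counts) <- paste0("chr", 1:22)
  counts
}

#' Simulation configuration
#'
#' Bundles the parameters of the copy-number evolution simulator. Defaults
#' reproduce the reference study conditions: five samples, an
#' exponential-growth coalescent tree with the samples' MRCA 20 years
#' before the first sample, 1000 segment sites, duplication and deletion at
#' 0.001 per haplotype per site per year, maximum total copy number 6, and
#' a patient aged 60 years at the first sample.
#'
#' @param n_samples Number of sampled genomes.
#' @param beta Exponential growth rate of the coalescent (1/years); 0 gives
#'   the basic coalescent.
#' @param dt Tip-time staggering increment in years (0 = same-time).
#' @param mode \code{"direct"} (site-level Markov model on segments) or
#'   \code{"waiting_time"} (multi-scale events on fixed bins).
#' @param m Number of segment sites (direct mode).
#' @param u,e Duplication/deletion rates per haplotype per site per year.
#' @param chr_gain,chr_loss Chromosome gain/loss rates per chromosome per
#'   year (waiting-time mode).
#' @param wgd Whole-genome doubling rate per year (waiting-time mode).
#' @param mean_dup_size,mean_del_size Mean duplication/deletion size in
#'   bins (waiting-time mode).
#' @param c_max Maximum total copy number.
#' @param mrca_height Years from the MRCA to the first-sampled tips.
#' @param patient_age Patient age in years at the first sample.
#' @param bins Per-chromosome bin counts (waiting-time mode and site
#'   placement).
#' @param bin_size Bin size in bp.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 5, beta = 1, dt = 0,
                       mode = c("direct", "waiting_time"), m = 1000,
                       u = 0.001, e = 0.001, chr_gain = 0, chr_loss = 0,
                       wgd = 0, mean_dup_size = 1, mean_del_size = 1,
                       c_max = 6, mrca_height = 20, patient_age = 60,
                       bins = genome_bins(), bin_size = 5e5) {
  mode <- match.arg(mode)
  stopifnot(n_samples >= 2, dt >= 0, u >= 0, e >= 0, chr_gain >= 0,
            chr_loss >= 0, wgd >= 0, c_max >= 2, mrca_height > 0,
            patient_age > 0)
  structure(as.list(environment()), class = "sim_config")
}

# coalescent intervals under exponential growth (backwards in time the
# population shrinks, so the coalescent rate grows as exp(beta * t))
.coal_times <- function(n, beta) {
  t <- 0
  times <- numeric(n - 1L)
  for (k in n:2) {
    rate <- k * (k - 1) / 2
    E <- stats::rexp(1)
    s <- if (beta > 0) log1p(beta * E * exp(-beta * t) / rate) / beta
         else E / rate
    t <- t + s
    times[n - k + 1L] <- t
  }
  times
}

#' Simulate a patient sample tree
#'
#' Generates a coalescent tree of the samples (basic or exponential-growth),
#' rescales it so the MRCA sits \code{mrca_height} years before the
#' first-sampled tips, prepends the LUCA with an exponentially distributed
#' LUCA-to-MRCA branch, and optionally staggers the sampling times by
#' random integer multiples of \code{dt} (the first sample is the
#' reference at offset 0; multipliers are uniform on 1..n). Internal
#' branches are rescaled if the tree height would exceed the patient age at
#' the last sample.
#'
#' @param config A \code{sim_config}.
#' @return A \code{cnp_tree} with tip times and \code{A0} set.
#' @export
sample_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  labels <- paste0("S", seq_len(n))
  coal <- .coal_times(n, config$beta)
  height <- coal[n - 1L]
  # random topology by successive pair merging at the coalescent times
  nodes <- as.list(labels)
  depth <- rep(0, n)  # depth below each current lineage's root
  for (k in seq_len(n - 1L)) {
    pick <- sample(length(nodes), 2L)
    t_k <- coal[k]
    sub <- sprintf("(%s:%.10g,%s:%.10g)",
                   nodes[[pick[1L]]], t_k - depth[pick[1L]],
                   nodes[[pick[2L]]], t_k - depth[pick[2L]])
    nodes <- c(nodes[-pick], sub)
    depth <- c(depth[-pick], t_k)
  }
  phy <- ape::read.tree(text = paste0(nodes[[1L]], ";"))
  phy$edge.length <- phy$edge.length * (config$mrca_height / height)
  # staggered sampling: lengthen terminal branches by multiples of dt
  tip_times <- stats::setNames(rep(0, n), labels)
  if (config$dt > 0) {
    mult <- sample.int(n, n - 1L, replace = TRUE)
    tip_times[labels[-1L]] <- mult * config$dt
    tip_idx <- match(phy$tip.label, labels)
    term <- match(seq_len(n), phy$edge[, 2L])
    phy$edge.length[term] <- phy$edge.length[term] + tip_times[phy$tip.label]
  }
  luca_rate <- if (config$beta > 0) config$beta else stats::runif(1)
  luca_len <- stats::rexp(1, rate = luca_rate)
  d <- max(tip_times)
  # height constraint: LUCA no earlier than patient birth
  max_height <- config$patient_age + d
  height_now <- luca_len + config$mrca_height + d
  if (height_now > max_height) {
    if (max_height <= d) stop("patient age too small for the tree",
                              call. = FALSE)
    sc <- (max_height - d) / (luca_len + config$mrca_height) * 0.999
    luca_len <- luca_len * sc
    # shrink internal structure, preserving tip offsets
    term <- match(seq_len(n), phy$edge[, 2L])
    off <- numeric(nrow(phy$edge))
    off[term] <- tip_times[phy$tip.label]
    phy$edge.length <- (phy$edge.length - off) * sc + off
  }
  cnp_tree(phy, luca_len = luca_len, tip_times = tip_times,
           A0 = config$patient_age)
}

# distribute m sites over chromosomes ~ Dirichlet around bin-count
# proportions (concentration keeps proportions near expectation)
.site_layout <- function(m, bins, bin_size, concentration = 100) {
  prop <- bins / sum(bins)
  g <- stats::rgamma(length(bins), shape = concentration * prop)
  w <- g / sum(g)
  counts <- diff(c(0L, round(cumsum(w * m))))
  counts[length(counts)] <- m - sum(counts[-length(counts)])
  if (any(counts < 0)) counts <- pmax(counts, 0L)
  out <- do.call(rbind, lapply(seq_along(bins), function(ci) {
    k <- counts[ci]
    if (k == 0) return(NULL)
    len <- bins[ci] * bin_size
    bound <- round(seq(0, len, length.out = k + 1))
    data.frame(chrom = names(bins)[ci], start = bound[-(k + 1)] + 1,
               end = bound[-1])
  }))
  rownames(out) <- NULL
  out
}

#' Simulate copy-number profiles directly under the Markov model
#'
#' Evolves every site independently along the tree: the LUCA carries the
#' normal state (1, 1) at all sites, and the state at the end of each
#' branch of length l is drawn from the row of P(l) = exp(Ql) indexed by
#' the parent state. This is the identical stochastic process assumed by
#' the likelihood, so inference on this output is a pure consistency check.
#'
#' @param tree A \code{cnp_tree}.
#' @param model A \code{cn_rate_model}.
#' @param m Number of segment sites.
#' @param config Optional \code{sim_config} supplying the site layout
#'   (bins, bin size).
#' @return List with \code{cn} (haplotype-kind \code{cn_matrix}),
#'   \code{node_states} (matrix of 1-based state rows for every node of the
#'   sample subtree, rows indexed as in the phylo), \code{tree} and
#'   \code{model}.
#' @export
simulate_direct <- function(tree, model, m = 1000, config = sim_config()) {
  stopifnot(inherits(tree, "cnp_tree"), inherits(model, "cn_rate_model"))
  space <- model$space
  phy <- tree$tree
  n_tip <- length(phy$tip.label)
  sites <- .site_layout(m, config$bins, config$bin_size)
  states <- matrix(0L, n_tip + phy$Nnode, m)
  draw_children <- function(parent_states, len) {
    P <- .pmat(model, len)
    out <- integer(m)
    for (s in unique(parent_states)) {
      idx <- which(parent_states == s)
      out[idx] <- sample.int(space$n_states, length(idx), replace = TRUE,
                             prob = P[s, ])
    }
    out
  }
  root <- n_tip + 1L
  states[root, ] <- draw_children(rep(space$normal, m), tree$luca_len)
  eo <- ape::reorder.phylo(phy, "postorder")
  pre <- rev(seq_len(nrow(eo$edge)))
  for (k in pre) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    states[ch, ] <- draw_children(states[p, ], eo$edge.length[k])
  }
  A <- matrix(space$states[states[seq_len(n_tip), ], 1L], n_tip, m)
  B <- matrix(space$states[states[seq_len(n_tip), ], 2L], n_tip, m)
  cn <- cn_matrix(sites = sites, sample_ids = phy$tip.label,
                  kind = "haplotype", A = A, B = B)
  list(cn = cn, node_states = states, tree = tree, model = model)
}

#' Simulate multi-scale copy-number events by exponential waiting times
#'
#' Gillespie-style simulation on fixed 500-Kbp bins. Along each branch,
#' waiting times are drawn from an exponential with the total mutation rate
#' (duplication and deletion summed over all haplotype copies present,
#' chromosome gain/loss over chromosomes, plus WGD); the event type is
#' chosen proportionally to its rate. Duplication/deletion segment sizes
#' are exponential with the configured mean (at least 1 bin), truncated at
#' the chromosome end; duplications are tandem or interspersed with equal
#' probability. Chromosome gains and WGD are suppressed when they would
#' push any bin past \code{c_max}.
#'
#' @param tree A \code{cnp_tree}.
#' @param config A \code{sim_config} in waiting-time mode.
#' @return List with \code{cn} (haplotype-kind bin-level \code{cn_matrix}),
#'   \code{events} (data frame log of all events), \code{node_cn} (list of
#'   per-node haplotype copy matrices) and \code{tree}.
#' @export
simulate_waiting_time <- function(tree, config) {
  stopifnot(inherits(tree, "cnp_tree"), inherits(config, "sim_config"))
  bins <- config$bins
  n_bins <- sum(bins)
  chrom_of <- rep(seq_along(bins), bins)
  chrom_end <- cumsum(bins)
  phy <- tree$tree
  n_tip <- length(phy$tip.label)
  events <- list()
  evolve <- function(hapA, hapB, branch_id, len) {
    t <- 0
    hap <- list(hapA, hapB)
    repeat {
      alive <- vapply(hap, function(h) sum(h > 0), numeric(1))
      rate_dup <- config$u * sum(alive)
      rate_del <- config$e * sum(alive)
      rate_cg <- config$chr_gain * 2 * length(bins)
      rate_cl <- config$chr_loss * 2 * length(bins)
      r <- rate_dup + rate_del + rate_cg + rate_cl + config$wgd
      if (r <= 0) break
      t <- t + stats::rexp(1, r)
      if (t >= len) break
      type <- sample(c("dup", "del", "chr_gain", "chr_loss", "wgd"), 1,
                     prob = c(rate_dup, rate_del, rate_cg, rate_cl,
                              config$wgd))
      h <- sample.int(2L, 1L)
      rec <- NULL
      if (type %in% c("dup", "del")) {
        live <- which(hap[[h]] > 0)
        if (length(live) == 0) next
        start <- live[sample.int(length(live), 1L)]
        mean_size <- if (type == "dup") config$mean_dup_size
                     else config$mean_del_size
        size <- max(1L, ceiling(stats::rexp(1, 1 / mean_size)))
        chr <- chrom_of[start]
        stop_bin <- min(start + size - 1L, chrom_end[chr])
        span <- start:stop_bin
        placement <- NA_character_
        if (type == "dup") {
          tot <- hap[[1L]][span] + hap[[2L]][span]
          # copy the haplotype's fragment; bins already at c_max stay put
          inc <- (hap[[h]][span] > 0L) & (tot < config$c_max)
          hap[[h]][span] <- hap[[h]][span] + inc
          placement <- sample(c("tandem", "interspersed"), 1L)
        } else {
          hap[[h]][span] <- pmax(hap[[h]][span] - 1L, 0L)
        }
        rec <- data.frame(type = type, branch = branch_id, time = t,
                          chrom = names(bins)[chr], start_bin = start,
                          size = length(span), haplotype = c("A", "B")[h],
                          placement = placement)
      } else if (type == "chr_gain") {
        chr <- sample.int(length(bins), 1L)
        span <- which(chrom_of == chr)
        tot <- hap[[1L]][span] + hap[[2L]][span]
        if (max(tot + (hap[[h]][span] > 0)) > config$c_max) next
        hap[[h]][span] <- hap[[h]][span] + (hap[[h]][span] > 0)
        rec <- data.frame(type = type, branch = branch_id, time = t,
                          chrom = names(bins)[chr], start_bin = span[1L],
                          size = length(span), haplotype = c("A", "B")[h],
                          placement = NA_character_)
      } else if (type == "chr_loss") {
        chr <- sample.int(length(bins), 1L)
        span <- which(chrom_of == chr)
        hap[[h]][span] <- pmax(hap[[h]][span] - 1L, 0L)
        rec <- data.frame(type = type, branch = branch_id, time = t,
                          chrom = names(bins)[chr], start_bin = span[1L],
                          size = length(span), haplotype = c("A", "B")[h],
                          placement = NA_character_)
      } else { # wgd
        tot <- hap[[1L]] + hap[[2L]]
        if (max(tot * 2L) > config$c_max) next
        hap[[1L]] <- hap[[1L]] * 2L
        hap[[2L]] <- hap[[2L]] * 2L
        rec <- data.frame(type = type, branch = branch_id, time = t,
                          chrom = NA_character_, start_bin = NA_integer_,
                          size = n_bins, haplotype = NA_character_,
                          placement = NA_character_)
      }
      if (!is.null(rec)) events[[length(events) + 1L]] <<- rec
    }
    hap
  }
  node_cn <- vector("list", n_tip + phy$Nnode)
  root <- n_tip + 1L
  start_hap <- list(rep(1L, n_bins), rep(1L, n_bins))
  node_cn[[root]] <- evolve(start_hap[[1L]], start_hap[[2L]], "luca",
                            tree$luca_len)
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in rev(seq_len(nrow(eo$edge)))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    node_cn[[ch]] <- evolve(node_cn[[p]][[1L]], node_cn[[p]][[2L]],
                            paste0("e", k), eo$edge.length[k])
  }
  A <- do.call(rbind, lapply(seq_len(n_tip), function(i) node_cn[[i]][[1L]]))
  B <- do.call(rbind, lapply(seq_len(n_tip), function(i) node_cn[[i]][[2L]]))
  sites <- data.frame(
    chrom = names(bins)[chrom_of],
    start = (sequence(bins) - 1) * config$bin_size + 1,
    end = sequence(bins) * config$bin_size
  )
  cn <- cn_matrix(sites = sites, sample_ids = phy$tip.label,
                  kind = "haplotype", A = A, B = B)
  ev <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(type = character(), branch = character(), time = numeric(),
               chrom = character(), start_bin = integer(), size = integer(),
               haplotype = character(), placement = character())
  list(cn = cn, events = ev, node_cn = node_cn, tree = tree)
}

#' Inject copy-number calling errors
#'
#' Per sample, exactly \code{round(m * f_e)} sites are selected at random
#' and their copy numbers replaced by a Poisson draw whose mean is the
#' original value, clamped to \code{[0, c_max]}.
#'
#' @param x A total-kind \code{cn_matrix}.
#' @param f_e Fraction of sites perturbed per sample, in [0, 1].
#' @param c_max Maximum total copy number.
#' @return A perturbed \code{cn_matrix}.
#' @export
inject_errors <- function(x, f_e, c_max) {
  stopifnot(inherits(x, "cn_matrix"), f_e >= 0, f_e <= 1)
  if (x$kind != "total") {
    stop("error injection operates on total copy numbers", call. = FALSE)
  }
  m <- ncol(x$values)
  k <- round(m * f_e)
  vals <- x$values
  if (k > 0) {
    for (i in seq_len(nrow(vals))) {
      idx <- sample.int(m, k)
      vals[i, idx] <- pmin(stats::rpois(k, lambda = vals[i, idx]), c_max)
    }
  }
  cn_matrix(vals, x$sites, x$sample_ids, kind = "total")
}

#' Mix clone profiles into bulk-sample profiles
#'
#' Treats each simulated genome as a clone and builds, for every sample, a
#' mixture of \code{n_clones} components: the original clone (fraction
#' \code{f_d}), the normal diploid clone, and \code{n_clones - 2} clones
#' drawn from the other samples; the remaining \code{1 - f_d} is split
#' among the non-original components by a uniform Dirichlet draw. The
#' mixed copy number per site is the weighted mean rounded to the nearest
#' integer, clamped to \code{[0, c_max]}.
#'
#' @param x A total-kind \code{cn_matrix} of clone profiles.
#' @param f_d Fraction of the original clone (0 < f_d <= 1).
#' @param n_clones Number of clones per sample (>= 2), including the
#'   original.
#' @param c_max Maximum total copy number.
#' @return A \code{cn_matrix} of mixed sample profiles.
#' @export
mix_subclones <- function(x, f_d, n_clones, c_max) {
  stopifnot(inherits(x, "cn_matrix"), f_d > 0, f_d <= 1, n_clones >= 2)
  if (x$kind != "total") {
    stop("subclonal mixing operates on total copy numbers", call. = FALSE)
  }
  n <- nrow(x$values)
  m <- ncol(x$values)
  profiles <- rbind(x$values, normal = rep(2L, m))  # last row: normal clone
  mixed <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    pick <- c(n + 1L,  # the normal clone is always present
              if (n_clones > 2L) others[sample.int(length(others),
                                                   n_clones - 2L)])
    w_other <- stats::rgamma(n_clones - 1L, 1)
    w_other <- w_other / sum(w_other) * (1 - f_d)
    w <- c(f_d, w_other)
    if (abs(sum(w) - 1) > 1e-9) stop("mixture fractions do not sum to 1")
    prof <- profiles[c(i, pick), , drop = FALSE]
    mixed[i, ] <- pmin(pmax(as.integer(round(colSums(prof * w))), 0L),
                       c_max)
  }
  cn_matrix(mixed, x$sites, x$sample_ids, kind = "total")
}

#' Convert absolute copy numbers to relative (ploidy-centred) values
#'
#' For total input the per-sample baseline is half the rounded mean copy
#' number (or \eqn{2^{N_{WGD}}} when the number of WGDs is known); values
#' are divided by the baseline, rounded (to the nearest integer, or
#' randomly up/down when the remainder is non-zero), reduced by the normal
#' ploidy 2, and clamped to [-2, 2]. For haplotype input each haplotype is
#' normalized by its own rounded mean (or the WGD baseline), rounded the
#' same way, reduced by the normal per-haplotype ploidy 1 and clamped to
#' [-2, 2].
#'
#' @param x A \code{cn_matrix} of absolute copy numbers.
#' @param baseline \code{"mean_rounded"} or \code{"power2_wgd"}.
#' @param rounding \code{"nearest"} or \code{"random"}.
#' @param n_wgd Per-sample WGD counts (required for \code{"power2_wgd"}).
#' @return A relative \code{cn_matrix} of the same kind.
#' @export
make_relative <- function(x, baseline = c("mean_rounded", "power2_wgd"),
                          rounding = c("nearest", "random"), n_wgd = NULL) {
  stopifnot(inherits(x, "cn_matrix"))
  baseline <- match.arg(baseline)
  rounding <- match.arg(rounding)
  rnd <- function(q) {
    if (rounding == "nearest") return(round(q))
    lo <- floor(q)
    frac <- q - lo
    lo + (frac > 0) * stats::rbinom(length(q), 1L, 0.5) * 1 +
      0  # random up/down on non-zero remainder
  }
  scale_rows <- function(vals, base) {
    if (any(base <= 0)) stop("zero baseline: degenerate sample",
                             call. = FALSE)
    out <- vals
    for (i in seq_len(nrow(vals))) out[i, ] <- rnd(vals[i, ] / base[i])
    out
  }
  if (x$kind == "total") {
    base <- if (baseline == "power2_wgd") {
      if (is.null(n_wgd)) stop("`n_wgd` required for power2_wgd baseline",
                               call. = FALSE)
      2^n_wgd
    } else {
      round(rowMeans(x$values)) / 2
    }
    rel <- scale_rows(x$values, base) - 2
    rel <- pmin(pmax(rel, -2), 2)
    cn_matrix(rel, x$sites, x$sample_ids, kind = "total")
  } else {
    baseH <- function(H) {
      if (baseline == "power2_wgd") {
        if (is.null(n_wgd)) stop("`n_wgd` required for power2_wgd baseline",
                                 call. = FALSE)
        2^n_wgd
      } else round(rowMeans(H))
    }
    relA <- pmin(pmax(scale_rows(x$A, baseH(x$A)) - 1, -2), 2)
    relB <- pmin(pmax(scale_rows(x$B, baseH(x$B)) - 1, -2), 2)
    out <- x
    out$A <- relA; out$B <- relB; out$values <- relA + relB
    out
  }
}

#' Collapse a haplotype-specific matrix to totals
#'
#' @param x A haplotype-kind \code{cn_matrix}.
#' @return A total-kind \code{cn_matrix} with the same sites.
#' @export
as_total <- function(x) {
  stopifnot(inherits(x, "cn_matrix"))
  if (x$kind == "total") return(x)
  cn_matrix(x$A + x$B, x$sites, x$sample_ids, kind = "total")
}
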