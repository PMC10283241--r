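#' Nonparametric bootstrap over sites
#'
#' Resamples the columns (sites) of the data matrix with replacement to
#' the original dimension and re-runs the configured tree search on each
#' pseudo-sample.
#'
#' @param data A \code{cn_matrix} (segment-level data recommended).
#' @param space A \code{cn_states}.
#' @param timing Optional \code{sample_timing}.
#' @param B Number of bootstrap replicates.
#' @param config A \code{search_config}.
#' @param u0,e0,u_init,e_init Rate settings passed to the search.
#' @return List of \code{cn_fit} objects, one per replicate.
#' @export
bootstrap_trees <- function(data, space, timing = NULL, B = 100,
                            config = search_config(), u0 = 0.001,
                            e0 = 0.001, u_init = 5e-4, e_init = 5e-4) {
  stopifnot(inherits(data, "cn_matrix"), B >= 1)
  m <- ncol(data$values)
  lapply(seq_len(B), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    boot <- if (data$kind == "total") {
      cn_matrix(data$values[, idx, drop = FALSE], data$sites[idx, ],
                data$sample_ids, kind = "total")
    } else {
      cn_matrix(sites = data$sites[idx, ], sample_ids = data$sample_ids,
                kind = "haplotype", A = data$A[, idx, drop = FALSE],
                B = data$B[, idx, drop = FALSE])
    }
    search_ml(boot, space, timing, u0, e0, u_init, e_init, config)
  })
}

#' Bootstrap branch support
#'
#' Percentage of bootstrap trees containing each internal branch (tip
#' bipartition/clade) of the reference tree.
#'
#' @param reference A \code{cnp_tree} or rooted \code{phylo}.
#' @param boot_trees List of \code{cn_fit}, \code{cnp_tree} or
#'   \code{phylo} objects over the same tips.
#' @return Numeric vector of support percentages, one per internal node of
#'   the reference sample subtree (MRCA first).
#' @export
branch_support <- function(reference, boot_trees) {
  ref <- .as_phylo(reference)
  boots <- lapply(boot_trees, .as_phylo)
  tipsets <- lapply(boots, function(b) sort(b$tip.label))
  if (!all(vapply(tipsets, identical, logical(1),
                  sort(ref$tip.label)))) {
    stop("bootstrap trees must share the reference tip set", call. = FALSE)
  }
  counts <- ape::prop.clades(ref, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  100 * counts / length(boots)
}

.as_phylo <- function(x) {
  if (inherits(x, "cn_fit")) x <- x$tree
  if (inherits(x, "cnp_tree")) x <- x$tree
  stopifnot(inherits(x, "phylo"))
  x
}

#' Bootstrap confidence intervals for rates and node ages
#'
#' Refits a fixed topology on \code{B} site-resampled pseudo-samples and
#' reports 2.5th/97.5th percentile intervals for the duplication and
#' deletion rates, the LUCA age and the internal-node ages. Initial rates
#' default to the point estimates.
#'
#' @param fit A \code{cn_fit} from a time-calibrated (or same-time) fit;
#'   its topology is held fixed.
#' @param data The original \code{cn_matrix}.
#' @param space A \code{cn_states}.
#' @param timing A \code{sample_timing} (required for age intervals).
#' @param B Number of bootstrap refits.
#' @param probs Percentiles to report.
#' @return Data frame with one row per parameter: point estimate and the
#'   requested percentiles over bootstrap refits.
#' @export
ci_from_bootstrap <- function(fit, data, space, timing = NULL, B = 100,
                              probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "cn_fit"), inherits(data, "cn_matrix"))
  phy <- fit$tree$tree
  m <- ncol(data$values)
  one <- function(dat) {
    if (fit$mode == "time_calibrated") {
      f <- fit_time_calibrated(phy, dat, space, timing,
                               u_init = fit$u, e_init = fit$e)
      ages <- node_ages(f$tree)
      n_tip <- length(phy$tip.label)
      c(u = f$u, e = f$e, luca_age = attr(ages, "luca_age"),
        stats::setNames(ages[(n_tip + 1L):length(ages)],
                        paste0("age_node_", (n_tip + 1L):length(ages))))
    } else {
      f <- fit_same_time(phy, dat, space, u0 = fit$u, e0 = fit$e)
      c(u = f$u, e = f$e, luca_len = f$tree$luca_len,
        total_length = sum(f$tree$tree$edge.length))
    }
  }
  point <- one(data)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    boot <- if (data$kind == "total") {
      cn_matrix(data$values[, idx, drop = FALSE], data$sites[idx, ],
                data$sample_ids, kind = "total")
    } else {
      cn_matrix(sites = data$sites[idx, ], sample_ids = data$sample_ids,
                kind = "haplotype", A = data$A[, idx, drop = FALSE],
                B = data$B[, idx, drop = FALSE])
    }
    one(boot)
  }, numeric(length(point)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  qs <- t(apply(reps, 1L, stats::quantile, probs = probs))
  out <- data.frame(parameter = names(point), estimate = unname(point),
                    lower = qs[, 1L], upper = qs[, 2L])
  rownames(out) <- NULL
  out
}

#' Normalized Robinson-Foulds distance between rooted trees
#'
#' Number of clades present in one tree but not the other, divided by the
#' maximum \eqn{2n - 4} for rooted binary trees with n tips; 0 means
#' identical topologies, 1 maximal disagreement.
#'
#' @param t1,t2 \code{cnp_tree}, \code{cn_fit} or \code{phylo} objects on
#'   the same tips.
#' @return Numeric in [0, 1].
#' @export
rf_normalized <- function(t1, t2) {
  p1 <- .as_phylo(t1); p2 <- .as_phylo(t2)
  if (!setequal(p1$tip.label, p2$tip.label)) {
    stop("trees must share the same tip set", call. = FALSE)
  }
  n <- length(p1$tip.label)
  c1 <- .clade_keys(p1); c2 <- .clade_keys(p2)
  rf <- length(setdiff(c1, c2)) + length(setdiff(c2, c1))
  denom <- 2 * n - 4
  if (denom <= 0) return(0)
  rf / denom
}

#' Branch score distance between trees
#'
#' Square root of the sum of squared branch-length differences, matching
#' branches by the tip clade below them (pendant branches by their tip,
#' plus the root branch); a branch absent from one tree counts with length
#' zero. Branch lengths are in years.
#'
#' @param t1,t2 \code{cnp_tree}, \code{cn_fit} or \code{phylo} objects on
#'   the same tips. \code{cnp_tree} inputs contribute their LUCA branch.
#' @return Non-negative number; 0 iff identical topology and lengths.
#' @export
branch_score <- function(t1, t2) {
  blen <- function(x) {
    luca <- if (inherits(x, "cn_fit")) x$tree$luca_len
            else if (inherits(x, "cnp_tree")) x$luca_len else NA_real_
    phy <- .as_phylo(x)
    keys <- vapply(seq_len(nrow(phy$edge)), function(k) {
      ch <- phy$edge[k, 2L]
      if (ch <= length(phy$tip.label)) phy$tip.label[ch]
      else paste(sort(ape::extract.clade(phy, ch)$tip.label),
                 collapse = "|")
    }, character(1))
    len <- stats::setNames(phy$edge.length, keys)
    if (!is.na(luca)) {
      len <- c(len, stats::setNames(luca, paste(sort(phy$tip.label),
                                                collapse = "|")))
    }
    len
  }
  b1 <- blen(t1); b2 <- blen(t2)
  if (!setequal(.as_phylo(t1)$tip.label, .as_phylo(t2)$tip.label)) {
    stop("trees must share the same tip set", call. = FALSE)
  }
  keys <- union(names(b1), names(b2))
  v1 <- ifelse(keys %in% names(b1), b1[keys], 0)
  v2 <- ifelse(keys %in% names(b2), b2[keys], 0)
  sqrt(sum((v1 - v2)^2))
}
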