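#' Marginal ancestral reconstruction at the MRCA
#'
#' Posterior distribution over haplotype-specific states of the samples'
#' most recent common ancestor at each unique variant site (a variant site
#' whose pattern occurs exactly once in the data), conditional on the
#' fitted tree and rates. The posterior is proportional to the transition
#' probability from the normal LUCA state along the LUCA branch times the
#' partial likelihood of the subtree below the MRCA.
#'
#' @param tree A fitted \code{cnp_tree}.
#' @param model A \code{cn_rate_model}.
#' @param data A \code{cn_matrix} or \code{cn_patterns}.
#' @param all_variant Reconstruct at every distinct variant pattern rather
#'   than only unique (multiplicity-1) variant sites.
#' @return List with \code{posterior} (patterns x states matrix, rows
#'   summing to 1), \code{state} (1-based argmax state index, ties to the
#'   lowest index), \code{pattern_index} (columns of the compressed
#'   patterns reconstructed) and \code{space}.
#' @export
marginal_mrca <- function(tree, model, data, all_variant = FALSE) {
  stopifnot(inherits(tree, "cnp_tree"), inherits(model, "cn_rate_model"))
  patterns <- if (inherits(data, "cn_matrix")) {
    compress_patterns(data, model$space)
  } else data
  phy <- tree$tree
  ord <- match(phy$tip.label, patterns$sample_ids)
  ts <- .tip_struct(patterns, model$space, ord)
  res <- .prune(phy, phy$edge.length, tree$luca_len, model, ts,
                patterns$counts)
  sel <- if (all_variant) which(patterns$variant)
         else which(patterns$variant & patterns$counts == 1L)
  prior <- .pmat(model, tree$luca_len)[model$space$normal, ]
  post <- t(res$mrca_partial[, sel, drop = FALSE] * prior)
  norm <- rowSums(post)
  if (any(norm <= 0)) {
    stop("zero posterior mass at pattern(s) ",
         paste(sel[norm <= 0], collapse = ", "), call. = FALSE)
  }
  post <- post / norm
  list(posterior = post, state = apply(post, 1L, which.max),
       pattern_index = sel, space = model$space)
}

#' Joint ancestral reconstruction of all internal nodes
#'
#' Finds the jointly most probable assignment of haplotype-specific states
#' to every internal node of the sample subtree at each unique variant
#' site, conditional on the LUCA (root) carrying the normal diploid state,
#' by max-product dynamic programming with back-pointers (ties broken
#' towards the lowest state index). Ambiguous tips (total input) are
#' maximized over their compatible states.
#'
#' @inheritParams marginal_mrca
#' @return List with \code{states} (internal-nodes x patterns matrix of
#'   1-based state indices; rows named by phylo node ids, MRCA first),
#'   \code{log_prob} (per-pattern log probability of the joint
#'   assignment), \code{pattern_index} and \code{space}.
#' @export
joint_reconstruct <- function(tree, model, data, all_variant = FALSE) {
  stopifnot(inherits(tree, "cnp_tree"), inherits(model, "cn_rate_model"))
  patterns <- if (inherits(data, "cn_matrix")) {
    compress_patterns(data, model$space)
  } else data
  space <- model$space
  S <- space$n_states
  phy <- tree$tree
  n_tip <- length(phy$tip.label)
  ord <- match(phy$tip.label, patterns$sample_ids)
  sel <- if (all_variant) which(patterns$variant)
         else which(patterns$variant & patterns$counts == 1L)
  p <- length(sel)
  if (p == 0L) {
    return(list(states = matrix(integer(0), phy$Nnode, 0),
                log_prob = numeric(0), pattern_index = sel, space = space))
  }
  obs <- patterns$obs[ord, sel, drop = FALSE]
  # tip state sets
  tip_sets <- lapply(seq_len(n_tip), function(i) {
    if (patterns$kind == "total") {
      lapply(obs[i, ], function(tot) space$compat[[tot + 1L]])
    } else {
      lapply(obs[i, ], function(s) s)
    }
  })
  eo <- ape::reorder.phylo(phy, "postorder")
  edges <- eo$edge
  lens <- eo$edge.length
  # C[[node]]: S x p best log contribution given the parent state
  # Bp[[node]]: S x p argmax own state
  C <- vector("list", n_tip + phy$Nnode)
  Bp <- vector("list", n_tip + phy$Nnode)
  inner_of <- vector("list", n_tip + phy$Nnode)
  k <- 1L
  n_edge <- nrow(edges)
  while (k <= n_edge) {
    parent <- edges[k, 1L]
    while (k <= n_edge && edges[k, 1L] == parent) {
      ch <- edges[k, 2L]
      logP <- log(.pmat(model, lens[k]))
      if (ch <= n_tip) {
        Cm <- matrix(-Inf, S, p); Bm <- matrix(1L, S, p)
        for (j in seq_len(p)) {
          ss <- tip_sets[[ch]][[j]]
          sub <- logP[, ss, drop = FALSE]
          pick <- max.col(sub, ties.method = "first")
          Cm[, j] <- sub[cbind(seq_len(S), pick)]
          Bm[, j] <- ss[pick]
        }
      } else {
        inner <- inner_of[[ch]]   # S x p: sum of children C given own state
        Cm <- matrix(-Inf, S, p); Bm <- matrix(1L, S, p)
        for (dj in seq_len(S)) {
          cand <- outer(logP[, dj], inner[dj, ], "+")
          better <- cand > Cm
          Bm[better] <- dj
          Cm[better] <- cand[better]
        }
      }
      inner_of[[parent]] <- if (is.null(inner_of[[parent]])) Cm
                            else inner_of[[parent]] + Cm
      C[[ch]] <- Cm; Bp[[ch]] <- Bm
      k <- k + 1L
    }
  }
  root <- n_tip + 1L
  logP_luca <- log(.pmat(model, tree$luca_len))
  root_score <- inner_of[[root]] + logP_luca[space$normal, ]
  mrca_state <- apply(root_score, 2L, which.max)
  log_prob <- root_score[cbind(mrca_state, seq_len(p))]
  # preorder: read back-pointers
  states <- matrix(1L, n_tip + phy$Nnode, p)
  states[root, ] <- mrca_state
  for (kk in rev(seq_len(n_edge))) {
    parent <- edges[kk, 1L]; ch <- edges[kk, 2L]
    states[ch, ] <- Bp[[ch]][cbind(states[parent, ], seq_len(p))]
  }
  internal <- root:(n_tip + phy$Nnode)
  out <- states[internal, , drop = FALSE]
  rownames(out) <- internal
  list(states = out, log_prob = log_prob, pattern_index = sel,
       space = space, tip_states = states[seq_len(n_tip), , drop = FALSE])
}

#' Accuracy of an ancestral reconstruction against simulated truth
#'
#' Fraction of correctly recovered haplotype-specific states over the
#' scored sites for each internal node, and the mean fraction over all
#' internal nodes of the sample subtree.
#'
#' @param truth Matrix of true 1-based state indices, nodes x sites, with
#'   rows indexed as in the phylo (e.g. \code{node_states} from
#'   \code{\link{simulate_direct}}).
#' @param recon Result of \code{\link{joint_reconstruct}}.
#' @param patterns The \code{cn_patterns} the reconstruction used.
#' @return List with \code{per_node} (named fractions) and \code{mean}.
#' @export
reconstruction_accuracy <- function(truth, recon, patterns) {
  nodes <- as.integer(rownames(recon$states))
  if (length(nodes) == 0 || ncol(recon$states) == 0) {
    return(list(per_node = numeric(0), mean = NA_real_))
  }
  if (max(nodes) > nrow(truth)) {
    stop("truth matrix does not cover the reconstructed nodes",
         call. = FALSE)
  }
  # map reconstructed patterns back to their (unique) originating sites
  site_ix <- vapply(recon$pattern_index,
                    function(jp) which(patterns$site_of == jp)[1L],
                    integer(1))
  per_node <- vapply(seq_along(nodes), function(r) {
    mean(recon$states[r, ] == truth[nodes[r], site_ix])
  }, numeric(1))
  names(per_node) <- rownames(recon$states)
  list(per_node = per_node, mean = mean(per_node))
}

#' Project reconstructed states to copy numbers
#'
#' @param states Matrix (or vector) of 1-based state indices.
#' @param space A \code{cn_states}.
#' @return Data frame with \code{cA}, \code{cB} and \code{total} per entry.
#' @export
states_to_cn <- function(states, space) {
  idx <- as.vector(states)
  data.frame(cA = space$states[idx, 1L], cB = space$states[idx, 2L],
             total = space$total[idx])
}
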