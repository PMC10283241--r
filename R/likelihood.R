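#' Compress a copy-number matrix into site patterns
#'
#' A site pattern is the tuple of observed states across all samples at one
#' site. The likelihood depends on the data only through the distinct
#' patterns and their multiplicities, so identical columns are collapsed and
#' computed once. A pattern is invariant when every sample shows the normal
#' state (total 2, or haplotype pair (1, 1)).
#'
#' @param x A \code{cn_matrix}.
#' @param space A \code{cn_states} defining the state space.
#' @return An object of class \code{cn_patterns} with fields:
#'   \item{obs}{n x p matrix of observation codes, one column per distinct
#'     pattern in order of first occurrence: total copy numbers for total
#'     input, 1-based state indices for haplotype input}
#'   \item{counts}{multiplicity of each pattern}
#'   \item{variant}{logical, pattern contains a non-normal observation}
#'   \item{site_of}{for each original site, its pattern index}
#'   \item{kind, n_samples, sample_ids}{bookkeeping}
#' @export
compress_patterns <- function(x, space) {
  stopifnot(inherits(x, "cn_matrix"), inherits(space, "cn_states"))
  if (x$kind == "total") {
    if (any(x$values < 0) || any(x$values > space$c_max)) {
      stop("total copy numbers outside [0, c_max]", call. = FALSE)
    }
    obs_full <- x$values                       # n x m of totals
    normal_code <- 2L
  } else {
    if (any(x$values > space$c_max)) {
      stop("haplotype copy-number totals exceed c_max", call. = FALSE)
    }
    obs_full <- matrix(state_index(space, x$A, x$B, zero_based = FALSE),
                       nrow = nrow(x$A))       # n x m of state rows
    normal_code <- space$normal
  }
  key <- apply(obs_full, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  site_of <- match(key, key[first])
  obs <- obs_full[, first, drop = FALSE]
  counts <- as.integer(tabulate(site_of, nbins = sum(first)))
  variant <- apply(obs != normal_code, 2L, any)
  structure(list(obs = obs, counts = counts, variant = variant,
                 site_of = site_of, kind = x$kind,
                 n_samples = nrow(obs_full), sample_ids = x$sample_ids),
            class = "cn_patterns")
}

#' Partial likelihood vector at a tip
#'
#' The conditional likelihood of the observation at a tip is an indicator
#' over the haplotype-specific states: a single 1 for haplotype-specific
#' input, and 1 on every compatible state for total input (the haplotype
#' split being missing information).
#'
#' @param observed The observation: a total copy number (kind
#'   \code{"total"}) or a length-2 vector \code{c(cA, cB)} (kind
#'   \code{"haplotype"}).
#' @param kind \code{"total"} or \code{"haplotype"}.
#' @param space A \code{cn_states}.
#' @return Numeric indicator vector over the states.
#' @export
tip_partial <- function(observed, kind = c("total", "haplotype"), space) {
  kind <- match.arg(kind)
  v <- numeric(space$n_states)
  if (kind == "total") {
    v[compatible_states(observed, space)] <- 1
  } else {
    v[state_index(space, observed[1L], observed[2L], zero_based = FALSE)] <- 1
  }
  v
}

# compact tip representation: per tip, an indicator basis over its
# distinct observations plus a per-pattern column code
.tip_struct <- function(patterns, space, tip_order) {
  S <- space$n_states
  basis <- vector("list", length(tip_order))
  code <- vector("list", length(tip_order))
  for (ii in seq_along(tip_order)) {
    i <- tip_order[ii]
    obs <- patterns$obs[i, ]
    distinct <- unique(obs)
    B <- matrix(0, S, length(distinct))
    for (kk in seq_along(distinct)) {
      if (patterns$kind == "total") {
        B[space$compat[[distinct[kk] + 1L]], kk] <- 1
      } else {
        B[distinct[kk], kk] <- 1
      }
    }
    basis[[ii]] <- B
    code[[ii]] <- match(obs, distinct)
  }
  list(basis = basis, code = code, p = ncol(patterns$obs))
}

# transition matrix for internal use: eigen path, no memo of individual t
.pmat <- function(model, t) {
  if (t <= 0) return(diag(model$space$n_states))
  eig <- .rate_eigen(model)
  if (eig$ok) {
    P <- Re(eig$V %*% (exp(eig$values * t) * eig$Vinv))
    P[P < 0] <- 0
    P
  } else {
    transition_matrix(model, t, cache = FALSE)
  }
}

# Postorder bookkeeping for a topology, computed once per tree.
.prep_tree <- function(phy) {
  eo <- ape::reorder.phylo(phy, "postorder")
  perm <- match(paste(eo$edge[, 1L], eo$edge[, 2L]),
                paste(phy$edge[, 1L], phy$edge[, 2L]))
  edges <- eo$edge
  storage.mode(edges) <- "integer"
  list(edges = edges, perm = perm,
       n_tip = length(phy$tip.label), n_node = phy$Nnode)
}

# Felsenstein pruning over compressed patterns. `prep` is a .prep_tree()
# structure (or a phylo, prepared on the fly); edge_len follows the
# original phylo edge order; `ts` is a .tip_struct() representation of the
# tip observations. Transition matrices are memoized per distinct branch
# length in the model object.
# Returns list(loglik, mrca_partial = S x p matrix, logscale, site_lik).
.prune <- function(prep, edge_len, luca_len, model, ts, counts) {
  if (inherits(prep, "phylo")) prep <- .prep_tree(prep)
  lens <- edge_len[prep$perm]
  eig <- .rate_eigen(model)
  res <- if (eig$ok) {
    ctx <- model$.cache$ctx
    if (is.null(ctx)) {
      ctx <- cpp_make_ctx(eig$V, eig$Vinv, eig$values)
      model$.cache$ctx <- ctx
    }
    cpp_prune_ctx(ctx, prep$edges, lens, luca_len, ts$basis, ts$code,
                  model$space$normal, as.numeric(counts),
                  prep$n_tip, prep$n_node)
  } else {
    # defective eigendecomposition: robust per-branch exponentials
    Ps <- lapply(lens, function(t) transition_matrix(model, t))
    Pl <- transition_matrix(model, luca_len)
    cpp_prune(prep$edges, Ps, Pl, ts$basis, ts$code,
              model$space$normal, as.numeric(counts),
              prep$n_tip, prep$n_node)
  }
  res
}

#' Phylogenetic log-likelihood of copy-number profiles
#'
#' Computes the log-probability of the observed profiles on a patient
#' sample tree under the duplication/deletion Markov model, by Felsenstein
#' pruning over compressed site patterns. The LUCA root carries a point-mass
#' prior on the normal diploid state (its zero-length branch to the normal
#' tip contributes an identity factor); the MRCA state is summed over.
#' Total copy numbers enter as ambiguous observations, so each site's
#' probability is the sum over all compatible haplotype-specific histories.
#'
#' @param tree A \code{cnp_tree} with branch lengths in years.
#' @param model A \code{cn_rate_model}.
#' @param data A \code{cn_patterns} (from \code{\link{compress_patterns}})
#'   or a \code{cn_matrix}.
#' @return The log-likelihood (scalar; \code{-Inf} if any pattern is
#'   impossible under the model).
#' @export
log_likelihood <- function(tree, model, data) {
  stopifnot(inherits(tree, "cnp_tree"), inherits(model, "cn_rate_model"))
  patterns <- if (inherits(data, "cn_matrix")) {
    compress_patterns(data, model$space)
  } else data
  stopifnot(inherits(patterns, "cn_patterns"))
  phy <- tree$tree
  ord <- match(phy$tip.label, patterns$sample_ids)
  if (anyNA(ord)) {
    stop("tree tips and sample ids do not match", call. = FALSE)
  }
  ts <- .tip_struct(patterns, model$space, ord)
  edge_len <- phy$edge.length
  if (any(edge_len < 0)) stop("negative branch length", call. = FALSE)
  res <- .prune(phy, edge_len, tree$luca_len, model, ts, patterns$counts)
  if (!is.finite(res$loglik)) {
    warning("zero likelihood for pattern(s) ",
            paste(which(res$site_lik <= 0), collapse = ", "),
            "; data impossible under the model", call. = FALSE)
  }
  res$loglik
}
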