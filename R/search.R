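#' Tree-search configuration
#'
#' @param n_initial Number of stepwise-addition start trees for the
#'   heuristic search.
#' @param n1 Start trees kept for NNI hill climbing.
#' @param n2 Trees fully optimized after NNI.
#' @param mode \code{"auto"} (exhaustive up to 7 samples, else heuristic),
#'   \code{"exhaustive"} or \code{"heuristic"}.
#' @param seed Optional RNG seed for reproducible searches.
#' @param screen_iter Optimizer iterations for the cheap screening fits
#'   used to rank candidate topologies.
#' @param refine_k Number of top-ranked topologies refined with a full
#'   optimization in exhaustive mode.
#' @param maxit Optimizer iterations for full fits.
#' @return A list of class \code{search_config}.
#' @export
search_config <- function(n_initial = 100, n1 = 20, n2 = 5,
                          mode = c("auto", "exhaustive", "heuristic"),
                          seed = NULL, screen_iter = 10, refine_k = 10,
                          maxit = 500) {
  mode <- match.arg(mode)
  if (!(n2 <= n1 && n1 <= n_initial)) {
    stop("need n2 <= n1 <= n_initial", call. = FALSE)
  }
  structure(as.list(environment()), class = "search_config")
}

# dispatch one fit (same-time or time-calibrated) at a given iteration cap
.fit_topology <- function(phy, patterns, space, timing, u0, e0, u_init,
                          e_init, maxit, l_m = 1e-3) {
  if (is.null(timing) ||
      length(unique(round(timing$times, 9))) < 2L) {
    fit_same_time(phy, patterns, space, u0 = u0, e0 = e0, l_m = l_m,
                  maxit = maxit)
  } else {
    fit_time_calibrated(phy, patterns, space, timing, u_init = u_init,
                        e_init = e_init, l_m = l_m, maxit = maxit)
  }
}

#' Exhaustive maximum-likelihood topology search
#'
#' Enumerates every rooted binary topology on the samples, ranks them by
#' the likelihood after a capped branch-length optimization, then fully
#' optimizes the top candidates and returns the best fit. Practical for up
#' to about seven samples.
#'
#' @param data A \code{cn_matrix} or \code{cn_patterns}.
#' @param space A \code{cn_states}.
#' @param timing Optional \code{sample_timing}; when absent (or one time
#'   point) branch lengths are fitted at the fixed rates \code{u0},
#'   \code{e0}, otherwise ages and rates are estimated jointly.
#' @param u0,e0 Fixed rates for same-time data.
#' @param u_init,e_init Initial rates for joint estimation.
#' @param config A \code{search_config}.
#' @return A \code{cn_fit} for the best topology, with the screened
#'   ranking in attribute \code{"ranking"}.
#' @export
exhaustive_search <- function(data, space, timing = NULL, u0 = 0.001,
                              e0 = 0.001, u_init = 5e-4, e_init = 5e-4,
                              config = search_config()) {
  patterns <- if (inherits(data, "cn_matrix")) compress_patterns(data, space)
              else data
  labels <- sort(patterns$sample_ids)
  topos <- enumerate_topologies(labels)
  screened <- vapply(topos, function(phy) {
    .fit_topology(phy, patterns, space, timing, u0, e0, u_init, e_init,
                  maxit = config$screen_iter)$loglik
  }, numeric(1))
  keep <- order(screened, decreasing = TRUE)[
    seq_len(min(config$refine_k, length(topos)))]
  fits <- lapply(topos[keep], function(phy) {
    .fit_topology(phy, patterns, space, timing, u0, e0, u_init, e_init,
                  maxit = config$maxit)
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  attr(best, "ranking") <- data.frame(topology = keep,
                                      screen_loglik = screened[keep])
  best
}

#' Parsimony stepwise-addition start trees
#'
#' Builds up to \code{n_initial} random-addition-order parsimony trees on
#' the copy-number characters (each haplotype appended as its own site for
#' haplotype input), rooted via an added normal diploid genome, with
#' duplicate topologies removed.
#'
#' @param data A \code{cn_matrix}.
#' @param n_initial Number of random addition orders.
#' @return List of unique rooted sample topologies (\code{phylo}).
#' @export
stepwise_addition_start_trees <- function(data, n_initial = 100) {
  stopifnot(inherits(data, "cn_matrix"))
  chars <- if (data$kind == "haplotype") cbind(data$A, data$B) else data$values
  chars <- rbind(chars, .normal. = rep(if (data$kind == "haplotype") 1L
                                       else 2L, ncol(chars)))
  lv <- sort(unique(as.vector(chars)))
  cmat <- matrix(as.character(chars), nrow(chars),
                 dimnames = list(rownames(chars), NULL))
  pd <- phangorn::phyDat(cmat, type = "USER", levels = as.character(lv))
  seen <- character(0)
  out <- list()
  for (i in seq_len(n_initial)) {
    tr <- phangorn::random.addition(pd)
    tr <- ape::root(tr, outgroup = ".normal.", resolve.root = TRUE)
    tr <- ape::drop.tip(tr, ".normal.")
    tr$edge.length <- NULL
    key <- .topo_key(.topo_from_phylo(tr))
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}

#' Fitch parsimony score of a topology on copy-number characters
#'
#' States are treated as unordered categories (each haplotype is a
#' separate character for haplotype input); the score is the minimum
#' number of state changes over the tree, summed over sites.
#'
#' @param phy Rooted sample topology.
#' @param data A \code{cn_matrix}.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(phy, data) {
  chars <- if (data$kind == "haplotype") cbind(data$A, data$B) else data$values
  lv <- sort(unique(as.vector(chars)))
  cmat <- matrix(as.character(chars), nrow(chars),
                 dimnames = list(rownames(chars), NULL))
  pd <- phangorn::phyDat(cmat, type = "USER", levels = as.character(lv))
  as.integer(phangorn::parsimony(phy, pd))
}

#' Heuristic maximum-likelihood tree search
#'
#' Stepwise-addition parsimony start trees are ranked by likelihood after
#' a capped optimization; the top \code{n1} undergo hill-climbing NNI
#' (accepting a neighbour only when its capped-fit likelihood improves);
#' the top \code{n2} trees are then fully optimized and the best fit
#' returned.
#'
#' @inheritParams exhaustive_search
#' @param data A \code{cn_matrix} (characters are needed for the parsimony
#'   start trees).
#' @param max_nni_rounds Cap on NNI sweeps per tree.
#' @return A \code{cn_fit}.
#' @export
heuristic_search <- function(data, space, timing = NULL, u0 = 0.001,
                             e0 = 0.001, u_init = 5e-4, e_init = 5e-4,
                             config = search_config(),
                             max_nni_rounds = 10) {
  stopifnot(inherits(data, "cn_matrix"))
  patterns <- compress_patterns(data, space)
  if (!is.null(config$seed)) set.seed(config$seed)
  starts <- stepwise_addition_start_trees(data, config$n_initial)
  screen <- function(phy) {
    .fit_topology(phy, patterns, space, timing, u0, e0, u_init, e_init,
                  maxit = config$screen_iter)$loglik
  }
  scr <- vapply(starts, screen, numeric(1))
  keep <- order(scr, decreasing = TRUE)[
    seq_len(min(config$n1, length(starts)))]
  climbed <- lapply(keep, function(ix) {
    cur <- starts[[ix]]
    cur_ll <- scr[ix]
    for (round in seq_len(max_nni_rounds)) {
      nbs <- nni_neighbors(cur)
      lls <- vapply(nbs, screen, numeric(1))
      if (max(lls) <= cur_ll + 1e-9) break
      cur <- nbs[[which.max(lls)]]
      cur_ll <- max(lls)
    }
    list(tree = cur, loglik = cur_ll)
  })
  # unique topologies, best first
  ord <- order(vapply(climbed, `[[`, numeric(1), "loglik"),
               decreasing = TRUE)
  seen <- character(0)
  finalists <- list()
  for (ix in ord) {
    key <- .topo_key(.topo_from_phylo(climbed[[ix]]$tree))
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      finalists[[length(finalists) + 1L]] <- climbed[[ix]]$tree
    }
    if (length(finalists) >= config$n2) break
  }
  fits <- lapply(finalists, function(phy) {
    .fit_topology(phy, patterns, space, timing, u0, e0, u_init, e_init,
                  maxit = config$maxit)
  })
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

#' Maximum-likelihood tree search (automatic mode)
#'
#' Dispatches to \code{\link{exhaustive_search}} for up to seven samples
#' and \code{\link{heuristic_search}} otherwise (or per
#' \code{config$mode}).
#'
#' @inheritParams heuristic_search
#' @return A \code{cn_fit}.
#' @export
search_ml <- function(data, space, timing = NULL, u0 = 0.001, e0 = 0.001,
                      u_init = 5e-4, e_init = 5e-4,
                      config = search_config()) {
  n <- if (inherits(data, "cn_matrix")) nrow(data$values)
       else data$n_samples
  mode <- config$mode
  if (mode == "auto") mode <- if (n <= 7) "exhaustive" else "heuristic"
  if (mode == "exhaustive") {
    if (!is.null(config$seed)) set.seed(config$seed)
    exhaustive_search(data, space, timing, u0, e0, u_init, e_init, config)
  } else {
    heuristic_search(data, space, timing, u0, e0, u_init, e_init, config)
  }
}
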