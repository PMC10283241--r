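#' @keywords internal
#' Per-node upper age limits: the largest age node i can take while leaving
#' every descendant room for a minimal branch length l_m per edge.
.max_ages <- function(phy, tip_ages, l_m) {
  n_tip <- length(phy$tip.label)
  M <- numeric(n_tip + phy$Nnode)
  M[seq_len(n_tip)] <- tip_ages
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    cand <- M[ch] - l_m
    if (M[p] == 0 || cand < M[p]) M[p] <- cand
  }
  M
}

# internal nodes of the sample subtree in preorder (MRCA first)
.internal_preorder <- function(phy) {
  n_tip <- length(phy$tip.label)
  eo <- ape::reorder.phylo(phy, "postorder")
  parents <- rev(eo$edge[, 1L])
  unique(parents)
}

#' Encode node ages into box-constrained optimizer variables
#'
#' The first variable is the tree height from the LUCA to the last-sampled
#' tip, bounded between \code{d + n * l_m} (room for minimal branches) and
#' \code{A0 + d} (LUCA no earlier than patient birth). Each remaining
#' internal node gets the fractional position of its age between its
#' parent's age plus \code{l_m} and the largest age leaving all descendants
#' room for minimal branches, clipped to [0.01, 0.99]. The map is a
#' bijection between the bound box and the set of valid age configurations.
#'
#' @param tree A \code{cnp_tree} with timing (\code{A0}, \code{tip_times}).
#' @param l_m Minimal branch length in years (default 1e-3).
#' @return List with \code{x}, \code{lower}, \code{upper}, and bookkeeping
#'   (\code{order}: internal nodes in preorder).
#' @export
encode_ages <- function(tree, l_m = 1e-3) {
  stopifnot(inherits(tree, "cnp_tree"))
  if (is.na(tree$A0)) stop("timing (A0) required", call. = FALSE)
  phy <- tree$tree
  n <- length(phy$tip.label)
  offs <- if (is.null(tree$tip_times)) rep(0, n) else tree$tip_times
  d <- max(offs)
  ages <- node_ages(tree)
  luca_age <- attr(ages, "luca_age")
  tip_ages <- tree$A0 + offs
  M <- .max_ages(phy, tip_ages, l_m)
  ord <- .internal_preorder(phy)
  parent_of <- integer(n + phy$Nnode)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  x <- numeric(1L + length(ord))
  x[1L] <- min(max(tree$A0 + d - luca_age, d + n * l_m), tree$A0 + d)
  for (k in seq_along(ord)) {
    node <- ord[k]
    parent_age <- if (node == n + 1L) tree$A0 + d - x[1L]
                  else ages[parent_of[node]]
    lo <- parent_age + l_m
    hi <- M[node]
    frac <- if (hi > lo) (ages[node] - lo) / (hi - lo) else 0.5
    x[k + 1L] <- min(max(frac, 0.01), 0.99)
  }
  list(x = x,
       lower = c(d + n * l_m, rep(0.01, length(ord))),
       upper = c(tree$A0 + d, rep(0.99, length(ord))),
       order = ord, l_m = l_m)
}

#' Decode optimizer variables into node ages and branch lengths
#'
#' Inverse of \code{\link{encode_ages}} for a fixed topology and timing.
#'
#' @param x Variable vector (length: number of internal nodes of the full
#'   tree, i.e. number of samples).
#' @param topology Sample subtree (\code{ape::phylo}, lengths ignored).
#' @param timing A \code{sample_timing}.
#' @param l_m Minimal branch length in years.
#' @return A \code{cnp_tree} with branch lengths implied by the decoded
#'   ages; node ages attached as attribute \code{"ages"}.
#' @export
decode_ages <- function(x, topology, timing, l_m = 1e-3) {
  phy <- topology
  n <- length(phy$tip.label)
  missing <- setdiff(phy$tip.label, names(timing$times))
  if (length(missing) > 0) {
    stop("timing missing for samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  offs <- timing$times[phy$tip.label]
  d <- max(timing$times)
  tip_ages <- timing$A0 + offs
  M <- .max_ages(phy, tip_ages, l_m)
  ord <- .internal_preorder(phy)
  stopifnot(length(x) == 1L + length(ord))
  parent_of <- integer(n + phy$Nnode)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  ages <- c(tip_ages, numeric(phy$Nnode))
  luca_age <- timing$A0 + d - x[1L]
  for (k in seq_along(ord)) {
    node <- ord[k]
    parent_age <- if (node == n + 1L) luca_age else ages[parent_of[node]]
    lo <- parent_age + l_m
    hi <- M[node]
    ages[node] <- if (hi > lo) lo + x[k + 1L] * (hi - lo) else lo
  }
  edge_len <- ages[phy$edge[, 2L]] - ages[phy$edge[, 1L]]
  phy$edge.length <- pmax(edge_len, 0)
  out <- cnp_tree(phy, luca_len = max(ages[n + 1L] - luca_age, 0),
                  tip_times = timing$times[phy$tip.label], A0 = timing$A0)
  attr(out, "ages") <- ages
  attr(out, "luca_age") <- luca_age
  out
}

#' Fit branch lengths when all samples share one sampling time
#'
#' With a single time point, mutation rates and times are confounded: only
#' the products \eqn{l_i = (u_0 + e_0) t_i} (expected CNAs per site on
#' branch i) are identifiable. Rates are therefore fixed at the supplied
#' \code{u0}, \code{e0} and branch lengths are optimized by bounded
#' quasi-Newton minimization of the negative log-likelihood on a log scale.
#'
#' @param topology Sample subtree (\code{ape::phylo}); branch lengths, if
#'   present, seed the optimizer.
#' @param data A \code{cn_patterns} or \code{cn_matrix}.
#' @param space A \code{cn_states}.
#' @param u0,e0 Fixed duplication/deletion rates (per haplotype per site
#'   per year, > 0).
#' @param l_m Minimal branch length in years.
#' @param init_len Initial branch length in years when the topology has
#'   none.
#' @param maxit Maximum optimizer iterations.
#' @return A \code{cn_fit}: fitted \code{cnp_tree} (lengths in years under
#'   the fixed rates), rates, maximized log-likelihood and diagnostics.
#' @export
fit_same_time <- function(topology, data, space, u0 = 0.001, e0 = 0.001,
                          l_m = 1e-3, init_len = 5, maxit = 500) {
  stopifnot(u0 > 0, e0 > 0)
  patterns <- if (inherits(data, "cn_matrix")) compress_patterns(data, space)
              else data
  phy <- topology
  n_edge <- nrow(phy$edge)
  init <- if (!is.null(phy$edge.length)) pmax(phy$edge.length, l_m)
          else rep(init_len, n_edge)
  init_luca <- max(attr(topology, "luca_len") %||% init_len, l_m)
  model <- build_rate_matrix(u0, e0, space)
  ord <- match(phy$tip.label, patterns$sample_ids)
  if (anyNA(ord)) stop("tree tips and sample ids do not match", call. = FALSE)
  ts <- .tip_struct(patterns, space, ord)
  prep <- .prep_tree(phy)
  negll <- function(z) {
    t_all <- exp(z)
    res <- .prune(prep, t_all[seq_len(n_edge)], t_all[n_edge + 1L],
                  model, ts, patterns$counts)
    if (!is.finite(res$loglik)) 1e10 else -res$loglik
  }
  z0 <- log(c(init, init_luca))
  opt <- stats::optim(z0, negll, method = "L-BFGS-B",
                      lower = log(l_m), upper = log(500),
                      control = list(maxit = maxit, factr = 1e7))
  t_hat <- exp(opt$par)
  phy$edge.length <- t_hat[seq_len(n_edge)]
  fit_tree <- cnp_tree(phy, luca_len = t_hat[n_edge + 1L])
  structure(list(tree = fit_tree, u = u0, e = e0, loglik = -opt$value,
                 convergence = opt$convergence,
                 iterations = opt$counts[["function"]],
                 mode = "same_time"),
            class = "cn_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jointly fit node ages and mutation rates from time-stamped samples
#'
#' With samples at two or more time points under a global clock, node ages
#' (in years since patient birth) and the duplication/deletion rates are
#' jointly identifiable. Ages are optimized through the box-constrained
#' transform of \code{\link{encode_ages}}; rates are optimized on a log10
#' scale within \code{rate_bounds}.
#'
#' @param topology Sample subtree (\code{ape::phylo}).
#' @param data A \code{cn_patterns} or \code{cn_matrix}.
#' @param space A \code{cn_states}.
#' @param timing A \code{sample_timing} with at least two distinct times
#'   over at least three samples.
#' @param u_init,e_init Initial rates (small starts are recommended when
#'   the plausible range is unknown).
#' @param rate_bounds Lower/upper bounds on each rate.
#' @param l_m Minimal branch length in years.
#' @param maxit Maximum optimizer iterations.
#' @param x_init Optional initial variable vector (e.g. from
#'   \code{\link{encode_ages}} of a starting tree).
#' @return A \code{cn_fit} with fitted tree, \code{u}, \code{e}, maximized
#'   log-likelihood and diagnostics.
#' @export
fit_time_calibrated <- function(topology, data, space, timing,
                                u_init = 5e-4, e_init = 5e-4,
                                rate_bounds = c(1e-6, 1), l_m = 1e-3,
                                maxit = 500, x_init = NULL) {
  stopifnot(inherits(timing, "sample_timing"))
  n <- length(topology$tip.label)
  if (length(unique(round(timing$times, 9))) < 2L) {
    stop("all samples share one time point; rates and ages are not ",
         "jointly identifiable -- use fit_same_time()", call. = FALSE)
  }
  if (n < 3L) {
    stop("joint estimation needs at least three samples", call. = FALSE)
  }
  patterns <- if (inherits(data, "cn_matrix")) compress_patterns(data, space)
              else data
  phy <- topology
  d <- max(timing$times)
  n_int <- phy$Nnode  # internal nodes of the sample subtree
  ord_tip <- match(phy$tip.label, patterns$sample_ids)
  if (anyNA(ord_tip)) stop("tree tips and sample ids do not match",
                           call. = FALSE)
  ts <- .tip_struct(patterns, space, ord_tip)
  lower <- c(d + n * l_m, rep(0.01, n_int), rep(log10(rate_bounds[1L]), 2))
  upper <- c(timing$A0 + d, rep(0.99, n_int), rep(log10(rate_bounds[2L]), 2))
  if (is.null(x_init)) {
    x_init <- c(min(max(20 + d, d + n * l_m + 1e-6), timing$A0 + d),
                rep(0.5, n_int))
  }
  p0 <- c(pmin(pmax(x_init, lower[seq_len(n_int + 1L)]),
               upper[seq_len(n_int + 1L)]),
          log10(u_init), log10(e_init))
  nv <- n_int + 1L
  # decode bookkeeping hoisted out of the objective
  offs <- timing$times[phy$tip.label]
  tip_ages <- timing$A0 + offs
  M <- .max_ages(phy, tip_ages, l_m)
  ordn <- .internal_preorder(phy)
  parent_of <- integer(n + phy$Nnode)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  decode_lean <- function(x) {
    ages <- c(tip_ages, numeric(n_int))
    luca_age <- timing$A0 + d - x[1L]
    for (k in seq_along(ordn)) {
      node <- ordn[k]
      parent_age <- if (node == n + 1L) luca_age else ages[parent_of[node]]
      lo <- parent_age + l_m
      hi <- M[node]
      ages[node] <- if (hi > lo) lo + x[k + 1L] * (hi - lo) else lo
    }
    list(edge_len = pmax(ages[phy$edge[, 2L]] - ages[phy$edge[, 1L]], 0),
         luca_len = max(ages[n + 1L] - luca_age, 0))
  }
  prep <- .prep_tree(phy)
  # models (with their eigendecomposition and P memo) cached per rate pair,
  # so coordinate-wise gradient steps in the age variables reuse them
  model_cache <- new.env(parent = emptyenv())
  get_model <- function(u, e) {
    key <- sprintf("%.15g_%.15g", u, e)
    mod <- model_cache[[key]]
    if (is.null(mod)) {
      mod <- build_rate_matrix(u, e, space)
      model_cache[[key]] <- mod
    }
    mod
  }
  negll <- function(par) {
    dec <- decode_lean(par[seq_len(nv)])
    u <- 10^par[nv + 1L]; e <- 10^par[nv + 2L]
    model <- get_model(u, e)
    res <- .prune(prep, dec$edge_len, dec$luca_len,
                  model, ts, patterns$counts)
    if (!is.finite(res$loglik)) 1e10 else -res$loglik
  }
  opt <- stats::optim(p0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e7,
                                     ndeps = rep(1e-5, length(p0))))
  fit_tree <- decode_ages(opt$par[seq_len(nv)], phy, timing, l_m)
  structure(list(tree = fit_tree,
                 u = 10^opt$par[nv + 1L], e = 10^opt$par[nv + 2L],
                 loglik = -opt$value, convergence = opt$convergence,
                 iterations = opt$counts[["function"]],
                 mode = "time_calibrated"),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("ML fit (%s): logL = %.4f, u = %.4g, e = %.4g\n",
              x$mode, x$loglik, x$u, x$e))
  invisible(x)
}
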