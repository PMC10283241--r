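#' Enumerate haplotype-specific copy-number states
#'
#' Builds the ordered state space of haplotype-specific copy numbers
#' \eqn{(c_A, c_B)} with total \eqn{c_A + c_B \le c_{max}}. States are listed
#' in order of increasing total copy number, ties broken by increasing
#' haplotype A copy number, so that the normal diploid state (1, 1) always
#' has (0-based) state id 4. The number of states is
#' \eqn{(c_{max}+1)(c_{max}+2)/2}.
#'
#' @param c_max Maximum total copy number (integer, at least 2).
#' @return An object of class \code{cn_states} with components:
#'   \item{c_max}{the maximum total copy number}
#'   \item{states}{integer matrix with columns \code{cA}, \code{cB}, one row
#'     per state, in canonical order}
#'   \item{n_states}{number of states}
#'   \item{total}{integer vector of per-state totals}
#'   \item{normal}{1-based row index of the normal state (1, 1)}
#'   \item{compat}{list mapping total copy number \code{c} (entry
#'     \code{c + 1}) to the 1-based indices of compatible states}
#' @examples
#' sp <- enumerate_states(4)
#' sp$n_states            # 15
#' sp$states[sp$normal, ] # c(1, 1); 0-based state id 4
#' @export
enumerate_states <- function(c_max) {
  if (length(c_max) != 1L || !is.finite(c_max) || c_max != round(c_max) ||
      c_max < 2) {
    stop("`c_max` must be a single integer >= 2", call. = FALSE)
  }
  c_max <- as.integer(c_max)
  states <- do.call(rbind, lapply(0:c_max, function(tot) {
    cA <- 0:tot
    cbind(cA = cA, cB = tot - cA)
  }))
  storage.mode(states) <- "integer"
  total <- states[, 1L] + states[, 2L]
  compat <- lapply(0:c_max, function(tot) which(total == tot))
  structure(
    list(
      c_max = c_max,
      states = states,
      n_states = nrow(states),
      total = total,
      normal = which(states[, 1L] == 1L & states[, 2L] == 1L),
      compat = compat
    ),
    class = "cn_states"
  )
}

#' Look up the state index of a haplotype-specific copy number
#'
#' @param space A \code{cn_states} object.
#' @param cA,cB Copy numbers on haplotypes A and B (vectorized).
#' @param zero_based If \code{TRUE} (default), return the conventional
#'   0-based state id (normal (1,1) is 4); otherwise the 1-based row index.
#' @return Integer vector of state indices.
#' @export
state_index <- function(space, cA, cB, zero_based = TRUE) {
  stopifnot(inherits(space, "cn_states"))
  if (any(cA < 0 | cB < 0 | cA + cB > space$c_max)) {
    stop("copy-number pair outside the state space", call. = FALSE)
  }
  tot <- cA + cB
  # states with total < tot precede; within a total, cA is the offset
  idx <- tot * (tot + 1L) / 2L + cA + 1L
  as.integer(if (zero_based) idx - 1L else idx)
}

#' States compatible with a total copy number
#'
#' Total copy numbers carry no haplotype phasing, so an observed total
#' \eqn{c} is compatible with the \eqn{c + 1} states
#' \eqn{(0, c), (1, c-1), \ldots, (c, 0)}.
#'
#' @param total_cn Observed total copy number (single integer).
#' @param space A \code{cn_states} object.
#' @return Integer vector of 1-based state row indices.
#' @export
compatible_states <- function(total_cn, space) {
  stopifnot(inherits(space, "cn_states"))
  if (length(total_cn) != 1L || !is.finite(total_cn) ||
      total_cn != round(total_cn) || total_cn < 0 || total_cn > space$c_max) {
    stop("`total_cn` must be an integer in [0, c_max]", call. = FALSE)
  }
  space$compat[[total_cn + 1L]]
}

#' Build the duplication/deletion rate matrix
#'
#' Constructs the generator matrix Q of the continuous-time Markov chain on
#' haplotype-specific copy-number states. A haplotype with at least one copy
#' gains one copy at rate \code{u} (when the resulting total does not exceed
#' \code{c_max}) and loses one copy at rate \code{e}, independently on the
#' two haplotypes; rates are per haplotype per site per year. The zero-copy
#' state (0, 0) is absorbing.
#'
#' @param u Duplication rate per haplotype per site per year (>= 0).
#' @param e Deletion rate per haplotype per site per year (>= 0).
#' @param space A \code{cn_states} object.
#' @param per_copy If \code{TRUE}, scale each haplotype's rates by its copy
#'   number instead of treating the haplotype as a single mutable unit.
#'   Default \code{FALSE}: the rate attaches to the haplotype, not the copy.
#' @return An object of class \code{cn_rate_model} with fields \code{u},
#'   \code{e}, \code{space} and the generator matrix \code{Q}.
#' @export
build_rate_matrix <- function(u, e, space, per_copy = FALSE) {
  stopifnot(inherits(space, "cn_states"))
  if (!is.finite(u) || !is.finite(e) || u < 0 || e < 0) {
    stop("rates `u` and `e` must be finite and non-negative", call. = FALSE)
  }
  S <- space$n_states
  st <- space$states
  Q <- matrix(0, S, S)
  for (i in seq_len(S)) {
    cA <- st[i, 1L]; cB <- st[i, 2L]
    for (h in 1:2) {
      ch <- if (h == 1L) cA else cB
      if (ch < 1L) next
      mult <- if (per_copy) ch else 1L
      # duplication: +1 copy on haplotype h, only within the state space
      if (cA + cB + 1L <= space$c_max) {
        j <- if (h == 1L) state_index(space, cA + 1L, cB, FALSE)
             else state_index(space, cA, cB + 1L, FALSE)
        Q[i, j] <- Q[i, j] + u * mult
      }
      # deletion: -1 copy on haplotype h
      j <- if (h == 1L) state_index(space, cA - 1L, cB, FALSE)
           else state_index(space, cA, cB - 1L, FALSE)
      Q[i, j] <- Q[i, j] + e * mult
    }
  }
  diag(Q) <- -rowSums(Q)
  structure(list(u = u, e = e, space = space, Q = Q,
                 .cache = new.env(parent = emptyenv())),
            class = "cn_rate_model")
}

# Eigen decomposition of Q, computed once per model and cached. P(t) is then
# two matrix products instead of a fresh matrix exponential per branch.
.rate_eigen <- function(model) {
  cache <- model$.cache
  if (!is.null(cache$eig)) return(cache$eig)
  eg <- eigen(model$Q)
  V <- eg$vectors
  if (!is.complex(V)) V <- V + 0i
  Vinv <- tryCatch(solve(V), error = function(err) NULL)
  ok <- FALSE
  if (!is.null(Vinv)) {
    # accept the decomposition only if it reproduces Q accurately
    err <- max(Mod(V %*% diag(eg$values, nrow = length(eg$values)) %*% Vinv -
                     model$Q))
    ok <- is.finite(err) && err < 1e-9 * max(1, max(abs(model$Q)))
  }
  values <- eg$values
  if (!is.complex(values)) values <- values + 0i
  cache$eig <- list(values = values, V = V, Vinv = Vinv, ok = ok)
  cache$eig
}

# Uniformization: P(t) as a Poisson mixture of powers of the stochastic
# matrix M = I + Q/L (L = max exit rate). Unconditionally stable for
# generator matrices; used when the eigendecomposition and the Pade
# exponential both fail their row-sum checks (stiff Q at long t).
.p_uniform <- function(Q, t) {
  S <- nrow(Q)
  lam <- max(-diag(Q))
  if (lam <= 0) return(diag(S))
  M <- diag(S) + Q / lam
  mu <- lam * t
  K <- ceiling(mu + 12 * sqrt(mu) + 20)
  P <- stats::dpois(0, mu) * diag(S)
  Mk <- diag(S)
  for (k in seq_len(K)) {
    Mk <- Mk %*% M
    w <- stats::dpois(k, mu)
    if (w > 0) P <- P + w * Mk
  }
  P / rowSums(P)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from a cached eigendecomposition of Q when it is numerically
#' sound, falling back to a scaling-and-squaring Pade matrix exponential
#' and, for stiff generators where that drifts, to uniformization.
#' Results are cached per distinct branch length.
#'
#' @param model A \code{cn_rate_model}.
#' @param t Branch duration in years (>= 0).
#' @param cache Memoize the result per distinct branch length (default
#'   \code{TRUE}; internal optimizer loops disable it).
#' @return Row-stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t, cache = TRUE) {
  stopifnot(inherits(model, "cn_rate_model"))
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single non-negative number", call. = FALSE)
  }
  S <- model$space$n_states
  if (t == 0) return(diag(S))
  key <- sprintf("t%.12e", t)
  memo <- model$.cache
  if (cache) {
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
  }
  eig <- .rate_eigen(model)
  if (eig$ok) {
    P <- Re(eig$V %*% (exp(eig$values * t) * eig$Vinv))
  } else {
    P <- pracma::expm(model$Q * t)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8) || any(P < -1e-8)) {
    # eigendecomposition too ill-conditioned at this t; recompute robustly
    P <- pracma::expm(model$Q * t)
    rs <- rowSums(P)
    if (any(!is.finite(rs)) || any(abs(rs - 1) > 1e-8) || any(P < -1e-8)) {
      P <- .p_uniform(model$Q, t)
      rs <- rowSums(P)
    }
  }
  if (any(!is.finite(rs)) || any(abs(rs - 1) > 1e-6)) {
    stop("transition matrix rows do not sum to 1; Q may be invalid",
         call. = FALSE)
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  if (cache) memo[[key]] <- P
  P
}
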