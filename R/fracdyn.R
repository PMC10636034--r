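#' Grunwald-Letnikov memory kernel
#'
#' Weights `psi[j] = Gamma(j - alpha) / (Gamma(-alpha) * Gamma(j + 1))` of the
#' fractional difference of order `alpha`: the contribution of the state `j`
#' steps in the past.  Computed by the multiplicative recurrence
#' `psi[j] = psi[j-1] * (j - 1 - alpha) / j`, which equals the Gamma-ratio
#' formula wherever `Gamma(-alpha)` is finite and extends it continuously to
#' integer `alpha` (where the recurrence's zero factor truncates the kernel:
#' `alpha = 1` gives `1, -1, 0, 0, ...`, the memoryless Markov limit).
#'
#' For fractional `alpha` in (0, 1) the weights are negative for `j >= 1` and
#' decay as a power law `|psi[j]| ~ j^{-(1+alpha)}`: long-term memory.
#'
#' @param alpha real fractional exponent (any real; integers handled by the
#'   recurrence limit).
#' @param J horizon; weights are returned for lags `0..J`.
#' @return an object of class `memory_kernel`: list with `alpha`, `J` and
#'   numeric `psi` of length `J + 1` (`psi[1]` is lag 0 and always 1).
#' @examples
#' psi_weights(0.5, 2)$psi  # 1, -0.5, -0.125
#' @export
psi_weights <- function(alpha, J) {
  J <- as.integer(J)
  if (is.na(J) || J < 0L) stop2("J must be >= 0")
  psi <- if (J == 0L) 1 else cumprod(c(1, (seq_len(J) - 1 - alpha) / seq_len(J)))
  structure(list(alpha = alpha, J = J, psi = psi), class = "memory_kernel")
}

#' @export
print.memory_kernel <- function(x, ...) {
  cat(sprintf("memory_kernel: alpha = %g, J = %d\n", x$alpha, x$J))
  invisible(x)
}

# psi values for several nodes at once: N x (J+1) matrix, row i = Psi(alpha_i, 0..J)
psi_matrix <- function(alpha, J) {
  t(vapply(alpha, function(a) psi_weights(a, J)$psi, numeric(J + 1)))
}

#' Fractional-order dynamical network
#'
#' Couples a topology with per-node fractional exponents and (optionally)
#' numeric edge weights, modelling
#' `Delta^alpha x[k+1] = A x[k] + B u[k]` under the Grunwald-Letnikov
#' discretisation.  With every `alpha_i` non-integer the network has
#' long-term power-law memory; `alpha_i = 1` for all nodes recovers the
#' Markov system `x[k+1] = (A + I) x[k] + B u[k]`.
#'
#' @param pattern a [directed_pattern()] (houses the structure of `A`:
#'   arc `(j, i)` means `A[i, j]` free).
#' @param alpha numeric vector of length `n_nodes` (recycled from a scalar).
#' @param weights optional numeric N x N matrix supported exactly on the
#'   pattern's arcs (`weights[i, j] != 0` iff arc `(j, i)`).
#' @return an object of class `fractional_network`.
#' @export
fractional_network <- function(pattern, alpha, weights = NULL) {
  assert_pattern(pattern)
  n <- pattern$n_nodes
  if (length(alpha) == 1L) alpha <- rep(alpha, n)
  if (length(alpha) != n) stop2("alpha must have length n_nodes (or 1)")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == c(n, n))) stop2("weights must be N x N")
    sup <- matrix(FALSE, n, n)
    sup[cbind(pattern$arcs[, 2], pattern$arcs[, 1])] <- TRUE
    if (any(weights[!sup] != 0))
      stop2("weights must be supported exactly on pattern arcs")
    if (any(weights[sup] == 0))
      stop2("weights must be nonzero on every pattern arc")
  }
  structure(list(pattern = pattern, alpha = as.numeric(alpha),
                 weights = weights),
            class = "fractional_network")
}

#' @export
print.fractional_network <- function(x, ...) {
  cat(sprintf(
    "fractional_network: %d nodes, %d arcs, alpha in [%.3g, %.3g]%s\n",
    x$pattern$n_nodes, nrow(x$pattern$arcs), min(x$alpha), max(x$alpha),
    if (is.null(x$weights)) " (no numeric weights)" else ""))
  invisible(x)
}

#' Sample a numeric realization of a structural network
#'
#' Draws nonzero entries for the free parameters of a pattern: arc weights
#' i.i.d. with magnitude uniform on `[0.5, 1.5]` and random sign (bounded
#' away from zero to avoid spurious numeric rank loss), and, when not fixed,
#' per-node exponents `alpha_i` i.i.d. uniform on `[0.2, 0.8]` so the
#' realization is in long-memory mode with heterogeneous exponents.
#'
#' @param x a [directed_pattern()] or a [fractional_network()] (whose fixed
#'   `alpha` is kept).
#' @param seed integer seed.
#' @param alpha optional fixed exponents overriding the sampling.
#' @return a [fractional_network()] with numeric `weights` filled in.
#' @export
sample_realization <- function(x, seed = 0L, alpha = NULL) {
  if (is_directed_pattern(x)) {
    pattern <- x
    fixed_alpha <- alpha
  } else {
    pattern <- x$pattern
    fixed_alpha <- if (is.null(alpha)) x$alpha else alpha
  }
  n <- pattern$n_nodes
  na <- nrow(pattern$arcs)
  vals <- with_seed(seed, {
    w <- (0.5 + runif(na)) * sign(runif(na) - 0.5)
    a <- if (is.null(fixed_alpha)) runif(n, 0.2, 0.8) else fixed_alpha
    list(w = w, a = a)
  })
  weights <- matrix(0, n, n)
  weights[cbind(pattern$arcs[, 2], pattern$arcs[, 1])] <- vals$w
  fractional_network(pattern, vals$a, weights)
}

#' Expanded system matrices of the fractional recursion
#'
#' Rewrites the fractional-order model as the explicit convolution recursion
#' `x[k+1] = sum_{j=0}^{k} A_j x[k-j] + B u[k]` with
#' `A_0 = A - D(alpha, 1)` and `A_j = -D(alpha, j+1)` for `j >= 1`, where
#' `D(alpha, j) = diag(Psi(alpha_i, j))`.  Since `Psi(alpha_i, 1) =
#' -alpha_i`, the instantaneous term is `A_0 = A + diag(alpha)`: the memory
#' introduces nodal dynamics even when `A` has a zero diagonal.
#'
#' @param net a [fractional_network()] with numeric weights (see
#'   [sample_realization()] if absent).
#' @param K horizon; matrices `A_0 .. A_K` are returned.
#' @return list of class `expanded_matrices` with element `A_seq`, a list of
#'   `K + 1` dense N x N matrices.
#' @export
expansion_matrices <- function(net, K) {
  if (!inherits(net, "fractional_network")) stop2("expected fractional_network")
  if (is.null(net$weights))
    stop2("network has no numeric weights; call sample_realization() first")
  K <- as.integer(K)
  if (K < 0L) stop2("K must be >= 0")
  n <- net$pattern$n_nodes
  psi <- psi_matrix(net$alpha, K + 1L)  # n x (K+2), column j+1 = Psi(., j)
  A_seq <- vector("list", K + 1L)
  A_seq[[1L]] <- net$weights - diag(psi[, 2L], n, n)
  if (K >= 1L)
    for (j in seq_len(K))
      A_seq[[j + 1L]] <- diag(-psi[, j + 2L], n, n)
  structure(list(A_seq = A_seq), class = "expanded_matrices")
}

# diagonal B matrix columns for a driven set
input_matrix <- function(n, driven, b_gains = NULL) {
  driven <- as.integer(driven)
  if (is.null(b_gains)) b_gains <- rep(1, length(driven))
  if (length(b_gains) != length(driven))
    stop2("b_gains must match driven in length")
  B <- matrix(0, n, length(driven))
  B[cbind(driven, seq_along(driven))] <- b_gains
  B
}

#' Simulate a fractional-order network trajectory
#'
#' Full-history (non-truncated) evaluation of the convolution recursion
#' `x[k+1] = sum_{j=0}^{k} A_j x[k-j] + B u[k]` with diagonal input matrix
#' `B` supported on the driven nodes.
#'
#' @param net a [fractional_network()] with numeric weights.
#' @param driven integer vector of driven node indices (may be empty).
#' @param b_gains numeric input gains, one per driven node (default 1).
#' @param inputs K x `length(driven)` matrix of inputs `u[0..K-1]` (or `NULL`
#'   for zero input).
#' @param x0 initial state vector (default zero).
#' @param K number of steps.
#' @return object of class `trajectory`: list with `states`
#'   (`(K+1) x N` matrix, row `k+1` is `x[k]`) and `inputs`.
#' @export
simulate_network <- function(net, driven = integer(), b_gains = NULL,
                             inputs = NULL, x0 = NULL, K) {
  K <- as.integer(K)
  if (K < 1L) stop2("K must be >= 1")
  n <- net$pattern$n_nodes
  if (is.null(x0)) x0 <- numeric(n)
  if (length(x0) != n) stop2("x0 must have length N")
  B <- input_matrix(n, driven, b_gains)
  if (length(driven) == 0) {
    inputs <- matrix(0, K, 0)
  } else {
    if (is.null(inputs)) inputs <- matrix(0, K, length(driven))
    inputs <- matrix(inputs, ncol = length(driven))
    if (nrow(inputs) != K) stop2("inputs must have K rows")
  }
  em <- expansion_matrices(net, K - 1L)$A_seq
  states <- matrix(0, K + 1L, n)
  states[1L, ] <- x0
  for (k in seq_len(K)) {  # compute x[k] from x[0..k-1] and u[k-1]
    acc <- numeric(n)
    for (j in 0:(k - 1L))
      acc <- acc + em[[j + 1L]] %*% states[k - j, ]
    if (length(driven) > 0) acc <- acc + B %*% inputs[k, ]
    states[k + 1L, ] <- acc
  }
  colnames(states) <- net$pattern$node_labels
  structure(list(states = states, inputs = inputs, driven = driven),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d steps, %d nodes, %d driven\n",
              nrow(x$states) - 1L, ncol(x$states), length(x$driven)))
  invisible(x)
}

#' T-step reachability matrix of a fractional network
#'
#' The linear map from the stacked inputs `u[0..T-1]` to the final state
#' `x[T]` (with `x[0] = 0`): `x[T] = sum_k G_{T-1-k} B u[k]` where `G_0 = I`
#' and `G_m = sum_{j=0}^{m-1} A_j G_{m-1-j}`.  The system is numerically
#' controllable in `T` steps iff this matrix has full row rank `N`.
#' Columns are ordered by injection time `k = 0, 1, ..., T-1` (earliest
#' first), each block over the driven nodes.
#'
#' @inheritParams simulate_network
#' @param T time-to-control horizon, `T >= 1`.
#' @return numeric `N x (length(driven) * T)` matrix.
#' @export
reachability_matrix <- function(net, driven, T, b_gains = NULL) {
  T <- as.integer(T)
  if (T < 1L) stop2("T must be >= 1")
  n <- net$pattern$n_nodes
  d <- length(driven)
  B <- input_matrix(n, driven, b_gains)
  if (d == 0) return(matrix(0, n, 0))
  em <- expansion_matrices(net, max(0L, T - 2L))$A_seq
  G <- vector("list", T)  # G[[m+1]] = G_m
  G[[1L]] <- diag(n)
  if (T >= 2L)
    for (m in seq_len(T - 1L)) {
      acc <- matrix(0, n, n)
      for (j in 0:(m - 1L))
        acc <- acc + em[[j + 1L]] %*% G[[m - j]]
      G[[m + 1L]] <- acc
    }
  R <- matrix(0, n, d * T)
  for (k in 0:(T - 1L))
    R[, k * d + seq_len(d)] <- G[[T - k]] %*% B
  R
}

# numerical rank with the standard tolerance max(dim) * eps * sigma_max
numeric_rank <- function(M, tol = NULL) {
  if (length(M) == 0) return(0L)
  sv <- svd(M, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol)
}

#' Numeric T-step controllability oracle
#'
#' Probabilistic realization of the generic statement `g-rank = max over
#' realizations of rank`: samples `trials` random numeric realizations of the
#' structure (weights, input gains, and exponents when not fixed) and reports
#' whether any realization's [reachability_matrix()] reaches full rank `N`.
#' Used as the independent oracle for structural-controllability claims.
#'
#' @param x a [directed_pattern()] or [fractional_network()]; a pattern (or a
#'   network without fixed exponents) gets `alpha ~ U(0.2, 0.8)` per trial.
#' @param driven integer vector of driven nodes.
#' @param T horizon.
#' @param trials number of random realizations (default 8; the generic
#'   property holds for almost every realization).
#' @param seed integer seed.
#' @param tol rank tolerance (default: standard singular-value rule).
#' @return logical.
#' @export
is_controllable_numeric <- function(x, driven, T, trials = 8L, seed = 0L,
                                    tol = NULL) {
  pattern <- if (is_directed_pattern(x)) x else x$pattern
  n <- pattern$n_nodes
  if (length(driven) == 0) return(FALSE)
  alpha_fixed <- if (is_directed_pattern(x)) NULL else x$alpha
  for (trial in seq_len(trials)) {
    s <- derive_seed(seed, trial)
    net <- sample_realization(pattern, seed = s, alpha = alpha_fixed)
    gains <- with_seed(derive_seed(s, 1L),
                       (0.5 + runif(length(driven))) *
                         sign(runif(length(driven)) - 0.5))
    R <- reachability_matrix(net, driven, T, b_gains = gains)
    if (numeric_rank(R, tol) == n) return(TRUE)
  }
  FALSE
}

#' Export a trajectory or reachability matrix as CSV
#'
#' @param x a `trajectory` or a numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  m <- if (inherits(x, "trajectory")) x$states else as.matrix(x)
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
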