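# Shared fixtures: small named patterns and random-instance builders.

# 3-node directed chain 1 -> 2 -> 3
p3_chain <- function() directed_pattern(3, rbind(c(1, 2), c(2, 3)))

# star: hub 1 -> leaves 2, 3
star3 <- function() directed_pattern(3, rbind(c(1, 2), c(1, 3)))

# random digraph with arc probability `p`, optional self-loop probability
rand_pattern <- function(n, p = 0.3, loop_p = 0, seed = 1) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  off <- pairs[pairs$from != pairs$to, ]
  keep <- off[runif(nrow(off)) < p, ]
  arcs <- as.matrix(keep)
  if (loop_p > 0) {
    loops <- which(runif(n) < loop_p)
    arcs <- rbind(arcs, cbind(loops, loops))
  }
  directed_pattern(n, arcs)
}

# direct Gamma-formula evaluation of the memory kernel (test oracle only;
# valid for non-integer alpha and moderate J where Gamma stays finite)
psi_gamma <- function(alpha, J) {
  j <- 0:J
  gamma(j - alpha) / (gamma(-alpha) * gamma(j + 1))
}

# numeric Kalman-matrix rank oracle in plain R (independent of the C++ path)
kalman_rank_R <- function(pattern, driven, T, trials = 8, seed = 1) {
  n <- pattern$n_nodes
  if (length(driven) == 0) return(0L)
  best <- 0L
  set.seed(seed)
  for (t in seq_len(trials)) {
    A <- matrix(0, n, n)
    na <- nrow(pattern$arcs)
    A[cbind(pattern$arcs[, 2], pattern$arcs[, 1])] <-
      (0.5 + runif(na)) * sign(runif(na) - 0.5)
    B <- matrix(0, n, length(driven))
    B[cbind(driven, seq_along(driven))] <-
      (0.5 + runif(length(driven))) * sign(runif(length(driven)) - 0.5)
    K <- B
    X <- B
    if (T > 1) for (k in 2:T) {
      X <- A %*% X
      K <- cbind(K, X)
    }
    best <- max(best, qr(K)$rank)
  }
  best
}
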