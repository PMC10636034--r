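test_that("memory kernel matches the Gamma formula and its integer limit", {
  k <- psi_weights(0.5, 2)
  expect_equal(k$psi, c(1, -0.5, -0.125))

  expect_equal(psi_weights(1, 4)$psi, c(1, -1, 0, 0, 0))
  expect_equal(psi_weights(2, 5)$psi, c(1, -2, 1, 0, 0, 0))
  for (a in c(-0.3, 0.17, 0.5, 0.99, 1.7)) {
    expect_equal(psi_weights(a, 0)$psi, 1)
  }

  # recurrence vs direct Gamma evaluation, relative 1e-10
  for (a in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(psi_weights(a, 50)$psi, psi_gamma(a, 50),
                 tolerance = 1e-10)
  }

  # signs and decay for fractional orders
  psi <- psi_weights(0.3, 200)$psi
  expect_true(all(psi[-1] < 0))
  expect_true(all(diff(abs(psi[-1])) < 0))
  # partial sums stay positive and decay toward zero (power-law memory)
  partial <- cumsum(psi)
  expect_true(all(partial > 0))
  expect_lt(partial[201], partial[11])
  expect_lt(partial[201], 0.25)
  expect_error(psi_weights(0.5, -1), "J")
})

test_that("kernel tail decays with log-log slope -(1 + alpha)", {
  for (a in c(0.3, 0.5, 0.7)) {
    psi <- psi_weights(a, 1e4)$psi
    j <- 100:10000
    slope <- coef(lm(log(abs(psi[j + 1])) ~ log(j)))[2]
    expect_lt(abs(slope + 1 + a), 0.05)
  }
})

test_that("expansion matrices follow A0 = A - D(alpha,1), Aj = -D(alpha,j+1)", {
  # Markov limit: alpha = 1 gives A0 = A + I, Aj = 0
  p <- p3_chain()
  net1 <- sample_realization(p, seed = 1, alpha = rep(1, 3))
  em <- expansion_matrices(net1, 3)$A_seq
  expect_equal(em[[1]], net1$weights + diag(3))
  for (j in 2:4) expect_equal(em[[j]], matrix(0, 3, 3))

  # alpha = 0.5 everywhere: A1 = diag(0.125)
  net5 <- sample_realization(p, seed = 1, alpha = rep(0.5, 3))
  em5 <- expansion_matrices(net5, 2)$A_seq
  expect_equal(em5[[2]], diag(0.125, 3))

  # scalar case N=1, A=0 (arcless), alpha=0.5
  s <- fractional_network(directed_pattern(1), 0.5, matrix(0, 1, 1))
  ems <- expansion_matrices(s, 2)$A_seq
  expect_equal(unlist(ems), c(0.5, 0.125, 0.0625))

  expect_error(expansion_matrices(fractional_network(p, 0.5), 2),
               "sample_realization")
})

test_that("simulation satisfies the convolution recursion", {
  s <- fractional_network(directed_pattern(1), 0.5, matrix(0, 1, 1))
  tr <- simulate_network(s, x0 = 1, K = 2)
  expect_equal(as.numeric(tr$states), c(1, 0.5, 0.375))

  # zero input from zero state stays at zero
  p <- rand_pattern(5, 0.4, seed = 2)
  net <- sample_realization(p, seed = 3)
  tr0 <- simulate_network(net, K = 6)
  expect_true(all(tr0$states == 0))

  # LTI limit: alpha = 1 reproduces x[k+1] = (A + I) x[k] + B u[k]
  netL <- sample_realization(p, seed = 3, alpha = rep(1, 5))
  set.seed(4)
  u <- matrix(rnorm(8 * 2), 8, 2)
  x0 <- rnorm(5)
  tr <- simulate_network(netL, driven = c(1, 4), inputs = u, x0 = x0, K = 8)
  B <- matrix(0, 5, 2); B[cbind(c(1, 4), 1:2)] <- 1
  x <- x0
  for (k in 1:8) {
    x <- (netL$weights + diag(5)) %*% x + B %*% u[k, ]
    expect_equal(as.numeric(tr$states[k + 1, ]), as.numeric(x))
  }

  # superposition: response is linear in (x0, inputs)
  netF <- sample_realization(p, seed = 5)
  u1 <- matrix(rnorm(6 * 1), 6, 1); u2 <- matrix(rnorm(6 * 1), 6, 1)
  x1 <- rnorm(5); x2 <- rnorm(5)
  t1 <- simulate_network(netF, 2, inputs = u1, x0 = x1, K = 6)$states
  t2 <- simulate_network(netF, 2, inputs = u2, x0 = x2, K = 6)$states
  t12 <- simulate_network(netF, 2, inputs = 2 * u1 - u2, x0 = 2 * x1 - x2,
                          K = 6)$states
  expect_equal(t12, 2 * t1 - t2)
})

test_that("reachability matrix generalises the Kalman construction", {
  p <- rand_pattern(5, 0.4, seed = 11)
  # T = 1: the map is just B on the driven columns
  net <- sample_realization(p, seed = 1)
  expect_equal(reachability_matrix(net, c(2, 5), 1),
               cbind(c(0, 1, 0, 0, 0), c(0, 0, 0, 0, 1)))

  # alpha = 1: column space equals the Kalman matrix of A + I
  netL <- sample_realization(p, seed = 2, alpha = rep(1, 5))
  R <- reachability_matrix(netL, c(1, 3), 4)
  AI <- netL$weights + diag(5)
  B <- matrix(0, 5, 2); B[cbind(c(1, 3), 1:2)] <- 1
  kal <- cbind(B, AI %*% B, AI %*% AI %*% B, AI %*% AI %*% AI %*% B)
  expect_equal(qr(cbind(R, kal))$rank, qr(kal)$rank)
  expect_equal(qr(R)$rank, qr(kal)$rank)

  # P3 path driven at the head reaches full rank at T = 3
  net3 <- sample_realization(p3_chain(), seed = 3, alpha = rep(1, 3))
  expect_equal(qr(reachability_matrix(net3, 1, 3))$rank, 3)

  # rank monotone in T and in driven-set inclusion
  netF <- sample_realization(p, seed = 4)
  ranks_T <- vapply(1:5, function(T)
    qr(reachability_matrix(netF, c(1, 2), T))$rank, 1L)
  expect_true(all(diff(ranks_T) >= 0))
  r_small <- qr(reachability_matrix(netF, 2, 3))$rank
  r_big <- qr(reachability_matrix(netF, c(1, 2, 4), 3))$rank
  expect_gte(r_big, r_small)
})

test_that("numeric controllability oracle honours trivial boundaries", {
  p <- rand_pattern(4, 0.3, seed = 21)
  expect_true(is_controllable_numeric(p, 1:4, 1, seed = 1))
  expect_false(is_controllable_numeric(p, integer(), 3, seed = 1))

  # star: fractional dynamics controllable from the hub, Markov (alpha=1,
  # no self-loops) is not
  st <- star3()
  expect_true(is_controllable_numeric(st, 1, 3, seed = 2))
  lti <- fractional_network(st, rep(1, 3))
  expect_false(is_controllable_numeric(lti, 1, 3, seed = 2))
})

test_that("weights validation enforces the pattern support", {
  p <- p3_chain()
  w <- matrix(0, 3, 3); w[2, 1] <- 1  # missing arc 2 -> 3
  expect_error(fractional_network(p, 0.5, w), "nonzero on every")
  w[3, 2] <- 1; w[1, 3] <- 5  # extra entry off the pattern
  expect_error(fractional_network(p, 0.5, w), "supported")
})
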