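test_that("selfloop_augment adds every loop and is idempotent", {
  p <- p3_chain()
  a <- selfloop_augment(p)
  expect_equal(nrow(a$arcs), 5L)
  loops <- a$arcs[a$arcs[, 1] == a$arcs[, 2], 1]
  expect_setequal(loops, 1:3)
  expect_identical(selfloop_augment(a)$arcs, a$arcs)
  iso <- selfloop_augment(directed_pattern(4))
  expect_equal(unname(iso$arcs), cbind(1:4, 1:4))
})

test_that("generic rank reproduces the worked chain and star cases", {
  ch <- p3_chain()
  expect_equal(vapply(1:3, function(T) generic_rank(ch, 1, T)$rank, 1L),
               1:3)
  st <- star3()
  expect_equal(generic_rank(st, 1, 2)$rank, 2L)  # dilation caps the rank
  expect_equal(generic_rank(st, 1, 5)$rank, 2L)
  expect_equal(generic_rank(selfloop_augment(st), 1, 3)$rank, 3L)
  expect_equal(generic_rank(st, integer(), 3)$rank, 0L)

  # single driven node on a complete graph with loops: full rank at T = N
  n <- 5
  cg <- selfloop_augment(directed_pattern(
    n, as.matrix(expand.grid(from = 1:n, to = 1:n))))
  expect_equal(generic_rank(cg, 3, n)$rank, n)
})

test_that("generic rank agrees with independent numeric oracles", {
  # R-level qr() oracle, fully independent of the compiled code
  set.seed(99)
  for (case in 1:40) {
    n <- sample(3:6, 1)
    p <- rand_pattern(n, runif(1, 0.15, 0.6), loop_p = runif(1, 0, 0.6),
                      seed = 1000 + case)
    driven <- sort(sample.int(n, sample.int(n, 1)))
    T <- sample.int(n, 1)
    expect_equal(generic_rank(p, driven, T)$rank,
                 kalman_rank_R(p, driven, T, seed = case),
                 info = sprintf("case %d", case))
  }

  # exhaustive sweep on 3 nodes: all 64 loop-free digraphs, all driven
  # subsets, T <= 3, against the packaged numeric oracle
  offdiag <- as.matrix(expand.grid(from = 1:3, to = 1:3))
  offdiag <- offdiag[offdiag[, 1] != offdiag[, 2], ]
  subsets <- lapply(0:7, function(b) which(bitwAnd(b, 2^(0:2)) > 0))
  for (b in 0:63) {
    p <- directed_pattern(3, offdiag[bitwAnd(b, 2^(0:5)) > 0, ,
                                     drop = FALSE])
    for (s in subsets) for (T in 1:3) {
      expect_equal(generic_rank(p, s, T)$rank,
                   generic_rank_numeric(p, s, T, seed = b + T),
                   info = sprintf("pattern %d driven %s T %d", b,
                                  paste(s, collapse = ","), T))
    }
  }
})

test_that("generic rank is monotone in T and driven-set inclusion", {
  for (seed in 1:8) {
    p <- rand_pattern(7, 0.3, loop_p = 0.3, seed = seed)
    driven <- sort(sample(1:7, 3))
    ranks <- vapply(1:7, function(T) generic_rank(p, driven, T)$rank, 1L)
    expect_true(all(diff(ranks) >= 0))
    r2 <- generic_rank(p, driven[1:2], 4)$rank
    r3 <- generic_rank(p, driven, 4)$rank
    expect_gte(r3, r2)
    expect_lte(r3, min(7, 3 * 4))
    # with all self-loops a single input yields at most T
    expect_lte(generic_rank(selfloop_augment(p), driven[1], 4)$rank, 4)
    # Cayley-Hamilton: full rank at some T implies full rank at T = N
    if (any(ranks == 7)) expect_equal(ranks[7], 7L)
  }
})

test_that("structural controllability dispatches on the memory mode", {
  st <- star3()
  expect_true(is_structurally_controllable(st, 1:3, 1))
  expect_true(is_structurally_controllable(st, 1, 3, long_memory = TRUE))
  expect_false(is_structurally_controllable(st, 1, 3, long_memory = FALSE))
  # with self-loops everywhere the flag is irrelevant
  p <- selfloop_augment(rand_pattern(5, 0.3, seed = 31))
  for (T in 1:5) for (d in list(1, c(2, 4), 1:5)) {
    expect_equal(is_structurally_controllable(p, d, T, TRUE),
                 is_structurally_controllable(p, d, T, FALSE))
  }
})

test_that("rank certificates are consistent vertex-disjoint paths", {
  p <- selfloop_augment(star3())
  res <- generic_rank(p, 1, 3, certificate = TRUE)
  expect_equal(res$rank, 3L)
  expect_length(res$paths, 3L)
  ends <- t(vapply(res$paths, function(m) m[nrow(m), ], c(1, 1)))
  expect_equal(sort(ends[, 1]), 1:3)       # distinct final-layer nodes
  expect_true(all(ends[, 2] == 3))         # all paths end at layer T
  # vertex-disjointness across state copies
  copies <- do.call(rbind, res$paths)
  expect_equal(nrow(copies), nrow(unique(copies)))
  # consecutive path steps follow pattern arcs
  arcs_key <- paste(p$arcs[, 1], p$arcs[, 2])
  for (m in res$paths) {
    if (nrow(m) > 1)
      expect_true(all(paste(m[-nrow(m), 1], m[-1, 1]) %in% arcs_key))
  }
})

test_that("time-expanded debug dump has the stated arc count", {
  p <- rand_pattern(6, 0.3, seed = 41)
  d <- c(2, 5)
  for (T in c(1, 3)) {
    te <- time_expanded_edges(p, d, T)
    expect_equal(nrow(te), T * nrow(p$arcs) + T * length(d))
    expect_true(all(te$to_layer - ifelse(is.na(te$from_layer), te$to_layer - 1,
                                         te$from_layer) == 1))
  }
})
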