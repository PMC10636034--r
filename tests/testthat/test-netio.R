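test_that("edge lists read, symmetrise and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a b", "b c"), f)
  p <- read_edgelist(f, directed = TRUE)
  expect_equal(p$n_nodes, 3L)
  expect_equal(unname(p$arcs), cbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(p$node_labels, c("a", "b", "c"))

  writeLines("a b", f)
  pu <- read_edgelist(f, directed = FALSE)
  expect_equal(unname(pu$arcs), cbind(c(1L, 2L), c(2L, 1L)))

  writeLines("a a", f)
  expect_equal(unname(read_edgelist(f)$arcs), cbind(1L, 1L))

  writeLines(c("a b", "malformed_line_here"), f)
  expect_error(read_edgelist(f), "line 2")
  writeLines(c("# only comments"), f)
  expect_error(read_edgelist(f), "no edges")

  # round-trip of an arbitrary pattern through the edge-list format
  p0 <- rand_pattern(12, 0.25, loop_p = 0.3, seed = 7)
  write_edgelist(p0, f)
  p1 <- read_edgelist(f)
  # first-appearance relabeling permutes indices; compare labeled arc sets
  a0 <- paste(p0$node_labels[p0$arcs[, 1]], p0$node_labels[p0$arcs[, 2]])
  a1 <- paste(p1$node_labels[p1$arcs[, 1]], p1$node_labels[p1$arcs[, 2]])
  expect_setequal(a0, a1)
})

test_that("Matrix Market coordinate files read per convention", {
  f <- withr::local_tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "2 1 0.5"), f)
  p <- read_matrix_market(f)
  expect_equal(unname(p$arcs), cbind(1L, 2L))  # entry (2,1) -> arc 1 -> 2

  writeLines(c("%%MatrixMarket matrix coordinate real symmetric",
               "2 2 1", "2 1 1"), f)
  ps <- read_matrix_market(f)
  expect_equal(unname(ps$arcs), cbind(c(1L, 2L), c(2L, 1L)))

  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 2", "2 1 0.0", "1 2 3"), f)
  expect_equal(unname(read_matrix_market(f)$arcs), cbind(2L, 1L))

  writeLines(c("%%MatrixMarket matrix array real general", "2 2",
               "1", "2", "3", "4"), f)
  expect_error(read_matrix_market(f), "unsupported")
})

test_that("Erdos-Renyi generator: exact arc count, no loops, deterministic", {
  p <- generate_erdos_renyi(4, 3, seed = 1)
  expect_equal(nrow(p$arcs), 3L)
  expect_true(all(p$arcs[, 1] != p$arcs[, 2]))
  expect_identical(p$arcs, generate_erdos_renyi(4, 3, seed = 1)$arcs)
  expect_false(identical(p$arcs, generate_erdos_renyi(4, 3, seed = 2)$arcs))
  expect_error(generate_erdos_renyi(4, 13, seed = 1), "0, n")

  p250 <- generate_erdos_renyi(250, 300, seed = 5)  # the 20%-surplus setting
  expect_equal(nrow(p250$arcs), 300L)

  # uniformity over arc sets: all n(n-1) ordered pairs occur across seeds
  seen <- unique(do.call(rbind, lapply(1:200, function(s)
    generate_erdos_renyi(3, 2, seed = s)$arcs)))
  expect_equal(nrow(seen), 6L)
})

test_that("Barabasi-Albert generator: growth-rule arc count, determinism", {
  # n=4, k=1: single-node seed, 3 attachments -> 3 undirected edges
  p <- generate_barabasi_albert(4, 1, seed = 1)
  expect_equal(nrow(p$arcs), 6L)
  expect_true(all(rowSums(as.matrix(pattern_matrix(p)) !=
                            t(as.matrix(pattern_matrix(p)))) == 0))
  for (k in c(2, 5)) {
    pk <- generate_barabasi_albert(30, k, seed = 3)
    expect_equal(nrow(pk$arcs), 2 * (choose(k, 2) + (30 - k) * k))
  }
  expect_identical(generate_barabasi_albert(25, 2, seed = 9)$arcs,
                   generate_barabasi_albert(25, 2, seed = 9)$arcs)
  expect_error(generate_barabasi_albert(4, 4, seed = 1), "k")
})

test_that("Watts-Strogatz generator: lattice limit and edge conservation", {
  p0 <- generate_watts_strogatz(20, 4, p = 0, seed = 1)
  deg <- tabulate(p0$arcs[, 1], 20)
  expect_true(all(deg == 4))  # exact ring lattice, symmetrised
  for (pr in c(0.2, 0.5, 0.8)) {
    pw <- generate_watts_strogatz(20, 4, p = pr, seed = 2)
    expect_equal(nrow(pw$arcs), 20L * 4L)  # rewiring conserves edges
    expect_true(all(pw$arcs[, 1] != pw$arcs[, 2]))
    m <- as.matrix(pattern_matrix(pw))
    expect_true(all(m == t(m)))
  }
  expect_error(generate_watts_strogatz(10, 3, p = 0.1, seed = 1), "even")
})

test_that("source SCCs: partition, source flags, isolated nodes", {
  s <- source_sccs(p3_chain())
  expect_length(s$components, 3L)
  expect_equal(vapply(s$components[s$is_source], min, 1L), 1L)

  p <- directed_pattern(3, rbind(c(1, 2), c(2, 1), c(2, 3)))
  s2 <- source_sccs(p)
  sizes <- sort(vapply(s2$components, length, 1L))
  expect_equal(sizes, c(1L, 2L))
  src <- s2$components[s2$is_source]
  expect_length(src, 1L)
  expect_setequal(src[[1]], c(1L, 2L))

  s3 <- source_sccs(directed_pattern(5))
  expect_length(s3$components, 5L)
  expect_true(all(s3$is_source))

  # property: components partition the node set; in-degree-0 nodes are in
  # source components
  for (seed in 1:5) {
    p <- rand_pattern(9, 0.2, seed = seed)
    dec <- source_sccs(p)
    expect_setequal(unlist(dec$components), 1:9)
    indeg0 <- setdiff(1:9, p$arcs[, 2])
    in_src <- unlist(dec$components[dec$is_source])
    expect_true(all(indeg0 %in% in_src))
  }
})

test_that("shipped example files load", {
  star <- read_edgelist(system.file("extdata", "toy_star.tsv",
                                    package = "fracctrl"))
  expect_equal(star$node_labels, c("hub", "leaf1", "leaf2"))
  expect_equal(nrow(star$arcs), 2L)
  ring <- read_matrix_market(system.file("extdata", "toy_ring8.mtx",
                                         package = "fracctrl"))
  expect_equal(ring$n_nodes, 8L)
  expect_equal(nrow(ring$arcs), 16L)  # symmetric header expanded
})

test_that("generate_network dispatches on config", {
  cfg <- list(family = "er", n = 10, m = 12, seed = 4)
  expect_identical(generate_network(cfg)$arcs,
                   generate_erdos_renyi(10, 12, seed = 4)$arcs)
  cfg <- list(family = "ws", n = 12, p = 0.3, seed = 4)
  expect_equal(nrow(generate_network(cfg)$arcs), 12L * 4L)  # default nb 4
})
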