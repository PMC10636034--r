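#' Directed sparsity pattern of a network
#'
#' A `directed_pattern` stores the zero/nonzero structure of the state matrix
#' of a dynamical network: `n_nodes` state vertices and a set of arcs.  An arc
#' `(j, i)` means that node `j` influences node `i`, i.e. entry `(i, j)` of the
#' structural state matrix is a free (nonzero) parameter and `x_i[k+1]` depends
#' on `x_j[k]`.  This orientation convention is fixed package-wide.
#'
#' Nodes are indexed `1..n_nodes` internally; original labels from input files
#' are preserved in `node_labels`.  Duplicate arcs collapse silently (pattern
#' semantics); self-loops are permitted and meaningful (nodal dynamics).
#'
#' @param n_nodes positive integer, number of nodes.
#' @param arcs two-column integer matrix (`from`, `to`), 1-based node indices.
#'   A zero-row matrix gives an arcless pattern.
#' @param node_labels optional character vector of length `n_nodes`.
#' @return an object of class `directed_pattern` with fields `n_nodes`,
#'   `arcs` (deduplicated, ordered by `(from, to)`) and `node_labels`.
#' @examples
#' p <- directed_pattern(3, rbind(c(1, 2), c(2, 3)))
#' p
#' @export
directed_pattern <- function(n_nodes, arcs = matrix(integer(), 0, 2),
                             node_labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L)
    stop2("n_nodes must be a positive integer")
  arcs <- matrix(as.integer(arcs), ncol = 2)
  if (anyNA(arcs)) stop2("arcs contain NA")
  if (nrow(arcs) > 0 && (min(arcs) < 1L || max(arcs) > n_nodes))
    stop2("arc endpoints must lie in [1, n_nodes]")
  if (nrow(arcs) > 0) {
    key <- (arcs[, 1] - 1) * as.double(n_nodes) + arcs[, 2]
    arcs <- arcs[!duplicated(key), , drop = FALSE]
    ord <- order(arcs[, 1], arcs[, 2])
    arcs <- arcs[ord, , drop = FALSE]
  }
  colnames(arcs) <- c("from", "to")
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != n_nodes)
      stop2("node_labels must have length n_nodes")
  } else {
    node_labels <- as.character(seq_len(n_nodes))
  }
  structure(list(n_nodes = n_nodes, arcs = arcs, node_labels = node_labels),
            class = "directed_pattern")
}

#' @export
print.directed_pattern <- function(x, ...) {
  cat(sprintf("directed_pattern: %d nodes, %d arcs (%d self-loops)\n",
              x$n_nodes, nrow(x$arcs), sum(x$arcs[, 1] == x$arcs[, 2])))
  invisible(x)
}

#' @export
format.directed_pattern <- function(x, ...) {
  sprintf("<directed_pattern %d nodes / %d arcs>", x$n_nodes, nrow(x$arcs))
}

n_arcs <- function(pattern) nrow(pattern$arcs)

is_directed_pattern <- function(x) inherits(x, "directed_pattern")

assert_pattern <- function(x) {
  if (!is_directed_pattern(x)) stop2("expected a directed_pattern")
  x
}

#' Sparse structural adjacency matrix of a pattern
#'
#' Returns the N x N sparse logical matrix `A` with `A[i, j] = TRUE` iff the
#' pattern contains arc `(j, i)` (node `j` influences node `i`).
#'
#' @param pattern a [directed_pattern()].
#' @return a `Matrix::sparseMatrix` logical pattern matrix.
#' @export
pattern_matrix <- function(pattern) {
  assert_pattern(pattern)
  Matrix::sparseMatrix(i = pattern$arcs[, 2], j = pattern$arcs[, 1],
                       x = TRUE, dims = c(pattern$n_nodes, pattern$n_nodes),
                       dimnames = list(pattern$node_labels,
                                       pattern$node_labels))
}

# igraph view of a pattern (arc from -> to as igraph edge from -> to)
pattern_igraph <- function(pattern, directed = TRUE) {
  igraph::graph_from_edgelist(pattern$arcs, directed = TRUE) |>
    (\(g) {
      g <- igraph::add_vertices(g, max(0L, pattern$n_nodes -
                                         igraph::vcount(g)))
      if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
      g
    })()
}

#' Read a directed pattern from a whitespace-separated edge list
#'
#' Each non-comment line holds `source target` separated by spaces or tabs.
#' Lines starting with `#` and blank lines are ignored.  Labels are arbitrary
#' strings and are mapped to node indices in order of first appearance.
#'
#' @param path file path.
#' @param directed if `FALSE`, every edge is symmetrised into two opposing
#'   arcs.
#' @return a [directed_pattern()] with the file's labels preserved.
#' @export
read_edgelist <- function(path, directed = TRUE) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop2("edge list '", path, "' contains no edges")
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad) > 0)
    stop2("malformed edge list line ", keep[bad[1]], " in '", path,
          "': expected 'source target'")
  src <- vapply(toks, `[`, "", 1L)
  dst <- vapply(toks, `[`, "", 2L)
  labels <- unique(c(rbind(src, dst)))
  from <- match(src, labels)
  to <- match(dst, labels)
  arcs <- cbind(from, to)
  if (!directed) arcs <- rbind(arcs, cbind(to, from))
  directed_pattern(length(labels), arcs, node_labels = labels)
}

#' Write a directed pattern as an edge list
#'
#' Inverse of [read_edgelist()]: one `source target` pair per line using the
#' pattern's node labels.
#'
#' @param pattern a [directed_pattern()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(pattern, path) {
  assert_pattern(pattern)
  lab <- pattern$node_labels
  writeLines(paste(lab[pattern$arcs[, 1]], lab[pattern$arcs[, 2]]), path)
  invisible(path)
}

#' Read a directed pattern from a Matrix Market coordinate file
#'
#' Any stored nonzero entry `(i, j)` marks arc `j -> i` (column influences
#' row, matching the package's adjacency convention).  Files with a
#' `symmetric` header are expanded to both arc directions; explicitly stored
#' zeros are dropped.
#'
#' @param path file path to a coordinate-format Matrix Market file.
#' @param directed if `FALSE`, the pattern is symmetrised regardless of the
#'   file header.
#' @return a [directed_pattern()].
#' @export
read_matrix_market <- function(path, directed = TRUE) {
  header <- tolower(readLines(path, n = 1L))
  if (!grepl("^%%matrixmarket\\s+matrix\\s+coordinate", header))
    stop2("unsupported Matrix Market format in '", path,
          "': only 'matrix coordinate' files are readable")
  m <- Matrix::readMM(path)
  if (nrow(m) != ncol(m)) stop2("Matrix Market file must be square")
  m <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  i <- m@i + 1L
  j <- m@j + 1L
  if (methods::.hasSlot(m, "x")) {
    nz <- m@x != 0
    i <- i[nz]
    j <- j[nz]
  }
  arcs <- cbind(from = j, to = i)
  if (!directed) arcs <- rbind(arcs, cbind(from = i, to = j))
  directed_pattern(nrow(m), arcs)
}

#' Erdos-Renyi G(n, m) directed network
#'
#' Draws a network uniformly at random from all directed graphs with `n`
#' nodes and exactly `m` arcs (self-loops excluded).
#'
#' @param n node count.
#' @param m arc count, `0 <= m <= n(n-1)`.
#' @param seed integer seed; the draw is reproducible per seed.
#' @return a [directed_pattern()] with exactly `m` arcs.
#' @export
generate_erdos_renyi <- function(n, m, seed = 0L) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L) stop2("n must be positive")
  if (m < 0L || as.double(m) > as.double(n) * (n - 1))
    stop2("m must lie in [0, n(n-1)]")
  idx <- with_seed(seed, sample.int(n * (n - 1L), m))
  from <- (idx - 1L) %/% (n - 1L) + 1L
  r <- (idx - 1L) %% (n - 1L) + 1L
  to <- r + (r >= from)
  directed_pattern(n, cbind(from, to))
}

#' Barabasi-Albert preferential-attachment network
#'
#' Grows an undirected scale-free graph from a `k`-node seed clique: each new
#' vertex attaches to `k` distinct existing vertices chosen with probability
#' proportional to their current degree (uniform while all degrees are zero).
#' The result is symmetrised into a [directed_pattern()].
#'
#' @param n node count.
#' @param k edges added per new vertex, `1 <= k < n`.
#' @param seed integer seed.
#' @return a [directed_pattern()] with `2 * (choose(k, 2) + (n - k) * k)`
#'   arcs.
#' @export
generate_barabasi_albert <- function(n, k, seed = 0L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop2("k must satisfy 1 <= k < n")
  edges <- with_seed(seed, {
    deg <- numeric(n)
    eu <- integer(0)
    ev <- integer(0)
    if (k >= 2L) {
      seed_pairs <- combn(k, 2L)
      eu <- seed_pairs[1L, ]
      ev <- seed_pairs[2L, ]
      deg[seq_len(k)] <- k - 1
    }
    for (v in seq.int(k + 1L, n)) {
      avail <- seq_len(v - 1L)
      w <- deg[avail]
      targets <- integer(k)
      for (e in seq_len(k)) {
        prob <- if (sum(w) > 0) w else rep(1, length(avail))
        t_i <- avail[sample.int(length(avail), 1L, prob = prob)]
        targets[e] <- t_i
        w[match(t_i, avail)] <- 0
      }
      eu <- c(eu, rep.int(v, k))
      ev <- c(ev, targets)
      deg[targets] <- deg[targets] + 1
      deg[v] <- deg[v] + k
    }
    cbind(eu, ev)
  })
  arcs <- rbind(edges, edges[, 2:1, drop = FALSE])
  directed_pattern(n, arcs)
}

#' Watts-Strogatz small-world network
#'
#' Starts from a ring lattice in which every node is joined to its
#' `neighbors` nearest neighbours (`neighbors / 2` on each side) and rewires
#' each lattice edge independently with probability `p` to a uniformly chosen
#' new endpoint, avoiding self-loops and duplicate edges.  Rewiring moves
#' edges, never adds or removes them.  The undirected result is symmetrised.
#'
#' @param n node count.
#' @param neighbors even lattice degree, `neighbors < n`; defaults to 4.
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a [directed_pattern()] with `n * neighbors` arcs.
#' @export
generate_watts_strogatz <- function(n, neighbors = 4L, p, seed = 0L) {
  n <- as.integer(n)
  neighbors <- as.integer(neighbors)
  if (neighbors %% 2L != 0L) stop2("neighbors must be even")
  if (neighbors < 2L || neighbors >= n) stop2("need 2 <= neighbors < n")
  if (p < 0 || p > 1) stop2("p must lie in [0, 1]")
  half <- neighbors %/% 2L
  edges <- with_seed(seed, {
    # adjacency as a set of undirected keys for O(1) duplicate checks
    key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    eu <- integer(0)
    ev <- integer(0)
    for (d in seq_len(half)) {
      eu <- c(eu, seq_len(n))
      ev <- c(ev, (seq_len(n) + d - 1L) %% n + 1L)
    }
    present <- new.env(hash = TRUE, parent = emptyenv())
    for (e in seq_along(eu)) assign(key(eu[e], ev[e]), TRUE, envir = present)
    deg <- tabulate(c(eu, ev), n)
    for (e in seq_along(eu)) {
      if (runif(1) < p) {
        a <- eu[e]
        if (deg[a] >= n - 1L) next  # saturated node: nothing to rewire to
        repeat {
          b <- sample.int(n, 1L)
          if (b != a && !exists(key(a, b), envir = present)) break
        }
        rm(list = key(eu[e], ev[e]), envir = present)
        assign(key(a, b), TRUE, envir = present)
        deg[ev[e]] <- deg[ev[e]] - 1L
        deg[b] <- deg[b] + 1L
        ev[e] <- b
      }
    }
    cbind(eu, ev)
  })
  arcs <- rbind(edges, edges[, 2:1, drop = FALSE])
  directed_pattern(n, arcs)
}

#' Generate a network from a JSON-style config
#'
#' Dispatches on `family` (`"er"`, `"ba"`, `"ws"`) with the family's
#' parameters, mirroring the serialised generator config
#' `{"family":..., "n":..., ..., "seed":...}`.
#'
#' @param config a named list with `family`, `n`, family parameters
#'   (`m` for ER; `k` for BA; `neighbors`, `p` for WS) and `seed`.
#' @return a [directed_pattern()].
#' @export
generate_network <- function(config) {
  fam <- match.arg(config$family, c("er", "ba", "ws"))
  seed <- if (is.null(config$seed)) 0L else config$seed
  switch(fam,
    er = generate_erdos_renyi(config$n, config$m, seed),
    ba = generate_barabasi_albert(config$n, config$k, seed),
    ws = generate_watts_strogatz(config$n,
                                 if (is.null(config$neighbors)) 4L
                                 else config$neighbors,
                                 config$p, seed))
}

#' Strongly connected components and source components
#'
#' Decomposes the pattern into strongly connected components (SCCs) and flags
#' the *source* components: those with no incoming arc from another component
#' in the condensation.  Every driven-node set must intersect every source
#' SCC, since nodes in a source SCC are reachable only from within it.
#'
#' @param pattern a [directed_pattern()].
#' @return an object of class `scc_decomposition`: list with `components`
#'   (list of increasing integer node vectors), `is_source` (logical per
#'   component) and `membership` (component id per node).
#' @export
source_sccs <- function(pattern) {
  assert_pattern(pattern)
  g <- pattern_igraph(pattern)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  is_source <- rep(TRUE, comp$no)
  if (nrow(pattern$arcs) > 0) {
    cross <- memb[pattern$arcs[, 1]] != memb[pattern$arcs[, 2]]
    is_source[unique(memb[pattern$arcs[cross, 2]])] <- FALSE
  }
  components <- split(seq_len(pattern$n_nodes), memb)
  names(components) <- NULL
  structure(list(components = components, is_source = is_source,
                 membership = as.integer(memb)),
            class = "scc_decomposition")
}

#' @export
print.scc_decomposition <- function(x, ...) {
  cat(sprintf("scc_decomposition: %d components, %d source\n",
              length(x$components), sum(x$is_source)))
  invisible(x)
}

# Smallest node index of each source SCC, in increasing order.
source_scc_representatives <- function(pattern) {
  dec <- source_sccs(pattern)
  reps <- vapply(dec$components[dec$is_source], min, 1L)
  sort(reps)
}
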