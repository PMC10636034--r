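# Sandbox multifractal spectrum of a network.  The sandbox method estimates
# mass exponents from the growth of node counts M_c(r) inside shortest-path
# balls around randomly sampled centers ("sandboxes"), avoiding the NP-hard
# box-covering minimisation.  The width of the resulting Lipschitz-Holder
# spectrum measures structural heterogeneity; its height, the prevalence of
# the dominant structure.

# undirected igraph of the largest connected component, with a warning for
# disconnected inputs
largest_component_graph <- function(pattern) {
  g <- pattern_igraph(pattern, directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("pattern is disconnected; restricting to the largest ",
            "connected component (", max(comp$csize), " of ",
            pattern$n_nodes, " nodes)", call. = FALSE)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}

#' Sandbox ball masses
#'
#' For `n_centers` uniformly sampled centers `c` and each radius `r`,
#' counts `M_c(r)`: the number of nodes within undirected shortest-path
#' distance `r` of `c` (the center included).  Directed patterns are
#' symmetrised for distances; disconnected inputs are restricted to the
#' largest connected component with a warning.
#'
#' @param pattern a [directed_pattern()].
#' @param radii increasing positive integer radii (default
#'   `1..ceiling(diameter / 2)`).
#' @param n_centers number of sampled centers (default 50, capped at the
#'   component size; sampling is without replacement).
#' @param seed integer seed.
#' @return numeric `n_centers x length(radii)` matrix of masses, with
#'   attributes `radii`, `centers`, `component_size` and `diameter`.
#' @export
sandbox_masses <- function(pattern, radii = NULL, n_centers = 50L,
                           seed = 0L) {
  assert_pattern(pattern)
  g <- largest_component_graph(pattern)
  nv <- igraph::vcount(g)
  diam <- igraph::diameter(g, directed = FALSE)
  if (is.null(radii)) radii <- seq_len(max(1L, ceiling(diam / 2)))
  radii <- sort(unique(as.integer(radii)))
  if (min(radii) < 1L || max(radii) > diam)
    stop2("radii must lie within [1, diameter = ", diam, "]")
  n_centers <- min(as.integer(n_centers), nv)
  centers <- with_seed(seed, sort(sample.int(nv, n_centers)))
  dmat <- igraph::distances(g, v = centers)
  M <- vapply(radii, function(r) rowSums(dmat <= r), numeric(n_centers))
  M <- matrix(M, nrow = n_centers,
              dimnames = list(NULL, paste0("r", radii)))
  attr(M, "radii") <- radii
  attr(M, "centers") <- centers
  attr(M, "component_size") <- nv
  attr(M, "diameter") <- diam
  M
}

#' Sandbox multifractal spectrum
#'
#' Estimates the mass exponents `tau(q)` as the least-squares slope of
#' `ln < (M_c(r) / N)^(q-1) >_c` versus `ln(r / d)` over the usable radius
#' range (`d` = component diameter, `N` = component size; radii where the
#' mean relative mass saturates near 1 are excluded from the fit).  The
#' Lipschitz-Holder exponents follow by central differences,
#' `alpha(q) = d tau / d q`, and the spectrum is
#' `f(alpha) = q * alpha(q) - tau(q)`.  Width `alpha_max - alpha_min`
#' measures structural heterogeneity; height is `max f(alpha)`.
#'
#' @inheritParams sandbox_masses
#' @param q_grid moment orders; must avoid a neighbourhood of `q = 1`
#'   (default `-5..5` in steps of 0.5 with the interval `(0.9, 1.1)`
#'   removed).
#' @param saturation radii with mean relative mass above this value are
#'   dropped from the fit (default 0.95).
#' @return object of class `multifractal_spectrum`: list with `q_grid`,
#'   `tau`, `alpha_lh`, `f_alpha`, `width`, `height`, `fit_r2`,
#'   `radii_used`.
#' @export
sandbox_spectrum <- function(pattern, q_grid = NULL, radii = NULL,
                             n_centers = 50L, seed = 0L,
                             saturation = 0.95) {
  if (is.null(q_grid)) {
    q_grid <- seq(-5, 5, by = 0.5)
    q_grid <- q_grid[q_grid <= 0.9 | q_grid >= 1.1]
  }
  q_grid <- sort(unique(q_grid))
  if (any(q_grid > 0.9 & q_grid < 1.1))
    stop2("q_grid must exclude the neighbourhood (0.9, 1.1) of q = 1")
  M <- sandbox_masses(pattern, radii = radii, n_centers = n_centers,
                      seed = seed)
  radii <- attr(M, "radii")
  nv <- attr(M, "component_size")
  d <- attr(M, "diameter")
  rel <- M / nv
  usable <- colMeans(rel) < saturation
  if (sum(usable) < 3L)
    stop2("fewer than 3 usable radii for the sandbox fit; ",
          "the graph's diameter is too small for a spectrum estimate")
  x <- log(radii[usable] / d)
  tau <- numeric(length(q_grid))
  r2 <- numeric(length(q_grid))
  for (i in seq_along(q_grid)) {
    y <- log(colMeans(rel[, usable, drop = FALSE]^(q_grid[i] - 1)))
    fit <- lm(y ~ x)
    tau[i] <- coef(fit)[2]
    r2[i] <- summary(fit)$r.squared
  }
  # alpha = d tau / d q by central differences (one-sided at the ends);
  # the grid gap at q = 1 is handled by the non-uniform spacing
  m <- length(q_grid)
  alpha <- numeric(m)
  alpha[1] <- (tau[2] - tau[1]) / (q_grid[2] - q_grid[1])
  alpha[m] <- (tau[m] - tau[m - 1]) / (q_grid[m] - q_grid[m - 1])
  if (m > 2)
    alpha[2:(m - 1)] <- (tau[3:m] - tau[1:(m - 2)]) /
      (q_grid[3:m] - q_grid[1:(m - 2)])
  f <- q_grid * alpha - tau
  structure(list(q_grid = q_grid, tau = tau, alpha_lh = alpha, f_alpha = f,
                 width = max(alpha) - min(alpha), height = max(f),
                 fit_r2 = r2, radii_used = radii[usable],
                 n_centers = nrow(M), component_size = nv, diameter = d),
            class = "multifractal_spectrum")
}

#' @export
print.multifractal_spectrum <- function(x, ...) {
  cat(sprintf(
    "multifractal_spectrum: width = %.3f, height = %.3f (q in [%g, %g], %d radii)\n",
    x$width, x$height, min(x$q_grid), max(x$q_grid), length(x$radii_used)))
  invisible(x)
}

#' Width and height of a multifractal spectrum
#'
#' Width is the spread of Lipschitz-Holder exponents,
#' `alpha_max - alpha_min`; height is the maximum of `f(alpha)` over the
#' grid (for a concave spectrum this is attained near `q = 0`, where
#' `f(alpha(0)) = -tau(0)` estimates the fractal dimension).
#'
#' @param s a `multifractal_spectrum`.
#' @return named numeric vector `c(width, height)`.
#' @export
width_height <- function(s) {
  if (!inherits(s, "multifractal_spectrum"))
    stop2("expected a multifractal_spectrum")
  c(width = max(s$alpha_lh) - min(s$alpha_lh), height = max(s$f_alpha))
}

#' Export a spectrum as CSV plus JSON summary
#'
#' @param s a `multifractal_spectrum`.
#' @param csv_path CSV output (columns `q`, `tau`, `alpha`, `f`).
#' @param json_path optional JSON output (`{width, height}`).
#' @return `csv_path`, invisibly.
#' @export
write_spectrum_csv <- function(s, csv_path, json_path = NULL) {
  write.csv(data.frame(q = s$q_grid, tau = s$tau, alpha = s$alpha_lh,
                       f = s$f_alpha),
            csv_path, row.names = FALSE)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(list(width = s$width, height = s$height),
                                auto_unbox = TRUE, digits = NA), json_path)
  invisible(csv_path)
}
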