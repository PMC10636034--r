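# Time-to-control sweeps and the comparison metrics between Markov and
# long-term power-law memory dynamics on a fixed topology:
#   n_T        = n_Markov - n_long-term-memory   (driven-node savings)
#   %D         = 100 * n_T / N
#   %ttc       = 100 * T / N
#   % savings  = 100 * n_T / n_Markov            (0 when n_Markov = 0)

#' Default time-to-control grid
#'
#' About `points` evenly spaced integer horizons including 1 and `N`.
#'
#' @param n network size.
#' @param points target number of grid values (default 20).
#' @return increasing integer vector within `1..n`.
#' @export
default_T_grid <- function(n, points = 20L) {
  sort(unique(pmin(n, pmax(1L, round(seq(1L, n, length.out =
                                           min(points, n)))))))
}

#' Driven-node control profile across the time-to-control
#'
#' Runs driven-node selection in both dynamics modes for every horizon in
#' `T_grid` and assembles the comparison metrics.  Deterministic given the
#' method.
#'
#' @param pattern a [directed_pattern()].
#' @param T_grid integer horizons within `1..N` (default:
#'   [default_T_grid()]).
#' @param method selection method passed to [min_driven()].
#' @return object of class `control_profile`: a data frame with columns
#'   `T`, `pct_ttc`, `n_markov`, `n_longmem`, `n_T`, `pct_D`, `pct_savings`,
#'   with attributes `n_nodes` and `method`.
#' @export
control_profile <- function(pattern, T_grid = NULL, method = "auto") {
  assert_pattern(pattern)
  n <- pattern$n_nodes
  if (is.null(T_grid)) T_grid <- default_T_grid(n)
  T_grid <- sort(unique(as.integer(T_grid)))
  if (length(T_grid) == 0) stop2("T_grid must be non-empty")
  if (min(T_grid) < 1L || max(T_grid) > n)
    stop2("T_grid must lie within 1..N")
  nm <- integer(length(T_grid))
  nl <- integer(length(T_grid))
  for (i in seq_along(T_grid)) {
    nm[i] <- min_driven(pattern, T_grid[i], "markov", method)$size
    nl[i] <- min_driven(pattern, T_grid[i], "long_memory", method)$size
  }
  profile_frame(T_grid, nm, nl, n, method)
}

profile_frame <- function(T_grid, n_markov, n_longmem, n, method) {
  n_T <- n_markov - n_longmem
  out <- data.frame(
    T = T_grid,
    pct_ttc = 100 * T_grid / n,
    n_markov = n_markov,
    n_longmem = n_longmem,
    n_T = n_T,
    pct_D = 100 * n_T / n,
    pct_savings = ifelse(n_markov > 0, 100 * n_T / n_markov, 0))
  attr(out, "n_nodes") <- n
  attr(out, "method") <- method
  class(out) <- c("control_profile", "data.frame")
  out
}

#' Ensemble experiment over seeded random networks
#'
#' Generates `reps` independent networks of one family, computes each
#' network's [control_profile()] on a common horizon grid, and averages the
#' metrics at matched `pct_ttc`.  Per-rep seeds are derived from `seed` and
#' recorded so any replicate can be replayed exactly.
#'
#' @param family `"er"`, `"ba"` or `"ws"`.
#' @param n network size.
#' @param params named list of family parameters (`m` for ER; `k` for BA;
#'   `neighbors` and `p` for WS).
#' @param reps ensemble size (default 20).
#' @param seed integer base seed.
#' @param method selection method.
#' @param T_grid optional common horizon grid.
#' @return object of class `ensemble_result`: list with `family`, `n`,
#'   `params`, `reps`, `rep_seeds`, `mean_profile` (a `control_profile` of
#'   means) and `n_T_reps` (reps x grid matrix).
#' @export
ensemble_experiment <- function(family, n, params, reps = 20L, seed = 0L,
                                method = "auto", T_grid = NULL) {
  family <- match.arg(family, c("er", "ba", "ws"))
  if (reps < 1L) stop2("reps must be >= 1")
  if (is.null(T_grid)) T_grid <- default_T_grid(n)
  rep_seeds <- vapply(seq_len(reps), function(k) derive_seed(seed, k), 1L)
  profiles <- lapply(rep_seeds, function(s) {
    cfg <- c(list(family = family, n = n, seed = s), params)
    control_profile(generate_network(cfg), T_grid = T_grid, method = method)
  })
  nm <- rowMeans(vapply(profiles, function(p) as.numeric(p$n_markov),
                        numeric(length(T_grid))) |> matrix(length(T_grid)))
  nl <- rowMeans(vapply(profiles, function(p) as.numeric(p$n_longmem),
                        numeric(length(T_grid))) |> matrix(length(T_grid)))
  n_T_reps <- t(vapply(profiles, function(p) as.numeric(p$n_T),
                       numeric(length(T_grid))))
  mean_profile <- profile_frame(T_grid, nm, nl, n, method)
  structure(list(family = family, n = n, params = params, reps = reps,
                 rep_seeds = rep_seeds, mean_profile = mean_profile,
                 n_T_reps = n_T_reps),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %s n=%d, %d reps, peak mean n_T = %.2f\n",
              x$family, x$n, x$reps, max(x$mean_profile$n_T)))
  invisible(x)
}

#' Control profile and summary for a single (real) network
#'
#' Full [control_profile()] plus headline scalars: the peak percent
#' difference in driven nodes, the time-to-control at which it occurs, the
#' percent savings at 20% of the time-to-control (nearest grid point), and
#' the percent difference at the final horizon.
#'
#' @inheritParams control_profile
#' @return object of class `network_report`: list with `profile` and
#'   `summary` (named list of scalars).
#' @export
real_network_report <- function(pattern, T_grid = NULL, method = "auto") {
  prof <- control_profile(pattern, T_grid = T_grid, method = method)
  ipk <- which.max(prof$pct_D)
  i20 <- which.min(abs(prof$pct_ttc - 20))
  summary <- list(
    peak_pct_D = prof$pct_D[ipk],
    pct_ttc_at_peak = prof$pct_ttc[ipk],
    pct_savings_at_20pct_ttc = prof$pct_savings[i20],
    pct_D_final = prof$pct_D[nrow(prof)])
  structure(list(profile = prof, summary = summary),
            class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "network_report: peak %%D = %.1f at %.1f%% ttc; ",
    "%%savings at ~20%% ttc = %.1f; final %%D = %.1f\n"),
    s$peak_pct_D, s$pct_ttc_at_peak, s$pct_savings_at_20pct_ttc,
    s$pct_D_final))
  invisible(x)
}

#' Write / read a control profile as CSV
#'
#' Round-trips exactly: metric columns are re-derived from the integer
#' counts on read.
#'
#' @param profile a `control_profile`.
#' @param path CSV file path.
#' @return `path` (write) or a `control_profile` (read).
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  attr(df, "n_nodes") <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @param n_nodes network size of the stored profile (defaults to the
#'   largest `T` in the file, valid whenever the grid includes `T = N`).
#' @export
read_profile_csv <- function(path, n_nodes = NULL) {
  df <- read.csv(path)
  need <- c("T", "n_markov", "n_longmem")
  if (!all(need %in% names(df)))
    stop2("profile CSV must contain columns T, n_markov, n_longmem")
  if (is.null(n_nodes)) {
    n_nodes <- if ("pct_ttc" %in% names(df))
      as.integer(round(100 * df$T[1] / df$pct_ttc[1]))
    else max(df$T)
  }
  profile_frame(as.integer(df$T), df$n_markov, df$n_longmem, n_nodes,
                method = "csv")
}
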