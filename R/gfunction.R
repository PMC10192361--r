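.gTrajectoryValues <- function(sites, L) {
  n <- length(sites)
  G <- seq_len(n) / n - sites / L
  list(G = G, dG = diff(c(0, G)))
}

# max over 0 <= j <= k <= n of G_k - G_j, with G_0 = 0 at virtual site 0
.gStatistic <- function(G) {
  g0 <- c(0, G)
  max(g0 - cummin(g0))
}

#' Compute the G-function trajectory of event positions
#'
#' G_j = j/n - site_j/L for the j-th of n sorted events (site = 1-based
#' alignment column, i.e. 0-based position + 1), the difference between the
#' relative rank of an event and its relative position along the alignment.
#' dG_j = G_j - G_{j-1} with G_0 = 0; runs of positive dG mark stretches of
#' events more tightly packed than the uniform expectation.
#'
#' @param x sorted, distinct 0-based event positions in \code{[0, L)}.
#' @param L alignment length in columns.
#' @return a \code{GTrajectory} with G and dG filled (no test fields).
#' @examples
#' gFunction(c(9, 10, 11), L = 100)
#' @export
gFunction <- function(x, L) {
  x <- as.integer(x)
  L <- as.integer(L)
  n <- length(x)
  if (n == 0L) stop("n = 0: at least one event position is required")
  if (n > L) stop("more events than alignment columns (n > L)")
  if (any(x < 0L) || any(x >= L)) stop("positions must lie in [0, L)")
  if (n > 1L && any(diff(x) <= 0L))
    stop("positions must be sorted and free of duplicates")
  tv <- .gTrajectoryValues(x + 1L, L)
  new("GTrajectory", L = L, n = n, x = x, G = tv$G, dG = tv$dG,
      statistic = numeric(0), pGlobal = numeric(0), nullQ95 = numeric(0),
      B = integer(0), stretches = .emptyStretches(), dGPValues = numeric(0))
}

.emptyStretches <- function() {
  data.frame(start = integer(0), end = integer(0), excess = numeric(0))
}

# Vectorised batch of null statistics: each row of `sites` holds n sorted
# distinct 1-based sites.  Returns max-rise statistic and max single-gap dG
# per row.
.nullStatsFromSites <- function(sites, L) {
  n <- ncol(sites)
  B <- nrow(sites)
  G <- sweep(sites / L, 2L, seq_len(n) / n, function(a, b) b - a)
  runMin <- rep(0, B)       # cummin of (G_0=0, G_1, ..., G_{k-1})
  stat <- rep(0, B)
  maxdg <- rep(-Inf, B)
  prev <- rep(0, B)
  for (k in seq_len(n)) {
    gk <- G[, k]
    stat <- pmax(stat, gk - runMin)
    maxdg <- pmax(maxdg, gk - prev)
    runMin <- pmin(runMin, gk)
    prev <- gk
  }
  list(stat = stat, maxdg = maxdg)
}

# Draw `m` rows of n distinct sorted sites from 1..L.  Vectorised rejection
# sampling when duplicates are rare, per-row sample.int otherwise.
.drawSortedSites <- function(m, n, L) {
  if (n == 1L) return(matrix(sample.int(L, m, replace = TRUE), ncol = 1L))
  expDup <- n * (n - 1) / (2 * L)
  if (expDup < 0.5) {
    x <- matrix(sample.int(L, m * n, replace = TRUE), nrow = m)
    x <- matrix(x[order(row(x), x)], nrow = m, byrow = TRUE)
    repeat {
      bad <- which(rowSums(x[, -1L, drop = FALSE] ==
                             x[, -n, drop = FALSE]) > 0)
      if (!length(bad)) break
      r <- matrix(sample.int(L, length(bad) * n, replace = TRUE),
                  nrow = length(bad))
      r <- matrix(r[order(row(r), r)], nrow = length(bad), byrow = TRUE)
      x[bad, ] <- r
    }
    x
  } else {
    t(vapply(seq_len(m), function(i) sort(sample.int(L, n)), integer(n)))
  }
}

#' Monte Carlo null distribution of the global G statistic
#'
#' Each replicate draws n distinct sites uniformly without replacement from
#' the L alignment columns and records the global statistic (maximal rise of
#' G over any event interval, including from the virtual origin G_0 = 0).
#'
#' @param n number of events.
#' @param L alignment length.
#' @param B replicates (the reference default is 100,000).
#' @param seed optional RNG seed for reproducibility.
#' @param chunk replicates per vectorised batch (memory knob).
#' @return numeric vector of B null statistics, with the per-replicate
#'   maximal single-gap dG attached as attribute \code{"maxdG"}.
#' @export
monteCarloNull <- function(n, L, B = 100000L, seed = NULL, chunk = 20000L) {
  if (n < 1L || n > L) stop("require 1 <= n <= L")
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stat <- numeric(B)
  maxdg <- numeric(B)
  done <- 0L
  while (done < B) {
    m <- min(chunk, B - done)
    sites <- .drawSortedSites(m, n, L)
    ns <- .nullStatsFromSites(sites, L)
    stat[(done + 1L):(done + m)] <- ns$stat
    maxdg[(done + 1L):(done + m)] <- ns$maxdg
    done <- done + m
  }
  attr(stat, "maxdG") <- maxdg
  stat
}

#' Exhaustive null distribution of the global G statistic
#'
#' Enumerates every n-subset of the L sites (all \code{choose(L, n)}
#' configurations) and returns the exact null distribution of the global
#' statistic.  Intended for small problems; guarded by \code{maxConfigs}.
#'
#' @param n,L as in \code{\link{monteCarloNull}}.
#' @param maxConfigs refuse enumeration beyond this many configurations.
#' @return numeric vector of \code{choose(L, n)} statistics with attribute
#'   \code{"maxdG"}.
#' @export
exhaustiveNull <- function(n, L, maxConfigs = 2e5) {
  if (n < 1L || n > L) stop("require 1 <= n <= L")
  nc <- choose(L, n)
  if (nc > maxConfigs)
    stop(sprintf("choose(%d, %d) = %g exceeds maxConfigs", L, n, nc))
  sites <- t(utils::combn(L, n))
  ns <- .nullStatsFromSites(sites, L)
  stat <- ns$stat
  attr(stat, "maxdG") <- ns$maxdg
  stat
}

.findStretches <- function(sites, G, nullQ95, pGlobal, alpha) {
  n <- length(G)
  g0 <- c(0, G)
  sites0 <- c(0L, sites)
  # all (j, k) with 0 <= j < k <= n and their G-excess
  jk <- which(upper.tri(matrix(0, n + 1L, n + 1L)), arr.ind = TRUE)
  exc <- g0[jk[, 2L]] - g0[jk[, 1L]]
  o <- order(exc, decreasing = TRUE)
  accepted <- .emptyStretches()
  for (idx in o) {
    e <- exc[idx]
    j <- jk[idx, 1L] - 1L   # event rank j (0-based, virtual origin = 0)
    k <- jk[idx, 2L] - 1L
    start <- sites0[j + 1L] + 1L
    end <- sites0[k + 1L]
    first <- nrow(accepted) == 0L
    if (first && pGlobal > alpha) break
    if (!first && e <= nullQ95) break
    overlaps <- nrow(accepted) > 0L &&
      any(start <= accepted$end & end >= accepted$start)
    if (!overlaps)
      accepted <- rbind(accepted,
                        data.frame(start = start, end = end, excess = e))
  }
  accepted[order(accepted$start), , drop = FALSE]
}

#' G-function test for non-random event accumulation
#'
#' Computes the trajectory, the observed global statistic, a Monte Carlo
#' (or exhaustive) null, the add-one p-value
#' \code{(1 + #\{null >= obs\}) / (1 + B)}, and significant stretches: the
#' event interval achieving the maximal rise of G is reported whenever
#' \code{pGlobal <= alpha}, then further non-overlapping intervals greedily
#' while their G-excess exceeds the null 95th percentile.  Per-gap dG
#' p-values against the null maximal single-gap dG are attached for
#' transparency.
#'
#' @param x sorted, distinct 0-based event positions.
#' @param L alignment length.
#' @param B Monte Carlo replicates (default 100,000).
#' @param seed optional RNG seed.
#' @param alpha significance level for stretch reporting (default 0.05).
#' @param exact use exhaustive enumeration instead of Monte Carlo (small
#'   problems only).
#' @return a \code{GTrajectory} with test fields filled; stretches are
#'   1-based inclusive site intervals.
#' @export
gTest <- function(x, L, B = 100000L, seed = NULL, alpha = 0.05,
                  exact = FALSE) {
  traj <- gFunction(x, L)
  obs <- .gStatistic(traj@G)
  null <- if (exact) exhaustiveNull(traj@n, L) else
    monteCarloNull(traj@n, L, B = B, seed = seed)
  nB <- length(null)
  p <- (1 + sum(null >= obs - 1e-12)) / (1 + nB)
  q95 <- unname(stats::quantile(null, 0.95))
  maxdg <- attr(null, "maxdG")
  dgp <- vapply(traj@dG, function(d)
    (1 + sum(maxdg >= d - 1e-12)) / (1 + nB), numeric(1))
  traj@statistic <- obs
  traj@pGlobal <- p
  traj@nullQ95 <- q95
  traj@B <- as.integer(nB)
  traj@dGPValues <- dgp
  traj@stretches <- .findStretches(traj@x + 1L, traj@G, q95, p, alpha)
  validObject(traj)
  traj
}

#' Export a GTrajectory as plain tables
#'
#' @param traj a \code{GTrajectory}.
#' @return list with \code{trajectory} (data.frame j, site, G, dG, dG_p) and
#'   \code{summary} (list n, L, statistic, p_global, null_q95, stretches) --
#'   the cumulative-G curve and test summary in serialisable form.
#' @export
gTrajectoryTables <- function(traj) {
  tr <- data.frame(j = seq_len(traj@n), site = traj@x + 1L,
                   G = traj@G, dG = traj@dG)
  if (length(traj@dGPValues)) tr$dG_p <- traj@dGPValues
  list(trajectory = tr,
       summary = list(n = traj@n, L = traj@L,
                      statistic = if (length(traj@statistic))
                        traj@statistic else NA_real_,
                      p_global = if (length(traj@pGlobal))
                        traj@pGlobal else NA_real_,
                      null_q95 = if (length(traj@nullQ95))
                        traj@nullQ95 else NA_real_,
                      stretches = traj@stretches))
}
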