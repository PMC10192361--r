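#' Sliding event (Se) scores
#'
#' Sums a binary event channel in a window of \code{halfWindow} positions
#' up- and downstream of each position (default 5, an 11-wide window),
#' truncating the window at the profile edges so every position keeps a
#' score.  When given an \code{EventVector} the channel is first projected
#' onto the reference/TSS coordinate grid (one value per reference
#' position), matching the per-nucleotide definition of Se.
#'
#' @param events an \code{EventVector}, or a plain binary vector (then
#'   positions default to 0-based indices).
#' @param channel which channel of an \code{EventVector} to score.
#' @param halfWindow window half-width in positions (>= 0).
#' @param geneId identifier carried on the profile (defaults to the
#'   EventVector's).
#' @return an \code{SeProfile}.
#' @export
slidingEventScore <- function(events, channel = c("all", "indel", "base"),
                              halfWindow = 5L, geneId = NULL) {
  channel <- match.arg(channel)
  if (halfWindow < 0L) stop("halfWindow must be >= 0")
  if (is(events, "EventVector")) {
    pr <- projectToReference(events, channel)
    v <- pr$events
    pos <- pr$positions
    if (is.null(geneId)) geneId <- events@geneId
  } else {
    v <- as.integer(events)
    if (any(!(v %in% c(0L, 1L)))) stop("channel must be binary 0/1")
    pos <- seq_along(v) - 1L
    if (is.null(geneId)) geneId <- NA_character_
  }
  n <- length(v)
  if (n == 0L) stop("empty channel")
  cs <- c(0L, cumsum(v))
  i <- seq_len(n)
  hi <- pmin(n, i + halfWindow)
  lo <- pmax(1L, i - halfWindow)
  se <- as.numeric(cs[hi + 1L] - cs[lo])
  new("SeProfile", geneId = geneId, channel = channel,
      positions = as.integer(pos), se = se)
}

.windowGrid <- function(window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing (start, end) pair, half-open")
  as.integer(seq.int(window[1], window[2] - 1L))
}

#' Restrict an Se profile to the TATA-distal promoter window
#'
#' Returns the Se values over the half-open offset window (default
#' \code{[-380, -30)}, the 350-nucleotide region upstream of the
#' approximated TATA box), in offset order.
#'
#' @param profile an \code{SeProfile} (TSS-anchored).
#' @param window half-open \code{c(start, end)} offset interval.
#' @return numeric vector of length \code{diff(window)}.
#' @export
promoterWindow <- function(profile, window = c(-380L, -30L)) {
  grid <- .windowGrid(window)
  idx <- match(grid, sePositions(profile))
  if (anyNA(idx))
    stop(sprintf(
      "coverage error: profile %s does not cover window [%d, %d) (missing %d positions)",
      profile@geneId, window[1], window[2], sum(is.na(idx))))
  seScores(profile)[idx]
}

#' Average control Se score (Se^C)
#'
#' Arithmetic mean of all control Se values pooled across genes and
#' positions within the promoter window.
#'
#' @param controlProfiles list of \code{SeProfile}s of control genes.
#' @param window half-open offset window.
#' @return a single number, Se^C.
#' @export
controlThreshold <- function(controlProfiles, window = c(-380L, -30L)) {
  if (length(controlProfiles) == 0L) stop("no control profiles supplied")
  mean(unlist(lapply(controlProfiles, promoterWindow, window = window)))
}

#' The d divergence statistic
#'
#' Percentage of window Se scores strictly greater than the control average
#' Se^C: \code{d = 100 * #\{Se > SeC\} / N}.  Ties count as not-above.
#'
#' @param windowValues Se scores in the promoter window (possibly pooled
#'   across a group's genes).
#' @param seC the control threshold Se^C.
#' @return list with \code{d}, \code{nAbove} and \code{N}.
#' @export
dStatistic <- function(windowValues, seC) {
  N <- length(windowValues)
  if (N == 0L) stop("N = 0: no window values")
  nAbove <- sum(windowValues > seC)
  list(d = 100 * nAbove / N, nAbove = as.integer(nAbove), N = as.integer(N))
}

#' Chi-squared contrast of a group's d against the control score
#'
#' One-degree-of-freedom goodness-of-fit of the observed (above, not-above)
#' counts against the expectation under the control proportion
#' \code{controlD}/100, with Bonferroni adjustment over
#' \code{mComparisons} tests.
#'
#' @param nAbove,N observed count above threshold and window size.
#' @param controlD control percentage in (0, 100).
#' @param mComparisons Bonferroni family size (default 1).
#' @return one-row data.frame: nAbove, N, d, chi2, p, pAdj.
#' @export
chiSquaredVsControl <- function(nAbove, N, controlD, mComparisons = 1L) {
  if (N < 1L) stop("N must be >= 1")
  if (nAbove < 0L || nAbove > N) stop("nAbove must lie in [0, N]")
  if (controlD <= 0 || controlD >= 100)
    stop("degenerate-expectation error: control d of ", controlD,
         "% leaves an expected cell of zero")
  e1 <- N * controlD / 100
  e0 <- N - e1
  chi2 <- (nAbove - e1)^2 / e1 + ((N - nAbove) - e0)^2 / e0
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  data.frame(nAbove = as.integer(nAbove), N = as.integer(N),
             d = 100 * nAbove / N, chi2 = chi2, p = p,
             pAdj = min(1, p * mComparisons))
}

#' Group-averaged Se heatmap matrix
#'
#' One row per group, one column per TSS offset over the anchor window;
#' each cell is the mean Se across the group's genes at that offset.
#'
#' @param profiles list of \code{SeProfile}s (one channel).
#' @param groups group label per profile.
#' @param window half-open offset window (default \code{[-1000, 1000)}).
#' @return numeric matrix, rows = groups, columns = offsets.
#' @export
heatmapMatrix <- function(profiles, groups, window = c(-1000L, 1000L)) {
  stopifnot(length(profiles) == length(groups))
  grid <- .windowGrid(window)
  labs <- unique(as.character(groups))
  out <- matrix(NA_real_, nrow = length(labs), ncol = length(grid),
                dimnames = list(labs, as.character(grid)))
  for (g in labs) {
    sub <- profiles[as.character(groups) == g]
    if (!length(sub)) stop("group with no profile: ", g)
    vals <- vapply(sub, function(p) {
      idx <- match(grid, sePositions(p))
      seScores(p)[idx]          # NA where a gene does not cover the grid
    }, numeric(length(grid)))
    out[g, ] <- rowMeans(matrix(vals, ncol = length(sub)), na.rm = TRUE)
  }
  out
}

#' Region statistics: d per group with chi-squared contrasts vs control
#'
#' Pools window Se values within each group (default), computes Se^C from
#' the control group, each group's d, and the chi-squared contrast of every
#' non-control group against the control's own d.  With
#' \code{perGene = TRUE} the reported d is instead the mean of per-gene d
#' values (the above/not-above counts for the chi-squared test stay pooled).
#'
#' @param profiles list of \code{SeProfile}s (one channel).
#' @param groups group label per profile.
#' @param controlGroup label of the control group.
#' @param window half-open promoter window.
#' @param mComparisons Bonferroni family size; defaults to the number of
#'   non-control groups.
#' @param perGene report mean per-gene d instead of pooled d.
#' @return data.frame, one row per group (control row has NA chi2/p).
#' @export
regionStats <- function(profiles, groups, controlGroup,
                        window = c(-380L, -30L), mComparisons = NULL,
                        perGene = FALSE) {
  groups <- as.character(groups)
  stopifnot(length(profiles) == length(groups))
  if (!controlGroup %in% groups)
    stop("control group '", controlGroup, "' has no profiles")
  labs <- unique(groups)
  if (is.null(mComparisons)) mComparisons <- length(labs) - 1L
  ctl <- profiles[groups == controlGroup]
  seC <- controlThreshold(ctl, window)
  ctlStat <- dStatistic(unlist(lapply(ctl, promoterWindow, window)), seC)
  rows <- lapply(labs, function(g) {
    sub <- profiles[groups == g]
    vals <- lapply(sub, promoterWindow, window)
    pooled <- dStatistic(unlist(vals), seC)
    dRep <- if (perGene)
      mean(vapply(vals, function(v) dStatistic(v, seC)$d, numeric(1)))
    else pooled$d
    if (g == controlGroup) {
      data.frame(group = g, nGenes = length(sub), nAbove = pooled$nAbove,
                 N = pooled$N, d = dRep, chi2 = NA_real_, p = NA_real_,
                 pAdj = NA_real_)
    } else {
      cs <- chiSquaredVsControl(pooled$nAbove, pooled$N, ctlStat$d,
                                mComparisons)
      data.frame(group = g, nGenes = length(sub), nAbove = cs$nAbove,
                 N = cs$N, d = dRep, chi2 = cs$chi2, p = cs$p,
                 pAdj = cs$pAdj)
    }
  })
  res <- do.call(rbind, rows)
  attr(res, "seC") <- seC
  res
}
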