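#' Read a per-base conservation track
#'
#' Reads bedGraph or wiggle (fixed/variable step) scores into a
#' \code{GRanges} with a \code{score} column.  bedGraph intervals are
#' half-open 0-based on disk and become 1-based closed ranges in the
#' returned object (the usual GRanges convention); annotation TSS
#' coordinates used elsewhere in this package stay 0-based and are
#' converted internally.
#'
#' @param path path to a \code{.bedgraph}/\code{.bg} or \code{.wig} file.
#' @param format \code{"auto"} (by extension), \code{"bedGraph"} or
#'   \code{"wig"}.
#' @return \code{GRanges} with numeric \code{score}.
#' @export
readScores <- function(path, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("score file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bedgraph = "bedGraph", bg = "bedGraph",
                     wig = "wig",
                     stop("cannot infer track format from extension '.",
                          ext, "'"))
  }
  tryCatch(rtracklayer::import(path, format = format),
           error = function(e)
             stop("parse error in ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

#' Write a conservation track as bedGraph
#'
#' @param track \code{GRanges} with a \code{score} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

# Expand a scored GRanges to one row per base: contig, 0-based pos, score.
.trackPerBase <- function(track) {
  w <- GenomicRanges::width(track)
  data.frame(
    contig = rep(as.character(GenomicRanges::seqnames(track)), w),
    pos = unlist(lapply(seq_along(track), function(i)
      seq.int(GenomicRanges::start(track)[i] - 1L,
              length.out = GenomicRanges::width(track)[i]))),
    score = rep(track$score, w))
}

.checkAnnotations <- function(annotations) {
  need <- c("gene_id", "contig", "tss", "strand", "group")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  if (any(!annotations$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(annotations$tss < 0)) stop("tss must be >= 0")
  annotations
}

#' Anchor conservation scores to gene TSSs
#'
#' Per gene, extracts the 1300 per-base scores covering offsets -1000 to
#' +299 relative to the TSS on the gene's own strand (minus-strand genes
#' read genome coordinates descending: offset o sits at genome position
#' tss - o).  Genes with any missing position in the window are omitted
#' with a message.
#'
#' @param track \code{GRanges} conservation track (see
#'   \code{\link{readScores}}).
#' @param annotations data.frame with columns \code{gene_id, contig, tss,
#'   strand, group}; \code{tss} is the 0-based genome coordinate of the
#'   first transcribed base.
#' @param window half-open offset interval, default \code{c(-1000, 300)}
#'   giving 1300 positions.
#' @return \code{SummarizedExperiment}: assay \code{"score"} with one row
#'   per offset and one column per retained gene; \code{rowData$offset},
#'   \code{colData} carries gene_id, group, strand.
#' @export
anchorScoresToTSS <- function(track, annotations,
                              window = c(-1000L, 300L)) {
  .checkAnnotations(annotations)
  offs <- .windowGrid(window)
  pb <- .trackPerBase(track)
  byContig <- split(pb, pb$contig)
  cols <- list()
  keep <- logical(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    cp <- byContig[[as.character(a$contig)]]
    pos <- if (a$strand == "+") a$tss + offs else a$tss - offs
    idx <- if (is.null(cp)) rep(NA_integer_, length(offs)) else
      match(pos, cp$pos)
    if (anyNA(idx)) {
      message("anchorScoresToTSS: omitting ", a$gene_id, " (",
              sum(is.na(idx)), " positions without data)")
      next
    }
    keep[i] <- TRUE
    cols[[a$gene_id]] <- cp$score[idx]
  }
  if (!length(cols)) stop("no gene covers the full window")
  assay <- do.call(cbind, cols)
  rownames(assay) <- as.character(offs)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(score = assay),
    rowData = S4Vectors::DataFrame(offset = offs),
    colData = S4Vectors::DataFrame(annotations[keep, , drop = FALSE],
                                   row.names = annotations$gene_id[keep]))
}

#' Combine TSS-anchored score cohorts column-wise
#'
#' Binds two or more anchored score containers (same offset grid) into one,
#' keeping per-gene group labels -- a thin wrapper over the Bioconductor
#' \code{cbind} generic.
#'
#' @param ... \code{SummarizedExperiment}s sharing the offset grid.
#' @return a single \code{SummarizedExperiment}.
#' @importFrom BiocGenerics cbind
#' @export
combineProfiles <- function(...) {
  do.call(BiocGenerics::cbind, list(...))
}

.seOffsets <- function(se) SummarizedExperiment::rowData(se)$offset

.seGroups <- function(se)
  as.character(SummarizedExperiment::colData(se)$group)

#' Group mean conservation profiles
#'
#' Arithmetic mean score per TSS offset within each group.
#'
#' @param se \code{SummarizedExperiment} from
#'   \code{\link{anchorScoresToTSS}} or
#'   \code{\link{simulateConservationTracks}}.
#' @return matrix, rows = offsets, columns = groups.
#' @export
groupMeanProfile <- function(se) {
  groups <- .seGroups(se)
  labs <- unique(groups)
  m <- SummarizedExperiment::assay(se, "score")
  out <- vapply(labs, function(g) {
    sub <- m[, groups == g, drop = FALSE]
    if (!ncol(sub)) stop("empty group: ", g)
    rowMeans(sub)
  }, numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}

#' Per-gene promoter-window mean scores
#'
#' @param se the anchored score container.
#' @param group optional group label filter.
#' @param window half-open offset window, default \code{[-380, -30)}.
#' @return named numeric vector of per-gene means over the window.
#' @export
promoterWindowMeans <- function(se, group = NULL,
                                window = c(-380L, -30L)) {
  offs <- .seOffsets(se)
  grid <- .windowGrid(window)
  idx <- match(grid, offs)
  if (anyNA(idx)) stop("coverage error: window not inside the anchor span")
  m <- SummarizedExperiment::assay(se, "score")
  if (!is.null(group)) m <- m[, .seGroups(se) == group, drop = FALSE]
  if (!ncol(m)) stop("no genes selected")
  colMeans(m[idx, , drop = FALSE])
}

#' Pooled promoter-window scores of a group
#'
#' All per-base scores of the group's genes inside the window, pooled.
#'
#' @inheritParams promoterWindowMeans
#' @return numeric vector of length 350 * (genes in group) by default.
#' @export
promoterScores <- function(se, group = NULL, window = c(-380L, -30L)) {
  offs <- .seOffsets(se)
  grid <- .windowGrid(window)
  idx <- match(grid, offs)
  if (anyNA(idx)) stop("coverage error: window not inside the anchor span")
  m <- SummarizedExperiment::assay(se, "score")
  if (!is.null(group)) m <- m[, .seGroups(se) == group, drop = FALSE]
  if (!ncol(m)) stop("no genes selected")
  as.numeric(m[idx, , drop = FALSE])
}

#' Unpaired t test of promoter conservation between two groups
#'
#' Per gene, the mean score over the promoter window; the two per-gene mean
#' collections are compared with an unpaired t test (Student by default).
#'
#' @param se the anchored score container.
#' @param groupA,groupB group labels to compare.
#' @param window half-open offset window.
#' @param variant \code{"student"} or \code{"welch"}.
#' @return list: \code{meanA}, \code{meanB}, \code{tStatistic},
#'   \code{pValue}, \code{nA}, \code{nB}.
#' @export
promoterMeanTTest <- function(se, groupA, groupB,
                              window = c(-380L, -30L),
                              variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- promoterWindowMeans(se, groupA, window)
  b <- promoterWindowMeans(se, groupB, window)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 genes (variance undefined otherwise)")
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(meanA = mean(a), meanB = mean(b),
       tStatistic = unname(tt$statistic), pValue = tt$p.value,
       nA = length(a), nB = length(b))
}

#' The dP conservation-divergence statistic
#'
#' Percentage of promoter-window scores strictly below the control group
#' promoter average p^C: \code{dP = 100 * #\{p < pC\} / N} (ties count as
#' not-below).  Significance is a 1-df chi-squared goodness-of-fit of the
#' observed (below, not-below) counts against the control group's own
#' below-threshold proportion, with optional Bonferroni adjustment.
#'
#' @param testScores window scores of the test group (pooled across genes).
#' @param controlScores window scores of the control group.
#' @param pC control threshold; defaults to \code{mean(controlScores)}.
#' @param mComparisons Bonferroni family size (default 1).
#' @return one-row data.frame: N, nBelow, dP, controlDP, chi2, p, pAdj.
#' @export
dPStatistic <- function(testScores, controlScores,
                        pC = mean(controlScores), mComparisons = 1L) {
  N <- length(testScores)
  if (N < 1L) stop("N = 0: no test scores")
  if (length(controlScores) < 1L) stop("no control scores")
  nBelow <- sum(testScores < pC)
  controlDP <- 100 * mean(controlScores < pC)
  cs <- chiSquaredVsControl(nBelow, N, controlDP, mComparisons)
  data.frame(N = as.integer(N), nBelow = as.integer(nBelow),
             dP = 100 * nBelow / N, controlDP = controlDP,
             chi2 = cs$chi2, p = cs$p, pAdj = cs$pAdj)
}
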