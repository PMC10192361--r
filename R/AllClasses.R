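#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet alphabetFrequency width writeXStringSet readDNAStringSet
NULL

.ALLOWED_LETTERS <- c("A", "C", "G", "T", "N", "-")

#' Multi-species promoter alignment with a designated reference
#'
#' Holds equal-length gapped sequences (alphabet \code{A,C,G,T,N,-}) keyed by
#' species, with one record playing the reference role (the D. melanogaster
#' role in a melanogaster-subgroup alignment).  All downstream event calling
#' measures divergence relative to this record.
#'
#' @slot seqs a \code{DNAStringSet} of equal-width gapped sequences, named by
#'   species identifier.
#' @slot reference the name of the reference record.
#' @export
setClass("PromoterAlignment",
  slots = c(seqs = "DNAStringSet", reference = "character"))

setValidity("PromoterAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 2L)
    return("alignment must contain at least 2 records")
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    return("records must carry unique, non-empty species names")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return(sprintf("alignment-shape error: record lengths differ (%s)",
                   paste(unique(w), collapse = ", ")))
  if (length(object@reference) != 1L || !(object@reference %in% names(s)))
    return(sprintf("reference record '%s' not found among: %s",
                   paste(object@reference, collapse = ","),
                   paste(names(s), collapse = ", ")))
  af <- Biostrings::alphabetFrequency(s, baseOnly = FALSE)
  bad <- setdiff(colnames(af)[colSums(af) > 0], .ALLOWED_LETTERS)
  if (length(bad))
    return(sprintf("alphabet error: disallowed character(s) %s (allowed: %s)",
                   paste(bad, collapse = ","),
                   paste(.ALLOWED_LETTERS, collapse = "")))
  TRUE
})

#' Construct a PromoterAlignment
#'
#' @param seqs named character vector or \code{DNAStringSet} of equal-length
#'   gapped sequences (case-insensitive; normalised to upper case).
#' @param reference name of the reference record; defaults to the first.
#' @return a validated \code{PromoterAlignment}.
#' @examples
#' aln <- PromoterAlignment(c(dmel = "ACGT", dsim = "A-GT"))
#' @export
PromoterAlignment <- function(seqs, reference = names(seqs)[1]) {
  if (is.character(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop(sprintf("alignment-shape error: record lengths differ (%s)",
                   paste(unique(lens), collapse = ", ")))
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
    names(seqs) <- nm
  }
  obj <- new("PromoterAlignment", seqs = seqs, reference = reference)
  validObject(obj)
  obj
}

#' Per-column binary event channels of an alignment
#'
#' Tang & Lewontin style 0/1 coding of a multiple alignment: a column is 1 in
#' a channel when at least one non-reference species diverges from the
#' reference there (base change) or when an indel gap run starts there
#' (indel; one event per maximal gap run, registered at its 5'-most column).
#' \code{allChanges} is the column-wise OR of the two.
#'
#' @slot geneId gene identifier (may be \code{NA}).
#' @slot allChanges,indels,baseChanges integer 0/1 vectors, one per column.
#' @slot refCoord 0-based ungapped reference coordinate of each column;
#'   columns that are gaps in the reference map to the preceding reference
#'   position (-1 before the first reference base).
#' @slot tssOffset optional signed position relative to the TSS in reference
#'   coordinates (negative upstream); length 0 until anchored.
#' @export
setClass("EventVector",
  slots = c(geneId = "character",
            allChanges = "integer",
            indels = "integer",
            baseChanges = "integer",
            refCoord = "integer",
            tssOffset = "integer"))

setValidity("EventVector", function(object) {
  L <- length(object@allChanges)
  if (length(object@indels) != L || length(object@baseChanges) != L ||
      length(object@refCoord) != L)
    return("channel and coordinate vectors must share one length")
  for (nm in c("allChanges", "indels", "baseChanges")) {
    v <- slot(object, nm)
    if (any(!(v %in% c(0L, 1L)))) return(sprintf("%s must be binary 0/1", nm))
  }
  if (any(object@allChanges != as.integer(object@indels | object@baseChanges)))
    return("allChanges must equal indels OR baseChanges")
  if (L > 1L && any(diff(object@refCoord) < 0L))
    return("refCoord must be non-decreasing")
  if (!(length(object@tssOffset) %in% c(0L, L)))
    return("tssOffset must be empty or one value per column")
  TRUE
})

#' Sliding event score profile
#'
#' Window sums of a binary event channel on the reference/TSS coordinate
#' grid: \code{se[i]} is the number of events within \code{halfWindow}
#' positions of position \code{i} (default 5 up- and downstream, an 11-wide
#' window), truncated at the profile edges.
#'
#' @slot geneId gene identifier.
#' @slot channel one of \code{"all"}, \code{"indel"}, \code{"base"}.
#' @slot positions integer position grid (TSS offsets when anchored,
#'   otherwise 0-based reference coordinates).
#' @slot se non-negative window sums, one per position.
#' @export
setClass("SeProfile",
  slots = c(geneId = "character", channel = "character",
            positions = "integer", se = "numeric"))

setValidity("SeProfile", function(object) {
  if (length(object@positions) != length(object@se))
    return("positions and se must have equal length")
  if (length(object@channel) != 1L ||
      !(object@channel %in% c("all", "indel", "base")))
    return("channel must be one of 'all', 'indel', 'base'")
  if (any(object@se < 0)) return("se scores must be non-negative")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0L))
    return("positions must be strictly increasing")
  TRUE
})

#' G-function trajectory of event positions along an alignment
#'
#' For n sorted event positions on an alignment of L columns, the G function
#' is the difference between the relative rank of each event and its relative
#' site, G_j = j/n - site_j/L (site = 1-based column).  Clusters of events
#' produce runs of positive increments dG; the global statistic is the
#' maximal rise of G over any event interval, tested against a Monte Carlo
#' (or exhaustive) null of n uniform sites without replacement.
#'
#' @slot L alignment columns.
#' @slot n number of events.
#' @slot x sorted 0-based event positions.
#' @slot G,dG G values and successive differences (G_0 = 0).
#' @slot statistic observed global statistic (max rise of G).
#' @slot pGlobal add-one Monte Carlo p-value (never exactly 0).
#' @slot nullQ95 95th percentile of the null statistic.
#' @slot B null replicates used (or exhaustive sample count).
#' @slot stretches data.frame of significant stretches (1-based inclusive
#'   site intervals with their G-excess).
#' @slot dGPValues per-gap p-values of each observed dG against the null
#'   distribution of the maximal single-gap dG.
#' @export
setClass("GTrajectory",
  slots = c(L = "integer", n = "integer", x = "integer",
            G = "numeric", dG = "numeric",
            statistic = "numeric", pGlobal = "numeric",
            nullQ95 = "numeric", B = "integer",
            stretches = "data.frame", dGPValues = "numeric"))

setValidity("GTrajectory", function(object) {
  n <- object@n
  if (n < 1L) return("n must be >= 1")
  if (n > object@L) return("n cannot exceed L")
  if (length(object@x) != n) return("x must hold n positions")
  if (any(object@x < 0L) || any(object@x >= object@L))
    return("positions must lie in [0, L)")
  if (n > 1L && any(diff(object@x) <= 0L))
    return("positions must be strictly increasing")
  if (length(object@G) != n || length(object@dG) != n)
    return("G and dG must hold n values")
  if (any(object@G <= -1) || any(object@G >= 1))
    return("G values must lie in (-1, 1)")
  if (abs(sum(object@dG) - object@G[n]) > 1e-9)
    return("dG must telescope to G_n")
  if (length(object@pGlobal) == 1L &&
      (object@pGlobal <= 0 || object@pGlobal > 1))
    return("pGlobal must lie in (0, 1]")
  TRUE
})

setMethod("show", "PromoterAlignment", function(object) {
  cat(sprintf("PromoterAlignment: %d records x %d columns (reference: %s)\n",
              length(object@seqs), Biostrings::width(object@seqs)[1],
              object@reference))
  cat("  species:", paste(names(object@seqs), collapse = ", "), "\n")
})

setMethod("show", "EventVector", function(object) {
  cat(sprintf(
    "EventVector%s: %d columns | events: all=%d indel=%d base=%d%s\n",
    if (is.na(object@geneId)) "" else sprintf(" [%s]", object@geneId),
    length(object@allChanges), sum(object@allChanges), sum(object@indels),
    sum(object@baseChanges),
    if (length(object@tssOffset)) " | TSS-anchored" else ""))
})

setMethod("show", "SeProfile", function(object) {
  cat(sprintf("SeProfile [%s, %s]: %d positions (%d..%d), max Se = %g\n",
              object@geneId, object@channel, length(object@positions),
              min(object@positions), max(object@positions), max(object@se)))
})

setMethod("show", "GTrajectory", function(object) {
  cat(sprintf("GTrajectory: n = %d events over L = %d columns\n",
              object@n, object@L))
  if (length(object@statistic))
    cat(sprintf("  statistic = %.4f, p = %.4g (B = %d), null q95 = %.4f\n",
                object@statistic, object@pGlobal, object@B, object@nullQ95))
  if (nrow(object@stretches))
    cat(sprintf("  %d significant stretch(es): %s\n", nrow(object@stretches),
                paste(sprintf("[%d,%d]", object@stretches$start,
                              object@stretches$end), collapse = " ")))
})
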