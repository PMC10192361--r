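#' Read an aligned FASTA into a PromoterAlignment
#'
#' Reads a gapped multi-FASTA (alphabet \code{A,C,G,T,N,-},
#' case-insensitive) and validates it as an equal-width alignment with the
#' given reference record.
#'
#' @param path path to an aligned FASTA file.
#' @param referenceId name of the reference record (FASTA header word).
#' @return a \code{PromoterAlignment}.
#' @export
readAlignment <- function(path, referenceId) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     stop("alphabet or parse error in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop(sprintf("alignment-shape error in %s: record lengths %s", path,
                 paste(unique(w), collapse = ", ")))
  PromoterAlignment(seqs, reference = referenceId)
}

#' Write a PromoterAlignment as aligned FASTA
#'
#' @param aln a \code{PromoterAlignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln@seqs, filepath = path)
  invisible(path)
}

.charMatrix <- function(aln) alignmentMatrix(aln)

#' Call per-column base-change events
#'
#' A column scores 1 when at least one non-reference species carries a
#' non-gap base different from the reference's non-gap base at that column.
#' Columns where the reference (or the differing species) has a gap score 0
#' in this channel; \code{N} is treated as missing data and never creates an
#' event.  With \code{comparison = "any_pair"} a column instead scores 1
#' when any two species differ (two distinct non-gap, non-N bases present).
#'
#' @param aln a \code{PromoterAlignment}.
#' @param comparison \code{"reference"} (default; divergence from the
#'   reference record) or \code{"any_pair"}.
#' @return integer 0/1 vector, one per alignment column.
#' @export
callBaseChangeEvents <- function(aln,
                                 comparison = c("reference", "any_pair")) {
  comparison <- match.arg(comparison)
  m <- .charMatrix(aln)
  if (comparison == "reference") {
    ref <- m[referenceSpecies(aln), ]
    others <- m[setdiff(rownames(m), referenceSpecies(aln)), , drop = FALSE]
    refOk <- ref != "-" & ref != "N"
    hit <- rep(FALSE, ncol(m))
    for (i in seq_len(nrow(others))) {
      row <- others[i, ]
      hit <- hit | (refOk & row != "-" & row != "N" & row != ref)
    }
  } else {
    hit <- apply(m, 2L, function(col) {
      col <- col[col != "-" & col != "N"]
      length(unique(col)) >= 2L
    })
  }
  as.integer(hit)
}

.gapRunStarts <- function(isGap) {
  which(isGap & !c(FALSE, isGap[-length(isGap)]))
}

#' Call per-column indel events
#'
#' Each maximal gap run in each record -- including gap runs in the
#' reference, which represent insertions in other species -- registers
#' exactly one event at the run's 5'-most column.  The channel is the
#' column-wise OR over species (coincident starts collapse to 1); interior
#' gap columns score 0.
#'
#' @param aln a \code{PromoterAlignment}.
#' @return integer 0/1 vector, one per alignment column.
#' @export
callIndelEvents <- function(aln) {
  m <- .charMatrix(aln)
  L <- ncol(m)
  ch <- integer(L)
  for (i in seq_len(nrow(m))) {
    starts <- .gapRunStarts(m[i, ] == "-")
    ch[starts] <- 1L
  }
  ch
}

#' Combine event channels by position-wise OR
#'
#' @param baseChanges,indels binary channels of equal length.
#' @return integer 0/1 vector.
#' @export
combineChannels <- function(baseChanges, indels) {
  if (length(baseChanges) != length(indels))
    stop("channel length mismatch: ", length(baseChanges), " vs ",
         length(indels))
  as.integer(baseChanges | indels)
}

.refCoordMap <- function(aln) {
  ref <- .charMatrix(aln)[referenceSpecies(aln), ]
  cumsum(ref != "-") - 1L
}

#' Build the EventVector of an alignment
#'
#' Calls both channels, combines them, and attaches the column-to-reference
#' coordinate map (0-based; reference-gap columns map to the preceding
#' reference position).
#'
#' @param aln a \code{PromoterAlignment}.
#' @param comparison passed to \code{\link{callBaseChangeEvents}}.
#' @param geneId optional gene identifier carried on the result.
#' @return an \code{EventVector}.
#' @export
eventVector <- function(aln, comparison = c("reference", "any_pair"),
                        geneId = NA_character_) {
  base <- callBaseChangeEvents(aln, comparison)
  ind <- callIndelEvents(aln)
  obj <- new("EventVector",
             geneId = geneId,
             allChanges = combineChannels(base, ind),
             indels = ind,
             baseChanges = base,
             refCoord = .refCoordMap(aln),
             tssOffset = integer(0))
  validObject(obj)
  obj
}

#' Anchor an EventVector to a transcription start site
#'
#' Fills the per-column TSS offset: the signed distance in ungapped
#' reference coordinates from the TSS, negative upstream, with offset 0 at
#' the TSS column.  For minus-strand genes upstream lies at larger reference
#' coordinates, so the sign is flipped.
#'
#' @param ev an \code{EventVector}.
#' @param tssColumn 0-based alignment column of the TSS (first transcribed
#'   base).
#' @param strand \code{"+"} or \code{"-"}.
#' @return the \code{EventVector} with \code{tssOffset} filled.
#' @export
anchorToTSS <- function(ev, tssColumn, strand = "+") {
  L <- alnLength(ev)
  if (tssColumn < 0L || tssColumn >= L)
    stop(sprintf("tssColumn %d out of range [0, %d)", tssColumn, L))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  rc <- refCoord(ev)
  off <- rc - rc[tssColumn + 1L]
  if (strand == "-") off <- -off
  ev@tssOffset <- as.integer(off)
  ev
}

#' Anchor by reference coordinate instead of alignment column
#'
#' Convenience wrapper locating the alignment column of a 0-based ungapped
#' reference position (the first column carrying that reference base).
#'
#' @param ev an \code{EventVector}.
#' @param tssRefPos 0-based reference coordinate of the TSS.
#' @param strand \code{"+"} or \code{"-"}.
#' @return the anchored \code{EventVector}.
#' @export
anchorToTSSByRef <- function(ev, tssRefPos, strand = "+") {
  hit <- which(refCoord(ev) == tssRefPos)
  if (!length(hit))
    stop("reference position ", tssRefPos, " not present in alignment")
  anchorToTSS(ev, hit[1L] - 1L, strand)
}

#' Project a binary channel onto the reference coordinate grid
#'
#' Collapses alignment columns sharing a reference position (insertion
#' columns attach to the preceding reference base) with a binary OR, giving
#' one 0/1 value per ungapped reference position.  Columns upstream of the
#' first reference base (refCoord -1) are dropped.
#'
#' @param ev an \code{EventVector}.
#' @param channel which channel to project.
#' @return list with \code{events} (integer 0/1 per reference position) and
#'   \code{positions} (TSS offsets when anchored, else 0-based reference
#'   coordinates).
#' @export
projectToReference <- function(ev, channel = c("all", "indel", "base")) {
  ch <- eventChannel(ev, channel)
  rc <- refCoord(ev)
  keep <- rc >= 0L
  ch <- ch[keep]
  rc <- rc[keep]
  ev01 <- as.integer(rowsum(ch, rc) > 0L)
  refPos <- sort(unique(rc))
  if (length(tssOffset(ev))) {
    off <- tssOffset(ev)[keep]
    # one offset per reference position (all columns of a position share it)
    pos <- off[match(refPos, rc)]
    o <- order(pos)
    list(events = ev01[o], positions = as.integer(pos[o]))
  } else {
    list(events = ev01, positions = refPos)
  }
}
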