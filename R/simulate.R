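.DEFAULT_SPECIES5 <- c("dmel", "dsim", "dsec", "dyak", "dere")

.simCheck <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

#' Simulate a multi-species promoter alignment with known ground truth
#'
#' A star phylogeny: the first record is an ungapped random reference and
#' every other species derives from it independently by planted
#' substitutions (per-site probability \code{subProb}) and indel events
#' (Poisson with \code{indelRate} expected events per kb, optionally
#' multiplied inside a hotspot window; geometric lengths, minimum 1;
#' insertions and deletions equally likely).  Deletions appear as gap runs
#' in the derived record; insertions as gap columns in all other records.
#' Indel events are kept mutually compatible (no two gap runs can merge,
#' no event's 5' start can hide inside another's run) by claiming a small
#' set of reference positions; a colliding event is shifted to the nearest
#' feasible position rather than redrawn, so the placement distribution --
#' including any hotspot enrichment -- is preserved.  Every planted event
#' therefore maps to exactly one detectable 5' gap-run start.
#'
#' @param nSpecies number of records including the reference (default 5).
#' @param seqLength ungapped reference length in nucleotides (default 2000).
#' @param subProb per-site substitution probability per derived species.
#' @param indelRate expected indel events per derived species per kb.
#' @param indelLenP success parameter of the geometric length distribution
#'   in (0, 1].
#' @param hotspot optional \code{c(start, end, multiplier)}: half-open
#'   reference interval whose indel rate is multiplied.
#' @param seed optional RNG seed (identical seed, identical output).
#' @param speciesNames optional record names; defaults to the five
#'   melanogaster-subgroup species when \code{nSpecies = 5}.
#' @param geneId identifier carried in the ground truth.
#' @param insFraction probability that a planted indel is an insertion.
#' @return list with \code{alignment} (a \code{PromoterAlignment}) and
#'   \code{truth}: data.frames \code{events} (species, type, refStart,
#'   length, alnStart) and \code{substitutions} (species, refSite, alnCol),
#'   per-species sorted position lists \code{trueIndelStarts} and
#'   \code{trueSubstitutionSites} (reference coordinates), the flattened
#'   0-based column sets \code{indelStartColumns} and
#'   \code{baseChangeColumns}, and \code{hotspot}.
#' @export
simulatePromoterAlignment <- function(nSpecies = 5L, seqLength = 2000L,
                                      subProb = 0.02, indelRate = 2,
                                      indelLenP = 0.5, hotspot = NULL,
                                      seed = NULL, speciesNames = NULL,
                                      geneId = "gene", insFraction = 0.5) {
  .simCheck(nSpecies >= 2L, "nSpecies", "need at least 2 species")
  .simCheck(seqLength >= 1L, "seqLength", "must be >= 1")
  .simCheck(subProb >= 0 && subProb <= 1, "subProb", "must lie in [0, 1]")
  .simCheck(indelRate >= 0, "indelRate", "must be >= 0")
  .simCheck(indelLenP > 0 && indelLenP <= 1, "indelLenP",
            "must lie in (0, 1]")
  if (!is.null(hotspot)) {
    .simCheck(length(hotspot) == 3L, "hotspot",
              "must be c(start, end, multiplier)")
    .simCheck(hotspot[1] >= 0 && hotspot[1] < hotspot[2] &&
                hotspot[2] <= seqLength, "hotspot",
              "interval must lie within [0, seqLength)")
    .simCheck(hotspot[3] >= 0, "hotspot", "multiplier must be >= 0")
  }
  if (is.null(speciesNames))
    speciesNames <- if (nSpecies == 5L) .DEFAULT_SPECIES5 else
      c("ref", paste0("sp", seq_len(nSpecies - 1L) + 1L))
  .simCheck(length(speciesNames) == nSpecies, "speciesNames",
            "one name per species")
  if (!is.null(seed)) set.seed(seed)

  L <- as.integer(seqLength)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)

  w <- rep(1, L)
  if (!is.null(hotspot) && hotspot[3] != 1)
    w[seq.int(hotspot[1] + 1L, hotspot[2])] <- hotspot[3]
  lambda <- indelRate / 1000 * sum(w)

  # Collision rules are the minimal set that keeps every planted event a
  # distinct, detectable 5' gap-run start.  Within one species, events keep
  # a 1-position buffer (runs in the same row must never merge and a
  # species' own insertion must not split its own deletion run).  Across
  # species only two point collisions matter: two insertions sharing an
  # anchor, and an insertion anchored exactly at a deletion start (either
  # would hide one event's 5' column behind the other's run).  Everything
  # else -- overlapping cross-species deletions, insertions inside another
  # species' deletion -- leaves all 5' starts detectable, so it is
  # allowed.
  spClaims <- stats::setNames(
    lapply(speciesNames[-1L], function(s) logical(L + 2L)),
    speciesNames[-1L])                      # [p + 2] marks ref position p
  anchorSet <- logical(L + 2L)
  delStartSet <- logical(L + 2L)
  free <- function(mask, ps) !any(mask[ps + 2L])
  clip <- function(ps) ps[ps >= -1L & ps <= L]

  feasibleIns <- function(sp, pos) {
    pos >= 1L && pos < L && !anchorSet[pos + 2L] &&
      !delStartSet[pos + 2L] && free(spClaims[[sp]], c(pos - 1L, pos))
  }
  feasibleDel <- function(sp, pos, len) {
    pos >= 0L && pos + len <= L && !anchorSet[pos + 2L] &&
      free(spClaims[[sp]], clip(seq.int(pos - 1L, pos + len)))
  }
  # Collisions are resolved by moving the event to the nearest feasible
  # position (alternating right/left), not by redrawing the position:
  # redrawing conditions the placement on empty space and measurably thins
  # dense regions such as hotspots, whereas a nearest-slot shift preserves
  # the target placement distribution up to a few nucleotides.
  nearestFeasible <- function(feasible) {
    function(sp, pos, len) {
      if (feasible(sp, pos, len)) return(pos)
      for (delta in seq_len(L)) {
        if (feasible(sp, pos + delta, len)) return(pos + delta)
        if (feasible(sp, pos - delta, len)) return(pos - delta)
      }
      NA_integer_
    }
  }
  placeIns <- nearestFeasible(function(sp, pos, len) feasibleIns(sp, pos))
  placeDel <- nearestFeasible(feasibleDel)

  events <- list()
  derived <- speciesNames[-1L]
  for (sp in derived) {
    nEv <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
    for (e in seq_len(nEv)) {
      isIns <- stats::runif(1) < insFraction
      len <- stats::rgeom(1L, indelLenP) + 1L
      pos <- sample.int(L, 1L, prob = w) - 1L
      if (isIns) {
        at <- placeIns(sp, pos, len)
        if (is.na(at))
          stop("no feasible insertion anchor left; rates too high ",
               "for the sequence length")
        spClaims[[sp]][c(at - 1L, at) + 2L] <- TRUE
        anchorSet[at + 2L] <- TRUE
        events[[length(events) + 1L]] <-
          data.frame(species = sp, type = "ins", refStart = at,
                     length = len)
      } else {
        at <- placeDel(sp, pos, len)
        if (is.na(at))
          stop("no feasible deletion site left; rates too high ",
               "for the sequence length")
        ps <- clip(seq.int(at - 1L, at + len))
        spClaims[[sp]][ps + 2L] <- TRUE
        delStartSet[at + 2L] <- TRUE
        events[[length(events) + 1L]] <-
          data.frame(species = sp, type = "del", refStart = at,
                     length = len)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(species = character(0), type = character(0),
               refStart = integer(0), length = integer(0),
               alnStart = integer(0))

  # substitutions, per derived species, avoiding own deleted positions
  subs <- list()
  for (sp in derived) {
    sites <- which(stats::runif(L) < subProb) - 1L
    own <- ev[ev$species == sp & ev$type == "del", , drop = FALSE]
    if (nrow(own)) {
      delPos <- unlist(mapply(function(p, l) seq.int(p, p + l - 1L),
                              own$refStart, own$length, SIMPLIFY = FALSE))
      sites <- setdiff(sites, delPos)
    }
    if (length(sites))
      subs[[length(subs) + 1L]] <-
        data.frame(species = sp, refSite = sites,
                   newBase = vapply(sites + 1L, function(i)
                     sample(setdiff(bases, ref[i]), 1L), character(1)))
  }
  sb <- if (length(subs)) do.call(rbind, subs) else
    data.frame(species = character(0), refSite = integer(0),
               newBase = character(0))

  # base matrix over reference positions
  M <- matrix(rep(ref, each = nSpecies), nrow = nSpecies,
              dimnames = list(speciesNames, NULL))
  if (nrow(sb))
    M[cbind(match(sb$species, speciesNames), sb$refSite + 1L)] <- sb$newBase
  dels <- ev[ev$type == "del", , drop = FALSE]
  for (i in seq_len(nrow(dels)))
    M[dels$species[i], seq.int(dels$refStart[i] + 1L,
                               dels$refStart[i] + dels$length[i])] <- "-"

  # splice insertion blocks (anchors are globally distinct by construction)
  ins <- ev[ev$type == "ins", , drop = FALSE]
  ins <- ins[order(ins$refStart), , drop = FALSE]
  shiftBefore <- function(r)     # inserted columns at anchors <= r
    if (nrow(ins)) sum(ins$length[ins$refStart <= r]) else 0L
  pieces <- list()
  prev <- 0L
  blockStart <- integer(nrow(ins))
  for (i in seq_len(nrow(ins))) {
    a <- ins$refStart[i]
    pieces[[length(pieces) + 1L]] <- M[, seq.int(prev + 1L, a),
                                       drop = FALSE]
    blk <- matrix("-", nrow = nSpecies, ncol = ins$length[i])
    blk[match(ins$species[i], speciesNames), ] <-
      sample(bases, ins$length[i], replace = TRUE)
    blockStart[i] <- a + (if (i > 1L) sum(ins$length[seq_len(i - 1L)])
                          else 0L)
    pieces[[length(pieces) + 1L]] <- blk
    prev <- a
  }
  pieces[[length(pieces) + 1L]] <- M[, seq.int(prev + 1L, L), drop = FALSE]
  A <- do.call(cbind, pieces)

  aln <- PromoterAlignment(
    stats::setNames(apply(A, 1L, paste, collapse = ""), speciesNames),
    reference = speciesNames[1L])

  if (nrow(ev)) {
    ev$alnStart <- NA_integer_
    isDel <- ev$type == "del"
    ev$alnStart[isDel] <- vapply(ev$refStart[isDel],
                                 function(p) p + shiftBefore(p), numeric(1))
    ev$alnStart[!isDel] <- blockStart[match(
      paste(ev$species[!isDel], ev$refStart[!isDel]),
      paste(ins$species, ins$refStart))]
    ev$alnStart <- as.integer(ev$alnStart)
  }
  sb$alnCol <- if (nrow(sb))
    as.integer(vapply(sb$refSite, function(p) p + shiftBefore(p),
                      numeric(1))) else integer(0)

  perSpecies <- function(df, col) {
    out <- lapply(stats::setNames(nm = derived), function(sp)
      sort(df[[col]][df$species == sp]))
    out
  }
  truth <- list(
    geneId = geneId,
    events = ev,
    substitutions = sb,
    trueIndelStarts = perSpecies(ev, "refStart"),
    trueSubstitutionSites = perSpecies(sb, "refSite"),
    indelStartColumns = sort(unique(ev$alnStart)),
    baseChangeColumns = sort(unique(sb$alnCol)),
    hotspot = hotspot)
  list(alignment = aln, truth = truth)
}

#' Simulate TSS-anchored conservation score vectors
#'
#' Per gene, a 1300-position score vector over offsets -1000..+299: a flat
#' baseline \code{baseMean}, minus \code{promoterDrop} inside
#' \code{dropWindow}, plus Gaussian noise.
#'
#' @param nGenes number of genes (>= 1).
#' @param window half-open offset interval; must span exactly 1300
#'   positions (default \code{c(-1000, 300)}).
#' @param baseMean baseline score.
#' @param promoterDrop score subtracted inside \code{dropWindow}.
#' @param dropWindow half-open offset interval of the depression (default
#'   the TATA-distal window \code{[-380, -30)}).
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed optional RNG seed.
#' @param group group label stored per gene.
#' @param genePrefix prefix of generated gene ids (defaults to the group).
#' @return \code{SummarizedExperiment} as from
#'   \code{\link{anchorScoresToTSS}}.
#' @export
simulateConservationTracks <- function(nGenes, window = c(-1000L, 300L),
                                       baseMean = 1, promoterDrop = 0,
                                       dropWindow = c(-380L, -30L),
                                       noiseSd = 0.1, seed = NULL,
                                       group = "genome",
                                       genePrefix = group) {
  .simCheck(nGenes >= 1L, "nGenes", "must be >= 1")
  .simCheck(noiseSd >= 0, "noiseSd", "must be >= 0")
  offs <- .windowGrid(window)
  if (length(offs) != 1300L)
    stop("window must span exactly 1300 positions, got ", length(offs))
  if (!is.null(seed)) set.seed(seed)
  inDrop <- offs >= dropWindow[1] & offs < dropWindow[2]
  mu <- baseMean - promoterDrop * inDrop
  m <- matrix(stats::rnorm(length(offs) * nGenes, mean = mu, sd = noiseSd),
              nrow = length(offs), ncol = nGenes)
  ids <- sprintf("%s_%03d", genePrefix, seq_len(nGenes))
  dimnames(m) <- list(as.character(offs), ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(score = m),
    rowData = S4Vectors::DataFrame(offset = offs),
    colData = S4Vectors::DataFrame(gene_id = ids, group = group,
                                   strand = "+", row.names = ids))
}

#' Lay TSS-anchored profiles onto a genome-coordinate track
#'
#' Places each gene's 1300-position vector at a distinct genomic TSS
#' (alternating strands by default) and returns the per-base track plus the
#' matching annotation table, so the \code{\link{readScores}} /
#' \code{\link{anchorScoresToTSS}} path can be exercised round-trip.
#'
#' @param se profiles from \code{\link{simulateConservationTracks}}.
#' @param contig contig name.
#' @param spacing distance between consecutive TSSs (must exceed the
#'   window span).
#' @param alternateStrands place every second gene on the minus strand.
#' @return list with \code{track} (\code{GRanges} with score) and
#'   \code{annotations} (data.frame gene_id, contig, tss, strand, group).
#' @export
profilesToTrack <- function(se, contig = "simChr", spacing = 4000L,
                            alternateStrands = TRUE) {
  offs <- .seOffsets(se)
  m <- SummarizedExperiment::assay(se, "score")
  cd <- SummarizedExperiment::colData(se)
  n <- ncol(m)
  tss <- 2000L + (seq_len(n) - 1L) * spacing
  strand <- if (alternateStrands) rep(c("+", "-"), length.out = n) else
    rep("+", n)
  pos <- unlist(lapply(seq_len(n), function(i)
    if (strand[i] == "+") tss[i] + offs else tss[i] - offs))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = pos + 1L, width = 1L),
                               score = as.numeric(m))
  gr <- GenomicRanges::sort(gr)
  list(track = gr,
       annotations = data.frame(gene_id = cd$gene_id, contig = contig,
                                tss = tss, strand = strand,
                                group = cd$group,
                                stringsAsFactors = FALSE))
}

#' Simulate McDonald-Kreitman count tables with a known pooled alpha
#'
#' Per gene: \code{Ps ~ Pois(meanPs)}, \code{Pn ~ Pois(pnPsRatio * meanPs)},
#' \code{Ds ~ Pois(meanDs)},
#' \code{Dn ~ Pois(meanDs * pnPsRatio / (1 - trueAlpha))}, so the pooled
#' alpha of the collection converges to \code{trueAlpha}.
#'
#' @param nGenes number of genes (>= 1).
#' @param trueAlpha target pooled alpha in [0, 1).
#' @param meanPs,meanDs expected synonymous polymorphism/divergence counts
#'   (> 0).
#' @param pnPsRatio expected Pn/Ps ratio under neutrality (> 0).
#' @param seed optional RNG seed.
#' @param genePrefix prefix of generated gene ids.
#' @return data.frame with columns gene_id, Pn, Ps, Dn, Ds.
#' @export
simulateMKTCounts <- function(nGenes, trueAlpha, meanPs = 20, meanDs = 20,
                              pnPsRatio = 0.3, seed = NULL,
                              genePrefix = "gene") {
  .simCheck(nGenes >= 1L, "nGenes", "must be >= 1")
  .simCheck(trueAlpha >= 0 && trueAlpha < 1, "trueAlpha",
            "must lie in [0, 1)")
  .simCheck(meanPs > 0 && meanDs > 0, "meanPs/meanDs", "must be > 0")
  .simCheck(pnPsRatio > 0, "pnPsRatio", "must be > 0")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    gene_id = sprintf("%s_%04d", genePrefix, seq_len(nGenes)),
    Pn = stats::rpois(nGenes, pnPsRatio * meanPs),
    Ps = stats::rpois(nGenes, meanPs),
    Dn = stats::rpois(nGenes, meanDs * pnPsRatio / (1 - trueAlpha)),
    Ds = stats::rpois(nGenes, meanDs),
    stringsAsFactors = FALSE)
}

#' Write ground truth as JSON
#'
#' @param truth the \code{truth} component of
#'   \code{\link{simulatePromoterAlignment}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
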