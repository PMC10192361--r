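#' Accessors for promdiv classes
#'
#' Small accessor generics so slots are never reached into directly:
#' species and reference names, alignment dimensions and character matrix,
#' event channels and coordinate maps, Se profile grids and scores.
#'
#' @param x a \code{PromoterAlignment}, \code{EventVector} or
#'   \code{SeProfile}.
#' @param channel which event channel: \code{"all"}, \code{"indel"} or
#'   \code{"base"}.
#' @name promdiv-accessors
NULL

#' @rdname promdiv-accessors
#' @export
setGeneric("referenceSpecies", function(x) standardGeneric("referenceSpecies"))
#' @rdname promdiv-accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname promdiv-accessors
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))
#' @rdname promdiv-accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname promdiv-accessors
#' @export
setGeneric("eventChannel",
           function(x, channel = c("all", "indel", "base"))
             standardGeneric("eventChannel"))
#' @rdname promdiv-accessors
#' @export
setGeneric("eventPositions",
           function(x, channel = c("all", "indel", "base"))
             standardGeneric("eventPositions"))
#' @rdname promdiv-accessors
#' @export
setGeneric("refCoord", function(x) standardGeneric("refCoord"))
#' @rdname promdiv-accessors
#' @export
setGeneric("tssOffset", function(x) standardGeneric("tssOffset"))
#' @rdname promdiv-accessors
#' @export
setGeneric("sePositions", function(x) standardGeneric("sePositions"))
#' @rdname promdiv-accessors
#' @export
setGeneric("seScores", function(x) standardGeneric("seScores"))

#' @rdname promdiv-accessors
#' @export
setMethod("referenceSpecies", "PromoterAlignment", function(x) x@reference)

#' @rdname promdiv-accessors
#' @export
setMethod("speciesNames", "PromoterAlignment", function(x) names(x@seqs))

#' @rdname promdiv-accessors
#' @export
setMethod("alnLength", "PromoterAlignment",
          function(x) Biostrings::width(x@seqs)[1])

#' @rdname promdiv-accessors
#' @export
setMethod("alnLength", "EventVector", function(x) length(x@allChanges))

#' @rdname promdiv-accessors
#' @export
setMethod("alignmentMatrix", "PromoterAlignment", function(x) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
  rownames(m) <- names(x@seqs)
  m
})

#' @rdname promdiv-accessors
#' @export
setMethod("eventChannel", "EventVector", function(x, channel) {
  channel <- match.arg(channel, c("all", "indel", "base"))
  switch(channel, all = x@allChanges, indel = x@indels,
         base = x@baseChanges)
})

#' @rdname promdiv-accessors
#' @export
setMethod("eventPositions", "EventVector", function(x, channel) {
  which(eventChannel(x, channel) == 1L) - 1L
})

#' @rdname promdiv-accessors
#' @export
setMethod("refCoord", "EventVector", function(x) x@refCoord)

#' @rdname promdiv-accessors
#' @export
setMethod("tssOffset", "EventVector", function(x) x@tssOffset)

#' @rdname promdiv-accessors
#' @export
setMethod("sePositions", "SeProfile", function(x) x@positions)

#' @rdname promdiv-accessors
#' @export
setMethod("seScores", "SeProfile", function(x) x@se)
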