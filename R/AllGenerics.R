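#' Accessors for panEC classes
#'
#' @param x an object.
#' @return \code{ecSet} returns the character vector of EC numbers;
#'   \code{uec} the number of distinct EC numbers (the "uEC" count);
#'   \code{entityId}, \code{entityKind} and \code{speciesLabel} the
#'   corresponding fields; \code{nReactions} the reaction count of a
#'   [Superpathway-class].
#' @examples
#' p <- ECProfile("s1", c("1.1.1.1", "2.2.2.2"))
#' ecSet(p)
#' uec(p)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ecSet", function(x) standardGeneric("ecSet"))

#' @rdname accessors
#' @export
setGeneric("uec", function(x) standardGeneric("uec"))

#' @rdname accessors
#' @export
setGeneric("entityId", function(x) standardGeneric("entityId"))

#' @rdname accessors
#' @export
setGeneric("entityKind", function(x) standardGeneric("entityKind"))

#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname accessors
#' @export
setMethod("ecSet", "ECProfile", function(x) x@ecSet)

#' @rdname accessors
#' @export
setMethod("uec", "ECProfile", function(x) length(x@ecSet))

#' @rdname accessors
#' @export
setMethod("entityId", "ECProfile", function(x) x@entityId)

#' @rdname accessors
#' @export
setMethod("entityKind", "ECProfile", function(x) x@entityKind)

#' @rdname accessors
#' @export
setMethod("speciesLabel", "ECProfile", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("nReactions", "Superpathway", function(x) length(x@reactionIds))

#' @rdname accessors
#' @export
setGeneric("pathwayId", function(x) standardGeneric("pathwayId"))

#' @rdname accessors
#' @export
setMethod("pathwayId", "Superpathway", function(x) x@pathwayId)

#' @rdname accessors
#' @export
setGeneric("reactionEcSets", function(x) standardGeneric("reactionEcSets"))

#' @rdname accessors
#' @export
setMethod("reactionEcSets", "Superpathway", function(x) {
  stats::setNames(x@reactionEc, x@reactionIds)
})

#' @rdname accessors
#' @export
setGeneric("replicateValues", function(x) standardGeneric("replicateValues"))

#' @rdname accessors
#' @export
setMethod("replicateValues", "BootstrapResult", function(x) x@replicateValues)

#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' @rdname accessors
#' @export
setMethod("nullMean", "BootstrapResult", function(x) x@nullMean)

#' @rdname accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))

#' @rdname accessors
#' @export
setMethod("nullSd", "BootstrapResult", function(x) x@nullSd)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setMethod("pValue", "BootstrapResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname accessors
#' @export
setMethod("zScore", "BootstrapResult", function(x) x@zScore)

#' @rdname accessors
#' @export
setGeneric("observedValue", function(x) standardGeneric("observedValue"))

#' @rdname accessors
#' @export
setMethod("observedValue", "BootstrapResult", function(x) x@observed)
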