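#' @import methods
NULL

# Regex for a fully specified 4-field EC number, e.g. "1.1.1.1".
.EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"
# GO term identifier, e.g. "GO:0004022".
.GO_PATTERN <- "^GO:[0-9]{7}$"

#' Test strings for the fully specified EC-number format
#'
#' A fully specified Enzyme Commission number has four dot-separated numeric
#' fields (e.g. \code{"1.1.1.1"}). Partial EC numbers such as
#' \code{"1.1.1.-"} do not qualify.
#'
#' @param x character vector.
#' @return logical vector, one element per input string.
#' @examples
#' isValidEc(c("1.1.1.1", "1.1.1.-", "foo"))
#' @export
isValidEc <- function(x) {
  grepl(.EC_PATTERN, x)
}

#' ECProfile: the EC-number repertoire of a strain, microbiome or aggregate
#'
#' An \code{ECProfile} holds the set of fully specified Enzyme Commission
#' numbers annotated to one entity. The entity may be a single bacterial
#' strain, a metagenome ("microbiome"), or an aggregate such as a pan-genome
#' (union over entities) or core-genome (intersection).
#'
#' @slot entityId single string identifying the entity.
#' @slot entityKind one of \code{"strain"}, \code{"microbiome"},
#'   \code{"aggregate"}.
#' @slot species species label for strains; \code{NA_character_} otherwise.
#' @slot ecSet character vector of distinct, fully specified EC numbers,
#'   stored sorted.
#'
#' @seealso [ECProfile()] for the constructor, [panGenome()], [coreGenome()].
#' @name ECProfile-class
#' @rdname ECProfile-class
#' @exportClass ECProfile
setClass("ECProfile",
  representation(
    entityId = "character",
    entityKind = "character",
    species = "character",
    ecSet = "character"
  ),
  prototype(
    entityId = NA_character_,
    entityKind = "strain",
    species = NA_character_,
    ecSet = character()
  )
)

setValidity("ECProfile", function(object) {
  msg <- character()
  if (length(object@entityId) != 1L || is.na(object@entityId) ||
      !nzchar(object@entityId)) {
    msg <- c(msg, "'entityId' must be a single non-empty string")
  }
  if (length(object@entityKind) != 1L ||
      !object@entityKind %in% c("strain", "microbiome", "aggregate")) {
    msg <- c(msg, "'entityKind' must be one of 'strain', 'microbiome', 'aggregate'")
  }
  if (length(object@species) != 1L) {
    msg <- c(msg, "'species' must be a single string (possibly NA)")
  }
  if (anyDuplicated(object@ecSet)) {
    msg <- c(msg, "'ecSet' must not contain duplicates")
  }
  bad <- object@ecSet[!isValidEc(object@ecSet)]
  if (length(bad)) {
    msg <- c(msg, paste0("'ecSet' contains invalid or partial EC numbers: ",
                         paste(utils::head(bad, 3L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ECProfile
#'
#' @param entityId single string identifying the entity.
#' @param ecSet character vector of EC numbers; duplicates are collapsed,
#'   the set is stored sorted. Partial EC numbers (any field \code{"-"})
#'   are rejected.
#' @param entityKind \code{"strain"}, \code{"microbiome"} or
#'   \code{"aggregate"}.
#' @param species optional species label (strains only).
#' @return an [ECProfile-class] object.
#' @examples
#' p <- ECProfile("strainA", c("1.1.1.1", "2.7.7.7"), species = "L. helveticus")
#' uec(p)
#' @export
ECProfile <- function(entityId, ecSet = character(), entityKind = "strain",
                      species = NA_character_) {
  new("ECProfile",
      entityId = as.character(entityId),
      entityKind = entityKind,
      species = as.character(species),
      ecSet = sort(unique(as.character(ecSet))))
}

setMethod("show", "ECProfile", function(object) {
  cat("ECProfile '", object@entityId, "' (", object@entityKind, ")\n",
      sep = "")
  if (!is.na(object@species)) cat("  species:", object@species, "\n")
  cat("  uEC:", length(object@ecSet), "\n")
  if (length(object@ecSet)) {
    cat("  ECs:", paste(utils::head(object@ecSet, 5L), collapse = ", "),
        if (length(object@ecSet) > 5L) "..." else "", "\n")
  }
})

#' Superpathway: an ordered reaction list with optional EC annotations
#'
#' Models a composite metabolic pathway ("superpathway") as an ordered list
#' of reactions, each annotated with zero or more EC numbers. Reactions with
#' an empty EC set can never be matched by an EC profile, which caps the
#' attainable coverage of the pathway below 1.
#'
#' @slot pathwayId single string, unique pathway identifier.
#' @slot name human-readable pathway name.
#' @slot reactionIds character vector of reaction identifiers, unique within
#'   the pathway.
#' @slot reactionEc list of character vectors, parallel to
#'   \code{reactionIds}; each element is the (possibly empty) EC set of the
#'   corresponding reaction.
#' @slot taxonomicRange character vector of taxon names the pathway is
#'   expected in (stored for reference, not used in computation).
#'
#' @seealso [Superpathway()], [pathwayCoverage()].
#' @name Superpathway-class
#' @rdname Superpathway-class
#' @exportClass Superpathway
setClass("Superpathway",
  representation(
    pathwayId = "character",
    name = "character",
    reactionIds = "character",
    reactionEc = "list",
    taxonomicRange = "character"
  )
)

setValidity("Superpathway", function(object) {
  msg <- character()
  if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId)) {
    msg <- c(msg, "'pathwayId' must be a single non-empty string")
  }
  if (length(object@reactionIds) < 1L) {
    msg <- c(msg, "a pathway must contain at least one reaction")
  }
  if (anyDuplicated(object@reactionIds)) {
    msg <- c(msg, "reaction ids must be unique within a pathway")
  }
  if (length(object@reactionEc) != length(object@reactionIds)) {
    msg <- c(msg, "'reactionEc' must be parallel to 'reactionIds'")
  }
  ecs <- unlist(object@reactionEc, use.names = FALSE)
  if (length(ecs) && !all(isValidEc(ecs))) {
    msg <- c(msg, "reaction EC annotations must be fully specified EC numbers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Superpathway
#'
#' @param pathwayId unique pathway identifier.
#' @param reactionIds character vector of reaction identifiers.
#' @param reactionEc list of character vectors (one per reaction); each the
#'   EC set of that reaction, possibly empty.
#' @param name human-readable name; defaults to \code{pathwayId}.
#' @param taxonomicRange optional character vector of taxon names.
#' @return a [Superpathway-class] object.
#' @examples
#' sp <- Superpathway("PWY1", c("R1", "R2"),
#'                    list("1.1.1.1", character()))
#' nReactions(sp)
#' @export
Superpathway <- function(pathwayId, reactionIds, reactionEc,
                         name = pathwayId, taxonomicRange = character()) {
  reactionEc <- lapply(reactionEc, function(e) sort(unique(as.character(e))))
  new("Superpathway",
      pathwayId = as.character(pathwayId),
      name = as.character(name),
      reactionIds = as.character(reactionIds),
      reactionEc = reactionEc,
      taxonomicRange = as.character(taxonomicRange))
}

setMethod("show", "Superpathway", function(object) {
  nr <- length(object@reactionIds)
  nAnn <- sum(lengths(object@reactionEc) > 0L)
  cat("Superpathway '", object@pathwayId, "': ", object@name, "\n",
      "  ", nr, " reactions (", nAnn, " EC-annotated)\n", sep = "")
})

#' BootstrapResult: a resampling null distribution for a selection statistic
#'
#' Holds the replicate values of a statistic computed on random selections of
#' k strains, the null mean and standard deviation over replicates, and --
#' once an observed value has been supplied via [normalPValue()] -- the
#' observed statistic, z-score and normal-approximation p-value.
#'
#' @slot nReps number of replicates.
#' @slot k subset size per replicate.
#' @slot statisticName \code{"pan_uec_count"} or
#'   \code{"pan_mean_pathway_coverage"}.
#' @slot replicateValues numeric vector of length \code{nReps}.
#' @slot nullMean,nullSd mean and sd (n-1 denominator) over replicates.
#' @slot observed observed value of the statistic (\code{NA} until set).
#' @slot zScore,pValue z-score and p-value (\code{NA} until set).
#' @slot alternative \code{"greater"}, \code{"less"} or \code{"two.sided"}.
#' @slot seed RNG seed used for the replicates.
#'
#' @seealso [randomSelectionNull()], [normalPValue()].
#' @name BootstrapResult-class
#' @rdname BootstrapResult-class
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(
    nReps = "integer",
    k = "integer",
    statisticName = "character",
    replicateValues = "numeric",
    nullMean = "numeric",
    nullSd = "numeric",
    observed = "numeric",
    zScore = "numeric",
    pValue = "numeric",
    alternative = "character",
    seed = "integer"
  ),
  prototype(
    observed = NA_real_, zScore = NA_real_, pValue = NA_real_,
    alternative = "greater"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (length(object@replicateValues) != object@nReps) {
    msg <- c(msg, "length(replicateValues) must equal nReps")
  }
  if (!is.na(object@nullSd) && object@nullSd < 0) {
    msg <- c(msg, "'nullSd' must be non-negative")
  }
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1)) {
    msg <- c(msg, "'pValue' must lie in [0, 1]")
  }
  if (!object@statisticName %in% c("pan_uec_count",
                                   "pan_mean_pathway_coverage")) {
    msg <- c(msg, "unknown statistic name")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult: ", object@statisticName,
      " over ", object@nReps, " random selections of k = ", object@k,
      " strains\n", sep = "")
  cat(sprintf("  null mean = %.4g, null sd = %.4g\n",
              object@nullMean, object@nullSd))
  if (!is.na(object@observed)) {
    cat(sprintf("  observed = %.4g, z = %.3f, p (%s) = %.3g\n",
                object@observed, object@zScore, object@alternative,
                object@pValue))
  } else {
    cat("  observed statistic not yet supplied (see normalPValue())\n")
  }
})
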