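#' Coverage of a superpathway by an EC repertoire
#'
#' A reaction is matched when any of its EC numbers is present in the
#' profile's EC set. Coverage is the fraction of matched reactions. With
#' the default denominator (\code{"all"}) reactions without EC annotation
#' count in the denominator but can never be matched, so a pathway
#' containing them cannot reach coverage 1; with
#' \code{denominator = "annotated"} only EC-annotated reactions are
#' counted (coverage of a pathway with no annotated reaction is then 0).
#'
#' @param profile an [ECProfile-class].
#' @param pathway a [Superpathway-class].
#' @param denominator \code{"all"} (default) or \code{"annotated"}.
#' @return fraction in [0, 1].
#' @examples
#' sp <- Superpathway("P", c("R1", "R2"), list("1.1.1.1", character()))
#' pathwayCoverage(ECProfile("s", "1.1.1.1"), sp)  # 0.5, cap is 0.5
#' @export
pathwayCoverage <- function(profile, pathway,
                            denominator = c("all", "annotated")) {
  denominator <- match.arg(denominator)
  ecs <- ecSet(profile)
  matched <- vapply(pathway@reactionEc,
                    function(r) length(r) > 0L && any(r %in% ecs),
                    logical(1))
  denom <- if (denominator == "all") {
    length(matched)
  } else {
    sum(lengths(pathway@reactionEc) > 0L)
  }
  if (denom == 0L) return(0)
  sum(matched) / denom
}

#' Entity-by-pathway coverage matrix
#'
#' @param entities non-empty list of [ECProfile-class] objects.
#' @param pathways non-empty list of [Superpathway-class] objects.
#' @param denominator see [pathwayCoverage()].
#' @return numeric matrix, rows = entities (named by entity id), columns =
#'   pathways (named by pathway id), values in [0, 1].
#' @export
coverageMatrix <- function(entities, pathways,
                           denominator = c("all", "annotated")) {
  denominator <- match.arg(denominator)
  if (length(entities) < 1L || length(pathways) < 1L) {
    stop("need at least one entity and one pathway")
  }
  m <- vapply(pathways, function(p) {
    vapply(entities, pathwayCoverage, numeric(1), pathway = p,
           denominator = denominator)
  }, numeric(length(entities)))
  m <- matrix(m, nrow = length(entities),
              dimnames = list(vapply(entities, entityId, character(1)),
                              vapply(pathways, pathwayId, character(1))))
  m
}

#' Per-entity coverage summary
#'
#' For each entity (matrix row) counts the pathways not covered (coverage
#' exactly 0), partially covered (strictly between 0 and 1) and completely
#' covered (exactly 1), and reports the mean coverage over all pathways.
#' The three counts always sum to the number of pathways.
#'
#' @param matrix coverage matrix from [coverageMatrix()].
#' @return data.frame with columns entity_id, n_not_covered, n_partial,
#'   n_complete, mean_coverage.
#' @export
summarizeCoverage <- function(matrix) {
  data.frame(
    entity_id = rownames(matrix),
    n_not_covered = rowSums(matrix == 0),
    n_partial = rowSums(matrix > 0 & matrix < 1),
    n_complete = rowSums(matrix == 1),
    mean_coverage = rowMeans(matrix),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Average coverage profile of a group of entities
#'
#' The "average strain" of a collection is defined by the arithmetic mean,
#' per pathway, of the coverage values of every member entity.
#'
#' @param matrix coverage matrix.
#' @param entities optional character vector of row names to average over;
#'   default: all rows.
#' @return named numeric vector, one mean per pathway.
#' @export
averageEntityCoverage <- function(matrix, entities = rownames(matrix)) {
  sub <- matrix[entities, , drop = FALSE]
  if (nrow(sub) < 1L) stop("need at least one entity row")
  colMeans(sub)
}

#' Rank pathways by coverage variance across reference entities
#'
#' Computes the population variance (denominator n) of each pathway's
#' coverage across the given reference entities -- typically the
#' metagenomes under comparison -- and returns the top \code{k} pathways,
#' ties broken by pathway id ascending. High-variance pathways are those
#' covered very differently across the references.
#'
#' @param matrix coverage matrix.
#' @param reference_entities character vector of >= 2 row names.
#' @param k number of pathways to return (default 15).
#' @return data.frame with columns pathway_id and variance, sorted by
#'   decreasing variance.
#' @export
topVariancePathways <- function(matrix, reference_entities, k = 15L) {
  if (length(reference_entities) < 2L) {
    stop("need at least two reference entities")
  }
  sub <- matrix[reference_entities, , drop = FALSE]
  n <- nrow(sub)
  v <- apply(sub, 2L, function(x) sum((x - mean(x))^2) / n)
  if (k > ncol(matrix)) {
    warning("k exceeds the number of pathways; truncating to ", ncol(matrix))
    k <- ncol(matrix)
  }
  ord <- order(-v, colnames(sub))
  data.frame(pathway_id = colnames(sub)[ord][seq_len(k)],
             variance = unname(v[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of a matrix axis
#'
#' Agglomerative clustering (average linkage by default, Euclidean
#' distance) of the rows or columns of a coverage or shared-uEC matrix, as
#' used to order heatmap axes. Returns the full merge tree.
#'
#' @param matrix numeric matrix with dimnames.
#' @param axis \code{"rows"} or \code{"columns"}.
#' @param method linkage method passed to [stats::hclust()].
#' @return an object of class \code{hclust}; leaves are the axis labels.
#' @seealso [dendrogramNewick()] to export the tree.
#' @export
hierarchicalCluster <- function(matrix, axis = c("rows", "columns"),
                                method = "average") {
  axis <- match.arg(axis)
  m <- if (axis == "rows") matrix else t(matrix)
  if (nrow(m) < 2L) stop("need at least two items on the clustered axis")
  stats::hclust(stats::dist(m, method = "euclidean"), method = method)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights of the clustering, so the
#' tree records at which distance items were joined.
#'
#' @param hc an \code{hclust} object from [hierarchicalCluster()].
#' @param path optional file path; if given the tree is written there.
#' @return the Newick string, invisibly if \code{path} is given.
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
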