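#' Filter homology hits by e-value
#'
#' Retains exactly the hits whose e-value lies strictly below
#' \code{max_evalue}, preserving input order. The default threshold of 1e-6
#' is the conventional cutoff for reliable annotation transfer from
#' Swiss-Prot homology hits.
#'
#' @param hits data.frame with at least an \code{e_value} column.
#' @param max_evalue positive threshold; hits at exactly this value are
#'   excluded (strict inequality).
#' @return the filtered data.frame, same columns, original relative order.
#' @examples
#' h <- data.frame(e_value = c(1e-10, 1e-6, 1e-3))
#' nrow(filterHits(h))  # 1: the boundary hit is excluded
#' @export
filterHits <- function(hits, max_evalue = 1e-6) {
  if (!is.numeric(max_evalue) || length(max_evalue) != 1L || max_evalue <= 0) {
    stop("'max_evalue' must be a single positive number")
  }
  hits[hits$e_value < max_evalue, , drop = FALSE]
}

#' Density-based clustering of hits in identity-coverage space
#'
#' Clusters the hits of one coding sequence by DBSCAN on the points
#' (percent identity, query coverage) with Euclidean distance. Core points
#' have at least \code{min_points} neighbours within \code{eps} (the point
#' itself included); density-reachable points share a cluster label;
#' points reachable from no core point are labelled noise (0).
#'
#' The defaults (\code{eps = 5} percent units, \code{min_points = 3})
#' reflect that homologs of a conserved protein land within a few percent
#' identity/coverage of each other; both are exposed because they control
#' how aggressively distinct homolog groups are merged.
#'
#' @param hits data.frame of hits that all share one \code{query_id}, with
#'   numeric \code{identity} and \code{query_coverage} columns.
#' @param eps neighbourhood radius, percent units (> 0).
#' @param min_points minimum neighbourhood size for a core point (>= 1).
#' @return integer vector of cluster labels parallel to \code{hits};
#'   positive integers for clusters, 0 for noise.
#' @examples
#' h <- data.frame(query_id = "c1",
#'                 identity = c(90, 91, 90.5, 20, 21, 20.5),
#'                 query_coverage = c(95, 94, 95.5, 30, 31, 30.5))
#' clusterHits(h, eps = 5, min_points = 3)
#' @export
clusterHits <- function(hits, eps = 5.0, min_points = 3L) {
  if (eps <= 0) stop("'eps' must be positive")
  if (min_points < 1L) stop("'min_points' must be >= 1")
  n <- nrow(hits)
  if (n == 0L) return(integer(0))
  if ("query_id" %in% names(hits) &&
      length(unique(hits$query_id)) > 1L) {
    stop("clusterHits() expects hits of a single query; found ",
         length(unique(hits$query_id)), " query ids")
  }
  pts <- cbind(hits$identity, hits$query_coverage)
  d <- as.matrix(stats::dist(pts))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  isCore <- lengths(neighbors) >= min_points

  labels <- integer(n)       # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !isCore[i]) next
    cl <- cl + 1L
    # expand the cluster from core point i by density reachability
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      if (isCore[p]) {
        for (q in neighbors[[p]]) {
          if (labels[q] == 0L) labels[q] <- cl
          if (!visited[q]) {
            visited[q] <- TRUE
            if (isCore[q]) queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

# Index of the best hit: minimum e-value, ties by maximum bit score, then
# lexicographically smallest subject id.
.bestHitIndex <- function(hits) {
  order(hits$e_value, -hits$bit_score, hits$subject_id)[1]
}

#' Assign GO terms to a CDS from the cluster containing the best hit
#'
#' The best hit is the hit with the minimum e-value (ties broken by maximum
#' bit score, then lexicographically smallest subject id). The CDS receives
#' the union of GO terms of all subjects in the best hit's cluster. If the
#' best hit is a noise point it is treated as a singleton cluster and only
#' its own GO terms are assigned.
#'
#' @param hits data.frame of (already filtered) hits of one CDS.
#' @param labels integer cluster labels from [clusterHits()], parallel to
#'   \code{hits}.
#' @param subject_go named list mapping subject id to a character vector of
#'   GO ids (see [readSubjectGo()]).
#' @return sorted character vector of GO ids; empty for an empty hit table.
#' @export
assignGo <- function(hits, labels, subject_go) {
  if (nrow(hits) == 0L) return(character(0))
  if (length(labels) != nrow(hits)) {
    stop("'labels' must be parallel to 'hits'")
  }
  best <- .bestHitIndex(hits)
  members <- if (labels[best] == 0L) {
    hits$subject_id[best]
  } else {
    hits$subject_id[labels == labels[best]]
  }
  gos <- unlist(subject_go[members], use.names = FALSE)
  sort(unique(gos))
}

#' Merge Pfam-derived GO terms into a CDS GO set
#'
#' Adds the GO terms of every Pfam domain hit passing the strict e-value
#' filter to the homology-derived GO set; a union, so an added Pfam hit can
#' never remove a term.
#'
#' @param cds_go character vector of GO ids from [assignGo()].
#' @param pfam_hits data.frame with columns \code{e_value} and a list
#'   column \code{go} (see [readPfamHits()]); may have zero rows.
#' @param max_evalue positive threshold, strict inequality.
#' @return sorted character vector of GO ids.
#' @export
mergePfamGo <- function(cds_go, pfam_hits, max_evalue = 1e-6) {
  if (max_evalue <= 0) stop("'max_evalue' must be positive")
  extra <- character(0)
  if (!is.null(pfam_hits) && nrow(pfam_hits)) {
    pass <- pfam_hits$e_value < max_evalue
    extra <- unlist(pfam_hits$go[pass], use.names = FALSE)
  }
  sort(unique(c(cds_go, extra)))
}

#' Map a GO set to EC numbers
#'
#' Returns the union of EC numbers mapped from every GO term present in the
#' mapping; GO terms absent from the mapping contribute nothing. Partial EC
#' numbers (any field \code{"-"}) are dropped so that downstream uEC counts
#' are counts of fully specified enzymes.
#'
#' @param go_set character vector of GO ids.
#' @param mapping named list GO id -> character vector of EC strings (see
#'   [readEc2Go()]).
#' @return sorted character vector of fully specified EC numbers.
#' @examples
#' mapGoToEc(c("GO:0000001"), list("GO:0000001" = c("1.1.1.1", "1.1.1.-")))
#' @export
mapGoToEc <- function(go_set, mapping) {
  ecs <- as.character(unlist(mapping[go_set[go_set %in% names(mapping)]],
                             use.names = FALSE))
  ecs <- ecs[isValidEc(ecs)]
  sort(unique(ecs))
}

#' Annotate a strain: homology hits to an EC profile
#'
#' Runs the full per-CDS annotation-transfer pipeline: e-value filtering,
#' DBSCAN clustering in identity-coverage space, GO assignment from the
#' best hit's cluster, union with Pfam-derived GO terms, and GO-to-EC
#' mapping. The strain's EC profile is the union of the per-CDS EC sets.
#'
#' @param hits data.frame of hits (all CDS of the strain), as from
#'   [readBlastHits()] or [generateHitTable()]\code{$hits}.
#' @param subject_go named list subject id -> GO ids.
#' @param pfam_hits optional data.frame of Pfam hits with a
#'   \code{query_id} column (see [readPfamHits()]); \code{NULL} for none.
#' @param mapping named list GO id -> EC strings; \code{NULL} to skip EC
#'   mapping (GO-level results only).
#' @param strain_id identifier for the resulting profile.
#' @param species optional species label.
#' @param n_genes total number of predicted genes; defaults to the number
#'   of distinct CDS seen in \code{hits} (and Pfam hits, if any).
#' @param max_evalue e-value threshold (strict), applied to both homology
#'   and Pfam hits.
#' @param eps,min_points DBSCAN parameters, see [clusterHits()].
#' @return a list with elements \code{profile} ([ECProfile-class]),
#'   \code{perCds} (named list with \code{go} and \code{ec} per CDS),
#'   \code{n_genes}, \code{n_ec_annotated_genes} and
#'   \code{annotation_rate}.
#' @export
annotateStrain <- function(hits, subject_go, pfam_hits = NULL, mapping = NULL,
                           strain_id = "strain", species = NA_character_,
                           n_genes = NULL, max_evalue = 1e-6,
                           eps = 5.0, min_points = 3L) {
  allCds <- unique(c(hits$query_id,
                     if (!is.null(pfam_hits)) pfam_hits$query_id))
  if (is.null(n_genes)) n_genes <- length(allCds)
  kept <- filterHits(hits, max_evalue)

  perCds <- lapply(allCds, function(q) {
    h <- kept[kept$query_id == q, , drop = FALSE]
    go <- assignGo(h, clusterHits(h, eps = eps, min_points = min_points),
                   subject_go)
    if (!is.null(pfam_hits)) {
      pf <- pfam_hits[pfam_hits$query_id == q, , drop = FALSE]
      go <- mergePfamGo(go, pf, max_evalue)
    }
    ec <- if (is.null(mapping)) character(0) else mapGoToEc(go, mapping)
    list(go = go, ec = ec)
  })
  names(perCds) <- allCds

  strainEc <- sort(unique(unlist(lapply(perCds, `[[`, "ec"),
                                 use.names = FALSE)))
  nAnn <- sum(vapply(perCds, function(x) length(x$ec) > 0L, logical(1)))
  list(
    profile = ECProfile(strain_id, strainEc, entityKind = "strain",
                        species = species),
    perCds = perCds,
    n_genes = n_genes,
    n_ec_annotated_genes = nAnn,
    annotation_rate = if (n_genes > 0L) nAnn / n_genes else 0
  )
}

#' Annotate a strain from files on disk
#'
#' File-based wrapper around [annotateStrain()]: reads a BLAST tabular hit
#' table, a subject-to-GO TSV, an optional Pfam TSV and an ec2go mapping.
#'
#' @param hit_file BLAST tabular file (13-column dialect, or 12-column with
#'   \code{queryLengths}).
#' @param subject_go_file subject-to-GO TSV.
#' @param pfam_file optional Pfam TSV; \code{NULL} for none.
#' @param ec2go_file optional ec2go mapping file; \code{NULL} for none.
#' @param queryLengths see [readBlastHits()].
#' @param ... passed on to [annotateStrain()].
#' @return see [annotateStrain()].
#' @export
annotateStrainFiles <- function(hit_file, subject_go_file, pfam_file = NULL,
                                ec2go_file = NULL, queryLengths = NULL, ...) {
  hits <- readBlastHits(hit_file, queryLengths = queryLengths)
  sg <- readSubjectGo(subject_go_file)
  pf <- if (!is.null(pfam_file)) readPfamHits(pfam_file) else NULL
  map <- if (!is.null(ec2go_file)) readEc2Go(ec2go_file) else NULL
  annotateStrain(hits, sg, pfam_hits = pf, mapping = map, ...)
}
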