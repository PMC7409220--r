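#' Read and write EC profiles as one-EC-per-line text
#'
#' The exchange format for EC repertoires is a plain text file with one
#' fully specified EC number per line; the entity id defaults to the file
#' name without extension.
#'
#' @param path file path.
#' @param entityId entity identifier; default: file name sans extension.
#' @param entityKind \code{"strain"}, \code{"microbiome"} or
#'   \code{"aggregate"}.
#' @param species optional species label.
#' @return an [ECProfile-class].
#' @export
readEcProfile <- function(path, entityId = NULL, entityKind = "strain",
                          species = NA_character_) {
  if (is.null(entityId)) {
    entityId <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- which(!isValidEc(lines))
  if (length(bad)) {
    stop("invalid EC number in ", path, " at line ", bad[1], ": ", lines[bad[1]])
  }
  ECProfile(entityId, lines, entityKind = entityKind, species = species)
}

#' @rdname readEcProfile
#' @param profile an [ECProfile-class] to write.
#' @export
writeEcProfile <- function(profile, path) {
  writeLines(ecSet(profile), path)
  invisible(path)
}

#' Read homology hits in BLAST tabular format
#'
#' Accepts the 13-column dialect (standard outfmt-6 columns qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore,
#' plus query coverage appended as column 13). A pure 12-column file is also
#' accepted when \code{queryLengths} is supplied, in which case query
#' coverage is computed as \code{100 * length / query_length}.
#'
#' @param path file path to a tab-separated hit table without header.
#' @param queryLengths optional named numeric vector mapping query ids to
#'   query lengths (required for 12-column input).
#' @return data.frame with columns query_id, subject_id, identity,
#'   query_coverage, e_value, bit_score.
#' @export
readBlastHits <- function(path, queryLengths = NULL) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) stop("cannot parse BLAST tabular file ", path, ": ",
                             conditionMessage(e)))
  if (!ncol(tab) %in% c(12L, 13L)) {
    stop("BLAST tabular file ", path, " must have 12 or 13 columns, found ",
         ncol(tab))
  }
  numCols <- c(3, 11, 12, if (ncol(tab) == 13L) 13)
  for (j in numCols) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1]
      stop("malformed row in ", path, " at line ", bad,
           ": non-numeric value in column ", j)
    }
  }
  if (ncol(tab) == 13L) {
    qcov <- tab[[13]]
  } else {
    if (is.null(queryLengths)) {
      stop("12-column BLAST file ", path,
           " requires 'queryLengths' to derive query coverage")
    }
    ql <- queryLengths[as.character(tab[[1]])]
    if (anyNA(ql)) {
      stop("query length missing for ",
           tab[[1]][which(is.na(ql))[1]], " in ", path)
    }
    qcov <- 100 * tab[[4]] / as.numeric(ql)
  }
  data.frame(query_id = as.character(tab[[1]]),
             subject_id = as.character(tab[[2]]),
             identity = tab[[3]],
             query_coverage = qcov,
             e_value = tab[[11]],
             bit_score = tab[[12]],
             stringsAsFactors = FALSE)
}

#' @rdname readBlastHits
#' @param hits data.frame as returned by [readBlastHits()] or
#'   [generateHitTable()].
#' @export
writeBlastHits <- function(hits, path) {
  n <- nrow(hits)
  # Unused outfmt-6 columns are filled with placeholder alignment geometry.
  out <- data.frame(hits$query_id, hits$subject_id,
                    round(hits$identity, 3), 100L, 0L, 0L, 1L, 100L, 1L, 100L,
                    format(hits$e_value, scientific = TRUE, digits = 4),
                    round(hits$bit_score, 1),
                    round(hits$query_coverage, 3))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subject-to-GO annotation table
#'
#' Tab-separated, no header: subject id, then semicolon-joined GO ids.
#'
#' @param path file path.
#' @return named list mapping subject id to character vector of GO ids.
#' @export
readSubjectGo <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("subject-GO table ", path, " needs two columns")
  gos <- strsplit(as.character(tab[[2]]), ";", fixed = TRUE)
  gos <- lapply(gos, function(g) {
    g <- trimws(g)
    g[nzchar(g)]
  })
  stats::setNames(gos, as.character(tab[[1]]))
}

#' Read Pfam domain hits
#'
#' Tab-separated, no header: query id, Pfam accession, e-value,
#' semicolon-joined GO ids (possibly empty).
#'
#' @param path file path.
#' @return data.frame with columns query_id, pfam_id, e_value, go (list
#'   column of character vectors).
#' @export
readPfamHits <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fill = TRUE)
  if (ncol(tab) < 3L) stop("Pfam table ", path, " needs >= 3 columns")
  ev <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(ev)) {
    stop("malformed row in ", path, " at line ", which(is.na(ev))[1],
         ": non-numeric e-value")
  }
  goCol <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    rep("", nrow(tab))
  go <- lapply(strsplit(goCol, ";", fixed = TRUE), function(g) {
    g <- trimws(g)
    g[nzchar(g)]
  })
  out <- data.frame(query_id = as.character(tab[[1]]),
                    pfam_id = as.character(tab[[2]]),
                    e_value = ev, stringsAsFactors = FALSE)
  out$go <- go
  out
}

#' Read a GO-to-EC mapping in the ec2go text dialect
#'
#' Lines of the form \code{"GO:0004022 > EC:1.1.1.1"}; comment lines start
#' with \code{"!"}. A GO term may map to several EC numbers (one per line).
#' Partial EC numbers (any field \code{"-"}) are retained in the returned
#' map but dropped later by [mapGoToEc()].
#'
#' @param path file path.
#' @return named list mapping GO id to character vector of EC strings.
#' @export
readEc2Go <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines,
                  regexec("^(GO:[0-9]{7})\\s*>\\s*EC:([0-9.\\-]+)\\s*$", lines))
  bad <- which(lengths(m) == 0L)
  if (length(bad)) {
    stop("malformed ec2go line in ", path, ": ", lines[bad[1]])
  }
  go <- vapply(m, `[`, character(1), 2L)
  ec <- vapply(m, `[`, character(1), 3L)
  split(ec, go)
}

#' Read and write superpathways as JSON
#'
#' The pathway exchange format is a JSON array of objects
#' \code{{pathway_id, name, taxonomic_range, reactions: [{reaction_id,
#' ec: [...]}, ...]}}.
#'
#' @param path file path.
#' @return list of [Superpathway-class].
#' @export
readPathwayJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    Superpathway(
      pathwayId = p$pathway_id,
      name = if (!is.null(p$name)) p$name else p$pathway_id,
      reactionIds = vapply(p$reactions, function(r) r$reaction_id,
                           character(1)),
      reactionEc = lapply(p$reactions, function(r)
        as.character(unlist(r$ec))),
      taxonomicRange = as.character(unlist(p$taxonomic_range)))
  })
}

#' @rdname readPathwayJson
#' @param pathways list of [Superpathway-class] to write.
#' @export
writePathwayJson <- function(pathways, path) {
  out <- lapply(pathways, function(p) {
    list(pathway_id = p@pathwayId, name = p@name,
         taxonomic_range = p@taxonomicRange,
         reactions = lapply(seq_along(p@reactionIds), function(i) {
           list(reaction_id = p@reactionIds[i], ec = p@reactionEc[[i]])
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a numeric matrix as TSV with a header row and row-name column
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
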