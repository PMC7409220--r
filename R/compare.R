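#' Compute a selection statistic on the pan-genome of a strain set
#'
#' Either the pan uEC count (number of distinct EC numbers in the union) or
#' the mean superpathway coverage of the pan profile over a pathway set.
#'
#' @param profiles non-empty list of [ECProfile-class] objects.
#' @param statistic \code{"pan_uec_count"} or
#'   \code{"pan_mean_pathway_coverage"}.
#' @param pathways list of [Superpathway-class]; required for the coverage
#'   statistic.
#' @param denominator see [pathwayCoverage()].
#' @return a single number.
#' @export
panStatistic <- function(profiles,
                         statistic = c("pan_uec_count",
                                       "pan_mean_pathway_coverage"),
                         pathways = NULL,
                         denominator = c("all", "annotated")) {
  statistic <- match.arg(statistic)
  denominator <- match.arg(denominator)
  pan <- panGenome(profiles)
  if (statistic == "pan_uec_count") {
    uec(pan)
  } else {
    if (is.null(pathways)) {
      stop("'pathways' is required for the coverage statistic")
    }
    mean(vapply(pathways, pathwayCoverage, numeric(1), profile = pan,
                denominator = denominator))
  }
}

# Flatten a pathway list into an indexed structure for fast repeated
# coverage evaluation: reaction -> indices into the EC vocabulary.
.pathwayIndex <- function(pathways, denominator) {
  ecVocab <- unique(unlist(lapply(pathways, function(p) p@reactionEc),
                           use.names = FALSE))
  rid <- integer(0)   # global reaction index per EC occurrence
  eci <- integer(0)   # EC vocabulary index per occurrence
  pwy <- integer(0)   # pathway index per reaction
  nReact <- integer(length(pathways))
  rCounter <- 0L
  for (pi in seq_along(pathways)) {
    p <- pathways[[pi]]
    nr <- length(p@reactionEc)
    if (denominator == "all") {
      nReact[pi] <- nr
    } else {
      nReact[pi] <- sum(lengths(p@reactionEc) > 0L)
    }
    for (ri in seq_len(nr)) {
      rCounter <- rCounter + 1L
      pwy[rCounter] <- pi
      ecs <- p@reactionEc[[ri]]
      if (length(ecs)) {
        rid <- c(rid, rep.int(rCounter, length(ecs)))
        eci <- c(eci, match(ecs, ecVocab))
      }
    }
  }
  list(ecVocab = ecVocab, rid = rid, eci = eci, pwy = pwy,
       nReact = nReact, totalReactions = rCounter)
}

# Mean pathway coverage from a logical membership vector over the EC
# vocabulary, using a precomputed index.
.coverageFromMembership <- function(member, idx) {
  hit <- member[idx$eci]
  matchedReactions <- tabulate(idx$rid[hit], nbins = idx$totalReactions) > 0L
  perPwy <- tabulate(idx$pwy[which(matchedReactions)],
                     nbins = length(idx$nReact))
  mean(ifelse(idx$nReact > 0L, perPwy / idx$nReact, 0))
}

#' Null distribution of a selection statistic under random strain choice
#'
#' Draws \code{n_reps} independent random selections of \code{k} distinct
#' strains (sampling without replacement within each replicate, uniformly,
#' without regard to species), forms each selection's pan-genome, and
#' computes the chosen statistic. The replicate values define the null
#' against which an observed (e.g. stratified, one-strain-per-species)
#' selection is compared via [normalPValue()].
#'
#' @param profiles list of strain [ECProfile-class] objects.
#' @param k selection size per replicate (<= number of strains).
#' @param n_reps number of replicates (>= 2; default 1000).
#' @param statistic \code{"pan_uec_count"} or
#'   \code{"pan_mean_pathway_coverage"}.
#' @param pathways pathway list, required for the coverage statistic.
#' @param seed integer RNG seed; replicates are deterministic per seed.
#' @param denominator see [pathwayCoverage()].
#' @return a [BootstrapResult-class] with the observed value unset.
#' @export
randomSelectionNull <- function(profiles, k, n_reps = 1000L,
                                statistic = c("pan_uec_count",
                                              "pan_mean_pathway_coverage"),
                                pathways = NULL, seed = 1L,
                                denominator = c("all", "annotated")) {
  statistic <- match.arg(statistic)
  denominator <- match.arg(denominator)
  n <- length(profiles)
  if (k > n) stop("'k' exceeds the number of strains (", k, " > ", n, ")")
  if (k < 1L) stop("'k' must be >= 1")
  if (n_reps < 2L) stop("'n_reps' must be >= 2 (sd undefined otherwise)")
  sets <- lapply(profiles, ecSet)

  useCoverage <- statistic == "pan_mean_pathway_coverage"
  if (useCoverage) {
    if (is.null(pathways)) {
      stop("'pathways' is required for the coverage statistic")
    }
    idx <- .pathwayIndex(pathways, denominator)
    setIdx <- lapply(sets, function(s) {
      m <- match(s, idx$ecVocab)
      m[!is.na(m)]
    })
    nVocab <- length(idx$ecVocab)
  }

  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_reps), function(r) {
    sel <- sample.int(n, k)
    if (useCoverage) {
      member <- logical(nVocab)
      member[unlist(setIdx[sel], use.names = FALSE)] <- TRUE
      .coverageFromMembership(member, idx)
    } else {
      length(unique(unlist(sets[sel], use.names = FALSE)))
    }
  }, numeric(1))

  new("BootstrapResult",
      nReps = as.integer(n_reps), k = as.integer(k),
      statisticName = statistic, replicateValues = reps,
      nullMean = mean(reps), nullSd = stats::sd(reps),
      observed = NA_real_, zScore = NA_real_, pValue = NA_real_,
      alternative = "greater", seed = as.integer(seed))
}

#' Normal-approximation p-value for an observed selection statistic
#'
#' Standardizes the observed value against the resampling null
#' (\code{z = (observed - null mean) / null sd}) and reports the standard
#' normal tail probability. The default is one-sided upper-tail, testing
#' whether the observed selection scores significantly higher than random
#' selections; two-sided and lower-tail alternatives are available.
#'
#' @param result a [BootstrapResult-class] from [randomSelectionNull()].
#' @param observed observed value of the statistic.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return the completed [BootstrapResult-class] with observed, z-score and
#'   p-value filled in.
#' @export
normalPValue <- function(result, observed,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.na(result@nullSd) || result@nullSd == 0) {
    stop("degenerate null: null sd is zero, z-score undefined")
  }
  z <- (observed - result@nullMean) / result@nullSd
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  result@observed <- as.numeric(observed)
  result@zScore <- z
  result@pValue <- min(p, 1)
  result@alternative <- alternative
  validObject(result)
  result
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Rank-sum U statistic for the first sample with midrank handling of ties:
#' \code{U} counts the pairs (a, b) with a > b, ties counting one half.
#' When both samples have at most \code{exact_max} observations the
#' two-sided p-value is computed by full enumeration of all assignments of
#' the pooled ranks; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact_max enumerate exactly when both sample sizes are at most
#'   this (default 8).
#' @return list with elements \code{U} (for \code{sample_a}), \code{p}
#'   (two-sided), and \code{method} (\code{"exact"} or \code{"normal"}).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, complete separation
#' @export
mannWhitneyU <- function(sample_a, sample_b, exact_max = 8L) {
  if (length(sample_a) < 1L || length(sample_b) < 1L) {
    stop("both samples must be non-empty")
  }
  na <- length(sample_a)
  nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  uFromRanks <- function(ra, n1) sum(ra) - n1 * (n1 + 1) / 2
  U <- uFromRanks(r[seq_len(na)], na)
  mu <- na * nb / 2

  if (na <= exact_max && nb <= exact_max) {
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2L, function(ix) uFromRanks(r[ix], na))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- na + nb
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tieCorr))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sigma  # continuity correction
      z <- max(z, 0)
      p <- min(2 * stats::pnorm(z, lower.tail = FALSE), 1)
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Mean of percentages with nearest-integer reporting
#'
#' Arithmetic mean of percentage values; by default rounded to the nearest
#' integer for reporting (x.5 rounds up), matching how aggregate
#' percentages are typically quoted. Set \code{round = FALSE} for the raw
#' mean.
#'
#' @param values non-empty numeric vector of percentages.
#' @param round round the result to the nearest integer (default TRUE).
#' @return a single number.
#' @examples
#' meanPercentage(c(92, 87, 87, 90))  # 89
#' meanPercentage(c(31, 8, 6, 24))    # mean 17.25 -> 17
#' @export
meanPercentage <- function(values, round = TRUE) {
  if (length(values) < 1L) stop("need at least one value")
  m <- mean(values)
  if (round) floor(m + 0.5) else m
}

#' Assemble the full comparison report
#'
#' Runs the headline comparisons of a culture collection against a set of
#' microbiomes in one pass: per-entity uEC counts; pan/core summaries for
#' the collection, the (stratified) selection and the microbiomes;
#' cross-coverage and gain tables; per-entity superpathway coverage
#' summaries; the top-variance pathway ranking across the microbiomes;
#' row/column dendrograms of the coverage matrix (as Newick strings); and
#' bootstrap null results with one-sided p-values for both selection
#' statistics.
#'
#' @param collection list of strain [ECProfile-class] (the QC-filtered
#'   collection).
#' @param selection_ids character vector of strain ids forming the
#'   selection (e.g. from [selectBestPerSpecies()]).
#' @param microbiomes list of microbiome [ECProfile-class].
#' @param pathways list of [Superpathway-class].
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param denominator see [pathwayCoverage()].
#' @param topK pathways in the variance ranking (default 15).
#' @return a nested list (the report); see [writeReport()].
#' @export
buildReport <- function(collection, selection_ids, microbiomes, pathways,
                        n_reps = 1000L, seed = 1L,
                        denominator = c("all", "annotated"), topK = 15L) {
  denominator <- match.arg(denominator)
  ids <- vapply(collection, entityId, character(1))
  missing <- setdiff(selection_ids, ids)
  if (length(missing)) {
    stop("selection ids absent from the collection: ",
         paste(missing, collapse = ", "))
  }
  if (length(microbiomes) < 1L) stop("missing input: microbiome profiles")
  if (length(pathways) < 1L) stop("missing input: pathways")
  selection <- collection[match(selection_ids, ids)]
  k <- length(selection)

  selPan <- panGenome(selection, "selection_pan")
  selCore <- coreGenome(selection, "selection_core")
  collPan <- panGenome(collection, "collection_pan")
  collCore <- coreGenome(collection, "collection_core")
  mbPan <- panGenome(microbiomes, "microbiome_pan")
  mbCore <- coreGenome(microbiomes, "microbiome_core")

  mbIds <- vapply(microbiomes, entityId, character(1))
  covSel <- vapply(microbiomes, function(m) crossCoverage(selPan, m),
                   numeric(1))
  covColl <- vapply(microbiomes, function(m) crossCoverage(collPan, m),
                    numeric(1))
  gains <- vapply(microbiomes, function(m) gainIfAdded(selPan, m),
                  numeric(1))
  crossTable <- data.frame(
    microbiome = mbIds,
    selection_pan_coverage = covSel,
    collection_pan_coverage = covColl,
    gain_from_selection = gains,
    stringsAsFactors = FALSE)

  entities <- c(selection, microbiomes, list(selPan, collPan, mbPan))
  cm <- coverageMatrix(entities, pathways, denominator = denominator)
  covSummary <- summarizeCoverage(cm)
  topVar <- topVariancePathways(cm, mbIds, k = min(topK, length(pathways)))

  dendRows <- dendrogramNewick(hierarchicalCluster(cm, "rows"))
  dendCols <- dendrogramNewick(hierarchicalCluster(cm, "columns"))

  obsUec <- panStatistic(selection, "pan_uec_count")
  obsCov <- panStatistic(selection, "pan_mean_pathway_coverage",
                         pathways = pathways, denominator = denominator)
  nullUec <- randomSelectionNull(collection, k, n_reps, "pan_uec_count",
                                 seed = seed)
  nullUec <- normalPValue(nullUec, obsUec)
  nullCov <- randomSelectionNull(collection, k, n_reps,
                                 "pan_mean_pathway_coverage",
                                 pathways = pathways, seed = seed + 1L,
                                 denominator = denominator)
  nullCov <- normalPValue(nullCov, obsCov)

  brSummary <- function(b) {
    list(statistic = b@statisticName, n_reps = b@nReps, k = b@k,
         null_mean = b@nullMean, null_sd = b@nullSd,
         observed = b@observed, z_score = b@zScore, p_value = b@pValue,
         alternative = b@alternative, seed = b@seed)
  }

  allProfiles <- c(collection, microbiomes)
  list(
    entities = data.frame(
      entity_id = vapply(allProfiles, entityId, character(1)),
      entity_kind = vapply(allProfiles, entityKind, character(1)),
      species = vapply(allProfiles, speciesLabel, character(1)),
      uec = vapply(allProfiles, uec, integer(1)),
      stringsAsFactors = FALSE),
    selection_ids = selection_ids,
    aggregates = data.frame(
      aggregate = c("selection_pan", "selection_core", "collection_pan",
                    "collection_core", "microbiome_pan", "microbiome_core"),
      uec = c(uec(selPan), uec(selCore), uec(collPan), uec(collCore),
              uec(mbPan), uec(mbCore)),
      stringsAsFactors = FALSE),
    cross_coverage = crossTable,
    mean_selection_coverage = meanPercentage(covSel),
    mean_collection_coverage = meanPercentage(covColl),
    mean_gain = meanPercentage(gains),
    coverage_summary = covSummary,
    top_variance_pathways = topVar,
    dendrogram_entities = dendRows,
    dendrogram_pathways = dendCols,
    bootstrap = list(pan_uec_count = brSummary(nullUec),
                     pan_mean_pathway_coverage = brSummary(nullCov))
  )
}

#' Write and read a comparison report as JSON
#'
#' @param report list from [buildReport()].
#' @param path output path.
#' @return \code{writeReport} returns \code{path} invisibly;
#'   \code{readReport} returns the report list with its tables restored as
#'   data.frames.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
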