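#' Configuration for the synthetic community generator
#'
#' Bundles the parameters of the synthetic-data generator, which emulates a
#' culture collection of sequenced strains (small, species-structured EC
#' repertoires) and a set of metagenomes (large EC repertoires with a tunable
#' overlap against the strain universe). Defaults are chosen at the scale of
#' a dairy culture collection compared against human gut metagenomes: strain
#' uEC counts land in the high hundreds to low thousands, microbiome uEC
#' counts around 1400--1800, with 89\% of microbiome ECs drawn from the
#' strain pan-genome.
#'
#' @param seed integer RNG seed.
#' @param n_ec_universe number of distinct EC strings in the universe.
#' @param n_species number of species in the collection.
#' @param strains_per_species strains simulated per species (single count).
#' @param species_core_size mean number of ECs shared by all strains of a
#'   species.
#' @param accessory_size mean number of strain-specific accessory ECs.
#' @param n_microbiomes number of metagenome profiles.
#' @param microbiome_size mean EC count per microbiome.
#' @param overlap_fraction target fraction of each microbiome's ECs drawn
#'   from the union of all strain ECs, in [0, 1].
#' @param strain_pool_fraction fraction of the universe from which strain
#'   ECs (cores and accessories) are drawn. The remainder of the universe
#'   is reachable only by microbiomes, guaranteeing that the out-of-pan
#'   fraction \code{1 - overlap_fraction} can actually be realized even
#'   when many strains jointly saturate their pool.
#' @param n_pathways number of synthetic superpathways.
#' @param pathway_size_range integer length-2 vector: min/max reactions per
#'   pathway.
#' @param frac_unannotated_reactions fraction of reactions carrying an empty
#'   EC set, in [0, 1].
#' @param qc_violation_fraction fraction of strains whose metadata violates
#'   each quality-control filter (scaffold count, BUSCO completeness,
#'   exclusion flag), so that filter tests are non-vacuous.
#' @param duplicate_fraction fraction of strains assigned to re-sequencing
#'   duplicate groups.
#' @return a named list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, n_species = 3, strains_per_species = 2)
#' @export
syntheticConfig <- function(seed = 1L,
                            n_ec_universe = 5000L,
                            n_species = 24L,
                            strains_per_species = 5L,
                            species_core_size = 800L,
                            accessory_size = 150L,
                            n_microbiomes = 4L,
                            microbiome_size = 1600L,
                            overlap_fraction = 0.89,
                            strain_pool_fraction = 0.6,
                            n_pathways = 190L,
                            pathway_size_range = c(5L, 40L),
                            frac_unannotated_reactions = 0.15,
                            qc_violation_fraction = 0.1,
                            duplicate_fraction = 0.1) {
  counts <- c(n_ec_universe = n_ec_universe, n_species = n_species,
              strains_per_species = strains_per_species,
              species_core_size = species_core_size,
              accessory_size = accessory_size,
              n_microbiomes = n_microbiomes,
              microbiome_size = microbiome_size,
              n_pathways = n_pathways)
  if (any(counts <= 0)) {
    stop("all counts must be positive; offending: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  }
  fracs <- c(overlap_fraction = overlap_fraction,
             frac_unannotated_reactions = frac_unannotated_reactions,
             qc_violation_fraction = qc_violation_fraction,
             duplicate_fraction = duplicate_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]; offending: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (strain_pool_fraction <= 0 || strain_pool_fraction > 1) {
    stop("'strain_pool_fraction' must lie in (0, 1]")
  }
  if (species_core_size + accessory_size > n_ec_universe) {
    stop("species_core_size + accessory_size exceeds the EC universe size")
  }
  if (species_core_size + accessory_size >
      floor(strain_pool_fraction * n_ec_universe)) {
    stop("species_core_size + accessory_size exceeds the strain EC pool ",
         "(strain_pool_fraction * n_ec_universe)")
  }
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[1] < 1L) {
    stop("'pathway_size_range' must be c(min, max) with 1 <= min <= max")
  }
  structure(list(
    seed = as.integer(seed),
    n_ec_universe = as.integer(n_ec_universe),
    n_species = as.integer(n_species),
    strains_per_species = as.integer(strains_per_species),
    species_core_size = as.integer(species_core_size),
    accessory_size = as.integer(accessory_size),
    n_microbiomes = as.integer(n_microbiomes),
    microbiome_size = as.integer(microbiome_size),
    overlap_fraction = overlap_fraction,
    strain_pool_fraction = strain_pool_fraction,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    frac_unannotated_reactions = frac_unannotated_reactions,
    qc_violation_fraction = qc_violation_fraction,
    duplicate_fraction = duplicate_fraction
  ), class = "SyntheticConfig")
}

#' Generate a universe of distinct syntactically valid EC numbers
#'
#' EC strings are sampled as syntactically valid 4-field codes without any
#' attempt to mimic real EC class frequencies: only set identity matters
#' downstream.
#'
#' @param n number of distinct EC strings (>= 1).
#' @param seed integer RNG seed; output is deterministic per seed.
#' @return character vector of \code{n} pairwise-distinct EC strings.
#' @examples
#' generateEcUniverse(5, seed = 7)
#' @export
generateEcUniverse <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a single count >= 1")
  }
  n <- as.integer(n)
  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(as.integer(seed))
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- paste(sample(1:7, 2L * need + 10L, replace = TRUE),
                  sample(1:30, 2L * need + 10L, replace = TRUE),
                  sample(1:30, 2L * need + 10L, replace = TRUE),
                  sample(1:400, 2L * need + 10L, replace = TRUE),
                  sep = ".")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# Save / restore .Random.seed so generators are deterministic per their own
# seed without clobbering the caller's RNG stream.
.saveRng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restoreRng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Poisson draw with a floor of 1, used for "mean count" config fields.
.rsize <- function(n, mean) pmax(1L, stats::rpois(n, mean))

#' Generate strain and microbiome EC profiles with metadata
#'
#' Strains of one species share a species core EC set and differ only in
#' accessory ECs; microbiomes are large EC sets with an expected fraction
#' \code{overlap_fraction} of members inside the strain pan-genome. Metadata
#' carries scaffold counts, BUSCO completeness, gene counts and annotation
#' counts, with a configurable fraction of strains violating each
#' quality-control filter.
#'
#' @param config a [syntheticConfig()] object.
#' @return a list with elements \code{strains} (list of [ECProfile-class]),
#'   \code{microbiomes} (list of [ECProfile-class]), \code{metadata}
#'   (data.frame: strain_id, species, n_scaffolds, busco_completeness,
#'   excluded_flag, duplicate_group, n_genes, n_ec_annotated_genes), and
#'   \code{universe} (the EC universe used).
#' @examples
#' sim <- generateProfiles(syntheticConfig(seed = 1, n_species = 2,
#'   strains_per_species = 2, species_core_size = 20, accessory_size = 5,
#'   microbiome_size = 50, n_ec_universe = 200))
#' length(sim$strains)
#' @export
generateProfiles <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  universe <- generateEcUniverse(config$n_ec_universe, seed = config$seed)
  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(config$seed + 1L)

  strainPool <- universe[seq_len(floor(config$strain_pool_fraction *
                                       length(universe)))]
  nSp <- config$n_species
  nStr <- config$strains_per_species
  strains <- vector("list", nSp * nStr)
  speciesNames <- sprintf("species_%02d", seq_len(nSp))
  idx <- 0L
  for (s in seq_len(nSp)) {
    coreSize <- .rsize(1L, config$species_core_size)
    if (coreSize + config$accessory_size > length(strainPool)) {
      stop("requested species core + accessory exceeds the strain EC pool")
    }
    core <- sample(strainPool, coreSize)
    rest <- setdiff(strainPool, core)
    for (t in seq_len(nStr)) {
      accSize <- min(.rsize(1L, config$accessory_size), length(rest))
      acc <- sample(rest, accSize)
      idx <- idx + 1L
      strains[[idx]] <- ECProfile(
        sprintf("%s_strain_%02d", speciesNames[s], t),
        c(core, acc), entityKind = "strain", species = speciesNames[s])
    }
  }

  pan <- sort(unique(unlist(lapply(strains, ecSet), use.names = FALSE)))
  outsidePool <- setdiff(universe, pan)
  microbiomes <- vector("list", config$n_microbiomes)
  for (m in seq_len(config$n_microbiomes)) {
    size <- .rsize(1L, config$microbiome_size)
    nIn <- stats::rbinom(1L, size, config$overlap_fraction)
    if (config$overlap_fraction >= 1) nIn <- size
    if (config$overlap_fraction <= 0) nIn <- 0L
    nIn <- min(nIn, length(pan))
    nOut <- min(size - nIn, length(outsidePool))
    if (nIn + nOut < 1L) {
      stop("microbiome size infeasible: universe pools exhausted")
    }
    ecs <- c(sample(pan, nIn), if (nOut > 0L) sample(outsidePool, nOut))
    microbiomes[[m]] <- ECProfile(sprintf("MB%04d", m), ecs,
                                  entityKind = "microbiome")
  }

  nTot <- length(strains)
  vio <- function() stats::runif(nTot) < config$qc_violation_fraction
  highScaffold <- vio()
  lowBusco <- vio()
  excluded <- vio()
  nScaf <- ifelse(highScaffold,
                  sample(501:1500, nTot, replace = TRUE),
                  sample(10:500, nTot, replace = TRUE))
  busco <- ifelse(lowBusco,
                  stats::runif(nTot, 60, 89.9),
                  stats::runif(nTot, 90, 100))
  nGenes <- vapply(strains, function(p) {
    # gene count loosely proportional to repertoire size plus scatter
    as.integer(round(uec(p) * 2.2 + stats::rnorm(1, 0, 60)))
  }, integer(1))
  nGenes <- pmax(nGenes, vapply(strains, uec, integer(1)))
  nAnn <- vapply(seq_along(strains), function(i) {
    rate <- stats::runif(1, 0.45, 0.75)
    min(nGenes[i], as.integer(round(rate * nGenes[i])))
  }, integer(1))

  dupGroup <- rep(NA_character_, nTot)
  nDupPairs <- floor(config$duplicate_fraction * nTot / 2)
  if (nDupPairs > 0L) {
    pick <- sample(nTot, 2L * nDupPairs)
    dupGroup[pick] <- rep(sprintf("dup%03d", seq_len(nDupPairs)), each = 2L)
  }

  metadata <- data.frame(
    strain_id = vapply(strains, entityId, character(1)),
    species = vapply(strains, speciesLabel, character(1)),
    n_scaffolds = nScaf,
    busco_completeness = busco,
    excluded_flag = excluded,
    duplicate_group = dupGroup,
    n_genes = nGenes,
    n_ec_annotated_genes = nAnn,
    stringsAsFactors = FALSE
  )
  list(strains = strains, microbiomes = microbiomes, metadata = metadata,
       universe = universe)
}

#' Generate synthetic superpathways over an EC universe
#'
#' Each pathway draws a reaction count uniformly from
#' \code{pathway_size_range}; each reaction independently carries an empty EC
#' set with probability \code{frac_unannotated_reactions}, otherwise 1--3 ECs
#' sampled from the universe.
#'
#' @param universe character vector of EC numbers (non-empty).
#' @param config a [syntheticConfig()] object.
#' @return list of [Superpathway-class] objects, length
#'   \code{config$n_pathways}.
#' @examples
#' u <- generateEcUniverse(50, seed = 2)
#' pws <- generatePathways(u, syntheticConfig(seed = 2, n_pathways = 3))
#' @export
generatePathways <- function(universe, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (length(universe) < 1L) stop("EC universe must be non-empty")
  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(config$seed + 2L)
  lapply(seq_len(config$n_pathways), function(p) {
    nr <- sample(seq(config$pathway_size_range[1],
                     config$pathway_size_range[2]), 1L)
    ecs <- lapply(seq_len(nr), function(r) {
      if (stats::runif(1) < config$frac_unannotated_reactions) {
        character()
      } else {
        sample(universe, sample(1:3, 1L))
      }
    })
    Superpathway(sprintf("PWY%04d", p),
                 reactionIds = sprintf("PWY%04d_R%03d", p, seq_len(nr)),
                 reactionEc = ecs,
                 name = sprintf("synthetic pathway %d", p))
  })
}

#' Generate a planted-truth homology hit table
#'
#' For each coding sequence (CDS), hits form well-separated isotropic
#' Gaussian blobs in (percent identity, query coverage) space, truncated to
#' [0, 100]^2, plus uniform noise points. Each blob carries a blob-specific
#' GO label set; the blob containing the globally lowest e-value hit is
#' recorded as the planted truth. E-values span both sides of the usual 1e-6
#' filtering threshold: a fraction of each blob's hits is assigned failing
#' e-values.
#'
#' @param n_cds number of CDS.
#' @param clusters_per_cds blobs per CDS.
#' @param noise_points uniform noise hits per CDS.
#' @param seed integer RNG seed.
#' @param hits_per_cluster hits per blob.
#' @param blob_sd standard deviation of each blob, percent units.
#' @param min_separation minimum Euclidean distance between blob centres,
#'   percent units; keep well above the DBSCAN \code{eps} so blobs are
#'   provably separable.
#' @param frac_failing_evalue fraction of hits per blob given an e-value
#'   above the filter threshold.
#' @return a list with elements \code{hits} (data.frame with columns
#'   query_id, subject_id, identity, query_coverage, e_value, bit_score),
#'   \code{subject_go} (data.frame subject_id, go_terms
#'   [semicolon-joined]), and \code{truth} (named list: per CDS, the GO set
#'   of the blob holding the best passing hit).
#' @examples
#' fx <- generateHitTable(2, clusters_per_cds = 2, noise_points = 1, seed = 3)
#' head(fx$hits)
#' @export
generateHitTable <- function(n_cds, clusters_per_cds = 3L, noise_points = 2L,
                             seed = 1L, hits_per_cluster = 6L,
                             blob_sd = 1.0, min_separation = 25,
                             frac_failing_evalue = 0.2) {
  if (n_cds < 0 || clusters_per_cds < 0 || noise_points < 0) {
    stop("counts must be non-negative")
  }
  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(as.integer(seed))

  # Fixed lattice of candidate centres with pairwise distance >= 25; stay
  # away from the [0,100] boundary so truncation cannot merge blobs.
  grid <- expand.grid(x = seq(15, 90, by = 25), y = seq(15, 90, by = 25))
  if (clusters_per_cds > nrow(grid)) {
    stop("too many clusters per CDS for the available well-separated centres")
  }

  rows <- list()
  subjGo <- list()
  truth <- list()
  subjCounter <- 0L
  for (cds in seq_len(n_cds)) {
    qid <- sprintf("cds_%04d", cds)
    centres <- grid[sample(nrow(grid), clusters_per_cds), , drop = FALSE]
    blobGo <- lapply(seq_len(clusters_per_cds), function(b) {
      sprintf("GO:%07d", sample(1:9999999, sample(1:3, 1L)))
    })
    bestEv <- Inf
    bestBlob <- NA_integer_
    for (b in seq_len(clusters_per_cds)) {
      nPass <- hits_per_cluster -
        stats::rbinom(1L, hits_per_cluster, frac_failing_evalue)
      nPass <- max(nPass, 1L)  # every blob keeps at least one passing hit
      for (h in seq_len(hits_per_cluster)) {
        subjCounter <- subjCounter + 1L
        sid <- sprintf("sp|P%06d", subjCounter)
        passing <- h <= nPass
        ev <- if (passing) 10^stats::runif(1, -60, -8) else
          10^stats::runif(1, -5, 2)
        ident <- min(100, max(0, stats::rnorm(1, centres$x[b], blob_sd)))
        qcov <- min(100, max(0, stats::rnorm(1, centres$y[b], blob_sd)))
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, subject_id = sid, identity = ident,
          query_coverage = qcov, e_value = ev,
          bit_score = stats::runif(1, 50, 500), stringsAsFactors = FALSE)
        subjGo[[length(subjGo) + 1L]] <- data.frame(
          subject_id = sid, go_terms = paste(blobGo[[b]], collapse = ";"),
          stringsAsFactors = FALSE)
        if (passing && ev < bestEv) {
          bestEv <- ev
          bestBlob <- b
        }
      }
    }
    for (np in seq_len(noise_points)) {
      if (noise_points == 0L) break
      subjCounter <- subjCounter + 1L
      sid <- sprintf("sp|P%06d", subjCounter)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = sid,
        identity = stats::runif(1, 0, 100),
        query_coverage = stats::runif(1, 0, 100),
        e_value = 10^stats::runif(1, -5, 2),  # noise hits fail the filter
        bit_score = stats::runif(1, 20, 60), stringsAsFactors = FALSE)
      subjGo[[length(subjGo) + 1L]] <- data.frame(
        subject_id = sid, go_terms = sprintf("GO:%07d", sample(1:9999999, 1L)),
        stringsAsFactors = FALSE)
    }
    truth[[qid]] <- if (clusters_per_cds > 0L && is.finite(bestEv)) {
      sort(blobGo[[bestBlob]])
    } else {
      character()
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), subject_id = character(),
               identity = numeric(), query_coverage = numeric(),
               e_value = numeric(), bit_score = numeric())
  sg <- if (length(subjGo)) do.call(rbind, subjGo) else
    data.frame(subject_id = character(), go_terms = character())
  list(hits = hits, subject_go = sg, truth = truth)
}

#' Write a synthetic dataset to disk in the pipeline's exchange formats
#'
#' Emits strain and microbiome EC profiles (one EC per line, file name =
#' entity id), a metadata TSV, a pathway JSON, 13-column BLAST tabular hit
#' tables, a subject-to-GO TSV, and a planted-truth JSON.
#'
#' @param sim result of [generateProfiles()].
#' @param pathways result of [generatePathways()].
#' @param hitFixture optional result of [generateHitTable()].
#' @param dir output directory (created if absent).
#' @return invisibly, the output directory.
#' @export
writeSyntheticData <- function(sim, pathways = NULL, hitFixture = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profDir <- file.path(dir, "profiles")
  dir.create(profDir, showWarnings = FALSE)
  for (p in c(sim$strains, sim$microbiomes)) {
    writeEcProfile(p, file.path(profDir, paste0(entityId(p), ".txt")))
  }
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathways)) {
    writePathwayJson(pathways, file.path(dir, "pathways.json"))
  }
  if (!is.null(hitFixture)) {
    writeBlastHits(hitFixture$hits, file.path(dir, "hits.tsv"))
    utils::write.table(hitFixture$subject_go, file.path(dir, "subject_go.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(hitFixture$truth, file.path(dir, "truth.json"))
  }
  invisible(dir)
}
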