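#' Default species exclusion list
#'
#' Species excluded from the dairy culture collection analysis because they
#' are irrelevant to dairy product development (cheese-rind specialists, a
#' likely raw-milk contaminant, and the disease-associated genus Listeria).
#' Shipped as a documented default for [filterStrains()]; any analysis can
#' supply its own list.
#'
#' @return character vector of seven species names.
#' @export
defaultExcludedSpecies <- function() {
  c("Brevibacterium linens",
    "Corynebacterium variabilis",
    "Desemzia incerta",
    "Glutamicibacter arilaitensis",
    "Anaerosphaera aminiphila",
    "Listeria monocytogenes",
    "Listeria innocua")
}

#' Quality-control filtering of strain assemblies
#'
#' Removes flagged strains (legal restriction, strain mixtures, uncertain
#' taxonomy), assemblies with more than \code{max_scaffolds} scaffolds or
#' less than \code{min_busco} percent BUSCO single-copy completeness (both
#' comparisons strict: a strain at exactly 500 scaffolds and exactly 90
#' percent is retained), strains of excluded species, and re-sequencing
#' duplicates. Within each duplicate group exactly one strain is kept: the
#' better assembly, defined as fewest scaffolds, ties broken by highest
#' BUSCO completeness, then by strain id ascending.
#'
#' @param metadata data.frame with columns strain_id, species, n_scaffolds,
#'   busco_completeness, excluded_flag, duplicate_group (NA for
#'   non-duplicates).
#' @param excluded_species character vector of species to drop; defaults to
#'   [defaultExcludedSpecies()].
#' @param max_scaffolds scaffold-count threshold (strict "more than").
#' @param min_busco BUSCO threshold in percent (strict "less than").
#' @return character vector of retained strain ids, in metadata order.
#' @export
filterStrains <- function(metadata,
                          excluded_species = defaultExcludedSpecies(),
                          max_scaffolds = 500L, min_busco = 90) {
  keep <- !metadata$excluded_flag &
    metadata$n_scaffolds <= max_scaffolds &
    metadata$busco_completeness >= min_busco &
    !metadata$species %in% excluded_species
  md <- metadata[keep, , drop = FALSE]

  hasDup <- !is.na(md$duplicate_group)
  if (any(hasDup)) {
    drop <- unlist(lapply(split(seq_len(nrow(md))[hasDup],
                                md$duplicate_group[hasDup]), function(ix) {
      ord <- order(md$n_scaffolds[ix], -md$busco_completeness[ix],
                   md$strain_id[ix])
      ix[ord[-1]]
    }), use.names = FALSE)
    if (length(drop)) md <- md[-drop, , drop = FALSE]
  }
  md$strain_id
}

.checkProfiles <- function(profiles) {
  if (length(profiles) < 1L) stop("at least one profile is required")
  ok <- vapply(profiles, is, logical(1), "ECProfile")
  if (!all(ok)) stop("all elements must be ECProfile objects")
}

#' Pan-genome of a set of EC profiles
#'
#' The pan-genome (here, of enzymatic functions) is the set of EC numbers
#' present in any of the given strains or microbiomes: the union of their
#' EC sets.
#'
#' @param profiles non-empty list of [ECProfile-class] objects.
#' @param entityId id for the aggregate profile.
#' @return an [ECProfile-class] of kind \code{"aggregate"}.
#' @examples
#' panGenome(list(ECProfile("a", "1.1.1.1"), ECProfile("b", "2.2.2.2")))
#' @export
panGenome <- function(profiles, entityId = "pan") {
  .checkProfiles(profiles)
  ECProfile(entityId,
            unique(unlist(lapply(profiles, ecSet), use.names = FALSE)),
            entityKind = "aggregate")
}

#' Core-genome of a set of EC profiles
#'
#' The set of EC numbers that occur in all of the given strains or
#' microbiomes: the intersection of their EC sets.
#'
#' @inheritParams panGenome
#' @return an [ECProfile-class] of kind \code{"aggregate"}.
#' @export
coreGenome <- function(profiles, entityId = "core") {
  .checkProfiles(profiles)
  core <- Reduce(intersect, lapply(profiles, ecSet))
  ECProfile(entityId, core, entityKind = "aggregate")
}

#' Cross-coverage of one EC repertoire by another
#'
#' The percentage of the target's EC numbers also present in the source:
#' \code{100 * |source intersect target| / |target|}. Used e.g. to ask what
#' fraction of a microbiome's enzymatic repertoire a strain selection's
#' pan-genome covers.
#'
#' @param source,target [ECProfile-class] objects; \code{target} non-empty.
#' @return percentage in [0, 100].
#' @examples
#' crossCoverage(ECProfile("s", c("1.1.1.1", "2.2.2.2")),
#'               ECProfile("t", c("2.2.2.2", "3.3.3.3", "4.4.4.4")))
#' @export
crossCoverage <- function(source, target) {
  tset <- ecSet(target)
  if (length(tset) == 0L) {
    stop("coverage of an empty target is undefined")
  }
  100 * length(intersect(ecSet(source), tset)) / length(tset)
}

#' Relative uEC gain if a profile were added to a base repertoire
#'
#' The percentage of new EC numbers the addition would contribute,
#' relative to the base's size: \code{100 * |addition \\ base| / |base|}.
#'
#' @param addition,base [ECProfile-class] objects; \code{base} non-empty.
#' @return percentage >= 0.
#' @export
gainIfAdded <- function(addition, base) {
  bset <- ecSet(base)
  if (length(bset) == 0L) stop("gain relative to an empty base is undefined")
  100 * length(setdiff(ecSet(addition), bset)) / length(bset)
}

#' Pairwise shared-uEC matrix
#'
#' Symmetric matrix of pairwise intersection sizes over a list of profiles;
#' the diagonal carries each entity's own uEC count.
#'
#' @param profiles non-empty list of [ECProfile-class] objects.
#' @return symmetric integer matrix with entity ids as dimnames.
#' @export
sharedUecMatrix <- function(profiles) {
  .checkProfiles(profiles)
  n <- length(profiles)
  ids <- vapply(profiles, entityId, character(1))
  sets <- lapply(profiles, ecSet)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- length(sets[[i]])
    if (i < n) {
      for (j in seq((i + 1L), n)) {
        v <- length(intersect(sets[[i]], sets[[j]]))
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Two-set Venn partition of EC repertoires
#'
#' @param a,b [ECProfile-class] objects.
#' @return named integer vector \code{c(only_a, shared, only_b)}; the three
#'   disjoint region sizes sum to the union size.
#' @export
vennPartition <- function(a, b) {
  sa <- ecSet(a)
  sb <- ecSet(b)
  c(only_a = length(setdiff(sa, sb)),
    shared = length(intersect(sa, sb)),
    only_b = length(setdiff(sb, sa)))
}

#' Select the strain with the most unique EC numbers per species
#'
#' For each species, picks the member strain maximizing the uEC count, with
#' ties broken by strain id ascending. This is the stratified "one
#' representative strain per species" selection heuristic.
#'
#' @param profiles list of strain [ECProfile-class] objects with species
#'   labels.
#' @return named list of [ECProfile-class], one per distinct species, named
#'   by species, ordered by species name.
#' @export
selectBestPerSpecies <- function(profiles) {
  .checkProfiles(profiles)
  sp <- vapply(profiles, speciesLabel, character(1))
  if (anyNA(sp)) stop("all profiles must carry a species label")
  groups <- split(profiles, sp)
  out <- lapply(groups, function(g) {
    uecs <- vapply(g, uec, integer(1))
    ids <- vapply(g, entityId, character(1))
    g[[order(-uecs, ids)[1]]]
  })
  out[order(names(out))]
}
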