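# Independent brute-force oracles and small fixture builders used across
# the suite. These re-derive expected values from first principles and
# must stay independent of the package implementations they check.

# Brute-force DBSCAN: core points = rows with >= min_points neighbours
# within eps (self included). Clusters are the connected components of
# core points under the eps-graph, numbered by their lowest core index;
# border points take the smallest label among their core neighbours;
# everything else is noise (0).
oracleDbscan <- function(pts, eps, min_points) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(pts))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- which(lengths(nb) >= min_points)
  labels <- integer(n)
  if (length(core)) {
    # connected components of cores via repeated expansion
    comp <- rep(NA_integer_, n)
    cl <- 0L
    for (c0 in core) {
      if (!is.na(comp[c0])) next
      cl <- cl + 1L
      frontier <- c0
      comp[c0] <- cl
      while (length(frontier)) {
        nxt <- unique(unlist(nb[frontier]))
        nxt <- nxt[nxt %in% core & is.na(comp[nxt])]
        comp[nxt] <- cl
        frontier <- nxt
      }
    }
    labels[core] <- comp[core]
    for (i in setdiff(seq_len(n), core)) {
      coreNb <- intersect(nb[[i]], core)
      if (length(coreNb)) labels[i] <- min(comp[coreNb])
    }
  }
  labels
}

# A hit table wrapper around 2-d points for clusterHits().
pointsAsHits <- function(pts, query_id = "q1") {
  data.frame(query_id = query_id, identity = pts[, 1],
             query_coverage = pts[, 2], stringsAsFactors = FALSE)
}

# Random EC-profile fixture over a small alphabet of valid EC strings.
randomProfiles <- function(n, alphabetSize = 40, minSize = 1,
                           maxSize = 25, kind = "strain") {
  alphabet <- paste0(rep(1:7, length.out = alphabetSize), ".",
                     rep(1:8, length.out = alphabetSize), ".1.",
                     seq_len(alphabetSize))
  lapply(seq_len(n), function(i) {
    ECProfile(sprintf("p%03d", i),
              sample(alphabet, sample(minSize:maxSize, 1)),
              entityKind = kind,
              species = if (kind == "strain") sprintf("sp%d", i %% 3 + 1)
                        else NA_character_)
  })
}

# Direct (pair-counting) Mann-Whitney U for sample a, ties count 1/2.
oracleU <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all ways to
# split the pooled values into the two groups.
oracleMwuExactP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  combs <- combn(length(pooled), na)
  mu <- na * length(b) / 2
  uObs <- oracleU(a, b)
  us <- apply(combs, 2, function(ix) oracleU(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# In-memory view of a subject-GO data.frame as the named list the
# annotation functions consume.
subjectGoAsList <- function(df) {
  setNames(lapply(strsplit(df$go_terms, ";", fixed = TRUE), trimws),
           df$subject_id)
}

# Small deterministic metadata table exercising every QC filter branch.
qcMetadataFixture <- function() {
  data.frame(
    strain_id = sprintf("s%02d", 1:8),
    species = c("A", "A", "B", "B", "C", "C", "D", "Excludedus spp"),
    n_scaffolds = c(100L, 500L, 501L, 200L, 150L, 200L, 300L, 50L),
    busco_completeness = c(95, 90, 99, 89.9, 91, 95, 97, 99),
    excluded_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    duplicate_group = c(NA, NA, NA, NA, "g1", "g1", NA, NA),
    n_genes = rep(1000L, 8),
    n_ec_annotated_genes = rep(600L, 8),
    stringsAsFactors = FALSE
  )
}
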