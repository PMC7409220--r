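test_that("e-value filtering is strict, order-preserving and idempotent", {
  h <- data.frame(query_id = "q", subject_id = sprintf("s%d", 1:10),
                  identity = 50, query_coverage = 50,
                  e_value = c(1e-10, 1e-6, 2e-7, 0.5, 1e-8, 10,
                              1e-3, 9.9e-7, 1, 100),
                  bit_score = 100, stringsAsFactors = FALSE)
  out <- filterHits(h, 1e-6)
  # the hit at exactly the threshold is excluded
  expect_identical(out$subject_id, c("s1", "s3", "s5", "s8"))
  expect_identical(filterHits(out, 1e-6), out)
  expect_identical(nrow(filterHits(h[0, ], 1e-6)), 0L)
  expect_error(filterHits(h, 0), "positive")
})

test_that("DBSCAN handles trivial and degenerate configurations", {
  one <- pointsAsHits(matrix(c(50, 50), 1))
  expect_identical(clusterHits(one, eps = 5, min_points = 1), 1L)

  # two tight blobs far apart: two clusters, no noise
  pts <- rbind(cbind(10 + runif(5), 10 + runif(5)),
               cbind(80 + runif(5), 80 + runif(5)))
  lab <- clusterHits(pointsAsHits(pts), eps = 5, min_points = 3)
  expect_identical(sort(unique(lab)), c(1L, 2L))
  expect_identical(lab[1:5], rep(1L, 5))
  expect_identical(lab[6:10], rep(2L, 5))

  # all isolated points with min_points = 2: all noise
  iso <- pointsAsHits(cbind(seq(0, 100, by = 20), seq(0, 100, by = 20)))
  expect_identical(clusterHits(iso, eps = 5, min_points = 2),
                   rep(0L, nrow(iso)))

  mixed <- data.frame(query_id = c("a", "b"), identity = 1,
                      query_coverage = 1)
  expect_error(clusterHits(mixed), "single query")
})

test_that("DBSCAN agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(1:30, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    eps <- runif(1, 2, 30)
    mp <- sample(1:5, 1)
    expect_identical(clusterHits(pointsAsHits(pts), eps, mp),
                     oracleDbscan(pts, eps, mp),
                     info = sprintf("instance %d (n=%d eps=%.2f mp=%d)",
                                    i, n, eps, mp))
  }
})

test_that("GO assignment takes the union over the best hit's cluster", {
  sg <- list(s1 = "GO:0000001", s2 = "GO:0000002", s3 = "GO:0000003")
  h <- data.frame(query_id = "q", subject_id = c("s1", "s2", "s3"),
                  identity = c(90, 91, 20), query_coverage = c(90, 91, 20),
                  e_value = c(1e-50, 1e-10, 1e-40), bit_score = 100,
                  stringsAsFactors = FALSE)
  lab <- c(1L, 1L, 2L)
  expect_identical(assignGo(h, lab, sg), c("GO:0000001", "GO:0000002"))

  # best hit labelled noise: only its own GO terms
  labNoise <- c(0L, 1L, 1L)
  expect_identical(assignGo(h, labNoise, sg), "GO:0000001")

  expect_identical(assignGo(h[0, ], integer(0), sg), character(0))
})

test_that("best-hit tie-breaking uses bit score then subject id", {
  sg <- list(s1 = "GO:0000001", s2 = "GO:0000002", s0 = "GO:0000003")
  h <- data.frame(query_id = "q", subject_id = c("s1", "s2", "s0"),
                  identity = 50, query_coverage = 50,
                  e_value = c(1e-10, 1e-10, 1e-10),
                  bit_score = c(200, 300, 300), stringsAsFactors = FALSE)
  # ties on e-value: s2 and s0 share the top bit score, s0 sorts first
  expect_identical(assignGo(h, c(1L, 2L, 3L), sg), "GO:0000003")
})

test_that("Pfam GO merging is a strict-threshold union", {
  pf <- data.frame(query_id = "q", pfam_id = c("PF1", "PF2"),
                   e_value = c(1e-8, 1e-6), stringsAsFactors = FALSE)
  pf$go <- list("GO:0000002", "GO:0000009")
  out <- mergePfamGo("GO:0000001", pf, 1e-6)
  # PF2 sits exactly at the threshold and is not merged
  expect_identical(out, c("GO:0000001", "GO:0000002"))
  expect_identical(mergePfamGo(c("GO:0000001"), pf[0, ], 1e-6),
                   "GO:0000001")
  # monotonicity: merging never removes a term
  expect_true(all(c("GO:0000001") %in% out))
})

test_that("GO-to-EC mapping unions full ECs and drops partial ones", {
  map <- list("GO:0000001" = "1.1.1.1",
              "GO:0000002" = character(0),
              "GO:0000003" = c("1.1.1.-", "2.2.2.2"))
  expect_identical(mapGoToEc(character(0), map), character(0))
  expect_identical(mapGoToEc(c("GO:0000001", "GO:0000002"), map), "1.1.1.1")
  expect_identical(mapGoToEc("GO:0000003", map), "2.2.2.2")
  expect_identical(mapGoToEc("GO:9999999", map), character(0))
  # a term mapping only to a partial EC contributes nothing
  expect_identical(mapGoToEc("GO:0000004",
                             list("GO:0000004" = "1.1.1.-")), character(0))
})

test_that("planted GO truth is recovered from well-separated hit blobs", {
  fx <- generateHitTable(50, clusters_per_cds = 3, noise_points = 2,
                         seed = 21)
  sg <- subjectGoAsList(fx$subject_go)
  kept <- filterHits(fx$hits, 1e-6)
  hit <- vapply(names(fx$truth), function(q) {
    h <- kept[kept$query_id == q, , drop = FALSE]
    go <- assignGo(h, clusterHits(h, eps = 5, min_points = 3), sg)
    identical(go, fx$truth[[q]])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("strain annotation composes the per-CDS pipeline correctly", {
  fx <- generateHitTable(15, clusters_per_cds = 2, noise_points = 1,
                         seed = 31)
  sg <- subjectGoAsList(fx$subject_go)
  # map every planted GO term to a unique EC so truth lifts to EC level
  allGo <- sort(unique(unlist(c(fx$truth, sg))))
  map <- setNames(lapply(seq_along(allGo), function(i)
    sprintf("%d.%d.%d.%d", i %% 7 + 1, i %% 9 + 1, i %% 5 + 1, i)),
    allGo)
  res <- annotateStrain(fx$hits, sg, mapping = map, strain_id = "st1")
  expect_s4_class(res$profile, "ECProfile")
  # strain EC set equals the union of per-CDS EC sets
  expect_identical(ecSet(res$profile),
                   sort(unique(unlist(lapply(res$perCds, `[[`, "ec")))))
  expect_lte(res$n_ec_annotated_genes, res$n_genes)
  expect_gte(res$annotation_rate, 0)
  expect_lte(res$annotation_rate, 1)
  # truth ECs for each CDS are contained in that CDS's assignment
  truthEc <- lapply(fx$truth, function(gos) {
    sort(unique(unlist(map[gos])))
  })
  hit <- vapply(names(truthEc), function(q) {
    identical(res$perCds[[q]]$ec, truthEc[[q]])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("a strain with no passing hits gets an empty profile and rate 0", {
  h <- data.frame(query_id = "q1", subject_id = "s1", identity = 50,
                  query_coverage = 50, e_value = 0.1, bit_score = 50,
                  stringsAsFactors = FALSE)
  res <- annotateStrain(h, list(s1 = "GO:0000001"),
                        mapping = list("GO:0000001" = "1.1.1.1"))
  expect_identical(uec(res$profile), 0L)
  expect_identical(res$annotation_rate, 0)
})

test_that("adding a Pfam hit never removes an EC from a CDS", {
  set.seed(77)
  map <- list("GO:0000001" = "1.1.1.1", "GO:0000002" = "2.2.2.2",
              "GO:0000003" = "3.3.3.3")
  for (i in 1:20) {
    baseGo <- sample(names(map), sample(0:3, 1))
    pf <- data.frame(query_id = "q", pfam_id = "PF1",
                     e_value = 10^runif(1, -12, -1),
                     stringsAsFactors = FALSE)
    pf$go <- list(sample(names(map), 1))
    before <- mapGoToEc(baseGo, map)
    after <- mapGoToEc(mergePfamGo(baseGo, pf, 1e-6), map)
    expect_true(all(before %in% after))
  }
})
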