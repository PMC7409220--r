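test_that("random-selection null has correct degenerate and deterministic behaviour", {
  set.seed(1)
  ps <- randomProfiles(4)
  # k = n: every replicate is the full pan-genome, sd collapses to 0
  b <- randomSelectionNull(ps, k = 4, n_reps = 10, seed = 2)
  expect_s4_class(b, "BootstrapResult")
  expect_equal(nullSd(b), 0)
  expect_equal(unique(replicateValues(b)), uec(panGenome(ps)))

  b1 <- randomSelectionNull(ps, k = 2, n_reps = 20, seed = 3)
  b2 <- randomSelectionNull(ps, k = 2, n_reps = 20, seed = 3)
  expect_identical(replicateValues(b1), replicateValues(b2))
  b3 <- randomSelectionNull(ps, k = 2, n_reps = 20, seed = 4)
  expect_false(identical(replicateValues(b1), replicateValues(b3)))

  expect_error(randomSelectionNull(ps, k = 5, n_reps = 10), "exceeds")
  expect_error(randomSelectionNull(ps, k = 2, n_reps = 1), "n_reps")
})

test_that("null replicates never exceed the collection pan uEC count", {
  set.seed(5)
  ps <- randomProfiles(8)
  b <- randomSelectionNull(ps, k = 3, n_reps = 100, seed = 6)
  expect_true(all(replicateValues(b) <= uec(panGenome(ps))))
})

test_that("null mean matches exhaustive subset enumeration on 4 choose 2", {
  set.seed(7)
  ps <- randomProfiles(4, minSize = 5, maxSize = 20)
  exact <- combn(4, 2, function(ix) uec(panGenome(ps[ix])))
  b <- randomSelectionNull(ps, k = 2, n_reps = 10000, seed = 8)
  se <- sd(exact) * sqrt(5 / 6) / sqrt(10000)  # population sd of the 6 subsets
  expect_lt(abs(nullMean(b) - mean(exact)), 3 * se)
  # every replicate value is one of the six attainable subset values
  expect_true(all(replicateValues(b) %in% exact))
})

test_that("coverage-statistic null agrees with direct panStatistic evaluation", {
  set.seed(9)
  ps <- randomProfiles(5)
  alphabet <- unique(unlist(lapply(ps, ecSet)))
  pws <- lapply(1:4, function(i) {
    Superpathway(sprintf("PW%d", i), sprintf("PW%d_R%d", i, 1:4),
                 lapply(1:4, function(r) {
                   if (r == 1) character() else sample(alphabet, 2)
                 }))
  })
  b <- randomSelectionNull(ps, k = 5, n_reps = 5,
                           statistic = "pan_mean_pathway_coverage",
                           pathways = pws, seed = 10)
  direct <- panStatistic(ps, "pan_mean_pathway_coverage", pathways = pws)
  expect_equal(unique(replicateValues(b)), direct)
  expect_error(randomSelectionNull(ps, k = 2, n_reps = 5,
                                   statistic = "pan_mean_pathway_coverage"),
               "pathways")
})

test_that("normal p-values match the standard normal tail", {
  set.seed(11)
  ps <- randomProfiles(6)
  b <- randomSelectionNull(ps, k = 3, n_reps = 200, seed = 12)
  atMean <- normalPValue(b, nullMean(b))
  expect_equal(pValue(atMean), 0.5)
  at2se <- normalPValue(b, nullMean(b) + 1.959964 * nullSd(b))
  expect_equal(pValue(at2se), 0.025, tolerance = 1e-5)

  # quadrature oracle on random z-scores
  for (z in c(-2.5, -0.3, 0.7, 1.9, 3.2)) {
    obs <- nullMean(b) + z * nullSd(b)
    p <- pValue(normalPValue(b, obs))
    quad <- integrate(dnorm, lower = z, upper = Inf,
                      rel.tol = 1e-12)$value
    expect_equal(p, quad, tolerance = 1e-9)
  }

  # monotonicity: p strictly decreases as the observed value increases
  obs <- nullMean(b) + seq(-2, 3, by = 0.5) * nullSd(b)
  pv <- vapply(obs, function(o) pValue(normalPValue(b, o)), numeric(1))
  expect_true(all(diff(pv) < 0))

  degenerate <- randomSelectionNull(ps, k = 6, n_reps = 5, seed = 13)
  expect_error(normalPValue(degenerate, 10), "degenerate")
})

test_that("two-sided and lower-tail alternatives are consistent", {
  set.seed(14)
  ps <- randomProfiles(6)
  b <- randomSelectionNull(ps, k = 3, n_reps = 100, seed = 15)
  obs <- nullMean(b) + 1.5 * nullSd(b)
  pg <- pValue(normalPValue(b, obs, "greater"))
  pl <- pValue(normalPValue(b, obs, "less"))
  pt <- pValue(normalPValue(b, obs, "two.sided"))
  expect_equal(pg + pl, 1)
  expect_equal(pt, 2 * pg)
})

test_that("Mann-Whitney U handles separation, ties and degenerate samples", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)

  same <- mannWhitneyU(5, 5)
  expect_equal(same$U, 0.5)
  expect_equal(same$p, 1)
})

test_that("exact Mann-Whitney p matches full enumeration at n = 4 vs 4", {
  set.seed(16)
  for (i in 1:10) {
    a <- sample(1:10, 4, replace = TRUE)
    b <- sample(1:10, 4, replace = TRUE)
    r <- mannWhitneyU(a, b)
    expect_identical(r$method, "exact")
    expect_equal(r$U, oracleU(a, b))
    expect_equal(r$p, oracleMwuExactP(a, b))
  }
})

test_that("large-sample Mann-Whitney agrees with the reference implementation", {
  set.seed(17)
  a <- rnorm(20, 0.5)
  b <- rnorm(15)
  r <- mannWhitneyU(a, b)
  expect_identical(r$method, "normal")
  w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)

  # with heavy ties
  a2 <- sample(1:4, 25, replace = TRUE)
  b2 <- sample(1:4, 25, replace = TRUE)
  r2 <- mannWhitneyU(a2, b2)
  w2 <- wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
  expect_equal(r2$p, w2$p.value, tolerance = 1e-10)
})

test_that("percentage means reproduce nearest-integer reporting", {
  expect_identical(meanPercentage(c(92, 87, 87, 90)), 89)
  expect_identical(meanPercentage(c(31, 8, 6, 24)), 17)  # 17.25 -> 17
  expect_identical(meanPercentage(42), 42)
  expect_equal(meanPercentage(c(1, 2), round = FALSE), 1.5)
  expect_identical(meanPercentage(c(17, 18)), 18)  # 17.5 rounds up
})

test_that("the report assembles self-consistent, recomputable tables", {
  cfg <- syntheticConfig(seed = 3, n_species = 4, strains_per_species = 3,
                         species_core_size = 80, accessory_size = 20,
                         n_microbiomes = 3, microbiome_size = 200,
                         n_ec_universe = 1000, n_pathways = 12)
  sim <- generateProfiles(cfg)
  pws <- generatePathways(sim$universe, cfg)
  sel <- selectBestPerSpecies(sim$strains)
  selIds <- vapply(sel, entityId, character(1))
  rep <- buildReport(sim$strains, selIds, sim$microbiomes, pws,
                     n_reps = 50, seed = 4)

  # independent recomputation of headline tables
  selPan <- panGenome(sim$strains[match(selIds,
    vapply(sim$strains, entityId, character(1)))])
  expect_equal(
    rep$aggregates$uec[rep$aggregates$aggregate == "selection_pan"],
    uec(selPan))
  covs <- vapply(sim$microbiomes, function(m) crossCoverage(selPan, m),
                 numeric(1))
  expect_equal(rep$cross_coverage$selection_pan_coverage, covs)
  expect_equal(rep$mean_selection_coverage, meanPercentage(covs))
  gains <- vapply(sim$microbiomes, function(m) gainIfAdded(selPan, m),
                  numeric(1))
  expect_equal(rep$mean_gain, meanPercentage(gains))

  # the observed statistic appears unchanged in the bootstrap summary
  expect_equal(rep$bootstrap$pan_uec_count$observed, uec(selPan))

  # coverage summary counts partition the pathway set
  cs <- rep$coverage_summary
  expect_true(all(cs$n_not_covered + cs$n_partial + cs$n_complete ==
                  length(pws)))

  expect_error(buildReport(sim$strains, "not_a_strain", sim$microbiomes,
                           pws, n_reps = 10), "absent")
  expect_error(buildReport(sim$strains, selIds, list(), pws, n_reps = 10),
               "missing input")
})

test_that("reports round-trip through JSON", {
  cfg <- syntheticConfig(seed = 6, n_species = 3, strains_per_species = 2,
                         species_core_size = 40, accessory_size = 10,
                         n_microbiomes = 2, microbiome_size = 100,
                         n_ec_universe = 600, n_pathways = 6)
  sim <- generateProfiles(cfg)
  pws <- generatePathways(sim$universe, cfg)
  selIds <- vapply(selectBestPerSpecies(sim$strains), entityId, character(1))
  rep <- buildReport(sim$strains, selIds, sim$microbiomes, pws,
                     n_reps = 20, seed = 7)
  f <- tempfile(fileext = ".json")
  writeReport(rep, f)
  back <- readReport(f)
  expect_equal(back$aggregates$uec, rep$aggregates$uec)
  expect_equal(back$cross_coverage$selection_pan_coverage,
               rep$cross_coverage$selection_pan_coverage)
  expect_equal(back$bootstrap$pan_uec_count$p_value,
               rep$bootstrap$pan_uec_count$p_value)
  expect_identical(back$dendrogram_entities, rep$dendrogram_entities)
})

test_that("stratified max-uEC selection beats the random null in direction", {
  hits <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    cfg <- syntheticConfig(seed = 100 + s, n_species = 5,
                           strains_per_species = 4, species_core_size = 80,
                           accessory_size = 30, n_microbiomes = 2,
                           microbiome_size = 200, n_ec_universe = 1500,
                           n_pathways = 5)
    sim <- generateProfiles(cfg)
    sel <- selectBestPerSpecies(sim$strains)
    obs <- panStatistic(sel, "pan_uec_count")
    b <- randomSelectionNull(sim$strains, k = length(sel), n_reps = 100,
                             seed = 100 + s)
    if (obs > nullMean(b)) hits <- hits + 1L
  }
  expect_gte(hits / nSeeds, 0.95)
})
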