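test_that("forward split separates cohorts by birth year", {
  ped <- data.frame(animal = paste0("a", 1:10),
                    birth_year = rep(2010:2014, each = 2))
  sp <- forwardSplit(ped, cutoffYear = 2014)
  expect_setequal(sp$valid, c("a9", "a10"))
  expect_setequal(sp$train, paste0("a", 1:8))
  expect_equal(length(sp$train) + length(sp$valid), 10)

  all14 <- data.frame(animal = c("x", "y"), birth_year = 2014)
  expect_error(forwardSplit(all14), "degenerate")
  expect_error(forwardSplit(ped, cutoffYear = 2009), "degenerate")
})

test_that("random k-fold assignment is balanced, covering, reproducible", {
  ids <- paste0("a", 1:10)
  folds <- randomKfold(ids, k = 5, seed = 3)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) length(f$valid), integer(1))
  expect_true(all(sizes == 2))
  expect_setequal(unlist(lapply(folds, `[[`, "valid")), ids)
  for (f in folds)
    expect_length(intersect(f$train, f$valid), 0)

  folds2 <- randomKfold(ids, k = 5, seed = 3)
  expect_identical(folds, folds2)
  expect_false(identical(folds, randomKfold(ids, k = 5, seed = 4)))

  # uneven n: sizes differ by at most one
  f11 <- randomKfold(paste0("b", 1:11), k = 5, seed = 1)
  s11 <- vapply(f11, function(f) length(f$valid), integer(1))
  expect_lte(diff(range(s11)), 1)

  expect_error(randomKfold(ids, k = 1), "at least 2")
  expect_error(randomKfold(ids[1:3], k = 5), "fewer")
})

test_that("k-means recovers separable breeds and honours restarts", {
  # founders of two well-diverged breeds, no admixture
  cfg <- simulationConfig(nBreeds = 2, founderFreqDivergence = 0.4,
                          nFoundersPerBreed = 60, nSnps = 1000,
                          seed = 66)
  f <- simulateFounders(cfg, seed = 66)
  G <- buildG(f$genotypes)
  S <- pcaOfG(G, 10)$scores
  lab <- kmeansClusters(S, k = 2, seed = 1)
  expect_equal(adjustedRandIndex(lab, f$breedLabels[names(lab)]), 1)

  # k = 1: single cluster
  lab1 <- kmeansClusters(S, k = 1, seed = 1)
  expect_true(all(lab1 == 1))

  # returned objective is no worse than single-restart solutions
  best <- attr(kmeansClusters(S, k = 3, seed = 2, nInit = 25),
               "tot.withinss")
  singles <- vapply(1:5, function(s)
    attr(kmeansClusters(S, k = 3, seed = s, nInit = 1),
         "tot.withinss"), numeric(1))
  expect_true(all(best <= singles + 1e-8))

  expect_error(kmeansClusters(S[1:3, ], k = 5), "more clusters")
})

test_that("hierarchical clustering recovers hand-checkable structure", {
  # two tight pairs: recovered under any linkage
  pts <- c(0, 0.1, 10, 10.1)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("a", 1:4), paste0("a", 1:4))
  dm <- DistanceMatrix(D, source = "EDM")
  for (link in c("complete", "average", "ward")) {
    lab <- hierarchicalClusters(dm, k = 2, linkage = link)
    expect_equal(lab[["a1"]], lab[["a2"]])
    expect_equal(lab[["a3"]], lab[["a4"]])
    expect_false(lab[["a1"]] == lab[["a3"]])
  }

  # k = n: singletons
  labn <- hierarchicalClusters(dm, k = 4)
  expect_length(unique(labn), 4)
  expect_error(hierarchicalClusters(dm, k = 5), "more clusters")

  # minSize exclusion
  lab2 <- hierarchicalClusters(dm, k = 2, minSize = 3)
  expect_true(all(is.na(lab2)))

  # an admixed composite population shows one dominant cluster plus
  # small satellites (the shape, not an exact size split)
  data <- fixtureData()
  DG <- genomicDistance(data$G0)
  labG <- hierarchicalClusters(DG, k = 5)
  sizes <- sort(table(labG), decreasing = TRUE)
  expect_gt(sizes[1] / sum(sizes), 0.35)
  expect_true(sum(sizes / sum(sizes) < 0.15) >= 2)
})

test_that("the scenario registry resolves all fourteen named designs", {
  reg <- scenarioRegistry()
  expect_setequal(names(reg),
                  c("GB0", "GB2PC", "GB4PC", "GB6PC", "GB10", "GB20",
                    "GBBP", "GBRCV", "GBKCV", "GBC", "K5G", "K10G",
                    "K5EDM", "K10EDM"))
  expect_equal(getScenario("GB10")@blendW, 0.10)
  expect_equal(getScenario("GB20")@blendW, 0.20)
  expect_equal(getScenario("GB4PC")@nPcs, 4L)
  expect_identical(getScenario("GBBP")@kernelKind, "GBBP")
  expect_identical(getScenario("GBKCV")@design, "kmeans_cv")
  expect_equal(getScenario("GBKCV")@k, 5L)
  expect_identical(getScenario("K10EDM")@distanceSource, "EDM")
  expect_error(getScenario("GB99"), "registry")
})

test_that("weighted mean accuracy is the record-weighted average", {
  expect_equal(weightedMeanAccuracy(c(0.2, 0.4), c(100, 300)), 0.35)
  expect_equal(weightedMeanAccuracy(c(0.2, 0.4), c(5, 5)), 0.3)
  expect_equal(weightedMeanAccuracy(0.7, 42), 0.7)
  expect_error(weightedMeanAccuracy(numeric(0), numeric(0)), "no group")
  expect_error(weightedMeanAccuracy(c(0.1, 0.2), c(1, 0)), "positive")
})

test_that("every scenario runs end to end on one bundle", {
  data <- fixtureData()
  all14 <- names(scenarioRegistry())
  rep <- runScenarios(all14, data, seed = 1L, minValid = 10L,
                      computeAccT = FALSE)
  rows <- reportRows(rep)
  expect_setequal(rows$scenario, all14)
  expect_equal(nrow(rows), 14)
  expect_true(all(is.finite(rows$accuracy)))
  expect_true(all(rows$n_valid > 10))
  expect_true(all(rows$alpha == (4 - rows$h2) / rows$h2))

  # forward scenarios share the identical split: same n_valid
  fwd <- rows[rows$scenario %in% c("GB0", "GB2PC", "GB10", "GBBP"), ]
  expect_equal(length(unique(fwd$n_valid)), 1)

  # reruns reproduce exactly (splits are (spec, seed)-deterministic)
  rep2 <- runScenario(getScenario("GBRCV", seed = 1L, minValid = 10L),
                      data, computeAccT = FALSE)
  expect_equal(reportRows(rep2)$accuracy,
               rows$accuracy[rows$scenario == "GBRCV"], tolerance = 1e-12)

  # the >150-type rule: with the default threshold this small population
  # has no retainable validation group
  expect_error(runScenario(getScenario("GB0"), data), "minimum size")
})

test_that("structured populations reproduce the qualitative accuracy
          ordering across validation designs", {
  nms <- c("GB0", "GBRCV", "GBKCV", "GBC")
  accs <- t(vapply(1:10, function(s) {
    cfg <- simulationConfig(nBreeds = 2, founderFreqDivergence = 0.3,
                            nFoundersPerBreed = 50, nSnps = 600,
                            nQtl = 150, heritability = 0.4,
                            seed = 1000 + s)
    pop <- simulatePopulation(cfg)
    data <- scenarioData(pop$genotypes, pop$pedigree, pop$phenotypes)
    vapply(nms, function(nm)
      reportRows(runScenario(getScenario(nm, seed = 1L, minValid = 10L),
                             data, computeAccT = FALSE))$accuracy,
      numeric(1))
  }, numeric(4)))
  colnames(accs) <- nms

  # random CV sits highest in the mean; within-cluster designs lose
  means <- colMeans(accs)
  expect_equal(names(which.max(means)), "GBRCV")
  expect_gt(means[["GB0"]], means[["GBKCV"]])

  # paired one-sided tests at alpha = 0.05 over the 10 seeds
  pRcvKcv <- t.test(accs[, "GBRCV"], accs[, "GBKCV"], paired = TRUE,
                    alternative = "greater")$p.value
  pRcvGbc <- t.test(accs[, "GBRCV"], accs[, "GBC"], paired = TRUE,
                    alternative = "greater")$p.value
  pGb0Gbc <- t.test(accs[, "GB0"], accs[, "GBC"], paired = TRUE,
                    alternative = "greater")$p.value
  expect_lt(pRcvKcv, 0.05)
  expect_lt(pRcvGbc, 0.05)
  expect_lt(pGb0Gbc, 0.05)
})

test_that("forward GB0 accuracy is consistent with the deterministic
          expectation at a pedigree-census Ne", {
  pop <- fixtureCal()
  data <- fixtureCalData()
  sp <- forwardSplit(pop$pedigree, cutoffYear = 2014,
                     ids = data$adj@ids)
  fit <- solveGblup(subsetAdjusted(data$adj, sp$train),
                    data$G0, data$vc, computeAccT = FALSE)
  r <- observedAccuracy(mbv(fit)[sp$valid],
                        adjustedValues(data$adj)[sp$valid],
                        heritability(data$vc))
  ne <- pedigreeNe(pop$pedigree)
  expect_gt(ne$ne, 100)                 # composite-scale population
  accE <- expectedAccuracy(length(sp$train), heritability(data$vc),
                           ne$ne)$accE
  expect_lt(abs(r - accE), 0.1)
})
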