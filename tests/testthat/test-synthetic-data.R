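test_that("founder simulation is deterministic and respects divergence", {
  cfg0 <- simulationConfig(nBreeds = 2, founderFreqDivergence = 0,
                           nFoundersPerBreed = 30, nSnps = 400, seed = 11)
  set.seed(11); f1 <- simulateFounders(cfg0)
  set.seed(11); f2 <- simulateFounders(cfg0)
  expect_identical(dosages(f1$genotypes), dosages(f2$genotypes))

  # no divergence: breed frequency differences centred at zero
  b1 <- f1$breedLabels == "breed1"
  p1 <- colMeans(dosages(f1$genotypes)[b1, ]) / 2
  p2 <- colMeans(dosages(f1$genotypes)[!b1, ]) / 2
  expect_identical(f1$breedFreqs[, 1], f1$breedFreqs[, 2])
  expect_lt(abs(mean(p1 - p2)), 0.01)

  expect_error(simulationConfig(nSnps = 0), "positive")
  expect_error(simulationConfig(nQtl = 50, nSnps = 10), "nQtl")
})

test_that("realized between-breed Fst tracks the configured divergence", {
  cfg <- simulationConfig(nBreeds = 2, founderFreqDivergence = 0.3,
                          nFoundersPerBreed = 100, nSnps = 2000,
                          seed = 12)
  f <- simulateFounders(cfg, seed = 12)
  d <- dosages(f$genotypes)
  b1 <- f$breedLabels == "breed1"
  n1 <- sum(b1); n2 <- sum(!b1)
  p1 <- colMeans(d[b1, ]) / 2
  p2 <- colMeans(d[!b1, ]) / 2
  # Hudson estimator, ratio of averages over SNPs
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- sum(num) / sum(den)
  expect_gt(fst, 0.3 * 0.8)
  expect_lt(fst, 0.3 * 1.2)
})

test_that("gene dropping is Mendelian and preserves allele frequencies", {
  cfg <- simulationConfig(nBreeds = 1, founderFreqDivergence = 0,
                          nFoundersPerBreed = 40, nSnps = 2000,
                          nQtl = 0, geneticVariance = 0, seed = 13)
  set.seed(13)
  f <- simulateFounders(cfg)
  ped <- simulatePedigree(cfg, f$sex)
  drop <- geneDrop(ped, f, cfg)
  d <- dosages(drop$genotypes)
  pedS <- drop$pedigree

  # forced outcome: both parents homozygous 2 => offspring 2
  off <- pedS[pedS$sire != "0", ]
  for (i in head(seq_len(nrow(off)), 50)) {
    hom <- d[off$sire[i], ] == 2 & d[off$dam[i], ] == 2
    expect_true(all(d[off$animal[i], hom] == 2))
  }

  # parent-offspring VanRaden relationship ~ 0.5 when G is centred with
  # base (founder) frequencies, the frequencies the expectation assumes
  founders <- pedS$animal[pedS$sire == "0"]
  pFound <- colMeans(d[founders, ]) / 2
  G <- as.matrix(buildG(drop$genotypes, freqs = pFound,
                        freqSource = "base"))
  po <- mapply(function(a, s) G[a, s], off$animal, off$sire)
  se <- sd(po) / sqrt(length(po))
  expect_lt(abs(mean(po) - 0.5), 3 * se)

  # allele frequency unchanged in expectation across one generation:
  # paired test founders vs 2010 cohort over SNPs, across 3 seeds
  pvals <- vapply(1:3, function(s) {
    set.seed(100 + s)
    f2 <- simulateFounders(cfg)
    ped2 <- simulatePedigree(cfg, f2$sex)
    dr2 <- geneDrop(ped2, f2, cfg)
    d2 <- dosages(dr2$genotypes)
    founders <- dr2$pedigree$animal[dr2$pedigree$sire == "0"]
    gen1 <- dr2$pedigree$animal[dr2$pedigree$birth_year == 2010]
    pf <- colMeans(d2[founders, ]) / 2
    pg <- colMeans(d2[gen1, ]) / 2
    t.test(pf - pg)$p.value
  }, numeric(1))
  expect_gt(min(pvals), 0.01)

  # one known parent is rejected
  bad <- rbind(ped, data.frame(animal = "X1", sire = ped$animal[1],
                               dam = "0", birth_year = 2014, sex = "F"))
  expect_error(geneDrop(bad, f, cfg), "exactly one known parent")
})

test_that("QTL effects are rescaled exactly and reproducible", {
  pop <- fixturePop()
  expect_equal(var(pop$tbv), pop$config$geneticVariance, tolerance = 1e-8)

  # independent dot-product oracle from the stored effects
  M <- dosages(pop$genotypes)
  p <- alleleFreqs(pop$genotypes)
  tbvOracle <- drop(sweep(M, 2, 2 * p) %*% pop$effects)
  expect_equal(cor(tbvOracle, unname(pop$tbv[rownames(M)])), 1,
               tolerance = 1e-12)

  # null genome
  cfg0 <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 10,
                           nSnps = 100, nQtl = 0, geneticVariance = 0,
                           seed = 5)
  pop0 <- simulatePopulation(cfg0)
  expect_true(all(pop0$tbv == 0))

  cfgBad <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 10,
                             nSnps = 100, nQtl = 0, geneticVariance = 1,
                             seed = 5)
  expect_error(simulatePopulation(cfgBad), "nQtl = 0")
})

test_that("phenotype simulation honours heritability and CG structure", {
  # h2 = 1: within-CG-centred phenotype equals CG-centred TBV
  cfg1 <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 30,
                           nSnps = 300, nQtl = 100, heritability = 1,
                           seed = 21)
  pop1 <- simulatePopulation(cfg1)
  ph <- pop1$phenotypes
  cg <- interaction(ph$flock, ph$birth_year, ph$sex, ph$mob, drop = TRUE)
  ycentred <- ph$value - ave(ph$value, cg)
  gcentred <- pop1$tbv[ph$animal] - ave(pop1$tbv[ph$animal], cg)
  expect_equal(ycentred, unname(gcentred), tolerance = 1e-10)

  # determinism of the full generator
  pop1b <- simulatePopulation(cfg1)
  expect_identical(pop1$phenotypes$value, pop1b$phenotypes$value)

  # h2 = 0 with positive genetic variance needs an explicit sigma2E
  cfg0 <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 30,
                           nSnps = 300, nQtl = 100, heritability = 0,
                           seed = 22)
  pop0 <- geneDrop(simulatePedigree(cfg0, simulateFounders(cfg0,
                                                           seed = 22)$sex),
                   simulateFounders(cfg0, seed = 22), cfg0)
  tbv <- assignQtlEffects(pop0$genotypes, cfg0, seed = 1)$tbv
  expect_error(simulatePhenotypes(tbv, pop0$pedigree, cfg0),
               "sigma2E")

  # h2 = 0.30 recovered by a parent-offspring regression oracle
  cfg <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 150,
                          nSnps = 1500, nQtl = 300, heritability = 0.30,
                          cgSd = 0, seed = 23)
  pop <- simulatePopulation(cfg)
  ph <- pop$phenotypes
  cg <- interaction(ph$flock, ph$birth_year, ph$sex, ph$mob, drop = TRUE)
  yadj <- setNames(ph$value - ave(ph$value, cg), ph$animal)
  ped <- pop$pedigree
  rec <- ped[ped$animal %in% names(yadj) & ped$sire %in% names(yadj), ]
  fit <- lm(yadj[rec$animal] ~ yadj[rec$sire])
  h2hat <- 2 * coef(fit)[2]
  se <- 2 * summary(fit)$coefficients[2, 2]
  expect_lt(abs(h2hat - 0.30), 3 * se)
})

test_that("simulated populations satisfy their structural invariants", {
  pop <- fixturePop()
  ped <- pop$pedigree
  nonF <- ped[ped$sire != "0", ]
  expect_true(all(nonF$sire %in% ped$animal))
  expect_true(all(nonF$dam %in% ped$animal))
  yrs <- setNames(ped$birth_year, ped$animal)
  expect_true(all(yrs[nonF$sire] < nonF$birth_year))
  expect_true(all(yrs[nonF$dam] < nonF$birth_year))

  # pedigree expectation matches realized G for sib pairs at >= 2000
  # SNPs, with G centred at base (founder) frequencies so that A and G
  # share the same reference population
  cfgB <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 80,
                           nSnps = 2000, nQtl = 0, geneticVariance = 0,
                           seed = 41)
  popB <- simulatePopulation(cfgB)
  A <- as.matrix(buildA(popB$pedigree))
  dB <- dosages(popB$genotypes)
  pFound <- colMeans(dB[popB$pedigree$animal[popB$pedigree$sire == "0"],
                        ]) / 2
  G <- as.matrix(buildG(popB$genotypes, freqs = pFound,
                        freqSource = "base"))
  expect_identical(rownames(A), rownames(G))
  sibs <- which(A > 0.2 & A < 0.8 & upper.tri(A), arr.ind = TRUE)
  expect_lt(mean(abs(A[sibs] - G[sibs])), 0.1)

  # genotype missingness mask is applied at the configured rate
  cfgM <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 20,
                           nSnps = 400, nQtl = 50, missingRate = 0.05,
                           seed = 31)
  popM <- simulatePopulation(cfgM)
  rate <- mean(is.na(dosages(popM$genotypes)))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})
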