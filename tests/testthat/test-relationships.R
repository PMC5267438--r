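test_that("tabular A reproduces hand recursion", {
  # all founders: identity
  ped0 <- data.frame(animal = c("x", "y", "z"), sire = "0", dam = "0")
  expect_equal(unname(as.matrix(buildA(ped0))), diag(3))

  # full sibs and parent-offspring from unrelated non-inbred parents
  ped <- data.frame(animal = c("s", "d", "o1", "o2"),
                    sire = c("0", "0", "s", "s"),
                    dam = c("0", "0", "d", "d"))
  A <- as.matrix(buildA(ped))
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["s", "o1"], 0.5)
  expect_equal(A["o1", "o1"], 1)        # parents unrelated: no inbreeding

  # offspring of half sibs: F = 0.125, diagonal 1.125
  ped2 <- data.frame(animal = c("s", "d1", "d2", "h1", "h2", "k"),
                     sire = c("0", "0", "0", "s", "s", "h1"),
                     dam = c("0", "0", "0", "d1", "d2", "h2"))
  A2 <- as.matrix(buildA(ped2))
  expect_equal(A2["h1", "h2"], 0.25)
  expect_equal(A2["k", "k"], 1.125)

  cyc <- data.frame(animal = c("a", "b"), sire = c("b", "a"),
                    dam = c("0", "0"))
  expect_error(buildA(cyc), "cycle")
})

test_that("VanRaden G matches hand linear algebra", {
  # 3 animals x 4 SNPs, hand-specified
  M <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 2, 0, 0, 1), nrow = 3,
              dimnames = list(c("a1", "a2", "a3"), paste0("s", 1:4)))
  gm <- GenotypeMatrix(M)
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p)
  Ghand <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  expect_equal(as.matrix(buildG(gm)), Ghand, tolerance = 1e-12)
  expect_identical(kind(buildG(gm)), "GB0")

  # with observed frequencies, G row sums are zero (centring identity)
  expect_lt(max(abs(rowSums(as.matrix(buildG(gm))))), 1e-12)

  # an animal whose dosages equal 2p everywhere has a zero row/column
  Mq <- rbind(M, a4 = 2 * p)
  Gq <- as.matrix(buildG(GenotypeMatrix(Mq), freqs = p))
  expect_lt(max(abs(Gq["a4", ])), 1e-12)

  # monomorphic-only panel: zero denominator
  mono <- GenotypeMatrix(matrix(2, 3, 2,
                                dimnames = list(paste0("a", 1:3),
                                                c("s1", "s2"))))
  expect_error(buildG(mono), "zero")

  # missing dosages are rejected
  Mna <- M; Mna[1, 1] <- NA
  expect_error(buildG(GenotypeMatrix(Mna)), "missing")
})

test_that("base-frequency estimation undoes drift toward the founders", {
  # A = identity collapses to the observed mean dosage / 2
  M <- matrix(rbinom(40, 2, 0.4), nrow = 10,
              dimnames = list(paste0("a", 1:10), paste0("s", 1:4)))
  gm <- GenotypeMatrix(M)
  A <- RelationshipMatrix(diag(10), ids = paste0("a", 1:10), kind = "A")
  expect_equal(unname(estimateBaseFrequencies(gm, A)),
               unname(colMeans(M) / 2), tolerance = 1e-12)

  # founders only: the estimate is the observed founder frequency
  pop <- fixturePop()
  ped <- pop$pedigree
  founders <- ped$animal[ped$sire == "0"]
  dF <- dosages(pop$genotypes)[founders, ]
  gmF <- GenotypeMatrix(dF, map = snpMap(pop$genotypes)[, c("chrom",
                                                            "pos")])
  AF <- buildA(ped[ped$animal %in% founders, ])
  pF <- estimateBaseFrequencies(gmF, AF)
  obs <- colMeans(dF) / 2
  n <- length(founders)
  expect_equal(unname(pF),
               unname(pmin(pmax(obs, 1 / (2 * n)), 1 - 1 / (2 * n))),
               tolerance = 1e-10)

  # drifted population: GLS estimate beats the descendant frequency in
  # MSE against the known founder truth
  cfg <- simulationConfig(nBreeds = 1, nFoundersPerBreed = 40,
                          nSnps = 1000, nQtl = 0, geneticVariance = 0,
                          seed = 77)
  popD <- simulatePopulation(cfg)
  pedD <- popD$pedigree
  foundersD <- pedD$animal[pedD$sire == "0"]
  truth <- colMeans(dosages(popD$genotypes)[foundersD, ]) / 2
  youngest <- pedD$animal[pedD$birth_year >= 2013]
  dY <- dosages(popD$genotypes)[youngest, ]
  gmY <- GenotypeMatrix(dY, map = snpMap(popD$genotypes)[, c("chrom",
                                                             "pos")])
  AY <- buildA(pedD)[youngest]
  pHat <- estimateBaseFrequencies(gmY, AY)
  pObs <- colMeans(dY) / 2
  expect_lt(mean((pHat - truth)^2), mean((pObs - truth)^2))
})

test_that("blending, distances and PCA behave as specified", {
  G <- RelationshipMatrix(diag(2), ids = c("a", "b"), kind = "GB0")
  A <- RelationshipMatrix(matrix(c(1, .5, .5, 1), 2),
                          ids = c("a", "b"), kind = "A")
  expect_identical(blendGA(G, A, 0), G)
  expect_identical(blendGA(G, A, 1), A)
  B <- blendGA(G, A, 0.2)
  expect_equal(unname(as.matrix(B)), matrix(c(1, .1, .1, 1), 2))
  expect_identical(kind(B), "blended")
  expect_equal(blendWeight(B), 0.2)
  A2 <- RelationshipMatrix(diag(2), ids = c("a", "c"), kind = "A")
  expect_error(blendGA(G, A2, 0.1), "same animals")

  # kernel-induced distance: zero diagonal, sqrt(2) for identity kernel
  D <- genomicDistance(G)
  expect_equal(unname(diag(as.matrix(D))), c(0, 0))
  expect_equal(as.matrix(D)["a", "b"], sqrt(2))
  # hand 3x3
  G3 <- RelationshipMatrix(matrix(c(1, .5, 0, .5, 1.2, .1,
                                    0, .1, .9), 3),
                           ids = c("x", "y", "z"))
  D3 <- as.matrix(genomicDistance(G3))
  expect_equal(D3["x", "y"], sqrt(1 + 1.2 - 2 * .5))
  expect_equal(D3["y", "z"], sqrt(1.2 + .9 - 2 * .1))

  # Euclidean distances: brute-force double loop on a 5 x 10 toy
  set.seed(3)
  M <- matrix(rbinom(50, 2, 0.5), 5, 10,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:10)))
  E <- as.matrix(euclideanDistance(GenotypeMatrix(M)))
  for (i in 1:5) for (j in 1:5)
    expect_equal(E[i, j], sqrt(sum((M[i, ] - M[j, ])^2)),
                 tolerance = 1e-12)
  # identical rows give zero; single differing SNP 0 vs 2 gives 2
  M2 <- rbind(a = c(0, 1), b = c(0, 1), c = c(2, 1))
  colnames(M2) <- c("s1", "s2")
  E2 <- as.matrix(euclideanDistance(GenotypeMatrix(M2)))
  expect_equal(E2["a", "b"], 0)
  expect_equal(E2["a", "c"], 2)

  # PCA of G: spectral reconstruction and breed separation
  data <- fixtureData()
  Gb <- data$G0
  n <- length(animalIds(Gb))
  full <- pcaOfG(Gb, n)
  expect_equal(full$scores %*% t(full$scores), as.matrix(Gb),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(ncol(pcaOfG(Gb, 0)$scores), 0L)
  expect_error(pcaOfG(Gb, n + 1), "exceeds")

  pop <- fixturePop()
  pc1 <- pcaOfG(Gb, 2)$scores[, 1]
  founders <- pop$pedigree$animal[pop$pedigree$sire == "0"]
  lab <- pop$breedLabels[founders]
  rb <- cor(pc1[founders], as.numeric(factor(lab)))
  expect_gt(abs(rb), 0.9)

  # diagonal of G near 1 for an unstructured population
  pop1 <- fixturePop1()
  G1 <- buildG(pop1$genotypes)
  expect_gt(mean(diag(as.matrix(G1))), 0.9)
  expect_lt(mean(diag(as.matrix(G1))), 1.1)
})

test_that("GBBP and GB0 give nearly identical rankings on founder data", {
  pop <- fixturePop1()
  ped <- pop$pedigree
  founders <- ped$animal[ped$sire == "0"]
  dF <- dosages(pop$genotypes)[founders, ]
  keep <- apply(dF, 2, var) > 0
  gmF <- GenotypeMatrix(dF[, keep],
                        map = snpMap(pop$genotypes)[keep, c("chrom",
                                                            "pos")])
  AF <- buildA(ped[ped$animal %in% founders, ])
  pBase <- estimateBaseFrequencies(gmF, AF)
  G0 <- buildG(gmF)
  GBP <- buildG(gmF, freqs = pBase, freqSource = "base")
  expect_identical(kind(GBP), "GBBP")

  # when base and observed frequencies coincide, mBVs from the two
  # kernels correlate almost perfectly
  set.seed(12)
  ids <- founders
  y <- rnorm(length(ids))
  adj <- new("AdjustedPhenotypes", ids = ids, values = y - mean(y),
             trait = "t", nPcsRemoved = 0L,
             fixedCoefs = c(`(Intercept)` = mean(y)),
             pcBetas = numeric(0))
  vc <- VarianceComponents(sigma2A = 0.4, sigma2E = 0.6)
  m0 <- mbv(solveGblup(adj, G0, vc, computeAccT = FALSE))
  mB <- mbv(solveGblup(adj, GBP, vc, computeAccT = FALSE))
  expect_gt(cor(m0, mB), 0.99)
})
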