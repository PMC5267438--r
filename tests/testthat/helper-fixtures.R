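# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Two diverged breeds, ~400 animals, 800 SNPs: the workhorse population
# for structure-sensitive tests.
fixturePop <- function() {
  cached("pop2b", simulatePopulation(simulationConfig(
    nBreeds = 2, founderFreqDivergence = 0.3, nFoundersPerBreed = 40,
    nSnps = 800, nQtl = 200, heritability = 0.3, seed = 101)))
}

fixtureData <- function() {
  cached("data2b", {
    pop <- fixturePop()
    scenarioData(pop$genotypes, pop$pedigree, pop$phenotypes)
  })
}

# Unstructured single-breed population for calibration-style checks.
fixturePop1 <- function() {
  cached("pop1b", simulatePopulation(simulationConfig(
    nBreeds = 1, founderFreqDivergence = 0, nFoundersPerBreed = 60,
    nSnps = 1000, nQtl = 250, heritability = 0.4, seed = 202)))
}

# Large unstructured population, h2 = 0.30 (~2000 phenotyped records):
# heritability-recovery and theoretical-accuracy checks.
fixtureH2 <- function() {
  cached("popH2", simulatePopulation(simulationConfig(
    nBreeds = 1, founderFreqDivergence = 0, nFoundersPerBreed = 400,
    nSnps = 2000, nQtl = 400, heritability = 0.3, seed = 3001)))
}

fixtureH2Data <- function() {
  cached("dataH2", {
    pop <- fixtureH2()
    scenarioData(pop$genotypes, pop$pedigree, pop$phenotypes)
  })
}

# Large unstructured population, h2 = 0.40 (~2500 phenotyped records):
# expected-accuracy consistency at scale.
fixtureCal <- function() {
  cached("popCal", simulatePopulation(simulationConfig(
    nBreeds = 1, founderFreqDivergence = 0, nFoundersPerBreed = 600,
    nSnps = 2000, nQtl = 400, heritability = 0.4, seed = 4001)))
}

fixtureCalData <- function() {
  cached("dataCal", {
    pop <- fixtureCal()
    scenarioData(pop$genotypes, pop$pedigree, pop$phenotypes)
  })
}

# Adjusted Rand index between two label vectors (closed-form from the
# pair-counting contingency table) - used as an independent clustering
# oracle.
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sumI * sumJ / comb2(n)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}

# Dense-matrix restricted log-likelihood oracle (up to a constant) for
# y = 1 mu + u + e, var(u) = K s2a, var(e) = I s2e.
remlLogLikOracle <- function(y, K, s2a, s2e) {
  V <- s2a * K + diag(s2e, length(y))
  Vi <- solve(V)
  one <- rep(1, length(y))
  xvx <- drop(crossprod(one, Vi %*% one))
  P <- Vi - (Vi %*% one %*% t(one) %*% Vi) / xvx
  -0.5 * (determinant(V)$modulus + log(xvx) + drop(t(y) %*% P %*% y))
}
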