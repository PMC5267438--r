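#' @include containers.R
NULL

# bp <-> Morgan conversion used by the simulated map (1 cM per Mb).
MORGAN_PER_BP <- 1e-8

#' Simulation configuration for a composite multi-breed population
#'
#' Bundles and validates the parameters of the synthetic-population
#' generator. Defaults emulate a terminal-sire composite flock: several
#' founder breeds with moderately diverged allele frequencies, overlapping
#' birth cohorts from 2007 to 2014 (founders in the first two years,
#' recorded progeny from 2010), a mean of 17 progeny per sire, and
#' contemporary groups formed by flock x birth year x sex x mob.
#'
#' @param nBreeds number of founder breeds.
#' @param founderFreqDivergence Fst-like divergence of breed allele
#'   frequencies around a common ancestral frequency, in `[0, 1]`.
#' @param nFoundersPerBreed founder animals per breed (sex-balanced).
#' @param nSnps,nChromosomes marker panel size and chromosome count.
#' @param nQtl number of causal SNPs drawn from the panel.
#' @param birthYears inclusive year range of the population.
#' @param progenyPerSireMean mean progeny per sire within a drop year.
#' @param heritability narrow-sense h2 of the simulated trait.
#' @param geneticVariance additive genetic variance sigma_A^2
#'   (trait units squared).
#' @param cgFactors list with the number of levels for `flock` and `mob`
#'   (sex and birth year come from the pedigree).
#' @param traitName,traitMean trait label and overall mean.
#' @param cgSd standard deviation of contemporary-group effects.
#' @param missingRate per-call Bernoulli missingness rate (default 0).
#' @param genomeLength total genome length in Morgans (default 26).
#' @param sigma2E residual variance override, required only when
#'   `heritability = 0` with positive genetic variance.
#' @param seed integer RNG seed; a fixed seed makes every downstream
#'   operation byte-identical across runs.
#' @return a validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nSnps = 200, nFoundersPerBreed = 10, seed = 1)
#' pop <- simulatePopulation(cfg)
#' pop$genotypes
#' @export
simulationConfig <- function(nBreeds = 3, founderFreqDivergence = 0.15,
                             nFoundersPerBreed = 60, nSnps = 2000,
                             nChromosomes = 26, nQtl = 300,
                             birthYears = 2007:2014,
                             progenyPerSireMean = 17, heritability = 0.30,
                             geneticVariance = 1,
                             cgFactors = list(flock = 3, mob = 2),
                             traitName = "WWT", traitMean = 30, cgSd = 1,
                             missingRate = 0, genomeLength = 26,
                             sigma2E = NULL, seed = 1L) {
  stopifnot_config <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_config(nBreeds >= 1, "nBreeds must be at least 1")
  stopifnot_config(nFoundersPerBreed >= 2,
                   "nFoundersPerBreed must be at least 2")
  stopifnot_config(nSnps >= 1 && nChromosomes >= 1,
                   "nSnps and nChromosomes must be positive")
  stopifnot_config(nQtl >= 0 && nQtl <= nSnps, "need 0 <= nQtl <= nSnps")
  stopifnot_config(founderFreqDivergence >= 0 && founderFreqDivergence <= 1,
                   "founderFreqDivergence must lie in [0, 1]")
  stopifnot_config(heritability >= 0 && heritability <= 1,
                   "heritability must lie in [0, 1]")
  stopifnot_config(geneticVariance >= 0, "geneticVariance must be >= 0")
  stopifnot_config(progenyPerSireMean >= 1,
                   "progenyPerSireMean must be at least 1")
  stopifnot_config(length(birthYears) >= 4,
                   "birthYears must span at least four years")
  stopifnot_config(missingRate >= 0 && missingRate < 1,
                   "missingRate must lie in [0, 1)")
  cfg <- list(nBreeds = as.integer(nBreeds),
              founderFreqDivergence = founderFreqDivergence,
              nFoundersPerBreed = as.integer(nFoundersPerBreed),
              nSnps = as.integer(nSnps),
              nChromosomes = as.integer(nChromosomes),
              nQtl = as.integer(nQtl), birthYears = as.integer(birthYears),
              progenyPerSireMean = progenyPerSireMean,
              heritability = heritability,
              geneticVariance = geneticVariance, cgFactors = cgFactors,
              traitName = traitName, traitMean = traitMean, cgSd = cgSd,
              missingRate = missingRate, genomeLength = genomeLength,
              sigma2E = sigma2E, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# Draws the simulated SNP map: SNPs spread uniformly over equal-length
# chromosomes (genomeLength / nChromosomes Morgans each), 1-based bp
# positions at 1 cM/Mb, sorted and de-duplicated within chromosome.
simulateMap <- function(config) {
  chrLen <- config$genomeLength / config$nChromosomes
  chrom <- sort(sample.int(config$nChromosomes, config$nSnps,
                           replace = TRUE))
  morgans <- runif(config$nSnps, 0, chrLen)
  ord <- order(chrom, morgans)
  chrom <- chrom[ord]
  morgans <- morgans[ord]
  pos <- pmax(1, round(morgans / MORGAN_PER_BP))
  # nudge rare bp collisions within a chromosome apart
  dup <- duplicated(paste(chrom, pos))
  while (any(dup)) {
    pos[dup] <- pos[dup] + 1
    dup <- duplicated(paste(chrom, pos))
  }
  data.frame(chrom = chrom, pos = pos, morgans = morgans)
}

#' Simulate founder genotypes for diverged breeds
#'
#' Draws per-breed allele frequencies around a common ancestral frequency
#' using the Balding-Nichols model: with divergence `F`, breed frequencies
#' follow Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean `p` and variance
#' `F p (1-p)`. Founder genotypes are then drawn in Hardy-Weinberg
#' proportions within breed, as two independent haplotypes per animal.
#'
#' @param config a [simulationConfig()].
#' @param seed optional seed; by default the RNG state is left as-is so the
#'   function can run inside [simulatePopulation()].
#' @return list with `genotypes` (a [GenotypeMatrix-class]), `breedLabels`
#'   (per-animal breed), `haplotypes` (two 0/1 matrices used by
#'   [geneDrop()]), `breedFreqs` (SNP x breed frequency matrix), `sex`,
#'   and `map` (with genetic positions in Morgans).
#' @export
simulateFounders <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$nBreeds < 1)
    stop("configuration error: nBreeds must be positive")
  map <- simulateMap(config)
  p0 <- runif(config$nSnps, 0.05, 0.95)
  Fst <- config$founderFreqDivergence
  breedFreqs <- sapply(seq_len(config$nBreeds), function(b) {
    if (Fst == 0) p0
    else stats::rbeta(config$nSnps, p0 * (1 - Fst) / Fst,
                      (1 - p0) * (1 - Fst) / Fst)
  })
  nF <- config$nFoundersPerBreed * config$nBreeds
  ids <- sprintf("F%05d", seq_len(nF))
  breedLabels <- rep(paste0("breed", seq_len(config$nBreeds)),
                     each = config$nFoundersPerBreed)
  h1 <- matrix(0L, nF, config$nSnps)
  h2 <- matrix(0L, nF, config$nSnps)
  for (b in seq_len(config$nBreeds)) {
    rows <- which(breedLabels == paste0("breed", b))
    pb <- breedFreqs[, b]
    h1[rows, ] <- matrix(rbinom(length(rows) * config$nSnps, 1,
                                rep(pb, each = length(rows))),
                         length(rows), config$nSnps)
    h2[rows, ] <- matrix(rbinom(length(rows) * config$nSnps, 1,
                                rep(pb, each = length(rows))),
                         length(rows), config$nSnps)
  }
  rownames(h1) <- rownames(h2) <- ids
  snpIds <- sprintf("snp%05d", seq_len(config$nSnps))
  colnames(h1) <- colnames(h2) <- snpIds
  dos <- h1 + h2
  # sex-balanced within breed so every breed contributes sires and dams
  sex <- rep(rep(c("M", "F"),
                 length.out = config$nFoundersPerBreed), config$nBreeds)
  gm <- GenotypeMatrix(dos, map = map[, c("chrom", "pos")],
                       animalIds = ids, snpIds = snpIds)
  list(genotypes = gm, breedLabels = setNames(breedLabels, ids),
       haplotypes = list(h1 = h1, h2 = h2), breedFreqs = breedFreqs,
       sex = setNames(sex, ids), map = map)
}

#' Simulate an overlapping-generation mating pedigree
#'
#' Founders occupy the first two birth years of the configured range;
#' recorded progeny are born from the fourth year onwards (e.g. founders
#' 2007-2008 and progeny 2010-2014 for the default 2007:2014 range). In
#' each drop year every available dam (females aged two or more) produces
#' one lamb; sires (males aged one or more) are drawn with family sizes
#' 1 + Poisson(mean - 1) around the configured mean progeny per sire, which
#' creates the large paternal half-sib families that the cluster-based
#' validation designs exploit.
#'
#' @inheritParams simulateFounders
#' @param founderSex named sex vector from [simulateFounders()].
#' @return a pedigree data.frame with columns `animal`, `sire`, `dam`
#'   (`"0"` for unknown), `birth_year` and `sex`.
#' @export
simulatePedigree <- function(config, founderSex, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  years <- config$birthYears
  founderYears <- years[1:2]
  progenyYears <- years[years >= years[1] + 3]
  ids <- names(founderSex)
  ped <- data.frame(animal = ids, sire = "0", dam = "0",
                    birth_year = rep(founderYears,
                                     length.out = length(ids)),
                    sex = unname(founderSex), stringsAsFactors = FALSE)
  counter <- 0L
  for (y in progenyYears) {
    dams <- ped$animal[ped$sex == "F" & ped$birth_year <= y - 2]
    males <- ped$animal[ped$sex == "M" & ped$birth_year <= y - 1]
    if (length(dams) == 0 || length(males) == 0) next
    dams <- sample(dams)
    sireOrder <- sample(males)
    assigned <- character(0)
    si <- 1
    while (length(assigned) < length(dams)) {
      fam <- 1 + rpois(1, config$progenyPerSireMean - 1)
      sire <- sireOrder[(si - 1) %% length(sireOrder) + 1]
      si <- si + 1
      assigned <- c(assigned, rep(sire, fam))
    }
    assigned <- assigned[seq_along(dams)]
    lambs <- data.frame(animal = sprintf("A%05d",
                                         counter + seq_along(dams)),
                        sire = assigned, dam = dams, birth_year = y,
                        sex = sample(c("M", "F"), length(dams),
                                     replace = TRUE),
                        stringsAsFactors = FALSE)
    counter <- counter + nrow(lambs)
    ped <- rbind(ped, lambs)
  }
  ped
}

# One recombinant gamete per (animal, chromosome): Poisson crossover count
# on the chromosome's genetic length, uniform crossover positions,
# random starting strand.
recombineGamete <- function(hapA, hapB, chromIdx, morgans, chrLen) {
  gam <- hapA
  for (ci in seq_along(chromIdx)) {
    snps <- chromIdx[[ci]]
    ncross <- rpois(1, chrLen)
    start <- sample.int(2, 1)
    if (ncross == 0) {
      strand <- rep(start, length(snps))
    } else {
      cuts <- sort(runif(ncross, 0, chrLen))
      seg <- findInterval(morgans[snps], cuts)
      strand <- (start + seg - 1) %% 2 + 1
    }
    pick <- strand == 2
    if (any(pick)) gam[snps[pick]] <- hapB[snps[pick]]
  }
  gam
}

#' Drop founder genomes through a pedigree
#'
#' Simulates Mendelian inheritance with linkage: each offspring receives
#' one recombinant gamete per parent, with crossover counts Poisson in the
#' chromosome genetic length and uniform crossover positions; loci on
#' different chromosomes segregate independently.
#'
#' @param pedigree pedigree data.frame (founders first or any order with
#'   parents defined; rows are sorted internally so parents precede
#'   offspring).
#' @param founders founder object from [simulateFounders()], or a list with
#'   `haplotypes` and `map` in the same layout. Founders supplied only as
#'   dosages are phased randomly at heterozygous sites.
#' @param config a [simulationConfig()] (for the chromosome genetic length).
#' @param seed optional seed.
#' @return list with `genotypes` (a [GenotypeMatrix-class] over all pedigree
#'   animals) and the phased `haplotypes`.
#' @export
geneDrop <- function(pedigree, founders, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  oneParent <- xor(pedigree$sire == "0", pedigree$dam == "0")
  if (any(oneParent))
    stop("animals with exactly one known parent are not supported: ",
         paste(head(pedigree$animal[oneParent]), collapse = ", "))
  ped <- sortPedigree(pedigree)
  map <- founders$map
  founderIds <- ped$animal[ped$sire == "0"]
  missingF <- setdiff(founderIds, rownames(founders$haplotypes$h1))
  if (length(missingF) > 0)
    stop("pedigree founders absent from founder genotypes: ",
         paste(head(missingF), collapse = ", "))
  nSnps <- ncol(founders$haplotypes$h1)
  n <- nrow(ped)
  h1 <- matrix(0L, n, nSnps, dimnames = list(ped$animal, NULL))
  h2 <- matrix(0L, n, nSnps, dimnames = list(ped$animal, NULL))
  h1[founderIds, ] <- founders$haplotypes$h1[founderIds, ]
  h2[founderIds, ] <- founders$haplotypes$h2[founderIds, ]
  chromIdx <- split(seq_len(nSnps), map$chrom)
  chrLen <- config$genomeLength / config$nChromosomes
  for (i in which(ped$sire != "0")) {
    s <- ped$sire[i]; d <- ped$dam[i]
    h1[i, ] <- recombineGamete(h1[s, ], h2[s, ], chromIdx, map$morgans,
                               chrLen)
    h2[i, ] <- recombineGamete(h1[d, ], h2[d, ], chromIdx, map$morgans,
                               chrLen)
  }
  dos <- h1 + h2
  snpIds <- snpIds(founders$genotypes)
  colnames(dos) <- snpIds
  gm <- GenotypeMatrix(dos, map = map[, c("chrom", "pos")],
                       animalIds = ped$animal, snpIds = snpIds)
  list(genotypes = gm, haplotypes = list(h1 = h1, h2 = h2),
       pedigree = ped)
}

#' Assign QTL effects and compute true breeding values
#'
#' Chooses `nQtl` panel SNPs without replacement, draws i.i.d. normal
#' additive effects and rescales them so that the realized sample variance
#' of the true breeding values equals the configured genetic variance
#' exactly. TBV_i = sum_j effect_j (dosage_ij - 2 p_j) with observed
#' frequencies p_j.
#'
#' @param genotypes a complete [GenotypeMatrix-class].
#' @param config a [simulationConfig()].
#' @param seed optional seed.
#' @return list with `tbv` (named per-animal vector), `effects` (named
#'   per-SNP vector, zero off the QTL) and `qtl` (the QTL SNP ids).
#' @export
assignQtlEffects <- function(genotypes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- dosages(genotypes)
  if (anyNA(M))
    stop("genotypes must be complete (impute first)")
  sigma2A <- config$geneticVariance
  effects <- setNames(numeric(ncol(M)), colnames(M))
  if (config$nQtl == 0) {
    if (sigma2A > 0)
      stop("nQtl = 0 cannot produce positive genetic variance")
    return(list(tbv = setNames(numeric(nrow(M)), rownames(M)),
                effects = effects, qtl = character(0)))
  }
  qtl <- sort(sample.int(ncol(M), config$nQtl))
  a <- rnorm(config$nQtl)
  p <- colMeans(M[, qtl, drop = FALSE]) / 2
  Z <- sweep(M[, qtl, drop = FALSE], 2, 2 * p)
  tbv <- drop(Z %*% a)
  v <- var(tbv)
  if (sigma2A > 0 && v <= 0)
    stop("degenerate QTL genotypes: realized TBV variance is zero")
  scale <- if (sigma2A > 0) sqrt(sigma2A / v) else 0
  a <- a * scale
  tbv <- tbv * scale
  effects[qtl] <- a
  list(tbv = setNames(tbv, rownames(M)), effects = effects,
       qtl = colnames(M)[qtl])
}

#' Simulate phenotypes with contemporary-group structure
#'
#' y = mu + CG + TBV + e with residual variance
#' sigma_A^2 (1 - h2) / h2 so that the narrow-sense heritability of the
#' CG-adjusted records equals `h2`. Contemporary groups are assembled from
#' flock x birth year x sex x mob, with flock and mob drawn per animal and
#' sex/birth year taken from the pedigree. Only non-founder (progeny)
#' animals are recorded, mirroring a progeny-test design.
#'
#' @param tbv named per-animal true breeding values.
#' @param pedigree pedigree data.frame.
#' @param config a [simulationConfig()].
#' @param seed optional seed.
#' @return a phenotype data.frame with columns `animal`, `trait`, `value`,
#'   `flock`, `birth_year`, `sex`, `mob`.
#' @export
simulatePhenotypes <- function(tbv, pedigree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h2 <- config$heritability
  sigma2A <- config$geneticVariance
  if (h2 == 0 && sigma2A > 0 && is.null(config$sigma2E))
    stop("h2 = 0 with positive genetic variance: supply sigma2E explicitly")
  sigma2E <- if (!is.null(config$sigma2E)) config$sigma2E
             else if (h2 == 0) 1
             else sigma2A * (1 - h2) / h2
  rec <- pedigree[pedigree$sire != "0", , drop = FALSE]
  if (nrow(rec) == 0)
    stop("pedigree contains no progeny to record")
  flock <- sample(paste0("flock", seq_len(config$cgFactors$flock)),
                  nrow(rec), replace = TRUE)
  mob <- sample(paste0("mob", seq_len(config$cgFactors$mob)),
                nrow(rec), replace = TRUE)
  cg <- interaction(flock, rec$birth_year, rec$sex, mob, drop = TRUE)
  cgEff <- setNames(rnorm(nlevels(cg), 0, config$cgSd), levels(cg))
  g <- if (h2 == 0 && sigma2A > 0) 0 else tbv[rec$animal]
  e <- rnorm(nrow(rec), 0, sqrt(sigma2E))
  if (h2 == 1 && is.null(config$sigma2E)) e <- 0
  value <- config$traitMean + cgEff[as.character(cg)] + g + e
  data.frame(animal = rec$animal, trait = config$traitName,
             value = unname(value), flock = flock,
             birth_year = rec$birth_year, sex = rec$sex, mob = mob,
             stringsAsFactors = FALSE)
}

#' Simulate a complete multi-breed population
#'
#' Runs the whole generator under one seed: founder breeds, overlapping
#' mating pedigree, gene dropping with linkage, QTL effects and true
#' breeding values, and contemporary-group phenotypes. Optionally masks a
#' fraction of genotype calls to exercise quality control.
#'
#' @param config a [simulationConfig()].
#' @return list with `genotypes`, `pedigree`, `phenotypes`, `tbv`,
#'   `effects`, `qtl`, `breedLabels` and the `config` used.
#' @export
simulatePopulation <- function(config) {
  set.seed(config$seed)
  founders <- simulateFounders(config)
  ped <- simulatePedigree(config, founders$sex)
  dropped <- geneDrop(ped, founders, config)
  qtl <- assignQtlEffects(dropped$genotypes, config)
  phen <- simulatePhenotypes(qtl$tbv, dropped$pedigree, config)
  geno <- dropped$genotypes
  if (config$missingRate > 0) {
    d <- dosages(geno)
    mask <- matrix(rbinom(length(d), 1, config$missingRate) == 1,
                   nrow(d), ncol(d))
    d[mask] <- NA
    geno <- GenotypeMatrix(d, map = snpMap(geno)[, c("chrom", "pos")],
                           animalIds = rownames(d), snpIds = colnames(d))
  }
  breed <- founders$breedLabels[dropped$pedigree$animal]
  # progeny inherit the (possibly mixed) breed of their parents; label by
  # sire-line breed for founders' descendants, "admixed" when parents differ
  for (i in which(dropped$pedigree$sire != "0")) {
    bs <- breed[dropped$pedigree$sire[i]]
    bd <- breed[dropped$pedigree$dam[i]]
    breed[i] <- if (identical(bs, bd)) bs else "admixed"
    names(breed)[i] <- dropped$pedigree$animal[i]
  }
  list(genotypes = geno, pedigree = dropped$pedigree, phenotypes = phen,
       tbv = qtl$tbv, effects = qtl$effects, qtl = qtl$qtl,
       breedLabels = breed, config = config)
}
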