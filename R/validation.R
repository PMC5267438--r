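#' @include containers.R
NULL

#' Forward (birth-year) training/validation split
#'
#' Training animals are born before the cutoff year, validation animals in
#' the cutoff year - the youngest cohort, mimicking selection candidates
#' without phenotypes predicted from older animals.
#'
#' @param pedigree data.frame with `animal` and `birth_year` (a phenotype
#'   table works too).
#' @param cutoffYear validation birth year (default 2014).
#' @param ids optional subset of animals to split (default: all with a
#'   known birth year).
#' @return list with `train` and `valid` id vectors.
#' @export
forwardSplit <- function(pedigree, cutoffYear = 2014, ids = NULL) {
  if (!all(c("animal", "birth_year") %in% colnames(pedigree)))
    stop("need 'animal' and 'birth_year' columns")
  tab <- pedigree[!is.na(pedigree$birth_year), c("animal", "birth_year")]
  if (!is.null(ids))
    tab <- tab[tab$animal %in% ids, , drop = FALSE]
  train <- tab$animal[tab$birth_year < cutoffYear]
  valid <- tab$animal[tab$birth_year == cutoffYear]
  if (length(train) == 0 || length(valid) == 0)
    stop("degenerate forward split: ", length(train), " training and ",
         length(valid), " validation animals at cutoff ", cutoffYear)
  list(train = train, valid = valid)
}

#' Random k-fold assignment
#'
#' Assigns each animal to one of `k` folds with sizes differing by at most
#' one; each fold validates once while the remaining folds train.
#'
#' @param ids animal identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed (fixed seed gives an identical assignment).
#' @return list of `k` groups, each with `train` and `valid` ids.
#' @export
randomKfold <- function(ids, k = 5, seed = 1L) {
  if (k < 2)
    stop("k must be at least 2")
  if (length(ids) < k)
    stop("fewer animals than folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(ids)))
  lapply(seq_len(k), function(g)
    list(train = ids[fold != g], valid = ids[fold == g]))
}

#' k-means clustering of animals on G-matrix principal components
#'
#' Hartigan-Wong k-means on the leading principal-component coordinates of
#' the genomic relationship matrix, keeping the best of `nInit` random
#' restarts by within-cluster sum of squares.
#'
#' @param pcScores score matrix from [pcaOfG()] (animals x components;
#'   10 components is the package default upstream).
#' @param k number of clusters (default 5).
#' @param seed RNG seed.
#' @param nInit number of restarts (default 25).
#' @return named integer cluster labels, plus the within-cluster sum of
#'   squares in attribute `"tot.withinss"`.
#' @export
kmeansClusters <- function(pcScores, k = 5, seed = 1L, nInit = 25) {
  if (k > nrow(pcScores))
    stop("more clusters than animals")
  set.seed(seed)
  if (k == 1) {
    labels <- setNames(rep(1L, nrow(pcScores)), rownames(pcScores))
    attr(labels, "tot.withinss") <-
      sum(scale(pcScores, scale = FALSE)^2)
    return(labels)
  }
  km <- kmeans(pcScores, centers = k, nstart = nInit, iter.max = 100,
               algorithm = "Hartigan-Wong")
  labels <- setNames(km$cluster, rownames(pcScores))
  attr(labels, "tot.withinss") <- km$tot.withinss
  labels
}

#' Hierarchical clustering of animals from a distance matrix
#'
#' Agglomerative clustering of the animal-by-animal distances, cut into
#' `k` groups. Clusters smaller than `minSize` are excluded (label `NA`)
#' rather than merged, so a handful of outlying animals does not dilute a
#' validation group.
#'
#' @param D a [DistanceMatrix-class].
#' @param k number of clusters.
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @param minSize clusters below this size are set to `NA` (default 1:
#'   keep everything; scenario runners apply their own validation-size
#'   rule).
#' @return named integer cluster labels (`NA` = excluded).
#' @export
hierarchicalClusters <- function(D, k,
                                 linkage = c("complete", "average",
                                             "ward"),
                                 minSize = 1) {
  linkage <- match.arg(linkage)
  n <- length(animalIds(D))
  if (k > n)
    stop("more clusters than animals")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(as.dist(as.matrix(D)), method = method)
  labels <- cutree(hc, k = k)
  names(labels) <- animalIds(D)
  sizes <- table(labels)
  tiny <- as.integer(names(sizes)[sizes < minSize])
  labels[labels %in% tiny] <- NA
  labels
}

#' The registry of named validation scenarios
#'
#' All fourteen scenario names resolve here: `GB0` (forward validation,
#' plain VanRaden G), `GB2PC`/`GB4PC`/`GB6PC` (forward, 2/4/6 G-matrix
#' principal components regressed out of the phenotypes), `GB10`/`GB20`
#' (forward, 10%/20% pedigree blend), `GBBP` (forward, base-population
#' allele frequencies), `GBRCV` (random 5-fold cross-validation), `GBKCV`
#' (k-means 5-cluster cross-validation), `GBC` (forward validation inside
#' each of 5 k-means clusters), and `K5G`/`K10G`/`K5EDM`/`K10EDM`
#' (forward validation inside hierarchical clusters from the G-induced or
#' Euclidean genotype distance matrix).
#'
#' @param seed seed recorded in each spec (used by the random designs).
#' @param minValid smallest retained validation group (default 150,
#'   encoding the "more than 150 records" reporting rule).
#' @return named list of [ScenarioSpec-class] objects.
#' @export
scenarioRegistry <- function(seed = 1L, minValid = 150L) {
  mk <- function(name, kernel = "GB0", w = 0, nPcs = 0L,
                 design = "forward", k = 5L, dist = "none")
    new("ScenarioSpec", name = name, kernelKind = kernel, blendW = w,
        nPcs = as.integer(nPcs), design = design, k = as.integer(k),
        distanceSource = dist, minValid = as.integer(minValid),
        seed = as.integer(seed))
  specs <- list(
    mk("GB0"),
    mk("GB2PC", nPcs = 2), mk("GB4PC", nPcs = 4), mk("GB6PC", nPcs = 6),
    mk("GB10", kernel = "blended", w = 0.10),
    mk("GB20", kernel = "blended", w = 0.20),
    mk("GBBP", kernel = "GBBP"),
    mk("GBRCV", design = "random_cv", k = 5),
    mk("GBKCV", design = "kmeans_cv", k = 5),
    mk("GBC", design = "cluster_forward", k = 5),
    mk("K5G", design = "genomic_cluster_forward", k = 5, dist = "G"),
    mk("K10G", design = "genomic_cluster_forward", k = 10, dist = "G"),
    mk("K5EDM", design = "genomic_cluster_forward", k = 5, dist = "EDM"),
    mk("K10EDM", design = "genomic_cluster_forward", k = 10,
       dist = "EDM"))
  setNames(specs, vapply(specs, function(s) s@name, character(1)))
}

#' Resolve a scenario by name
#'
#' @param name a registry scenario name.
#' @param ... passed to [scenarioRegistry()] (`seed`, `minValid`).
#' @return a [ScenarioSpec-class].
#' @export
getScenario <- function(name, ...) {
  reg <- scenarioRegistry(...)
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; registry: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Restrict adjusted phenotypes to a set of animals
#'
#' Used by the split designs to pass only training records into the
#' GBLUP solve while the kernel keeps every animal.
#'
#' @param adj an [AdjustedPhenotypes-class].
#' @param ids animals to keep (order of the original records).
#' @return an [AdjustedPhenotypes-class] over `ids`.
#' @export
subsetAdjusted <- function(adj, ids) {
  keep <- adj@ids %in% ids
  new("AdjustedPhenotypes", ids = adj@ids[keep],
      values = adj@values[keep], trait = adj@trait,
      nPcsRemoved = adj@nPcsRemoved, fixedCoefs = adj@fixedCoefs,
      pcBetas = adj@pcBetas)
}

#' Precompute the shared inputs of scenario runs
#'
#' Builds, once, everything several scenarios re-use: the fixed-effect
#' adjusted phenotypes, the VanRaden G matrix over all genotyped animals,
#' its leading principal components, and the REML variance components on
#' the full data (the same-dataset heritability used for accuracy
#' scaling). The pedigree A matrix and base-frequency G are built lazily
#' on first use and cached.
#'
#' @param genotypes a complete (QC'd, imputed) [GenotypeMatrix-class].
#' @param pedigree pedigree data.frame (with `birth_year`).
#' @param phenotypes phenotype data.frame.
#' @param fixedSpec fixed-effect specification for [adjustPhenotypes()];
#'   defaults to the contemporary-group factors present.
#' @param trait trait name (default: the single trait).
#' @param vc optional pre-computed [VarianceComponents-class]; otherwise
#'   REML on G over the full data.
#' @param ne effective population size used for expected accuracies.
#' @param nPcCoordinates PC coordinates used by k-means (default 10).
#' @return a list bundle for [runScenario()].
#' @export
scenarioData <- function(genotypes, pedigree, phenotypes,
                         fixedSpec = NULL, trait = NULL, vc = NULL,
                         ne = 380, nPcCoordinates = 10) {
  if (is.null(fixedSpec)) {
    # the contemporary group is the joint flock x year x sex x mob level,
    # fitted as a single factor (not additive main effects)
    cgCols <- intersect(c("flock", "birth_year", "sex", "mob"),
                        colnames(phenotypes))
    if (length(cgCols) == 0)
      stop("no contemporary-group columns found; supply fixedSpec")
    phenotypes$cg <- as.character(interaction(phenotypes[, cgCols],
                                              drop = TRUE))
    fixedSpec <- list(factors = "cg", covariates = character(0))
  }
  adj <- adjustPhenotypes(phenotypes, fixedSpec, trait = trait)
  keep <- adj@ids %in% animalIds(genotypes)
  adj <- subsetAdjusted(adj, adj@ids[keep])
  G0 <- buildG(genotypes)
  pc <- pcaOfG(G0, min(nPcCoordinates, length(animalIds(G0))))
  if (is.null(vc))
    vc <- remlVarianceComponents(adj, G0)
  years <- setNames(phenotypes$birth_year, phenotypes$animal)
  list(genotypes = genotypes, pedigree = pedigree,
       phenotypes = phenotypes, adj = adj, G0 = G0,
       pcScores = pc$scores, vc = vc, ne = ne,
       birthYears = years, cache = new.env(parent = emptyenv()))
}

scenarioKernel <- function(spec, data) {
  if (spec@kernelKind == "GB0") return(data$G0)
  cache <- data$cache
  if (is.null(cache$A)) {
    A <- buildA(data$pedigree)
    cache$A <- A[animalIds(data$G0)]
  }
  if (spec@kernelKind == "blended")
    return(blendGA(data$G0, cache$A, spec@blendW))
  if (is.null(cache$GBBP)) {
    pBase <- estimateBaseFrequencies(data$genotypes, cache$A)
    cache$GBBP <- buildG(data$genotypes, freqs = pBase,
                         freqSource = "base")
  }
  cache$GBBP
}

scenarioGroups <- function(spec, data, phenoIds) {
  cutoff <- max(data$birthYears[phenoIds])
  fwd <- function(ids, label) {
    sp <- tryCatch(forwardSplit(data.frame(animal = ids,
                                           birth_year =
                                             data$birthYears[ids]),
                                cutoffYear = cutoff),
                   error = function(e) NULL)
    if (is.null(sp)) return(NULL)
    list(train = sp$train, valid = sp$valid, label = label)
  }
  switch(spec@design,
    forward = list(fwd(phenoIds, "forward")),
    random_cv = {
      gr <- randomKfold(phenoIds, k = spec@k, seed = spec@seed)
      lapply(seq_along(gr), function(i)
        c(gr[[i]], list(label = paste0("fold", i))))
    },
    kmeans_cv = {
      lab <- kmeansClusters(data$pcScores, k = spec@k, seed = spec@seed)
      lab <- lab[phenoIds]
      lapply(sort(unique(lab)), function(cl)
        list(train = phenoIds[lab != cl], valid = phenoIds[lab == cl],
             label = paste0("cluster", cl)))
    },
    cluster_forward = {
      lab <- kmeansClusters(data$pcScores, k = spec@k, seed = spec@seed)
      lab <- lab[phenoIds]
      out <- lapply(sort(unique(lab)), function(cl)
        fwd(phenoIds[lab == cl], paste0("cluster", cl)))
      Filter(Negate(is.null), out)
    },
    genomic_cluster_forward = {
      cache <- data$cache
      key <- paste0("dist_", spec@distanceSource)
      if (is.null(cache[[key]]))
        cache[[key]] <- if (spec@distanceSource == "G")
          genomicDistance(data$G0)
        else euclideanDistance(data$genotypes)
      lab <- hierarchicalClusters(cache[[key]], k = spec@k)
      lab <- lab[phenoIds]
      keepLab <- sort(unique(lab[!is.na(lab)]))
      out <- lapply(keepLab, function(cl) {
        ids <- phenoIds[!is.na(lab) & lab == cl]
        if (length(ids) < 2) return(NULL)
        fwd(ids, paste0("hclust", cl))
      })
      Filter(Negate(is.null), out)
    },
    stop("unknown design: ", spec@design))
}

#' Run a named validation scenario end to end
#'
#' Builds the scenario's kernel, applies any principal-component
#' adjustment to the phenotypes, constructs the training/validation
#' groups of the split design, solves GBLUP per training set (all animals
#' in the kernel, only training phenotypes in the equations), and scores
#' each retained validation group: observed accuracy
#' cor(mBV, adjusted phenotype)/sqrt(h2), mean theoretical accuracy over
#' the validation animals, and the K spread factor. Validation groups at
#' or below `minValid` animals are skipped and logged; retained groups are
#' combined by record-weighted means.
#'
#' @param spec a [ScenarioSpec-class] (see [getScenario()]).
#' @param data bundle from [scenarioData()].
#' @param minValid override of the spec's smallest retained validation
#'   group.
#' @param computeAccT compute theoretical accuracies (full MME inverse;
#'   disable for speed on large kernels).
#' @return an [AccuracyReport-class] with one row.
#' @export
runScenario <- function(spec, data, minValid = NULL,
                        computeAccT = TRUE) {
  if (is.null(minValid)) minValid <- spec@minValid
  kernel <- scenarioKernel(spec, data)
  adj <- data$adj
  if (spec@nPcs > 0)
    adj <- regressOutPcs(adj, data$pcScores, spec@nPcs)
  h2 <- heritability(data$vc)
  phenoIds <- adj@ids
  groups <- scenarioGroups(spec, data, phenoIds)
  if (length(groups) == 0)
    stop("scenario '", spec@name, "' produced no usable validation groups")
  metrics <- list()
  skipped <- list()
  for (g in groups) {
    if (length(g$valid) <= minValid) {
      skipped[[length(skipped) + 1]] <-
        data.frame(scenario = spec@name, group = g$label,
                   n_valid = length(g$valid),
                   reason = "validation group too small")
      next
    }
    fit <- solveGblup(subsetAdjusted(adj, g$train), kernel, data$vc,
                      computeAccT = computeAccT)
    m <- mbv(fit)[g$valid]
    yv <- adjustedValues(adj)[g$valid]
    r <- observedAccuracy(m, yv, h2)
    accT <- if (computeAccT) mean(accTheoretical(fit)[g$valid])
            else NA_real_
    metrics[[length(metrics) + 1]] <-
      data.frame(scenario = spec@name, group = g$label, accuracy = r,
                 n_train = length(g$train), n_valid = length(g$valid),
                 mean_accT = accT,
                 k_factor = spreadFactor(r, sigma2A(data$vc), m))
  }
  skippedDf <- if (length(skipped) > 0) do.call(rbind, skipped)
               else data.frame()
  if (length(metrics) == 0)
    stop("scenario '", spec@name, "': every validation group was at or ",
         "below the minimum size ", minValid)
  assembleReport(do.call(rbind, metrics), trait = adj@trait,
                 scenario = spec@name, h2 = h2,
                 sigma2A = sigma2A(data$vc), ne = data$ne,
                 skipped = skippedDf)
}

#' Run several registry scenarios on one data bundle
#'
#' @param names registry scenario names.
#' @param data bundle from [scenarioData()].
#' @param ... passed to [runScenario()] and [scenarioRegistry()]
#'   (`seed`, `minValid`, `computeAccT`).
#' @param seed,minValid registry parameters.
#' @param computeAccT compute theoretical accuracies per solve.
#' @return a combined [AccuracyReport-class], one row per scenario.
#' @export
runScenarios <- function(names, data, seed = 1L, minValid = 150L,
                         computeAccT = TRUE) {
  reg <- scenarioRegistry(seed = seed, minValid = minValid)
  bad <- setdiff(names, names(reg))
  if (length(bad) > 0)
    stop("unknown scenarios: ", paste(bad, collapse = ", "))
  combineReports(lapply(names, function(nm)
    runScenario(reg[[nm]], data, computeAccT = computeAccT)))
}
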