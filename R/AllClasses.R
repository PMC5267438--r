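#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd cor rnorm rbinom rpois runif pchisq na.omit
#'   optimize lm resid coef kmeans hclust cutree dist as.dist prcomp
#'   model.matrix aggregate ave setNames pnorm complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Allele-dosage genotype container
#'
#' `GenotypeMatrix` stores SNP allele dosages for a set of animals together
#' with the SNP map (chromosome, base-pair position). It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"dosage"`
#' assay holding SNPs in rows and animals in columns, following the
#' rows-are-features convention. Dosages count copies of the "A" allele
#' (0, 1 or 2); missing calls are `NA`, and mean-imputed dosages may be
#' real-valued in `[0, 2]`.
#'
#' Use [dosages()] to obtain the animals-by-SNPs matrix that the
#' relationship-matrix algebra operates on, and [alleleFreqs()] for per-SNP
#' frequencies of the counted allele, computed over non-missing calls.
#'
#' @seealso [GenotypeMatrix()] (constructor), [buildG()], [filterSnps()]
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!is.numeric(d))
    return("dosages must be numeric")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    return("dosages must lie in [0, 2] (or NA)")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    return("rowData must contain 'chrom' and 'pos' (the SNP map)")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("animal ids (colnames) must be present and unique")
  TRUE
})

#' Pedigree or genomic relationship matrix
#'
#' A symmetric animal-by-animal kernel with a provenance tag: `"A"` for the
#' pedigree numerator relationship matrix, `"GB0"` for the VanRaden genomic
#' matrix built from observed allele frequencies, `"GBBP"` for the same
#' matrix built from estimated base-population frequencies, and `"blended"`
#' for the polygenic blend (1 - w) G + w A.
#'
#' @slot ids character vector of animal identifiers (row/column order).
#' @slot values symmetric numeric matrix of relationships.
#' @slot kind one of `"A"`, `"GB0"`, `"GBBP"`, `"blended"`.
#' @slot blendWeight weight w on the A matrix (0 unless `kind == "blended"`).
#' @slot freqSource `"observed"`, `"base"` or `"none"` (for A).
#' @aliases RelationshipMatrix-class
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(ids = "character", values = "matrix", kind = "character",
                 blendWeight = "numeric", freqSource = "character"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  n <- length(object@ids)
  if (nrow(v) != n || ncol(v) != n)
    return("values must be square with one row/column per id")
  if (anyDuplicated(object@ids))
    return("animal ids must be unique")
  if (max(abs(v - t(v))) > 1e-10)
    return("values must be symmetric to 1e-10")
  if (any(diag(v) < 0))
    return("diagonal entries must be non-negative")
  if (!object@kind %in% c("A", "GB0", "GBBP", "blended"))
    return("kind must be one of A, GB0, GBBP, blended")
  if (object@blendWeight < 0 || object@blendWeight > 1)
    return("blendWeight must lie in [0, 1]")
  TRUE
})

#' Animal-by-animal distance matrix
#'
#' Symmetric non-negative distances with zero diagonal, derived either from
#' a genomic relationship matrix (kernel-induced metric, `source = "G"`) or
#' directly from allele dosages (Euclidean genotype distances,
#' `source = "EDM"`). Used by the hierarchical clustering validation
#' designs.
#'
#' @slot ids animal identifiers.
#' @slot values symmetric distance matrix.
#' @slot source `"G"` or `"EDM"`.
#' @aliases DistanceMatrix-class
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(ids = "character", values = "matrix", source = "character"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  n <- length(object@ids)
  if (nrow(v) != n || ncol(v) != n)
    return("values must be square with one row/column per id")
  if (max(abs(v - t(v))) > 1e-8)
    return("distances must be symmetric")
  if (any(v < -1e-12))
    return("distances must be non-negative")
  if (any(abs(diag(v)) > 1e-10))
    return("diagonal must be zero")
  if (!object@source %in% c("G", "EDM"))
    return("source must be 'G' or 'EDM'")
  TRUE
})

#' REML variance components for a single-kernel animal model
#'
#' Additive and residual variances for y = 1 mu + u + e with
#' var(u) = K sigma_A^2, the implied heritability
#' h^2 = sigma_A^2 / (sigma_A^2 + sigma_e^2), and the approximate standard
#' error of h^2 from the average-information matrix.
#'
#' @slot sigma2A additive genetic variance (trait units squared).
#' @slot sigma2E residual variance.
#' @slot h2 heritability on the adjusted-phenotype scale.
#' @slot seH2 approximate standard error of h2.
#' @slot iterations iterations used by the REML solver.
#' @slot converged logical convergence flag.
#' @slot logLik restricted log-likelihood at the optimum.
#' @aliases VarianceComponents-class
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigma2A = "numeric", sigma2E = "numeric", h2 = "numeric",
                 seH2 = "numeric", iterations = "integer",
                 converged = "logical", logLik = "numeric"))

setValidity("VarianceComponents", function(object) {
  if (object@sigma2A < 0 || object@sigma2E < 0)
    return("variances must be non-negative")
  if (object@h2 < 0 || object@h2 > 1)
    return("h2 must lie in [0, 1]")
  TRUE
})

#' Fixed-effect-adjusted phenotypes
#'
#' Residual phenotypes after ordinary least-squares removal of systematic
#' and contemporary-group effects, optionally followed by regression on
#' leading principal components of the genomic relationship matrix. The PC
#' betas are retained so that the removed component can be added back onto
#' molecular breeding values.
#'
#' @slot ids animal identifiers (one record per animal).
#' @slot values adjusted phenotype values (trait units).
#' @slot trait trait name.
#' @slot nPcsRemoved number of PCs regressed out (0 if none).
#' @slot fixedCoefs fitted fixed-effect coefficients.
#' @slot pcBetas coefficients of the PC regression (length `nPcsRemoved`).
#' @aliases AdjustedPhenotypes-class
#' @exportClass AdjustedPhenotypes
setClass("AdjustedPhenotypes",
  representation(ids = "character", values = "numeric", trait = "character",
                 nPcsRemoved = "integer", fixedCoefs = "numeric",
                 pcBetas = "numeric"))

setValidity("AdjustedPhenotypes", function(object) {
  if (length(object@ids) != length(object@values))
    return("ids and values must have equal length")
  if (anyDuplicated(object@ids))
    return("one record per animal is required")
  if (length(object@pcBetas) != object@nPcsRemoved)
    return("pcBetas must have one entry per removed PC")
  TRUE
})

#' GBLUP solution
#'
#' Molecular breeding values (predicted random animal effects), the overall
#' mean, and optionally per-animal prediction-error variances and
#' theoretical accuracies from the inverse of the mixed-model-equation
#' coefficient matrix.
#'
#' @slot ids animal identifiers (all animals in the kernel).
#' @slot mu overall mean estimate.
#' @slot mbv molecular breeding values, one per id.
#' @slot pev prediction-error variances (NA when not requested).
#' @slot accT theoretical accuracies sqrt(1 - PEV / (sigma_g^2 K_ii)).
#' @slot sigma2G,sigma2E variance components used in the solve.
#' @slot kernelKind provenance tag of the kernel used.
#' @aliases GBLUPResult-class
#' @exportClass GBLUPResult
setClass("GBLUPResult",
  representation(ids = "character", mu = "numeric", mbv = "numeric",
                 pev = "numeric", accT = "numeric", sigma2G = "numeric",
                 sigma2E = "numeric", kernelKind = "character"))

setValidity("GBLUPResult", function(object) {
  n <- length(object@ids)
  if (length(object@mbv) != n)
    return("one mBV per animal id is required")
  if (length(object@pev) != n || length(object@accT) != n)
    return("pev and accT must have one entry per id (NA allowed)")
  if (any(object@pev < 0, na.rm = TRUE))
    return("prediction-error variances must be non-negative")
  TRUE
})

#' Named validation scenario
#'
#' Binds a kernel recipe (GB0 / GBBP / blended), a population-structure
#' adjustment (number of G-matrix principal components regressed out of the
#' phenotypes), and a training/validation split design. Scenarios are
#' normally obtained from [scenarioRegistry()] by name.
#'
#' @slot name scenario name (e.g. `"GB0"`, `"GBKCV"`, `"K10G"`).
#' @slot kernelKind `"GB0"`, `"GBBP"` or `"blended"`.
#' @slot blendW weight on A when blending.
#' @slot nPcs number of PCs removed from the phenotypes (0, 2, 4 or 6).
#' @slot design one of `"forward"`, `"random_cv"`, `"kmeans_cv"`,
#'   `"cluster_forward"`, `"genomic_cluster_forward"`.
#' @slot k number of folds or clusters for the design.
#' @slot distanceSource `"G"` or `"EDM"` for hierarchical clustering
#'   designs, `"none"` otherwise.
#' @slot minValid smallest validation group that is retained (groups at or
#'   below this size are skipped and logged).
#' @slot seed RNG seed recorded with the scenario.
#' @aliases ScenarioSpec-class
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(name = "character", kernelKind = "character",
                 blendW = "numeric", nPcs = "integer", design = "character",
                 k = "integer", distanceSource = "character",
                 minValid = "integer", seed = "integer"))

setValidity("ScenarioSpec", function(object) {
  if (!object@design %in% c("forward", "random_cv", "kmeans_cv",
                            "cluster_forward", "genomic_cluster_forward"))
    return("unknown split design")
  if (!object@kernelKind %in% c("GB0", "GBBP", "blended"))
    return("kernelKind must be GB0, GBBP or blended")
  if (object@blendW < 0 || object@blendW > 1)
    return("blendW must lie in [0, 1]")
  TRUE
})

#' Per-trait, per-scenario accuracy report
#'
#' One row per trait-by-scenario combination with the observed accuracy
#' (weighted across validation groups), its SD across groups, group sizes,
#' the expected accuracy AccE, the mean theoretical accuracy AccT, the
#' effective number of progeny ENP and the K spread factor.
#'
#' @slot rows data.frame of report rows (see [assembleReport()]).
#' @slot groups data.frame of retained per-group metrics.
#' @slot skipped data.frame of validation groups excluded by the
#'   minimum-size rule.
#' @aliases AccuracyReport-class
#' @exportClass AccuracyReport
setClass("AccuracyReport",
  representation(rows = "data.frame", groups = "data.frame",
                 skipped = "data.frame"))

REPORT_COLUMNS <- c("trait", "scenario", "accuracy", "accuracy_sd",
                    "n_train", "n_valid", "n_groups", "h2", "acc_expected",
                    "acc_theoretical", "enp", "k_factor", "alpha")

setValidity("AccuracyReport", function(object) {
  if (!all(REPORT_COLUMNS %in% colnames(object@rows)))
    return(paste("report rows must contain columns:",
                 paste(REPORT_COLUMNS, collapse = ", ")))
  TRUE
})
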