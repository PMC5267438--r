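#' @include AllGenerics.R
NULL

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of allele dosages, animals in rows and SNPs
#'   in columns, values in `{0, 1, 2}` or `NA` (real values in `[0, 2]` are
#'   accepted for imputed data). Row and column names supply animal and SNP
#'   ids; `animalIds`/`snpIds` override them.
#' @param map data.frame with one row per SNP and columns `chrom` and `pos`
#'   (1-based base-pair position). Defaults to a single pseudo-chromosome
#'   with consecutive positions.
#' @param animalIds,snpIds optional identifier vectors.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'                             dimnames = list(c("a1", "a2", "a3"),
#'                                             c("s1", "s2"))))
#' alleleFreqs(gm)
#' @export
GenotypeMatrix <- function(dosages, map = NULL, animalIds = NULL,
                           snpIds = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(animalIds))
    animalIds <- rownames(dosages)
  if (is.null(snpIds))
    snpIds <- colnames(dosages)
  if (is.null(animalIds))
    animalIds <- paste0("animal", seq_len(nrow(dosages)))
  if (is.null(snpIds))
    snpIds <- paste0("snp", seq_len(ncol(dosages)))
  if (is.null(map))
    map <- data.frame(chrom = rep(1L, ncol(dosages)),
                      pos = seq_len(ncol(dosages)))
  if (nrow(map) != ncol(dosages))
    stop("map must have one row per SNP")
  storage.mode(dosages) <- "double"    # canonical storage for roundtrips
  map$pos <- as.numeric(map$pos)
  a <- t(dosages)                      # assay convention: SNPs x animals
  dimnames(a) <- list(snpIds, animalIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = a),
    rowData = S4Vectors::DataFrame(chrom = map$chrom, pos = map$pos,
                                   row.names = snpIds))
  new("GenotypeMatrix", se)
}

#' @rdname accessors
#' @export
setMethod("animalIds", "GenotypeMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname accessors
#' @export
setMethod("snpMap", "GenotypeMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(snp_id = rownames(x), chrom = rd$chrom, pos = rd$pos,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @details For `alleleFreqs()` the frequency of a SNP with no observed
#'   calls is `NaN` (undefined), never 0.
#' @export
setMethod("alleleFreqs", "GenotypeMatrix", function(x) {
  d <- SummarizedExperiment::assay(x, "dosage")
  rowMeans(d, na.rm = TRUE) / 2
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  nmiss <- sum(is.na(d))
  cat("GenotypeMatrix:", ncol(object), "animals x", nrow(object), "SNPs\n")
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(d)))
  cat("  chromosomes:",
      length(unique(SummarizedExperiment::rowData(object)$chrom)), "\n")
})

#' Construct a RelationshipMatrix
#'
#' Low-level constructor; most users obtain relationship matrices from
#' [buildA()], [buildG()] or [blendGA()].
#'
#' @param values symmetric numeric matrix.
#' @param ids animal identifiers (defaults to rownames).
#' @param kind provenance tag: `"A"`, `"GB0"`, `"GBBP"` or `"blended"`.
#' @param blendWeight weight on A for blended kernels.
#' @param freqSource `"observed"`, `"base"` or `"none"`.
#' @return a [RelationshipMatrix-class].
#' @export
RelationshipMatrix <- function(values, ids = rownames(values), kind = "GB0",
                               blendWeight = 0, freqSource = "none") {
  values <- as.matrix(values)
  if (is.null(ids))
    ids <- paste0("animal", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  new("RelationshipMatrix", ids = as.character(ids), values = values,
      kind = kind, blendWeight = blendWeight, freqSource = freqSource)
}

#' @rdname accessors
#' @export
setMethod("animalIds", "RelationshipMatrix", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("kind", "RelationshipMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("blendWeight", "RelationshipMatrix", function(x) x@blendWeight)

#' @export
#' @describeIn RelationshipMatrix coerce to a base matrix.
#' @param x,... see base [as.matrix()].
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix (%s): %d animals\n", object@kind,
              length(object@ids)))
  if (object@kind == "blended")
    cat("  blend weight on A:", object@blendWeight, "\n")
  cat(sprintf("  mean diagonal: %.4f; mean off-diagonal: %.4f\n",
              mean(diag(object@values)),
              mean(object@values[upper.tri(object@values)])))
})

#' Subset a relationship matrix to a set of animals
#'
#' @param x a [RelationshipMatrix-class] or [DistanceMatrix-class].
#' @param i animal identifiers (or indices) to keep, in the requested order.
#' @param j,drop,... ignored; subsetting is symmetric in both dimensions.
#' @return an object of the same class restricted to the requested animals.
#' @export
setMethod("[", "RelationshipMatrix", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i) && !all(i %in% x@ids))
    stop("unknown animal ids in subset")
  v <- x@values[i, i, drop = FALSE]
  RelationshipMatrix(v, ids = rownames(v), kind = x@kind,
                     blendWeight = x@blendWeight, freqSource = x@freqSource)
})

#' Construct a DistanceMatrix
#'
#' @param values symmetric non-negative matrix with zero diagonal.
#' @param ids animal identifiers.
#' @param source `"G"` or `"EDM"`.
#' @return a [DistanceMatrix-class].
#' @export
DistanceMatrix <- function(values, ids = rownames(values), source = "G") {
  values <- as.matrix(values)
  if (is.null(ids))
    ids <- paste0("animal", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  new("DistanceMatrix", ids = as.character(ids), values = values,
      source = source)
}

#' @rdname accessors
#' @export
setMethod("animalIds", "DistanceMatrix", function(x) x@ids)

#' @export
#' @describeIn DistanceMatrix coerce to a base matrix.
#' @param x,... see base [as.matrix()].
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d animals, mean distance %.4f\n",
              object@source, length(object@ids),
              mean(object@values[upper.tri(object@values)])))
})

#' Construct a VarianceComponents object
#'
#' @param sigma2A,sigma2E additive and residual variances.
#' @param seH2 approximate standard error of the heritability.
#' @param iterations,converged,logLik solver diagnostics.
#' @return a [VarianceComponents-class].
#' @export
VarianceComponents <- function(sigma2A, sigma2E, seH2 = NA_real_,
                               iterations = 0L, converged = TRUE,
                               logLik = NA_real_) {
  h2 <- if (sigma2A + sigma2E > 0) sigma2A / (sigma2A + sigma2E) else 0
  new("VarianceComponents", sigma2A = sigma2A, sigma2E = sigma2E, h2 = h2,
      seH2 = seH2, iterations = as.integer(iterations),
      converged = converged, logLik = logLik)
}

#' @rdname accessors
#' @export
setMethod("sigma2A", "VarianceComponents", function(x) x@sigma2A)

#' @rdname accessors
#' @export
setMethod("sigma2E", "VarianceComponents", function(x) x@sigma2E)

#' @rdname accessors
#' @export
setMethod("heritability", "VarianceComponents", function(x) x@h2)

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: sigma2A = %.4f, sigma2E = %.4f\n",
              object@sigma2A, object@sigma2E))
  cat(sprintf("  h2 = %.3f (SE %.3f), %d iterations, converged: %s\n",
              object@h2, object@seH2, object@iterations, object@converged))
})

#' @rdname accessors
#' @export
setMethod("animalIds", "AdjustedPhenotypes", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("adjustedValues", "AdjustedPhenotypes", function(x)
  setNames(x@values, x@ids))

setMethod("show", "AdjustedPhenotypes", function(object) {
  cat(sprintf("AdjustedPhenotypes ('%s'): %d records, %d PCs removed\n",
              object@trait, length(object@ids), object@nPcsRemoved))
  cat(sprintf("  mean %.4g, sd %.4g\n", mean(object@values),
              sd(object@values)))
})

#' @rdname accessors
#' @export
setMethod("animalIds", "GBLUPResult", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("mbv", "GBLUPResult", function(x) setNames(x@mbv, x@ids))

#' @rdname accessors
#' @export
setMethod("pev", "GBLUPResult", function(x) setNames(x@pev, x@ids))

#' @rdname accessors
#' @export
setMethod("accTheoretical", "GBLUPResult", function(x)
  setNames(x@accT, x@ids))

#' @rdname accessors
#' @export
setMethod("overallMean", "GBLUPResult", function(x) x@mu)

setMethod("show", "GBLUPResult", function(object) {
  cat(sprintf("GBLUPResult (%s kernel): %d animals, mu = %.4f\n",
              object@kernelKind, length(object@ids), object@mu))
  cat(sprintf("  sd(mBV) = %.4f", sd(object@mbv)))
  if (!all(is.na(object@accT)))
    cat(sprintf(", mean AccT = %.3f", mean(object@accT, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec '%s': kernel %s", object@name,
              object@kernelKind))
  if (object@kernelKind == "blended")
    cat(sprintf(" (w = %.2f)", object@blendW))
  if (object@nPcs > 0)
    cat(sprintf(", %d PCs removed", object@nPcs))
  cat(sprintf("; design %s", object@design))
  if (object@design != "forward")
    cat(sprintf(" (k = %d)", object@k))
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("reportRows", "AccuracyReport", function(x) x@rows)

setMethod("show", "AccuracyReport", function(object) {
  cat("AccuracyReport:", nrow(object@rows), "trait x scenario rows\n")
  if (nrow(object@rows) > 0)
    print(head(object@rows[, c("trait", "scenario", "accuracy", "n_train",
                               "n_valid", "enp", "k_factor")], 10))
  if (nrow(object@skipped) > 0)
    cat("  skipped validation groups:", nrow(object@skipped), "\n")
})
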