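#' @include containers.R
NULL

# Adds a small diagonal ridge (relative to the mean diagonal) before
# factorising near-singular kernels; returns the ridged matrix.
ridgeKernel <- function(K, rel = 1e-6) {
  K + diag(rel * mean(diag(K)), nrow(K))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds A by the tabular recursion over a topologically sorted pedigree:
#' founders are unrelated and non-inbred (A_ii = 1), an offspring's
#' relationship to any older animal is the average of its parents'
#' relationships, and its diagonal is 1 plus half the parents'
#' relationship (inbreeding from related parents).
#'
#' @param pedigree pedigree data.frame with `animal`, `sire`, `dam`
#'   (`"0"` = unknown).
#' @return a [RelationshipMatrix-class] with `kind = "A"`, rows/columns in
#'   pedigree (sorted) order.
#' @examples
#' ped <- data.frame(animal = c("s", "d", "o"), sire = c("0", "0", "s"),
#'                   dam = c("0", "0", "d"))
#' as.matrix(buildA(ped))
#' @export
buildA <- function(pedigree) {
  ped <- checkPedigree(pedigree)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- ifelse(ped$sire == UNKNOWN_PARENT, 0L, idx[ped$sire])
  di <- ifelse(ped$dam == UNKNOWN_PARENT, 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (s > 0) A[s, j] else 0
      ad_ <- if (d > 0) A[d, j] else 0
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  RelationshipMatrix(A, ids = ped$animal, kind = "A", freqSource = "none")
}

#' VanRaden genomic relationship matrix
#'
#' G = (M - 2P)(M - 2P)' / (2 sum_i p_i (1 - p_i)), where M holds allele
#' dosages (animals x SNPs) and row i of P repeats the counted-allele
#' frequency p_i. With observed frequencies the centred dosages sum to zero
#' per SNP and G row-sums vanish; with estimated base-population
#' frequencies the matrix is tagged `"GBBP"`.
#'
#' @param geno a complete (imputed) [GenotypeMatrix-class].
#' @param freqs per-SNP frequencies of the counted allele; default: the
#'   observed frequencies.
#' @param freqSource `"observed"` or `"base"` (controls the provenance
#'   tag).
#' @return a [RelationshipMatrix-class] (`kind` `"GB0"` or `"GBBP"`).
#' @export
buildG <- function(geno, freqs = NULL,
                   freqSource = c("observed", "base")) {
  freqSource <- match.arg(freqSource)
  M <- dosages(geno)
  if (anyNA(M))
    stop("genotypes contain missing dosages; run imputeMissing() first")
  if (is.null(freqs)) freqs <- alleleFreqs(geno)
  if (length(freqs) != ncol(M))
    stop("one frequency per SNP is required")
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("2 * sum(p (1 - p)) is zero: no polymorphic SNPs at these ",
         "frequencies")
  Z <- sweep(M, 2, 2 * freqs)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  RelationshipMatrix(G, ids = rownames(M),
                     kind = if (freqSource == "observed") "GB0" else "GBBP",
                     freqSource = freqSource)
}

#' Estimate base-population allele frequencies
#'
#' Generalized-least-squares estimator of the founder (base) allele
#' frequency per SNP, using the pedigree relationship matrix as the
#' covariance of drift among genotyped animals:
#' p_hat = (1' A^-1 m) / (2 * 1' A^-1 1), where m is the dosage vector of
#' the genotyped animals. Estimates are clamped to
#' `[1/(2n), 1 - 1/(2n)]`. With A = I this collapses to half the mean
#' dosage; on founders it returns the observed founder frequency.
#'
#' @param geno a complete [GenotypeMatrix-class].
#' @param A a pedigree [RelationshipMatrix-class] covering (at least) the
#'   genotyped animals.
#' @return named per-SNP base frequencies.
#' @export
estimateBaseFrequencies <- function(geno, A) {
  M <- dosages(geno)
  if (anyNA(M))
    stop("genotypes must be complete")
  ids <- rownames(M)
  if (!all(ids %in% animalIds(A)))
    stop("genotyped animals missing from A: ",
         paste(head(setdiff(ids, animalIds(A))), collapse = ", "))
  Asub <- as.matrix(A)[ids, ids]
  w <- tryCatch(solve(Asub, rep(1, length(ids))),
                error = function(e) stop("singular A submatrix: ",
                                         conditionMessage(e)))
  p <- drop(crossprod(w, M)) / (2 * sum(w))
  n <- length(ids)
  pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Census effective population size from a pedigree
#'
#' Sex-ratio census estimator Ne = 4 Nm Nf / (Nm + Nf), with Nm and Nf
#' the numbers of breeding males and females entering per generation:
#' distinct sires (dams) per drop year, scaled by the mean generation
#' interval (average parent age at progeny birth). A deliberately simple
#' input for the expected-accuracy formula; populations with real
#' linkage-disequilibrium estimates should pass their own Ne instead.
#'
#' @param pedigree pedigree data.frame with `sire`, `dam`, `birth_year`.
#' @return list with `ne`, `nm`, `nf` and the generation interval `L`.
#' @export
pedigreeNe <- function(pedigree) {
  off <- pedigree[pedigree$sire != UNKNOWN_PARENT, , drop = FALSE]
  if (nrow(off) == 0)
    stop("pedigree has no progeny records")
  yr <- setNames(pedigree$birth_year, pedigree$animal)
  genInterval <- mean(c(off$birth_year - yr[off$sire],
                        off$birth_year - yr[off$dam]), na.rm = TRUE)
  nmYear <- mean(tapply(off$sire, off$birth_year,
                        function(x) length(unique(x))))
  nfYear <- mean(tapply(off$dam, off$birth_year,
                        function(x) length(unique(x))))
  nm <- min(nmYear * genInterval, length(unique(off$sire)))
  nf <- min(nfYear * genInterval, length(unique(off$dam)))
  list(ne = 4 * nm * nf / (nm + nf), nm = nm, nf = nf, L = genInterval)
}

#' Blend genomic and pedigree relationship matrices
#'
#' G* = (1 - w) G + w A, the polygenic blend equivalent to fitting a
#' residual polygenic effect with weight w (w = 0.10 and 0.20 correspond
#' to giving 10% or 20% of the variance to the pedigree).
#'
#' @param G,A [RelationshipMatrix-class] objects over the same animals in
#'   the same order.
#' @param w weight on A, in `[0, 1]`.
#' @return a [RelationshipMatrix-class] with `kind = "blended"` (or the
#'   untouched input when w is exactly 0 or 1).
#' @export
blendGA <- function(G, A, w) {
  if (w < 0 || w > 1)
    stop("blend weight must lie in [0, 1]")
  if (!identical(animalIds(G), animalIds(A)))
    stop("G and A must cover the same animals in the same order")
  if (w == 0) return(G)
  if (w == 1) return(A)
  RelationshipMatrix((1 - w) * as.matrix(G) + w * as.matrix(A),
                     ids = animalIds(G), kind = "blended",
                     blendWeight = w, freqSource = G@freqSource)
}

#' Kernel-induced genomic distance
#'
#' d_ij = sqrt(max(0, G_ii + G_jj - 2 G_ij)), the metric induced by
#' treating G as an inner-product (kernel) matrix.
#'
#' @param G a [RelationshipMatrix-class].
#' @return a [DistanceMatrix-class] with `source = "G"`.
#' @export
genomicDistance <- function(G) {
  v <- as.matrix(G)
  dg <- diag(v)
  d2 <- outer(dg, dg, "+") - 2 * v
  d <- sqrt(pmax(d2, 0))
  diag(d) <- 0
  d <- (d + t(d)) / 2
  DistanceMatrix(d, ids = animalIds(G), source = "G")
}

#' Euclidean genotype distance matrix (EDM)
#'
#' Plain Euclidean distances between raw (uncentred) dosage rows:
#' d_ij = sqrt(sum_k (m_ik - m_jk)^2).
#'
#' @param geno a complete [GenotypeMatrix-class].
#' @return a [DistanceMatrix-class] with `source = "EDM"`.
#' @export
euclideanDistance <- function(geno) {
  M <- dosages(geno)
  if (anyNA(M))
    stop("genotypes must be complete")
  d <- as.matrix(dist(M))
  DistanceMatrix(d, ids = rownames(M), source = "EDM")
}

#' Principal components of a genomic relationship matrix
#'
#' Eigen-decomposes G and returns per-animal scores scaled so that
#' scores %*% t(scores) over all components reconstructs G: score column k
#' is eigenvector k times sqrt(eigenvalue k), in descending eigenvalue
#' order. The sign of each component is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param G a [RelationshipMatrix-class].
#' @param nComponents number of leading components to return.
#' @return list with `scores` (animals x nComponents matrix) and
#'   `eigenvalues` (all n, descending).
#' @export
pcaOfG <- function(G, nComponents = 10) {
  v <- as.matrix(G)
  n <- nrow(v)
  if (nComponents > n)
    stop("nComponents exceeds the number of animals")
  e <- eigen(v, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  k <- seq_len(nComponents)
  scores <- e$vectors[, k, drop = FALSE] %*%
    diag(sqrt(lambda[k]), nComponents)
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (length(i) == 1 && scores[i, j] < 0)
      scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(animalIds(G),
                           if (nComponents > 0)
                             paste0("PC", k) else NULL)
  list(scores = scores, eigenvalues = e$values)
}
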