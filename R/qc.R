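#' @include containers.R
NULL

#' Quality-control thresholds
#'
#' Default values are the editing rules of a typical HD-chip sheep
#' evaluation: SNPs are dropped when the minor allele frequency is below
#' 0.01, the call rate below 0.95, or the Hardy-Weinberg chi-square p-value
#' below 1e-15 (an extreme-departure screen); contemporary groups must
#' contain more than three records, and records more than three standard
#' deviations from their contemporary-group mean are treated as outliers.
#'
#' @param mafMin minimum minor allele frequency.
#' @param callRateMin minimum per-SNP call rate.
#' @param hwePMin minimum Hardy-Weinberg p-value.
#' @param cgMinRecords minimum contemporary-group size (a CG is kept when
#'   it has at least this many records; the default 4 encodes "more than
#'   three").
#' @param outlierSd outlier cutoff in CG standard deviations.
#' @return a validated list of class `QCThresholds`.
#' @export
qcThresholds <- function(mafMin = 0.01, callRateMin = 0.95,
                         hwePMin = 1e-15, cgMinRecords = 4, outlierSd = 3) {
  if (mafMin < 0 || mafMin > 0.5)
    stop("mafMin must lie in [0, 0.5]")
  if (callRateMin < 0 || callRateMin > 1)
    stop("callRateMin must lie in [0, 1]")
  if (hwePMin < 0 || hwePMin > 1)
    stop("hwePMin must lie in [0, 1]")
  if (cgMinRecords < 0 || outlierSd <= 0)
    stop("cgMinRecords must be >= 0 and outlierSd > 0")
  structure(list(mafMin = mafMin, callRateMin = callRateMin,
                 hwePMin = hwePMin, cgMinRecords = as.integer(cgMinRecords),
                 outlierSd = outlierSd),
            class = "QCThresholds")
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against Hardy-Weinberg expectations at the observed allele
#' frequency. Monomorphic input returns p = 1 by convention: with one
#' allele absent there is no departure to test.
#'
#' @param nAA,nAB,nBB genotype counts (AA carries two counted alleles).
#' @return the chi-square p-value.
#' @examples
#' hweChisqP(25, 50, 25)   # exact HWE proportions: p = 1
#' hweChisqP(10, 0, 10)    # total heterozygote deficit
#' @export
hweChisqP <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n <= 0)
    stop("total genotype count must be positive")
  p <- (2 * nAA + nAB) / (2 * n)
  if (p == 0 || p == 1)
    return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(nAA, nAB, nBB) - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Filter SNPs on frequency, call rate, HWE and map sanity
#'
#' Applies the marker editing rules in a fixed order and logs the first
#' failing rule for every dropped SNP: minor allele frequency (computed
#' from non-missing calls, before any imputation), call rate,
#' Hardy-Weinberg departure, unknown map position, non-autosomal
#' chromosome code, and duplicated (chromosome, position) pairs (all SNPs
#' sharing a duplicated position are removed).
#'
#' @param geno a [GenotypeMatrix-class] with integer (unimputed) dosages.
#' @param thresholds a [qcThresholds()] list.
#' @param autosomes chromosome codes accepted as autosomal; defaults to
#'   every strictly positive integer code.
#' @return list with `genotypes` (the surviving panel) and `exclusions`
#'   (data.frame `snp_id`, `reason`).
#' @export
filterSnps <- function(geno, thresholds = qcThresholds(),
                       autosomes = NULL) {
  d <- dosages(geno)
  map <- snpMap(geno)
  nSnp <- ncol(d)
  reason <- rep(NA_character_, nSnp)

  p <- alleleFreqs(geno)
  maf <- pmin(p, 1 - p)
  callRate <- colMeans(!is.na(d))
  hweP <- vapply(seq_len(nSnp), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    hweChisqP(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))

  chromNum <- suppressWarnings(as.numeric(as.character(map$chrom)))
  unknownPos <- is.na(map$pos) | map$pos <= 0 | is.na(map$chrom)
  if (is.null(autosomes)) {
    nonAuto <- !is.na(map$chrom) &
      (is.na(chromNum) | chromNum <= 0 | chromNum != round(chromNum))
  } else {
    nonAuto <- !(as.character(map$chrom) %in% as.character(autosomes))
  }
  key <- paste(map$chrom, map$pos)
  dupPos <- key %in% key[duplicated(key)] & !unknownPos

  fail <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  fail(!is.na(maf) & maf < thresholds$mafMin, "low_maf")
  fail(callRate < thresholds$callRateMin, "low_call_rate")
  fail(!is.na(hweP) & hweP < thresholds$hwePMin, "hwe_departure")
  fail(unknownPos, "unknown_position")
  fail(nonAuto, "non_autosomal")
  fail(dupPos, "duplicate_position")

  keep <- is.na(reason)
  if (!any(keep))
    stop("all SNPs removed by quality control: empty panel")
  exclusions <- data.frame(snp_id = colnames(d)[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  out <- GenotypeMatrix(d[, keep, drop = FALSE],
                        map = map[keep, c("chrom", "pos")],
                        animalIds = rownames(d),
                        snpIds = colnames(d)[keep])
  list(genotypes = out, exclusions = exclusions)
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing call by the SNP's mean observed dosage, i.e. twice
#' the observed allele frequency. Observed calls are never modified. This
#' is a deliberately simple single-site imputer: it preserves allele
#' frequencies and keeps the centred dosage of imputed calls at zero, so
#' imputed animals contribute no spurious relationship signal.
#'
#' @param geno a [GenotypeMatrix-class]; every SNP must have at least one
#'   observed call (run [filterSnps()] first).
#' @return a complete [GenotypeMatrix-class] with real-valued dosages.
#' @export
imputeMissing <- function(geno) {
  d <- dosages(geno)
  if (!anyNA(d))
    return(geno)
  obs <- colSums(!is.na(d))
  if (any(obs == 0))
    stop("SNP(s) with zero observed calls: ",
         paste(head(colnames(d)[obs == 0]), collapse = ", "),
         " (filter before imputing)")
  mean_dosage <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mean_dosage[idx[, 2]]
  GenotypeMatrix(d, map = snpMap(geno)[, c("chrom", "pos")],
                 animalIds = rownames(d), snpIds = colnames(d))
}

#' Filter phenotype records by contemporary-group rules
#'
#' Single-pass editing: records in contemporary groups with fewer than
#' `cgMinRecords` observations are dropped; then records more than
#' `outlierSd` standard deviations from their CG mean (mean and SD computed
#' over all CG records including the candidate) are dropped; finally the
#' CG-size rule is re-applied once, since outlier removal can shrink a
#' group below the minimum.
#'
#' @param pheno phenotype data.frame (see [readPhenotypes()]).
#' @param thresholds a [qcThresholds()] list.
#' @param trait trait to edit (default: the single trait present).
#' @param cgCols columns defining the contemporary group.
#' @return list with `phenotypes` (retained records) and `exclusions`
#'   (data.frame `animal`, `reason`).
#' @export
filterPhenotypes <- function(pheno, thresholds = qcThresholds(),
                             trait = NULL,
                             cgCols = intersect(c("flock", "birth_year",
                                                  "sex", "mob"),
                                                colnames(pheno))) {
  if (is.null(trait)) {
    trait <- unique(pheno$trait)
    if (length(trait) != 1)
      stop("multiple traits present; specify 'trait'")
  }
  if (!trait %in% pheno$trait)
    stop("trait '", trait, "' absent from phenotype table")
  if (length(cgCols) == 0)
    stop("no contemporary-group columns present")
  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  cg <- interaction(ph[, cgCols], drop = TRUE)
  removed <- list()

  small <- ave(seq_along(cg), cg, FUN = length) < thresholds$cgMinRecords
  if (any(small))
    removed$small <- data.frame(animal = ph$animal[small],
                                reason = "small_cg")
  ph2 <- ph[!small, , drop = FALSE]
  cg2 <- droplevels(cg[!small])

  cgMean <- ave(ph2$value, cg2, FUN = mean)
  cgSd <- ave(ph2$value, cg2, FUN = sd)
  outlier <- !is.na(cgSd) & cgSd > 0 &
    abs(ph2$value - cgMean) > thresholds$outlierSd * cgSd
  if (any(outlier))
    removed$outlier <- data.frame(animal = ph2$animal[outlier],
                                  reason = "cg_outlier")
  ph3 <- ph2[!outlier, , drop = FALSE]
  cg3 <- droplevels(cg2[!outlier])

  small2 <- ave(seq_along(cg3), cg3, FUN = length) < thresholds$cgMinRecords
  if (any(small2))
    removed$small2 <- data.frame(animal = ph3$animal[small2],
                                 reason = "small_cg_after_outliers")
  out <- ph3[!small2, , drop = FALSE]
  exclusions <- if (length(removed) > 0) do.call(rbind, removed)
                else data.frame(animal = character(0),
                                reason = character(0))
  rownames(exclusions) <- NULL
  list(phenotypes = out, exclusions = exclusions)
}
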