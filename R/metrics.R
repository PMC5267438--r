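#' @include containers.R
NULL

#' Observed accuracy of molecular breeding values
#'
#' Pearson correlation between mBVs and fixed-effect-adjusted phenotypes
#' in a validation population, divided by the square root of the trait
#' heritability to account for the upper limit a phenotype places on the
#' correlation. Values can exceed 1 by sampling and are reported as
#' computed (with a message), never clipped; negative values are likewise
#' kept.
#'
#' @param mbvValues,adjustedPhenotypes paired numeric vectors over the
#'   validation animals.
#' @param h2 trait heritability (positive).
#' @return the observed accuracy r.
#' @export
observedAccuracy <- function(mbvValues, adjustedPhenotypes, h2) {
  if (length(mbvValues) != length(adjustedPhenotypes))
    stop("mBVs and phenotypes must be paired")
  if (length(mbvValues) < 2)
    stop("at least two pairs are required")
  if (h2 <= 0)
    stop("heritability must be positive")
  if (sd(mbvValues) == 0 || sd(adjustedPhenotypes) == 0) {
    warning("zero variance in mBVs or phenotypes: accuracy undefined")
    return(NA_real_)
  }
  r <- cor(mbvValues, adjustedPhenotypes) / sqrt(h2)
  if (is.finite(r) && abs(r) > 1)
    message("observed accuracy ", format(round(r, 3)),
            " exceeds 1 in magnitude (sampling); reported unclipped")
  r
}

#' Expected accuracy of genomic prediction
#'
#' Deterministic accuracy formula in the training size, heritability and
#' the effective number of independently segregating loci:
#' AccE = sqrt(Np h2 / (Np h2 + Me)) with Me = 2 Ne L / log(4 Ne L)
#' (natural logarithm, configurable via `logBase`).
#'
#' @param nTraining number of training animals Np.
#' @param h2 trait heritability.
#' @param ne effective population size.
#' @param genomeLength genome length L in Morgans (default 26).
#' @param logBase base of the logarithm in Me (default natural).
#' @return list with `accE` and `me`.
#' @examples
#' expectedAccuracy(2000, 0.3, ne = 380)
#' @export
expectedAccuracy <- function(nTraining, h2, ne, genomeLength = 26,
                             logBase = exp(1)) {
  if (nTraining < 0 || h2 < 0 || ne < 0 || genomeLength < 0)
    stop("all parameters must be non-negative")
  x <- 4 * ne * genomeLength
  if (x <= 1)
    stop("4 Ne L must exceed 1 for the Me formula")
  me <- 2 * ne * genomeLength / log(x, base = logBase)
  list(accE = sqrt(nTraining * h2 / (nTraining * h2 + me)), me = me)
}

#' Effective number of progeny
#'
#' The number of progeny records needed to complement the parent average
#' to match the accuracy of a molecular breeding value:
#' ENP = r^2 alpha / (1 - r^2) with alpha = (4 - h2) / h2.
#'
#' @param r observed accuracy of the mBVs (|r| < 1).
#' @param h2 trait heritability in (0, 1].
#' @param rounded return the nearest integer (as reported in summary
#'   tables) instead of the raw value.
#' @return ENP (raw, or nearest integer when `rounded = TRUE`).
#' @examples
#' effectiveNumberOfProgeny(0.40, 0.35)            # ~2 progeny
#' effectiveNumberOfProgeny(0.67, 0.24, rounded = TRUE)
#' @export
effectiveNumberOfProgeny <- function(r, h2, rounded = FALSE) {
  if (any(h2 <= 0 | h2 > 1))
    stop("heritability must lie in (0, 1]")
  if (any(abs(r) >= 1))
    stop("|r| must be below 1 (ENP is infinite at r = 1)")
  alpha <- (4 - h2) / h2
  enp <- r^2 * alpha / (1 - r^2)
  if (rounded) round(enp) else enp
}

#' K spread factor of molecular breeding values
#'
#' Ratio of the expected to the observed spread of mBVs,
#' K = r sigma_A / sd(mBV), with sd over the validation animals' mBVs
#' (denominator n - 1). K = 1 indicates well-calibrated dispersion;
#' K < 1 means the mBVs are more spread than their accuracy warrants
#' (inflation), K > 1 less spread.
#'
#' @param r observed accuracy for the scenario and trait.
#' @param sigma2A additive genetic variance of the trait.
#' @param mbvValues mBVs of the validation animals.
#' @return the K factor (NA with a warning for constant mBVs).
#' @export
spreadFactor <- function(r, sigma2A, mbvValues) {
  if (sigma2A < 0)
    stop("genetic variance must be non-negative")
  s <- sd(mbvValues)
  if (is.na(s) || s == 0) {
    warning("constant mBVs: spread factor undefined")
    return(NA_real_)
  }
  r * sqrt(sigma2A) / s
}

#' Dressing-out percentage
#'
#' Hot carcass weight as a percentage of pre-slaughter live weight,
#' 100 * HCW / PRESLT, computed per animal.
#'
#' @param hotCarcassWeight,preslaughterWeight paired positive weights (kg).
#' @return per-animal dressing-out percentages.
#' @export
dressingOutPct <- function(hotCarcassWeight, preslaughterWeight) {
  if (any(hotCarcassWeight <= 0) || any(preslaughterWeight <= 0))
    stop("weights must be positive")
  100 * hotCarcassWeight / preslaughterWeight
}

#' Weighted mean accuracy across validation groups
#'
#' sum(a_g n_g) / sum(n_g): group accuracies weighted by the number of
#' records in each validation group.
#'
#' @param accuracies per-group accuracies.
#' @param groupSizes per-group validation record counts (positive).
#' @return the weighted mean.
#' @export
weightedMeanAccuracy <- function(accuracies, groupSizes) {
  if (length(accuracies) == 0)
    stop("no group accuracies supplied")
  if (length(accuracies) != length(groupSizes))
    stop("accuracies and group sizes must be paired")
  if (any(groupSizes <= 0))
    stop("group sizes must be positive")
  sum(accuracies * groupSizes) / sum(groupSizes)
}

#' Assemble a per-trait, per-scenario accuracy report
#'
#' Combines retained validation-group metrics into one report row:
#' accuracy weighted by validation records, SD of accuracy across groups
#' (NA for a single group), total sizes, ENP and K recomputed from the
#' combined accuracy, and AccE evaluated at the mean training size.
#'
#' @param groupMetrics data.frame with one row per retained validation
#'   group and columns `accuracy`, `n_train`, `n_valid`, `mean_accT`,
#'   `k_factor`.
#' @param trait,scenario labels for the row.
#' @param h2 heritability used for scaling.
#' @param sigma2A additive variance (for K on the combined scale).
#' @param ne,genomeLength parameters of the expected-accuracy formula.
#' @param skipped data.frame of excluded groups (for the report record).
#' @return an [AccuracyReport-class] with a single row.
#' @export
assembleReport <- function(groupMetrics, trait, scenario, h2, sigma2A,
                           ne = 380, genomeLength = 26,
                           skipped = data.frame()) {
  if (nrow(groupMetrics) == 0)
    stop("all validation groups were excluded: empty report for ",
         trait, " / ", scenario)
  acc <- weightedMeanAccuracy(groupMetrics$accuracy,
                              groupMetrics$n_valid)
  accSd <- if (nrow(groupMetrics) > 1) sd(groupMetrics$accuracy)
           else NA_real_
  accE <- expectedAccuracy(mean(groupMetrics$n_train), h2, ne,
                           genomeLength)$accE
  enp <- if (abs(acc) < 1) effectiveNumberOfProgeny(acc, h2) else NA_real_
  kf <- weightedMeanAccuracy(groupMetrics$k_factor,
                             groupMetrics$n_valid)
  rows <- data.frame(trait = trait, scenario = scenario, accuracy = acc,
                     accuracy_sd = accSd,
                     n_train = sum(groupMetrics$n_train),
                     n_valid = sum(groupMetrics$n_valid),
                     n_groups = nrow(groupMetrics), h2 = h2,
                     acc_expected = accE,
                     acc_theoretical = weightedMeanAccuracy(
                       groupMetrics$mean_accT, groupMetrics$n_valid),
                     enp = enp, k_factor = kf,
                     alpha = (4 - h2) / h2,
                     stringsAsFactors = FALSE)
  new("AccuracyReport", rows = rows, groups = groupMetrics,
      skipped = as.data.frame(skipped))
}

#' Construct an (optionally empty) AccuracyReport
#'
#' @param rows report rows with the full column schema; defaults to an
#'   empty report, which [writeReport()] renders as a header-only file.
#' @param groups,skipped per-group detail tables.
#' @return an [AccuracyReport-class].
#' @export
AccuracyReport <- function(rows = NULL, groups = data.frame(),
                           skipped = data.frame()) {
  if (is.null(rows)) {
    rows <- as.data.frame(setNames(rep(list(numeric(0)),
                                       length(REPORT_COLUMNS)),
                                   REPORT_COLUMNS))
    rows$trait <- character(0)
    rows$scenario <- character(0)
  }
  new("AccuracyReport", rows = rows, groups = groups, skipped = skipped)
}

# rbind two AccuracyReports (used by scenario sweeps)
combineReports <- function(reports) {
  new("AccuracyReport",
      rows = do.call(rbind, lapply(reports, reportRows)),
      groups = do.call(rbind, lapply(reports, function(r) r@groups)),
      skipped = do.call(rbind, lapply(reports, function(r) r@skipped)))
}
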