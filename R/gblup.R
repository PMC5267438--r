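#' @include containers.R
NULL

#' Solve the GBLUP mixed-model equations
#'
#' Henderson's mixed-model equations for y = 1 mu + W a + e with
#' var(a) = K sigma_g^2 and var(e) = I sigma_e^2: every animal in the
#' kernel enters the random effect, while only phenotyped animals enter
#' the incidence matrix W, so validation candidates without records
#' receive molecular breeding values through their kernel relationships.
#' The kernel is ridged (1e-6 of the mean diagonal) before inversion.
#'
#' @param adj an [AdjustedPhenotypes-class]; its animals must be a subset
#'   of the kernel's.
#' @param kernel a [RelationshipMatrix-class].
#' @param vc a [VarianceComponents-class] (sigma_e^2 must be positive).
#' @param predictIds animals whose predictions are required; must be in
#'   the kernel. Purely a validity check - the result always covers every
#'   kernel animal.
#' @param computeAccT when `TRUE` (default) the coefficient-matrix inverse
#'   is formed and per-animal prediction-error variances and theoretical
#'   accuracies AccT_i = sqrt(1 - PEV_i / (sigma_g^2 K_ii)) are returned.
#' @return a [GBLUPResult-class].
#' @export
solveGblup <- function(adj, kernel, vc, predictIds = NULL,
                       computeAccT = TRUE) {
  ids <- animalIds(kernel)
  obs <- adj@ids
  if (!all(obs %in% ids))
    stop("phenotyped animals missing from the kernel: ",
         paste(head(setdiff(obs, ids)), collapse = ", "))
  if (!is.null(predictIds) && !all(predictIds %in% ids))
    stop("predictIds missing from the kernel: ",
         paste(head(setdiff(predictIds, ids)), collapse = ", "))
  s2g <- sigma2A(vc)
  s2e <- sigma2E(vc)
  if (s2e <= 0)
    stop("residual variance must be positive")
  y <- setNames(adj@values, obs)
  n <- length(ids)
  phen <- ids %in% obs
  yFull <- numeric(n)
  yFull[phen] <- y[ids[phen]]

  if (s2g <= 1e-12 * s2e) {       # no-signal limit: all mBVs vanish
    return(new("GBLUPResult", ids = ids, mu = mean(y),
               mbv = numeric(n), pev = rep(NA_real_, n),
               accT = rep(0, n), sigma2G = s2g, sigma2E = s2e,
               kernelKind = kind(kernel)))
  }

  K <- ridgeKernel(as.matrix(kernel))
  Kinv <- tryCatch(solve(K), error = function(e)
    stop("kernel is singular even after ridging: ", conditionMessage(e)))
  lambda <- s2e / s2g
  C <- matrix(0, n + 1, n + 1)
  C[1, 1] <- sum(phen)
  C[1, -1] <- C[-1, 1] <- as.numeric(phen)
  C[-1, -1] <- diag(as.numeric(phen)) + lambda * Kinv
  rhs <- c(sum(yFull), yFull)
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("singular mixed-model coefficient matrix: ",
         conditionMessage(e)))
  mu <- sol[1]
  a <- sol[-1]
  pevOut <- rep(NA_real_, n)
  accT <- rep(NA_real_, n)
  if (computeAccT) {
    Cinv <- solve(C)
    pevOut <- s2e * diag(Cinv)[-1]
    denom <- s2g * diag(K)
    ratio <- pevOut / denom
    if (any(ratio > 1 + 1e-8))
      stop("numerical error: PEV exceeds sigma_g^2 * K_ii (max ratio ",
           format(max(ratio)), ")")
    accT <- sqrt(pmax(0, 1 - ratio))
  }
  new("GBLUPResult", ids = ids, mu = mu, mbv = unname(a), pev = pevOut,
      accT = accT, sigma2G = s2g, sigma2E = s2e,
      kernelKind = kind(kernel))
}

#' Add back regressed-out PC effects onto molecular breeding values
#'
#' When phenotypes were pre-adjusted for principal components of G, part
#' of the between-group genetic signal sits in the PC regression rather
#' than in the mBVs; this restores it as
#' mBV*_i = mBV_i + sum_k score_ik beta_k.
#'
#' @param result a [GBLUPResult-class].
#' @param pcScores score matrix with animal rownames covering the result's
#'   animals.
#' @param pcBetas PC coefficients (normally `adj@pcBetas` from
#'   [regressOutPcs()]).
#' @return a [GBLUPResult-class] with shifted mBVs.
#' @export
addBackPcEffects <- function(result, pcScores, pcBetas) {
  if (length(pcBetas) == 0) return(result)
  if (length(pcBetas) > ncol(pcScores))
    stop("more betas than score columns")
  missing <- setdiff(result@ids, rownames(pcScores))
  if (length(missing) > 0)
    stop("PC scores missing for animals: ",
         paste(head(missing), collapse = ", "))
  S <- pcScores[result@ids, seq_along(pcBetas), drop = FALSE]
  shift <- drop(S %*% pcBetas)
  methods::initialize(result, mbv = result@mbv + shift)
}
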