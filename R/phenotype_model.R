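#' @include containers.R
NULL

#' Adjust phenotypes for fixed effects
#'
#' Ordinary least-squares fit of the trait on the declared factors and
#' covariates (typically the contemporary-group factors); the adjusted
#' phenotype is the residual. With no fixed effects the records are simply
#' mean-centred; with a single factor the residual is the value minus its
#' group mean.
#'
#' @param pheno phenotype data.frame (one record per animal for the trait).
#' @param fixedSpec list with character vectors `factors` and `covariates`
#'   naming phenotype columns; both may be empty.
#' @param trait trait to adjust (default: the single trait present).
#' @return an [AdjustedPhenotypes-class].
#' @export
adjustPhenotypes <- function(pheno,
                             fixedSpec = list(factors = character(0),
                                              covariates = character(0)),
                             trait = NULL) {
  if (is.null(trait)) {
    trait <- unique(pheno$trait)
    if (length(trait) != 1)
      stop("multiple traits present; specify 'trait'")
  }
  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0)
    stop("no records for trait '", trait, "'")
  if (anyDuplicated(ph$animal))
    stop("multiple records per animal for trait '", trait, "'")
  fac <- fixedSpec$factors %||% character(0)
  cov <- fixedSpec$covariates %||% character(0)
  miss <- setdiff(c(fac, cov), colnames(ph))
  if (length(miss) > 0)
    stop("fixed-effect columns absent from phenotypes: ",
         paste(miss, collapse = ", "))
  df <- ph
  for (f in fac) df[[f]] <- factor(df[[f]])
  terms <- c(fac, cov)
  form <- if (length(terms) == 0) value ~ 1
          else stats::as.formula(paste("value ~",
                                       paste(terms, collapse = " + ")))
  fit <- lm(form, data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient fixed-effect design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  new("AdjustedPhenotypes", ids = as.character(ph$animal),
      values = unname(resid(fit)), trait = trait, nPcsRemoved = 0L,
      fixedCoefs = cf, pcBetas = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regress principal components out of adjusted phenotypes
#'
#' Removes population structure by taking the OLS residual of the adjusted
#' phenotype on the first `nPcs` principal-component score columns of the
#' genomic relationship matrix (with intercept). The fitted PC
#' coefficients are retained so that [addBackPcEffects()] can restore the
#' removed component on the molecular breeding values.
#'
#' @param adj an [AdjustedPhenotypes-class].
#' @param pcScores score matrix from [pcaOfG()] with animal rownames.
#' @param nPcs number of leading components to remove (0 = identity).
#' @return an [AdjustedPhenotypes-class] with `nPcsRemoved` updated.
#' @export
regressOutPcs <- function(adj, pcScores, nPcs) {
  if (nPcs == 0) return(adj)
  if (nPcs > ncol(pcScores))
    stop("nPcs exceeds the available components (", ncol(pcScores), ")")
  missing <- setdiff(adj@ids, rownames(pcScores))
  if (length(missing) > 0)
    stop("PC scores missing for phenotyped animals: ",
         paste(head(missing), collapse = ", "))
  S <- pcScores[adj@ids, seq_len(nPcs), drop = FALSE]
  fit <- lm(adj@values ~ S)
  betas <- coef(fit)[-1]
  new("AdjustedPhenotypes", ids = adj@ids, values = unname(resid(fit)),
      trait = adj@trait, nPcsRemoved = as.integer(nPcs),
      fixedCoefs = adj@fixedCoefs,
      pcBetas = setNames(unname(betas), colnames(S)))
}

# Profiled restricted log-likelihood over the heritability ratio: for
# V0 = h2 * Lambda + (1 - h2) I the phenotypic variance has the closed
# form sigma2P = y' P0 y / (n - 1), leaving a 1-D function of h2.
profiledReml <- function(yt, xt, lambda, h2) {
  v0 <- h2 * lambda + (1 - h2)
  if (any(v0 <= 0)) return(list(ll = -Inf))
  vi <- 1 / v0
  xvx <- sum(xt^2 * vi)
  xvy <- sum(xt * yt * vi)
  yPy <- sum(yt^2 * vi) - xvy^2 / xvx
  n <- length(yt)
  s2p <- yPy / (n - 1)
  ll <- -0.5 * ((n - 1) * log(s2p) + sum(log(v0)) + log(xvx) + (n - 1))
  list(ll = ll, sigma2A = h2 * s2p, sigma2E = (1 - h2) * s2p)
}

# Restricted log-likelihood (up to a constant) of y = 1 mu + u + e on the
# eigen-transformed scale: v = sigma2A * lambda + sigma2E,
# -2 logLik = sum(log v) + log(x' V^-1 x) + y' P y.
remlObjective <- function(yt, xt, lambda, sigma2A, sigma2E) {
  v <- sigma2A * lambda + sigma2E
  if (any(v <= 0)) return(-Inf)
  vi <- 1 / v
  xvx <- sum(xt^2 * vi)
  xvy <- sum(xt * yt * vi)
  yPy <- sum(yt^2 * vi) - xvy^2 / xvx
  -0.5 * (sum(log(v)) + log(xvx) + yPy)
}

#' REML variance components for a single-kernel animal model
#'
#' Average-information REML for y = 1 mu + u + e with var(u) = K sigma_A^2
#' and var(e) = I sigma_e^2, run on the eigen-decomposition of the
#' (ridged) kernel so each iteration costs O(n). Starts from an equal
#' split of the phenotypic variance with an EM-damped first step; AI steps
#' that leave the parameter space are halved back (EM-style fallback).
#' Convergence is declared when successive h2 estimates change by less
#' than 1e-6 (at most 200 iterations), and variances are floored at
#' 1e-8 times the phenotypic variance. The standard error of h2 comes from
#' the inverse average-information matrix by the delta method.
#'
#' @param adj an [AdjustedPhenotypes-class] (at least 30 records).
#' @param kernel a [RelationshipMatrix-class] covering the phenotyped
#'   animals.
#' @return a [VarianceComponents-class].
#' @export
remlVarianceComponents <- function(adj, kernel) {
  ids <- adj@ids
  if (length(ids) < 30)
    stop("at least 30 records are required for REML")
  if (!all(ids %in% animalIds(kernel)))
    stop("kernel does not cover all phenotyped animals")
  y <- adj@values
  K <- ridgeKernel(as.matrix(kernel)[ids, ids])
  e <- eigen(K, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  xt <- drop(crossprod(e$vectors, rep(1, length(y))))
  vp <- var(y)
  floor_ <- 1e-8 * vp
  theta <- c(vp / 2, vp / 2)          # (sigma2A, sigma2E)
  h2old <- theta[1] / sum(theta)
  trace <- numeric(0)
  converged <- FALSE
  AI <- diag(2)
  for (it in seq_len(200)) {
    v <- theta[1] * lambda + theta[2]
    vi <- 1 / v
    xvx <- sum(xt^2 * vi)
    # Py on the transformed scale (P is diagonal minus a rank-one term)
    py <- yt * vi - xt * vi * sum(xt * yt * vi) / xvx
    # tr(P D) for D = diag(lambda) and D = I
    trPD <- sum(lambda * vi) - sum(xt^2 * vi^2 * lambda) / xvx
    trPI <- sum(vi) - sum(xt^2 * vi^2) / xvx
    Dpy <- lambda * py
    PDpy <- Dpy * vi - xt * vi * sum(xt * Dpy * vi) / xvx
    PIpy <- py * vi - xt * vi * sum(xt * py * vi) / xvx
    score <- 0.5 * c(sum(py * Dpy) - trPD, sum(py * py) - trPI)
    AI <- 0.5 * matrix(c(sum(Dpy * PDpy), sum(Dpy * PIpy),
                         sum(Dpy * PIpy), sum(py * PIpy)), 2, 2)
    step <- tryCatch(solve(AI, score), error = function(err) score * 0)
    damp <- 1
    repeat {
      cand <- theta + damp * step
      if (all(cand >= floor_) || damp < 1e-6) break
      damp <- damp / 2
    }
    theta <- pmax(cand, floor_)
    h2 <- theta[1] / sum(theta)
    trace <- c(trace, h2)
    if (abs(h2 - h2old) < 1e-6) { converged <- TRUE; break }
    h2old <- h2
  }
  if (!converged) {
    cond <- simpleError(paste("REML did not converge in 200 iterations;",
                              "last h2 values:",
                              paste(round(utils::tail(trace, 5), 6),
                                    collapse = ", ")))
    cond$trace <- trace
    stop(cond)
  }
  # polish: 1-D profiled-likelihood refinement around the AI optimum,
  # so the reported estimates sit at the restricted-likelihood maximum
  # to optimiser precision rather than the iteration stop rule
  h2 <- theta[1] / sum(theta)
  lo <- max(0, h2 - 0.05); hi <- min(1, h2 + 0.05)
  opt <- optimize(function(h) profiledReml(yt, xt, lambda, h)$ll,
                  c(lo, hi), maximum = TRUE, tol = 1e-10)
  pr <- profiledReml(yt, xt, lambda, opt$maximum)
  theta <- pmax(c(pr$sigma2A, pr$sigma2E), floor_)
  covTheta <- tryCatch(solve(AI), error = function(err)
    matrix(NA_real_, 2, 2))
  s <- sum(theta)
  grad <- c(theta[2], -theta[1]) / s^2
  seH2 <- sqrt(pmax(drop(t(grad) %*% covTheta %*% grad), 0))
  VarianceComponents(sigma2A = theta[1], sigma2E = theta[2], seH2 = seH2,
                     iterations = length(trace), converged = TRUE,
                     logLik = remlObjective(yt, xt, lambda, theta[1],
                                            theta[2]))
}
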