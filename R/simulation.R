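# Simulation engine: synthetic genotypes with configurable LD, the linear
# phenotype model with a one-dimensional covariate, covariate-adjusted
# Wald statistics, and Monte-Carlo type-I-error / power estimation.

#' AR(1) correlation matrix
#'
#' @param rho autocorrelation parameter in (-1, 1).
#' @param p dimension.
#' @return p x p matrix with entries `rho^|i-j|`.
#' @export
arCorrelation <- function(rho, p) {
  stopifnot(abs(rho) < 1, p >= 1)
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

#' Default non-identity trait correlation for six traits
#'
#' A fixed two-block correlation structure emulating a panel of six
#' metabolically related traits that split into two pathway families
#' (e.g. omega-6 and omega-3 fatty-acid species): moderate-to-strong
#' correlation within each family of three, weak correlation across
#' families. Used as the package's default realistic trait correlation in
#' null simulations when no explicit matrix is given.
#'
#' @return a 6 x 6 positive-definite correlation matrix.
#' @export
defaultTraitCorrelation6 <- function() {
  r <- diag(6)
  within1 <- matrix(c(1, .60, .45, .60, 1, .50, .45, .50, 1), 3, 3)
  within2 <- matrix(c(1, .40, .30, .40, 1, .55, .30, .55, 1), 3, 3)
  r[1:3, 1:3] <- within1
  r[4:6, 4:6] <- within2
  r[1:3, 4:6] <- 0.15
  r[4:6, 1:3] <- 0.15
  dimnames(r) <- list(paste0("trait", 1:6), paste0("trait", 1:6))
  r
}

#' Generate genotype dosages with latent-Gaussian LD
#'
#' Each individual's two haplotypes are independent draws of a latent
#' vector from N(0, ldCorr); at each SNP the haplotype carries the counted
#' allele when its latent value falls below the MAF quantile of the
#' standard normal. Dosages are the sum of the two haplotypes, in
#' \{0, 1, 2\}, with marginal allele frequency equal to the target MAF and
#' LD inherited from the latent correlation.
#'
#' @param n number of individuals.
#' @param m number of SNPs.
#' @param ld LD specification: an m x m positive-definite latent
#'   correlation matrix, or a scalar AR(1) parameter.
#' @param maf minor-allele frequencies, recycled to length m; in (0, 0.5].
#' @param seed optional RNG seed.
#' @return n x m integer dosage matrix with SNP colnames.
#' @examples
#' g <- generateGenotypes(100, 5, ld = 0.8, maf = 0.3, seed = 1)
#' colMeans(g) / 2  # close to 0.3
#' @export
generateGenotypes <- function(n, m, ld = 0, maf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ldCorr <- if (is.matrix(ld)) ld else arCorrelation(ld, m)
  if (nrow(ldCorr) != m) stop("LD matrix dimension must equal m")
  maf <- rep_len(maf, m)
  if (any(maf <= 0 | maf > 0.5)) stop("MAF must lie in (0, 0.5]")
  indep <- identical(unname(ldCorr), diag(m))
  U <- if (indep) NULL else tryCatch(chol(ldCorr), error = function(e)
    stop("LD specification is not positive definite", call. = FALSE))
  thr <- qnorm(maf)
  hap <- function() {
    lat <- matrix(rnorm(n * m), n, m)
    if (!indep) lat <- lat %*% U
    sweep(lat, 2, thr, "<") + 0L
  }
  g <- hap() + hap()
  colnames(g) <- paste0("snp", seq_len(m))
  g
}

#' Simulation scenario configuration
#'
#' Full specification of one simulation scenario for the linear phenotype
#' model \eqn{y_{ij} = \alpha_j + \sum_k g_{ik} \beta_{jk} + c_i \gamma_j +
#' \epsilon_{ij}} with jointly normal errors (correlation `traitCorr`) and
#' a one-dimensional covariate.
#'
#' @slot n,q,m sample size, number of traits, number of SNPs.
#' @slot traitCorr q x q error (trait) correlation matrix.
#' @slot ld m x m latent LD matrix for the genotype generator.
#' @slot maf length-m minor-allele frequencies.
#' @slot beta q x m coefficient matrix B.
#' @slot allocation `"NONE"`, `"SINGLE"`, `"ROW"` or `"COLUMN"`.
#' @slot gamma length-q covariate coefficients.
#' @slot covariate `"normal"` (standard normal) or `"twocluster"`
#'   (two-group mean shift emulating stratification).
#' @slot nullSnps number of independent null SNPs used to estimate the
#'   trait correlation.
#' @slot calibB parametric-bootstrap size for the truncation calibration.
#' @slot nReps Monte-Carlo replications.
#' @slot alpha significance levels at which rejections are counted.
#' @slot seed master RNG seed (sub-seeds are seed, seed+1, seed+2 for the
#'   data pre-pass, calibration, and the replication loop).
#'
#' @aliases ScenarioConfig-class
#' @name ScenarioConfig
#' @rdname ScenarioConfig
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
         representation(n = "integer", q = "integer", m = "integer",
                        traitCorr = "matrix", ld = "matrix",
                        maf = "numeric", beta = "matrix",
                        allocation = "character", gamma = "numeric",
                        covariate = "character", nullSnps = "integer",
                        calibB = "integer", nReps = "integer",
                        alpha = "numeric", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msgs <- character()
  if (object@nReps < 1L) msgs <- c(msgs, "nReps must be >= 1")
  if (any(object@maf <= 0 | object@maf > 0.5))
    msgs <- c(msgs, "MAF must lie in (0, 0.5]")
  if (!object@allocation %in% c("NONE", "SINGLE", "ROW", "COLUMN"))
    msgs <- c(msgs, "unknown allocation")
  nz <- which(object@beta != 0, arr.ind = TRUE)
  ok <- switch(object@allocation,
               NONE = nrow(nz) == 0L,
               SINGLE = nrow(nz) == 1L,
               ROW = length(unique(nz[, 1])) <= 1L,
               COLUMN = length(unique(nz[, 2])) <= 1L)
  if (!ok) msgs <- c(msgs, "nonzero pattern of beta contradicts allocation")
  if (length(object@gamma) != object@q)
    msgs <- c(msgs, "gamma must have length q")
  if (length(msgs)) msgs else TRUE
})

#' @param n,q,m sample size, traits, SNPs.
#' @param traitCorr trait correlation: a matrix, or `NULL` for the default
#'   (two-block matrix for q = 6, else AR(1) with parameter 0.5).
#' @param ld LD matrix or scalar AR(1) parameter (default 0.8).
#' @param maf MAF vector, or `NULL` to draw once from U(0.05, 0.5).
#' @param allocation signal allocation pattern.
#' @param effect nonzero coefficient value used to fill the allocation.
#' @param target for `SINGLE` a (row, column) pair; for `ROW` the row
#'   index; for `COLUMN` the column index. Defaults to 1 (and (1, 1)).
#' @param gamma covariate coefficients, recycled to length q.
#' @param covariate covariate generator kind.
#' @param nullSnps,calibB,nReps,alpha,seed see slot documentation.
#' @return `scenarioConfig()` returns a validated `ScenarioConfig`.
#' @examples
#' sc <- scenarioConfig(n = 500, q = 6, m = 9, nReps = 100, seed = 1)
#' @rdname ScenarioConfig
#' @export
scenarioConfig <- function(n = 2504, q = 6, m = 9, traitCorr = NULL,
                           ld = 0.8, maf = NULL,
                           allocation = c("NONE", "SINGLE", "ROW",
                                          "COLUMN"),
                           effect = 0, target = NULL, gamma = 0.5,
                           covariate = c("normal", "twocluster"),
                           nullSnps = 1e5, calibB = 1e5, nReps = 1000,
                           alpha = c(1e-3, 1e-5), seed = 1L) {
  allocation <- match.arg(allocation)
  covariate <- match.arg(covariate)
  if (is.null(traitCorr))
    traitCorr <- if (q == 6) defaultTraitCorrelation6() else
      arCorrelation(0.5, q)
  ldCorr <- if (is.matrix(ld)) ld else arCorrelation(ld, m)
  if (is.null(maf)) {
    set.seed(as.integer(seed))
    maf <- runif(m, 0.05, 0.5)
  }
  beta <- matrix(0, q, m)
  if (allocation == "SINGLE") {
    tg <- target %||% c(1L, 1L)
    beta[tg[1], tg[2]] <- effect
  } else if (allocation == "ROW") {
    beta[(target %||% 1L), ] <- effect
  } else if (allocation == "COLUMN") {
    beta[, (target %||% 1L)] <- effect
  }
  new("ScenarioConfig", n = as.integer(n), q = as.integer(q),
      m = as.integer(m), traitCorr = as.matrix(traitCorr), ld = ldCorr,
      maf = rep_len(maf, m), beta = beta, allocation = allocation,
      gamma = rep_len(gamma, q), covariate = covariate,
      nullSnps = as.integer(nullSnps), calibB = as.integer(calibB),
      nReps = as.integer(nReps), alpha = alpha, seed = as.integer(seed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(paste0("ScenarioConfig: n = %d, q = %d, m = %d, ",
                     "allocation = %s, %d replications, seed = %d\n"),
              object@n, object@q, object@m, object@allocation,
              object@nReps, object@seed))
  invisible(NULL)
})

#' Simulate phenotypes under the linear model
#'
#' \eqn{y_{ij} = \alpha_j + \sum_k g_{ik}\beta_{jk} + c_i\gamma_j +
#' \epsilon_{ij}} with per-individual error vectors jointly normal with
#' correlation `traitCorr`.
#'
#' @param genotypes n x m dosage matrix.
#' @param beta q x m coefficient matrix.
#' @param gamma length-q covariate coefficients.
#' @param covariate length-n covariate vector.
#' @param traitCorr q x q error correlation matrix.
#' @param alpha0 intercepts, recycled to length q (default 0).
#' @param seed optional RNG seed.
#' @return n x q phenotype matrix.
#' @export
simulatePhenotypes <- function(genotypes, beta, gamma, covariate,
                               traitCorr, alpha0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  q <- nrow(beta)
  if (ncol(beta) != ncol(genotypes))
    stop("beta and genotypes disagree on the number of SNPs")
  if (length(covariate) != n) stop("covariate must have length n")
  U <- chol(traitCorr)
  E <- matrix(rnorm(n * q), n, q) %*% U
  Y <- matrix(rep(rep_len(alpha0, q), each = n), n, q) +
    genotypes %*% t(beta) + outer(covariate, rep_len(gamma, q)) + E
  colnames(Y) <- rownames(beta) %||% paste0("trait", seq_len(q))
  Y
}

#' Covariate-adjusted Wald Z statistics
#'
#' For every trait j and SNP k, fits the univariate linear regression of
#' trait j on SNP k plus the covariates (always including an intercept)
#' and returns the Wald t-statistic of the SNP coefficient. Computed for
#' all q x m pairs at once through the residualization identity: with
#' both trait and genotype projected off the covariate space,
#' \eqn{t = \tilde g^\top \tilde y / \sqrt{\|\tilde g\|^2 \,
#' \mathrm{RSS} / \mathrm{df}}}.
#'
#' @param phenotypes n x q phenotype matrix.
#' @param genotypes n x m dosage matrix.
#' @param covariates n x c covariate matrix (without intercept), a
#'   [CovariateDesign], or `NULL` for intercept-only adjustment.
#' @param onDegenerate `"error"` (default) to fail when a regression has
#'   numerically zero residual variance, or `"inf"` to return signed Inf.
#' @return a [ZMatrix] (q traits x m SNPs).
#' @examples
#' g <- generateGenotypes(200, 3, seed = 1)
#' y <- simulatePhenotypes(g, matrix(0, 2, 3), c(0, 0), rnorm(200),
#'                         diag(2), seed = 2)
#' computeWaldZ(y, g, covariates = NULL)
#' @export
computeWaldZ <- function(phenotypes, genotypes, covariates = NULL,
                         onDegenerate = c("error", "inf")) {
  onDegenerate <- match.arg(onDegenerate)
  Y <- as.matrix(phenotypes)
  G <- as.matrix(genotypes)
  n <- nrow(Y)
  if (nrow(G) != n) stop("phenotypes and genotypes disagree on n")
  C <- if (is.null(covariates)) matrix(1, n, 1) else if
    (is(covariates, "CovariateDesign")) designMatrix(covariates) else
      cbind(1, as.matrix(covariates))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("collinear covariate design")
  df <- n - ncol(C) - 1L
  if (df < 1L) stop("sample size too small for the covariate design")
  Gres <- G - qr.fitted(qrC, G)
  Yres <- Y - qr.fitted(qrC, Y)
  gnorm2 <- colSums(Gres^2)
  if (any(gnorm2 < 1e-12))
    stop("genotype column collinear with the covariates: ",
         paste(colnames(G)[gnorm2 < 1e-12], collapse = ", "))
  cross <- crossprod(Gres, Yres)              # m x q
  ynorm2 <- colSums(Yres^2)
  ymat <- matrix(ynorm2, nrow(cross), ncol(cross), byrow = TRUE)
  rss <- ymat - cross^2 / gnorm2
  bad <- rss <= 1e-10 * ymat
  if (any(bad) && onDegenerate == "error")
    stop("degenerate regression fit (residual variance ~ 0); ",
         "rerun with onDegenerate = \"inf\" to report signed Inf")
  z <- cross / sqrt(gnorm2 * rss / df)
  if (any(bad)) z[bad] <- sign(cross[bad]) * Inf
  zm <- t(z)                                  # q x m
  dimnames(zm) <- list(colnames(Y) %||% paste0("trait", seq_len(ncol(Y))),
                       colnames(G) %||% paste0("snp", seq_len(ncol(G))))
  if (any(bad)) return(zm)                    # Inf: not a valid ZMatrix
  ZMatrix(zm)
}

# block sizes (at most `by` each) covering L items
splitIndices <- function(L, by) {
  k <- ceiling(L / by)
  sizes <- rep(L %/% k, k)
  extra <- L - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Fixed per-scenario data: genotypes, covariate, mean matrix, estimated
# correlation matrices (regularized), calibration, and the precomputed
# pieces the C++ replication loop needs.
.scenarioSetup <- function(scenario, epsPd = 1e-6) {
  stopifnot(is(scenario, "ScenarioConfig"))
  set.seed(scenario@seed)
  n <- scenario@n
  G <- generateGenotypes(n, scenario@m, ld = scenario@ld,
                         maf = scenario@maf)
  cvec <- if (scenario@covariate == "twocluster") {
    grp <- rep(c(0, 1), length.out = n)
    grp * 1.5 + rnorm(n)
  } else rnorm(n)
  Ymean <- G %*% t(scenario@beta) +
    outer(cvec, scenario@gamma)

  # trait correlation from an auxiliary null-SNP pre-pass. Null SNPs are
  # drawn in blocks with a fresh phenotype realization per block: a
  # single shared realization would pull the estimate toward that
  # realization's sample correlation (an O(1/sqrt(n)) offset from the
  # error correlation the test replications actually follow), while
  # blockwise refreshing targets the marginal null law directly.
  L <- scenario@nullSnps
  blocks <- splitIndices(L, 1000L)
  znull <- do.call(rbind, lapply(blocks, function(Lb) {
    Gb <- generateGenotypes(n, Lb, ld = 0, maf = runif(Lb, 0.05, 0.5))
    Yb <- simulatePhenotypes(Gb, matrix(0, scenario@q, Lb),
                             scenario@gamma, cvec, scenario@traitCorr)
    t(zValues(computeWaldZ(Yb, Gb, covariates = cvec)))
  }))
  rhoHat <- regularizeCorrelation(estimateTraitCorrelation(znull), epsPd)

  # SNP correlation from the panel itself (environment-only covariate)
  thetaHat <- regularizeCorrelation(pearsonGenotypeCorrelation(G), epsPd)

  calib <- calibrateTruncated(thetaHat, rhoHat, B = scenario@calibB,
                              seed = scenario@seed + 1L)

  C <- cbind(1, cvec)
  Qc <- qr.Q(qr(C))
  Gres <- G - Qc %*% crossprod(Qc, G)
  theta <- corrValues(thetaHat)
  rho <- corrValues(rhoHat)
  list(G = G, cvec = cvec, Ymean = Ymean, Qc = Qc, Gres = Gres,
       gnorm2 = colSums(Gres^2), rhoHat = rhoHat, thetaHat = thetaHat,
       calibration = calib,
       cholRhoGen = chol(scenario@traitCorr),
       cholThetaHat = chol(theta), cholRhoHat = chol(rho),
       kronHat = kronecker(theta, rho))
}

.calibVectors <- function(calib) {
  list(a = vapply(calib@params, slot, 0, name = "a"),
       b = vapply(calib@params, slot, 0, name = "b"),
       d = vapply(calib@params, slot, 0, name = "d"),
       dist = vapply(calib@params, slot, "", name = "dist"))
}

#' Run a simulation scenario
#'
#' Generates the scenario's genotypes and covariate once, estimates the
#' trait and SNP correlation matrices as an analyst would (null-SNP
#' Z-scores and the reference panel), calibrates the truncation grid once
#' (the null law of the truncated statistics depends only on the
#' correlation matrices), then replicates the phenotype model, computes
#' covariate-adjusted Wald Z matrices and the Three-Way Test, and counts
#' rejections at each significance level.
#'
#' @param scenario a [ScenarioConfig].
#' @param etas truncation grid.
#' @param pFloor numerical p-value floor.
#' @param epsPd regularization floor for estimated correlations.
#' @return list with `rates` (data.frame: alpha, component, rejections,
#'   reps, rate, se), `pvalues` (nReps x 4 matrix of P1, P2, P3, TWT),
#'   the estimated `traitCorr` and `snpCorr`, and the `calibration` used.
#' @examples
#' sc <- scenarioConfig(n = 300, q = 3, m = 4, nReps = 50, calibB = 2000,
#'                      nullSnps = 200, alpha = 0.5, seed = 1)
#' runScenario(sc)$rates
#' @export
runScenario <- function(scenario, etas = defaultTruncationGrid(),
                        pFloor = 1e-14, epsPd = 1e-6) {
  setup <- .scenarioSetup(scenario, epsPd)
  gc <- .calibVectors(setup$calibration)
  if (any(gc$dist != "genchi2"))
    stop("normal-fallback calibration cannot be used in the fast ",
         "replication loop; increase calibB")
  M <- scenario@q * scenario@m
  ks <- truncationSize(etas, M)
  if (ks[length(ks)] != M)
    stop("the truncation grid must include eta = 1")
  set.seed(scenario@seed + 2L)
  pv <- cpp_simulate_pvalues(setup$Ymean, setup$cholRhoGen, setup$Qc,
                             setup$Gres, setup$gnorm2, setup$cholThetaHat,
                             setup$cholRhoHat, setup$kronHat, ks,
                             gc$a, gc$b, gc$d, scenario@nReps, pFloor)
  colnames(pv) <- c("P1", "P2", "P3", "TWT")
  rates <- do.call(rbind, lapply(scenario@alpha, function(a) {
    rej <- colSums(pv < a)
    data.frame(alpha = a, component = colnames(pv),
               rejections = as.integer(rej), reps = scenario@nReps,
               rate = rej / scenario@nReps,
               se = sqrt(a * (1 - a) / scenario@nReps),
               row.names = NULL)
  }))
  list(rates = rates, pvalues = pv, traitCorr = setup$rhoHat,
       snpCorr = setup$thetaHat, calibration = setup$calibration)
}

#' Null Z-matrix draws from the individual-data pipeline
#'
#' Replicates the scenario's phenotype model under its (fixed) genotypes
#' and covariate and returns the vectorized covariate-adjusted Wald Z
#' matrix of every replication. Used to verify the product structure
#' \eqn{\mathrm{corr}(Z_{jk}, Z_{j'k'}) = \rho_{jj'}\theta_{kk'}} of the
#' null covariance.
#'
#' @param scenario a [ScenarioConfig] (its `beta` is used as configured,
#'   so pass a NONE allocation for null draws).
#' @param nReps number of replications (defaults to the scenario's).
#' @return list with `zdraws` (M x nReps matrix), the fixed `genotypes`
#'   and `covariate`, and the Kronecker factors implied by the generator:
#'   `traitCorr` (the scenario's) and `snpCorr` (partial correlation of
#'   the fixed genotypes given the covariate design).
#' @export
simulateNullZ <- function(scenario, nReps = scenario@nReps) {
  setup <- .scenarioSetup0(scenario)
  set.seed(scenario@seed + 2L)
  zdraws <- cpp_simulate_zdraws(setup$Ymean, setup$cholRhoGen, setup$Qc,
                                setup$Gres, setup$gnorm2,
                                as.integer(nReps))
  # conditional on (G, c) the SNP factor is the correlation of the
  # covariate-residualized genotypes
  theta <- cor(setup$Gres)
  list(zdraws = zdraws, genotypes = setup$G, covariate = setup$cvec,
       traitCorr = scenario@traitCorr, snpCorr = theta)
}

# setup without the (costly) estimation + calibration steps
.scenarioSetup0 <- function(scenario) {
  set.seed(scenario@seed)
  n <- scenario@n
  G <- generateGenotypes(n, scenario@m, ld = scenario@ld,
                         maf = scenario@maf)
  cvec <- if (scenario@covariate == "twocluster") {
    grp <- rep(c(0, 1), length.out = n)
    grp * 1.5 + rnorm(n)
  } else rnorm(n)
  Ymean <- G %*% t(scenario@beta) + outer(cvec, scenario@gamma)
  C <- cbind(1, cvec)
  Qc <- qr.Q(qr(C))
  Gres <- G - Qc %*% crossprod(Qc, G)
  list(G = G, cvec = cvec, Ymean = Ymean, Qc = Qc, Gres = Gres,
       gnorm2 = colSums(Gres^2),
       cholRhoGen = chol(scenario@traitCorr))
}
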