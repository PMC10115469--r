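# Estimation of the two correlation matrices whose Kronecker product is
# the null correlation of vec(Z): trait correlation from null-SNP
# Z-scores, SNP (partial) correlation from a reference genotype panel.

#' Estimate the trait correlation matrix from null-SNP Z-scores
#'
#' Under the global null the Wald Z-scores of two traits at the same SNP
#' are correlated exactly as the traits themselves, so the trait
#' correlation \eqn{\rho_{jj'}} is estimated by the sample Pearson
#' correlation of the two traits' Z-score columns over a set of
#' independent null SNPs.
#'
#' @param nullZ numeric L x q matrix (or data.frame) of Wald Z-scores at
#'   presumed-null SNPs; columns are traits.
#' @param minSnps minimum acceptable number of null SNPs (default 50).
#' @return a [TraitCorrMatrix].
#' @examples
#' z <- matrix(rnorm(400), 100, 4,
#'             dimnames = list(NULL, paste0("trait", 1:4)))
#' estimateTraitCorrelation(z)
#' @export
estimateTraitCorrelation <- function(nullZ, minSnps = 50L) {
  nullZ <- as.matrix(nullZ)
  if (!is.numeric(nullZ) || any(!is.finite(nullZ)))
    stop("null-SNP Z table must be numeric and finite")
  if (nrow(nullZ) < minSnps)
    stop(sprintf(paste("only %d null SNPs provided, %d required;",
                       "supply more null SNPs for a stable trait",
                       "correlation estimate"),
         nrow(nullZ), minSnps))
  sds <- apply(nullZ, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(nullZ)[sds == 0] %||% which(sds == 0)
    stop("degenerate (zero-variance) Z column for trait: ",
         paste(bad, collapse = ", "))
  }
  r <- cor(nullZ)
  diag(r) <- 1
  TraitCorrMatrix(r, labels = colnames(nullZ))
}

#' SNP correlation from a reference panel (no genetic confounders)
#'
#' Sample Pearson correlation of genotype dosage columns; the appropriate
#' estimator of the SNP correlation when all regression covariates are
#' environmental variables independent of genotype (or when there are no
#' covariates). Missing dosages are mean-imputed per SNP.
#'
#' @param panel numeric N x m matrix of dosages in \eqn{[0, 2]}; columns
#'   are SNPs.
#' @param maxMissing maximum tolerated fraction of missing dosages per SNP.
#' @return a [SnpCorrMatrix].
#' @examples
#' g <- cbind(rs1 = c(0, 1, 1, 2, 0, 2), rs2 = c(0, 1, 2, 2, 0, 1))
#' pearsonGenotypeCorrelation(g)
#' @export
pearsonGenotypeCorrelation <- function(panel, maxMissing = 0.05) {
  panel <- .validatePanel(panel, maxMissing)
  r <- cor(panel)
  diag(r) <- 1
  SnpCorrMatrix(r, labels = colnames(panel))
}

.validatePanel <- function(panel, maxMissing = 0.05) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 2L) stop("reference panel needs at least 2 individuals")
  if (is.null(colnames(panel)))
    colnames(panel) <- paste0("snp", seq_len(ncol(panel)))
  missFrac <- colMeans(is.na(panel))
  if (any(missFrac > maxMissing))
    stop("missing dosage fraction exceeds ", maxMissing, " for SNP: ",
         paste(colnames(panel)[missFrac > maxMissing], collapse = ", "))
  if (any(missFrac > 0)) {
    mu <- colMeans(panel, na.rm = TRUE)
    idx <- which(is.na(panel), arr.ind = TRUE)
    panel[idx] <- mu[idx[, 2]]
  }
  rng <- range(panel)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]")
  sds <- apply(panel, 2, sd)
  if (any(sds == 0))
    stop("monomorphic SNP (zero dosage variance): ",
         paste(colnames(panel)[sds == 0], collapse = ", "))
  panel
}

#' Residualize genotype dosages on a covariate design
#'
#' Applies the annihilator projection
#' \eqn{I - C (C^\top C)^{-1} C^\top} of the design to every dosage
#' column, removing the linear effect of the covariates (population
#' stratification axes) from the genotypes.
#'
#' @param panel numeric N x m dosage matrix.
#' @param design a [CovariateDesign] with N rows.
#' @return N x m matrix of residuals, orthogonal to every design column.
#' @export
residualizeGenotypes <- function(panel, design) {
  stopifnot(is(design, "CovariateDesign"))
  panel <- as.matrix(panel)
  C <- designMatrix(design)
  if (nrow(panel) != nrow(C))
    stop("panel and design have different numbers of individuals")
  if (nrow(C) <= ncol(C))
    stop("need more individuals than design columns (N > s + 1)")
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("design matrix is rank deficient")
  res <- panel - qr.fitted(qrC, panel)
  dimnames(res) <- dimnames(panel)
  res
}

#' SNP partial correlation given covariates
#'
#' Implements the three covariate cases for estimating the SNP correlation
#' entering the null covariance of the Z matrix:
#' environment-only covariates leave genotypes untouched (plain Pearson
#' correlation); stratification (and mixed) covariates are projected out
#' of each dosage column and the Pearson correlation of the residuals is
#' the partial-correlation estimate \eqn{\hat\theta_{kk'}}.
#'
#' @inheritParams residualizeGenotypes
#' @param maxMissing maximum tolerated fraction of missing dosages per SNP.
#' @return a [SnpCorrMatrix].
#' @seealso [principalCoordinates()] to build the stratification design
#'   from the panel itself.
#' @export
partialGenotypeCorrelation <- function(panel, design, maxMissing = 0.05) {
  stopifnot(is(design, "CovariateDesign"))
  if (designKind(design) == "environment_only")
    return(pearsonGenotypeCorrelation(panel, maxMissing))
  panel <- .validatePanel(panel, maxMissing)
  h <- residualizeGenotypes(panel, design)
  sds <- apply(h, 2, sd)
  if (any(sds < 1e-12))
    stop("SNP fully explained by covariates (zero residual variance): ",
         paste(colnames(panel)[sds < 1e-12], collapse = ", "))
  r <- cor(h)
  diag(r) <- 1
  SnpCorrMatrix(r, labels = colnames(panel))
}

#' Principal coordinates of a genotype panel
#'
#' Classical multidimensional scaling (principal coordinates) of the
#' pairwise Euclidean distances between individuals' mean-imputed dosage
#' vectors. The top `s` coordinate axes, ordered by decreasing eigenvalue,
#' are returned as a stratification [CovariateDesign] (intercept first).
#' Axis orientation is fixed by making each axis's largest-magnitude
#' loading positive.
#'
#' @param panel numeric N x m dosage matrix.
#' @param s number of coordinate axes to keep (`s = 0` gives an
#'   intercept-only design).
#' @param kind covariate case recorded on the returned design
#'   (`"stratification"` by default).
#' @return a [CovariateDesign] with `s + 1` columns.
#' @examples
#' g <- matrix(rbinom(200, 2, 0.3), 20, 10)
#' principalCoordinates(g, s = 2)
#' @export
principalCoordinates <- function(panel, s = 2L,
                                 kind = c("stratification", "mixed")) {
  kind <- match.arg(kind)
  panel <- as.matrix(panel)
  n <- nrow(panel)
  s <- as.integer(s)
  if (s == 0L) return(covariateDesign(NULL, kind = "environment_only",
                                      n = n))
  if (n < s + 2L) stop("need at least s + 2 individuals")
  if (anyNA(panel)) {
    mu <- colMeans(panel, na.rm = TRUE)
    idx <- which(is.na(panel), arr.ind = TRUE)
    panel[idx] <- mu[idx[, 2]]
  }
  mds <- cmdscale(dist(panel), k = min(s, n - 1L), eig = TRUE)
  nPos <- sum(mds$eig > 1e-8 * max(mds$eig))
  if (nPos < s)
    stop(sprintf("only %d positive principal-coordinate axes available, %d requested",
                 nPos, s))
  coords <- mds$points[, seq_len(s), drop = FALSE]
  for (j in seq_len(s)) {
    top <- which.max(abs(coords[, j]))
    if (coords[top, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(s))
  covariateDesign(coords, kind = kind)
}

#' Regularize an estimated correlation matrix
#'
#' Clips eigenvalues below `epsPd` and rescales the result back to unit
#' diagonal, guaranteeing a positive-definite correlation matrix for the
#' quadratic forms. Inputs already satisfying the eigenvalue floor are
#' returned unchanged.
#'
#' @param x a [CorrMatrix] (returned as the same class) or a plain
#'   symmetric unit-diagonal matrix.
#' @param epsPd eigenvalue floor (default 1e-6).
#' @return the regularized object, same type as the input.
#' @export
regularizeCorrelation <- function(x, epsPd = 1e-6) {
  if (is(x, "CorrMatrix")) {
    out <- x
    out@values <- regularizeCorrelation(x@values, epsPd)
    validObject(out)
    return(out)
  }
  v <- as.matrix(x)
  if (max(abs(v - t(v))) > 1e-8) stop("input matrix is not symmetric")
  v <- (v + t(v)) / 2
  es <- eigen(v, symmetric = TRUE)
  if (min(es$values) >= epsPd) return(x)
  lam <- pmax(es$values, epsPd)
  w <- es$vectors %*% (lam * t(es$vectors))
  dd <- sqrt(diag(w))
  w <- w / tcrossprod(dd)
  diag(w) <- 1
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(v)
  w
}

#' Select independent null SNPs for trait-correlation estimation
#'
#' Keeps SNPs whose per-trait two-sided p-values exceed `pThreshold` for
#' every trait, then greedily LD-prunes them using the reference panel so
#' that no retained pair has squared correlation above `r2Threshold`
#' (first-come order by input position).
#'
#' @param nullZ L x q matrix of Z-scores with SNP rownames.
#' @param panel reference dosage matrix whose columns cover the SNPs in
#'   `nullZ` (matched by name).
#' @param pThreshold per-trait null p-value threshold (default 0.05).
#' @param r2Threshold LD pruning threshold on squared correlation.
#' @return character vector of retained SNP ids.
#' @export
selectNullSnps <- function(nullZ, panel, pThreshold = 0.05,
                           r2Threshold = 0.1) {
  nullZ <- as.matrix(nullZ)
  if (is.null(rownames(nullZ))) stop("nullZ needs SNP rownames")
  p <- 2 * pnorm(-abs(nullZ))
  keep <- rownames(nullZ)[apply(p > pThreshold, 1, all)]
  keep <- keep[keep %in% colnames(panel)]
  if (length(keep) < 2L) return(keep)
  r2 <- cor(panel[, keep, drop = FALSE])^2
  retained <- character()
  for (snp in keep) {
    if (all(r2[snp, retained] < r2Threshold)) retained <- c(retained, snp)
  }
  retained
}

#' @importFrom stats pnorm dist
NULL
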