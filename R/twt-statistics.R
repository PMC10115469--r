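# The three component statistics and their Cauchy combination.
#
# T1 aggregates per-trait row quadratic forms (intrinsic genetic
# structure: LD spreads one causal variant over many Z's in a row), T2
# aggregates per-SNP column quadratic forms (pleiotropy), and T3 scans
# truncated quadratic forms over the largest-|Z| entries to catch
# irregular signal patterns. Each level of aggregation and the final
# combination use the Cauchy combination test, whose null tail is
# standard Cauchy under arbitrary dependence.

#' Default truncation grid
#'
#' The truncation levels eta scanned by the third component:
#' \{0.1, 0.2, ..., 0.9, 1\}. The eta = 1 case keeps the full vector and
#' has an exact chi-square reference with q*m degrees of freedom.
#'
#' @return numeric vector of truncation levels.
#' @export
defaultTruncationGrid <- function() (1:10) / 10

#' Number of entries kept at a truncation level
#'
#' Computes \eqn{\lceil \eta M \rceil} with a small downward nudge before
#' the ceiling so that products such as 0.1 * 60, which float just above
#' the exact integer, are not rounded up a full step.
#'
#' @param eta truncation level(s) in (0, 1].
#' @param M total number of Z entries (q * m).
#' @return integer vector of kept counts.
#' @export
truncationSize <- function(eta, M) {
  if (any(eta <= 0 | eta > 1)) stop("eta must lie in (0, 1]")
  pmin(as.integer(ceiling(eta * M - 1e-9)), M)
}

.clipP <- function(p, pFloor = 1e-14) pmin(pmax(p, pFloor), 1)

# upper cap applied to tan-transform inputs only: a p-value at (or within
# 1e-6 of) 1 contributes a bounded negative Cauchy term (~ -3.2e5) instead
# of an arbitrarily large one, so certain-null components cannot veto a
# genuine signal elsewhere; the significance (right) tail is unaffected
.clipTan <- function(p, pFloor = 1e-14) pmin(pmax(p, pFloor), 1 - 1e-6)

.etaKey <- function(eta) sprintf("%g", eta)

#' Cauchy combination of dependent p-values
#'
#' Transforms each p-value to a standard Cauchy variate via
#' \eqn{\tan\{(0.5 - p)\pi\}}, forms the weighted sum, and converts back
#' with \eqn{0.5 - \arctan(\cdot)/\pi}. The null tail of the weighted sum
#' is standard Cauchy under arbitrary correlation between the inputs.
#' Inputs are clipped to `[pFloor, 1 - 1e-6]` before the transform: the
#' tan/arctan pair cannot represent p-values below about 1e-14, and the
#' upper cap bounds the negative contribution of components at (or
#' numerically indistinguishable from) 1 so that certain-null components
#' cannot veto a strong signal elsewhere; the significance tail of the
#' combination is unaffected.
#'
#' @param pvals vector of p-values.
#' @param weights nonnegative weights summing to 1; default uniform.
#' @param pFloor numerical floor (default 1e-14).
#' @return list with `statistic` (the weighted Cauchy sum) and `pvalue`.
#' @examples
#' cauchyCombine(c(0.01, 0.5))$pvalue
#' @export
cauchyCombine <- function(pvals, weights = NULL, pFloor = 1e-14) {
  if (length(pvals) == 0L) stop("no p-values to combine")
  if (any(!is.finite(pvals))) stop("p-values must be finite")
  if (is.null(weights)) weights <- rep(1 / length(pvals), length(pvals))
  if (length(weights) != length(pvals))
    stop("weights and p-values have different lengths")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  p <- .clipTan(pvals, pFloor)
  stat <- sum(weights * tan((0.5 - p) * pi))
  list(statistic = stat, pvalue = .clipP(0.5 - atan(stat) / pi, pFloor))
}

.cholUpper <- function(corr, what = "correlation matrix") {
  U <- tryCatch(chol(corr), error = function(e)
    stop(what, " is not positive definite; regularize it first",
         call. = FALSE))
  U
}

.quadFormsCols <- function(X, corr, what) {
  # quadratic form x' corr^{-1} x for every column of X, by triangular solve
  U <- .cholUpper(corr, what)
  W <- forwardsolve(t(U), X)
  colSums(W^2)
}

#' Per-trait row quadratic-form p-values
#'
#' For each trait j the statistic \eqn{Z_{\{j\}}^\top \Delta_\theta^{-1}
#' Z_{\{j\}}} aggregates that trait's m SNP Z-scores and follows
#' chi-square with m degrees of freedom under the null.
#'
#' @param z a [ZMatrix] (or plain q x m matrix).
#' @param snpCorr the SNP correlation [SnpCorrMatrix] (or matrix), assumed
#'   positive definite (see [regularizeCorrelation()]).
#' @return named vector of q upper-tail p-values.
#' @export
rowQuadraticPvalues <- function(z, snpCorr) {
  zm <- if (is(z, "ZMatrix")) zValues(z) else as.matrix(z)
  theta <- if (is(snpCorr, "CorrMatrix")) corrValues(snpCorr) else
    as.matrix(snpCorr)
  if (ncol(zm) != ncol(theta))
    stop("Z matrix and SNP correlation dimensions disagree")
  stats <- .quadFormsCols(t(zm), theta, "SNP correlation matrix")
  p <- pchisq(stats, df = ncol(zm), lower.tail = FALSE)
  names(p) <- rownames(zm)
  p
}

#' Per-SNP column quadratic-form p-values
#'
#' For each SNP k the statistic \eqn{Z_{[k]}^\top \Delta_\rho^{-1}
#' Z_{[k]}} aggregates the q traits' Z-scores at that SNP (the
#' pleiotropy direction) and follows chi-square with q degrees of freedom
#' under the null.
#'
#' @param z a [ZMatrix] (or plain q x m matrix).
#' @param traitCorr the trait correlation [TraitCorrMatrix] (or matrix).
#' @return named vector of m upper-tail p-values.
#' @export
colQuadraticPvalues <- function(z, traitCorr) {
  zm <- if (is(z, "ZMatrix")) zValues(z) else as.matrix(z)
  rho <- if (is(traitCorr, "CorrMatrix")) corrValues(traitCorr) else
    as.matrix(traitCorr)
  if (nrow(zm) != ncol(rho))
    stop("Z matrix and trait correlation dimensions disagree")
  stats <- .quadFormsCols(zm, rho, "trait correlation matrix")
  p <- pchisq(stats, df = nrow(zm), lower.tail = FALSE)
  names(p) <- colnames(zm)
  p
}

#' Ranking of Z entries for truncation
#'
#' Indices of `zvec` ordered by decreasing absolute value, ties broken by
#' ascending vector index (deterministic).
#' @param zvec vectorized Z matrix.
#' @return integer permutation of `seq_along(zvec)`.
#' @keywords internal
.truncationOrder <- function(zvec) order(-abs(zvec), seq_along(zvec))

#' Truncated quadratic-form statistic
#'
#' Keeps the \eqn{\lceil \eta M \rceil} largest-|Z| entries of the
#' vectorized Z matrix and returns the quadratic form of the kept
#' subvector against the matching principal submatrix of the null
#' correlation \eqn{\Delta_\theta \otimes \Delta_\rho}.
#'
#' @param zvec vectorized Z matrix (column-stacked), length M.
#' @param kron the M x M Kronecker null correlation matrix.
#' @param eta truncation level in (0, 1].
#' @return the statistic value (scalar).
#' @examples
#' truncatedStatistic(c(1, 2, 3), diag(3), eta = 1)  # 14
#' @export
truncatedStatistic <- function(zvec, kron, eta) {
  zvec <- as.numeric(zvec)
  M <- length(zvec)
  if (!is.matrix(kron) || nrow(kron) != M || ncol(kron) != M)
    stop("Kronecker correlation must be M x M")
  k <- truncationSize(eta, M)
  idx <- .truncationOrder(zvec)[seq_len(k)]
  zs <- zvec[idx]
  sub <- kron[idx, idx, drop = FALSE]
  U <- .cholUpper(sub, "truncated correlation submatrix")
  sum(forwardsolve(t(U), zs)^2)
}

#' Truncated statistics for a whole grid at once
#'
#' Because the kept sets are nested across eta, all grid statistics can be
#' computed from a single Cholesky factorization of the permuted
#' Kronecker matrix: the factor of each leading principal block is the
#' leading block of the full factor.
#'
#' @inheritParams truncatedStatistic
#' @param etas truncation levels (default [defaultTruncationGrid()]).
#' @return named vector of statistics, one per eta.
#' @export
truncatedStatisticGrid <- function(zvec, kron,
                                   etas = defaultTruncationGrid()) {
  zvec <- as.numeric(zvec)
  M <- length(zvec)
  ks <- truncationSize(etas, M)
  ord <- .truncationOrder(zvec)
  U <- .cholUpper(kron[ord, ord, drop = FALSE],
                  "permuted Kronecker correlation")
  w <- forwardsolve(t(U), zvec[ord])
  cums <- cumsum(w^2)
  out <- cums[ks]
  names(out) <- .etaKey(etas)
  out
}

#' First component: Cauchy combination of per-trait p-values
#'
#' @inheritParams rowQuadraticPvalues
#' @param weights optional weights (default uniform 1/q).
#' @param pFloor numerical p-value floor.
#' @return combined p-value P1.
#' @export
computeP1 <- function(z, snpCorr, weights = NULL, pFloor = 1e-14) {
  cauchyCombine(rowQuadraticPvalues(z, snpCorr), weights, pFloor)$pvalue
}

#' Second component: Cauchy combination of per-SNP p-values
#'
#' @inheritParams colQuadraticPvalues
#' @param weights optional weights (default uniform 1/m).
#' @param pFloor numerical p-value floor.
#' @return combined p-value P2.
#' @export
computeP2 <- function(z, traitCorr, weights = NULL, pFloor = 1e-14) {
  cauchyCombine(colQuadraticPvalues(z, traitCorr), weights, pFloor)$pvalue
}

.etaPvalues <- function(stats, etas, M, calibration, pFloor = 1e-14) {
  p <- numeric(length(etas))
  for (i in seq_along(etas)) {
    if (etas[i] >= 1) {
      p[i] <- pchisq(stats[i], df = M, lower.tail = FALSE)
    } else {
      pars <- calibrationParams(calibration, etas[i])
      p[i] <- genChi2Survival(stats[i], pars)
    }
  }
  names(p) <- .etaKey(etas)
  .clipP(p, pFloor)
}

#' Third component: Cauchy combination over the truncation grid
#'
#' Computes every truncated statistic, converts each to a p-value (exact
#' chi-square with M degrees of freedom at eta = 1; the calibrated
#' generalized chi-square surrogate below 1) and combines them with
#' uniform weights.
#'
#' @param z a [ZMatrix] or plain q x m matrix.
#' @param snpCorr,traitCorr the two correlation matrices (PD).
#' @param calibration a [CalibrationTable] covering every eta < 1 in the
#'   grid (see [calibrateTruncated()]).
#' @param etas truncation grid (default [defaultTruncationGrid()]).
#' @param pFloor numerical p-value floor.
#' @return combined p-value P3.
#' @export
computeP3 <- function(z, snpCorr, traitCorr, calibration,
                      etas = defaultTruncationGrid(), pFloor = 1e-14) {
  zm <- if (is(z, "ZMatrix")) zValues(z) else as.matrix(z)
  theta <- if (is(snpCorr, "CorrMatrix")) corrValues(snpCorr) else
    as.matrix(snpCorr)
  rho <- if (is(traitCorr, "CorrMatrix")) corrValues(traitCorr) else
    as.matrix(traitCorr)
  kron <- kronecker(theta, rho)
  stats <- truncatedStatisticGrid(as.vector(zm), kron, etas)
  p <- .etaPvalues(stats, etas, length(zm), calibration, pFloor)
  cauchyCombine(p, pFloor = pFloor)$pvalue
}

#' The Three-Way Test
#'
#' Runs all three components on one Z matrix and combines P1, P2 and P3
#' with uniform weights 1/3 by the Cauchy combination test. If no
#' calibration table is supplied, one is computed via
#' [calibrateTruncated()] (parametric bootstrap of size `B`).
#'
#' @param z a [ZMatrix] or plain q x m matrix of Wald Z statistics.
#' @param snpCorr SNP correlation ([SnpCorrMatrix] or matrix).
#' @param traitCorr trait correlation ([TraitCorrMatrix] or matrix).
#' @param calibration optional [CalibrationTable]; computed when `NULL`.
#' @param etas truncation grid.
#' @param B parametric-bootstrap size used when calibrating here.
#' @param seed RNG seed for the calibration bootstrap.
#' @param pFloor numerical p-value floor (default 1e-14); p-values below
#'   it are reported as the floor.
#' @param epsPd eigenvalue floor used to regularize the correlation
#'   estimates before inversion.
#' @return a [TWTResult].
#' @examples
#' set.seed(7)
#' z <- matrix(rnorm(12), 3, 4)
#' res <- twtTest(z, diag(4), diag(3), B = 2000, seed = 1)
#' twtPvalue(res)
#' @export
twtTest <- function(z, snpCorr, traitCorr, calibration = NULL,
                    etas = defaultTruncationGrid(), B = 1e5,
                    seed = 1L, pFloor = 1e-14, epsPd = 1e-6) {
  zm <- if (is(z, "ZMatrix")) zValues(z) else as.matrix(z)
  if (any(!is.finite(zm))) stop("Z matrix has non-finite entries")
  theta <- if (is(snpCorr, "CorrMatrix")) corrValues(snpCorr) else
    as.matrix(snpCorr)
  rho <- if (is(traitCorr, "CorrMatrix")) corrValues(traitCorr) else
    as.matrix(traitCorr)
  if (ncol(zm) != ncol(theta) || nrow(zm) != ncol(rho))
    stop("Z matrix dimensions do not match the correlation matrices")
  theta <- regularizeCorrelation(theta, epsPd)
  rho <- regularizeCorrelation(rho, epsPd)

  pj <- .clipP(rowQuadraticPvalues(zm, theta), pFloor)
  pk <- .clipP(colQuadraticPvalues(zm, rho), pFloor)
  P1 <- cauchyCombine(pj, pFloor = pFloor)$pvalue
  P2 <- cauchyCombine(pk, pFloor = pFloor)$pvalue

  if (is.null(calibration))
    calibration <- calibrateTruncated(theta, rho,
                                      etas = etas[etas < 1],
                                      B = B, seed = seed)
  kron <- kronecker(theta, rho)
  stats <- truncatedStatisticGrid(as.vector(zm), kron, etas)
  petas <- .etaPvalues(stats, etas, length(zm), calibration, pFloor)
  P3 <- cauchyCombine(petas, pFloor = pFloor)$pvalue

  comb <- cauchyCombine(c(P1, P2, P3), pFloor = pFloor)
  new("TWTResult", traitPvalues = pj, snpPvalues = pk,
      etaPvalues = petas, P1 = P1, P2 = P2, P3 = P3,
      statistic = comb$statistic, pvalue = comb$pvalue, pFloor = pFloor)
}

#' Serialize a test result to a one-row data.frame
#'
#' @param result a [TWTResult].
#' @param gene optional gene label.
#' @return data.frame with gene, q, m, P1, P2, P3 and the TWT p-value.
#' @export
resultRecord <- function(result, gene = NA_character_) {
  stopifnot(is(result, "TWTResult"))
  data.frame(gene = gene,
             q = length(result@traitPvalues),
             m = length(result@snpPvalues),
             P1 = result@P1, P2 = result@P2, P3 = result@P3,
             twt_pvalue = result@pvalue,
             stringsAsFactors = FALSE)
}
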