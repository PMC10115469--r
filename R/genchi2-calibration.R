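# Parametric-bootstrap calibration of the truncated statistics.
#
# The truncated quadratic form has no classical null law (the kept set is
# data-dependent), so its null distribution is approximated by a
# generalized chi-square surrogate a * chisq_d + b fitted by matching the
# first three cumulants of bootstrap samples drawn from
# N(0, kron(theta, rho)).

#' Draw null samples of the truncated statistics
#'
#' Generates `B` draws of vec(Z) from N(0, kron(theta, rho)) and evaluates
#' the truncated statistic at every requested truncation level for each
#' draw, exactly as [truncatedStatistic()] would.
#'
#' @param snpCorr SNP correlation ([SnpCorrMatrix] or PD matrix).
#' @param traitCorr trait correlation ([TraitCorrMatrix] or PD matrix).
#' @param etas truncation levels to evaluate (may include 1).
#' @param B number of bootstrap draws (>= 1000 recommended).
#' @param seed RNG seed (integer); the draw is reproducible given the seed.
#' @return B x length(etas) matrix of statistics, columns named by eta.
#' @export
sampleNullTruncated <- function(snpCorr, traitCorr,
                                etas = defaultTruncationGrid(),
                                B = 1e5, seed = 1L) {
  theta <- if (is(snpCorr, "CorrMatrix")) corrValues(snpCorr) else
    as.matrix(snpCorr)
  rho <- if (is(traitCorr, "CorrMatrix")) corrValues(traitCorr) else
    as.matrix(traitCorr)
  if (any(etas <= 0 | etas > 1)) stop("eta must lie in (0, 1]")
  M <- ncol(theta) * ncol(rho)
  ks <- truncationSize(etas, M)
  cholTheta <- .cholUpper(theta, "SNP correlation matrix")
  cholRho <- .cholUpper(rho, "trait correlation matrix")
  kron <- kronecker(theta, rho)
  set.seed(as.integer(seed))
  out <- cpp_null_trunc_samples(cholTheta, cholRho, kron, ks,
                                as.integer(B))
  colnames(out) <- .etaKey(etas)
  out
}

#' Fit generalized chi-square parameters by cumulant matching
#'
#' Matches the sample mean, variance and third central moment
#' (1/B-normalized, as cumulant estimates) of bootstrap statistics to the
#' first three cumulants of a * chisq_d + b, giving
#' a = mu3 / (4 mu2), b = kappa1 - 2 mu2^2 / mu3, d = 8 mu2^3 / mu3^2.
#' The matching requires right skew (mu3 > 0); by default a non-positive
#' third moment is an error, or a moment-matched normal surrogate can be
#' returned instead.
#'
#' @param samples numeric vector of bootstrap statistics.
#' @param onNonpositiveSkew `"error"` (default) or `"normal"` to fall back
#'   to a moment-matched normal surrogate (logged via a warning).
#' @return a [GenChi2Params].
#' @examples
#' x <- 2 * rchisq(5e4, df = 3) + 1
#' matchCumulants(x)
#' @export
matchCumulants <- function(samples, onNonpositiveSkew = c("error",
                                                          "normal")) {
  onNonpositiveSkew <- match.arg(onNonpositiveSkew)
  samples <- as.numeric(samples)
  B <- length(samples)
  if (B < 2L) stop("need at least 2 samples")
  kappa1 <- mean(samples)
  centered <- samples - kappa1
  mu2 <- mean(centered^2)
  mu3 <- mean(centered^3)
  if (mu2 <= 0) stop("all samples equal; cannot match cumulants")
  if (mu3 <= 0) {
    if (onNonpositiveSkew == "error")
      stop("left-skewed or symmetric sample; generalized chi-square ",
           "matching invalid (third central moment <= 0)")
    warning("non-positive skew; using moment-matched normal surrogate")
    return(genChi2Params(a = sqrt(mu2), b = kappa1, dist = "normal"))
  }
  genChi2Params(a = mu3 / (4 * mu2),
                b = kappa1 - 2 * mu2^2 / mu3,
                d = 8 * mu2^3 / mu3^2)
}

#' Upper-tail probability of the generalized chi-square surrogate
#'
#' P(a * chisq_d + b > x), i.e. the chi-square survival function at
#' (x - b) / a; returns 1 for x <= b. For the normal fallback the normal
#' survival function is used.
#'
#' @param x statistic value(s).
#' @param params a [GenChi2Params].
#' @return upper-tail probability in [0, 1].
#' @export
genChi2Survival <- function(x, params) {
  stopifnot(is(params, "GenChi2Params"))
  if (params@dist == "normal")
    return(pnorm(x, mean = params@b, sd = params@a, lower.tail = FALSE))
  q <- (x - params@b) / params@a
  ifelse(q <= 0, 1, pchisq(q, df = params@d, lower.tail = FALSE))
}

#' Calibrate the truncation grid by parametric bootstrap
#'
#' Draws `B` null Z matrices from N(0, kron(theta, rho)), computes each
#' truncated statistic, and fits a generalized chi-square surrogate per
#' truncation level below 1. The calibration depends only on the two
#' correlation matrices, so one table can be reused across all tests and
#' simulation replications sharing them.
#'
#' @inheritParams sampleNullTruncated
#' @param etas truncation levels to calibrate (levels >= 1 are dropped:
#'   eta = 1 has an exact chi-square reference).
#' @param onNonpositiveSkew forwarded to [matchCumulants()].
#' @return a [CalibrationTable].
#' @examples
#' tab <- calibrateTruncated(diag(3), diag(2), B = 5000, seed = 42)
#' calibrationParams(tab, 0.5)
#' @export
calibrateTruncated <- function(snpCorr, traitCorr,
                               etas = defaultTruncationGrid(),
                               B = 1e5, seed = 1L,
                               onNonpositiveSkew = c("error", "normal")) {
  onNonpositiveSkew <- match.arg(onNonpositiveSkew)
  etas <- etas[etas < 1]
  if (length(etas) == 0L) stop("no truncation level below 1 to calibrate")
  if (B < 1000) stop("B >= 1000 is required for stable cumulants")
  samples <- sampleNullTruncated(snpCorr, traitCorr, etas = etas,
                                 B = B, seed = seed)
  params <- lapply(seq_along(etas), function(i)
    matchCumulants(samples[, i], onNonpositiveSkew))
  names(params) <- .etaKey(etas)
  new("CalibrationTable", eta = etas, params = params, B = as.integer(B),
      seed = as.integer(seed))
}

#' Write / read a calibration table as JSON
#'
#' @param x a [CalibrationTable].
#' @param path file path.
#' @return `readCalibration()` returns the restored [CalibrationTable];
#'   `writeCalibration()` returns `path` invisibly.
#' @export
writeCalibration <- function(x, path) {
  stopifnot(is(x, "CalibrationTable"))
  rec <- list(B = x@B, seed = x@seed,
              eta = x@eta,
              a = vapply(x@params, slot, 0, name = "a"),
              b = vapply(x@params, slot, 0, name = "b"),
              d = vapply(x@params, slot, 0, name = "d"),
              dist = vapply(x@params, slot, "", name = "dist"))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(seq_along(rec$eta), function(i)
    genChi2Params(rec$a[i], rec$b[i], rec$d[i], dist = rec$dist[i]))
  names(params) <- .etaKey(rec$eta)
  new("CalibrationTable", eta = rec$eta, params = params,
      B = as.integer(rec$B), seed = as.integer(rec$seed))
}

#' @importFrom stats rchisq
NULL
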