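# S4 classes for the Three-Way Test machinery.

.checkCorrMatrix <- function(values, what = "correlation matrix",
                             tol = 1e-8) {
  msgs <- character()
  if (!is.matrix(values) || !is.numeric(values))
    return(sprintf("%s: 'values' must be a numeric matrix", what))
  if (nrow(values) != ncol(values))
    msgs <- c(msgs, sprintf("%s must be square", what))
  else {
    if (any(!is.finite(values)))
      msgs <- c(msgs, sprintf("%s has non-finite entries", what))
    if (max(abs(values - t(values))) > tol)
      msgs <- c(msgs, sprintf("%s is not symmetric", what))
    if (max(abs(diag(values) - 1)) > tol)
      msgs <- c(msgs, sprintf("%s does not have unit diagonal", what))
    if (max(abs(values)) > 1 + tol)
      msgs <- c(msgs, sprintf("%s has entries outside [-1, 1]", what))
  }
  if (length(msgs)) msgs else TRUE
}

#' Correlation-matrix containers
#'
#' `TraitCorrMatrix` holds the estimated trait correlation matrix
#' \eqn{\Delta_\rho} (q x q) and `SnpCorrMatrix` the SNP (partial)
#' correlation matrix \eqn{\Delta_\theta} (m x m). Both are symmetric with
#' unit diagonal and entries in \eqn{[-1, 1]}; their Kronecker product is
#' the null correlation of the vectorized Z matrix. Use
#' [regularizeCorrelation()] to enforce positive definiteness before
#' quadratic forms.
#'
#' @slot values square numeric correlation matrix with labels as dimnames.
#'
#' @aliases TraitCorrMatrix-class SnpCorrMatrix-class CorrMatrix-class
#' @name CorrMatrix
#' @rdname CorrMatrix
#' @exportClass CorrMatrix TraitCorrMatrix SnpCorrMatrix
setClass("CorrMatrix", representation("VIRTUAL", values = "matrix"))

setClass("TraitCorrMatrix", contains = "CorrMatrix")
setClass("SnpCorrMatrix", contains = "CorrMatrix")

setValidity("CorrMatrix", function(object) {
  .checkCorrMatrix(object@values, class(object))
})

#' @param values square numeric correlation matrix.
#' @param labels optional character labels (traits or SNPs); defaults to
#'   existing dimnames or `V1..Vn`.
#' @return `TraitCorrMatrix()` and `SnpCorrMatrix()` return validated
#'   objects of the corresponding class.
#' @examples
#' TraitCorrMatrix(diag(3), labels = c("HDL", "LDL", "TG"))
#' @rdname CorrMatrix
#' @export
TraitCorrMatrix <- function(values, labels = NULL) {
  new("TraitCorrMatrix", values = .labelled(values, labels))
}

#' @rdname CorrMatrix
#' @export
SnpCorrMatrix <- function(values, labels = NULL) {
  new("SnpCorrMatrix", values = .labelled(values, labels))
}

.labelled <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels) && ncol(values) > 0)
      labels <- paste0("V", seq_len(ncol(values)))
  }
  stopifnot(length(labels) == ncol(values))
  dimnames(values) <- list(labels, labels)
  values
}

#' @param object,x a `CorrMatrix`.
#' @rdname CorrMatrix
#' @export
corrValues <- function(x) {
  stopifnot(is(x, "CorrMatrix"))
  x@values
}

#' @rdname CorrMatrix
#' @export
corrLabels <- function(x) {
  stopifnot(is(x, "CorrMatrix"))
  colnames(x@values)
}

setMethod("show", "CorrMatrix", function(object) {
  v <- object@values
  cat(sprintf("%s with %d variables\n", class(object), ncol(v)))
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("  eigenvalue range: [%.4g, %.4g]\n", min(ev), max(ev)))
  print(round(v[seq_len(min(6, nrow(v))), seq_len(min(6, ncol(v))),
                drop = FALSE], 3))
  if (ncol(v) > 6) cat("  ...\n")
  invisible(NULL)
})

#' Matrix of summary Wald Z statistics
#'
#' A q (traits) x m (SNPs) matrix of Wald Z-scores. Vectorization is
#' column-stacking (all traits for SNP 1, then SNP 2, ...), matching the
#' null correlation \eqn{\Delta_\theta \otimes \Delta_\rho}.
#'
#' @slot scores numeric q x m matrix; rownames are traits, colnames SNPs.
#'
#' @aliases ZMatrix-class
#' @name ZMatrix
#' @rdname ZMatrix
#' @exportClass ZMatrix
setClass("ZMatrix", representation(scores = "matrix"))

setValidity("ZMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s)) return("'scores' must be numeric")
  if (nrow(s) < 1L || ncol(s) < 1L)
    return("ZMatrix needs at least one trait and one SNP")
  if (any(!is.finite(s))) return("ZMatrix has non-finite entries")
  TRUE
})

#' @param scores numeric q x m matrix of Wald Z statistics.
#' @param traits,snps optional label vectors (default from dimnames).
#' @return `ZMatrix()` returns a validated `ZMatrix`.
#' @examples
#' z <- ZMatrix(matrix(rnorm(6), 2, 3), traits = c("t1", "t2"),
#'              snps = c("rs1", "rs2", "rs3"))
#' zValues(z)
#' @rdname ZMatrix
#' @export
ZMatrix <- function(scores, traits = NULL, snps = NULL) {
  scores <- as.matrix(scores)
  if (is.null(traits))
    traits <- rownames(scores) %||% paste0("trait", seq_len(nrow(scores)))
  if (is.null(snps))
    snps <- colnames(scores) %||% paste0("snp", seq_len(ncol(scores)))
  dimnames(scores) <- list(traits, snps)
  new("ZMatrix", scores = scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param x,object a `ZMatrix`.
#' @rdname ZMatrix
#' @export
zValues <- function(x) {
  stopifnot(is(x, "ZMatrix"))
  x@scores
}

#' @rdname ZMatrix
#' @export
zTraits <- function(x) rownames(zValues(x))

#' @rdname ZMatrix
#' @export
zSnps <- function(x) colnames(zValues(x))

setMethod("show", "ZMatrix", function(object) {
  s <- object@scores
  cat(sprintf("ZMatrix: %d traits x %d SNPs (M = %d)\n",
              nrow(s), ncol(s), length(s)))
  cat(sprintf("  max |Z| = %.3f at (%s, %s)\n", max(abs(s)),
              rownames(s)[which.max(apply(abs(s), 1, max))],
              colnames(s)[which.max(apply(abs(s), 2, max))]))
  invisible(NULL)
})

#' Covariate design for partial-correlation estimation
#'
#' An N x (s+1) design matrix whose first column is the intercept. `kind`
#' records how the SNP correlation should be estimated:
#' `"environment_only"` (covariates independent of genotype, plain Pearson
#' correlation suffices), `"stratification"` (project genotypes on the
#' design before correlating), or `"mixed"` (environmental variables are
#' ignored and only stratification axes are projected out, so the
#' estimator coincides with the stratification case).
#'
#' @slot matrix N x (s+1) numeric design, intercept first.
#' @slot kind one of `"environment_only"`, `"stratification"`, `"mixed"`.
#' @slot s number of stratification axes (columns beyond the intercept).
#'
#' @aliases CovariateDesign-class
#' @name CovariateDesign
#' @rdname CovariateDesign
#' @exportClass CovariateDesign
setClass("CovariateDesign",
         representation(matrix = "matrix", kind = "character",
                        s = "integer"))

setValidity("CovariateDesign", function(object) {
  m <- object@matrix
  msgs <- character()
  if (!object@kind %in% c("environment_only", "stratification", "mixed"))
    msgs <- c(msgs, "unknown covariate kind")
  if (ncol(m) < 1L || any(m[, 1] != 1))
    msgs <- c(msgs, "first design column must be the all-ones intercept")
  if (qr(m)$rank < ncol(m))
    msgs <- c(msgs, "design matrix is rank deficient")
  if (object@s != ncol(m) - 1L)
    msgs <- c(msgs, "'s' must equal ncol(matrix) - 1")
  if (length(msgs)) msgs else TRUE
})

#' @param matrix covariate columns *without* the intercept (N x s), or
#'   `NULL` for an intercept-only design.
#' @param kind covariate case (see slot description).
#' @param n number of individuals (required when `matrix` is `NULL`).
#' @return `covariateDesign()` returns a validated `CovariateDesign`.
#' @examples
#' covariateDesign(NULL, kind = "environment_only", n = 10)
#' @rdname CovariateDesign
#' @export
covariateDesign <- function(matrix = NULL,
                            kind = c("environment_only", "stratification",
                                     "mixed"),
                            n = if (is.null(matrix)) NULL else nrow(matrix)) {
  kind <- match.arg(kind)
  if (is.null(matrix)) {
    if (is.null(n)) stop("'n' is required for an intercept-only design")
    m <- base::matrix(1, nrow = n, ncol = 1L,
                      dimnames = list(NULL, "intercept"))
  } else {
    matrix <- as.matrix(matrix)
    m <- cbind(intercept = 1, matrix)
  }
  new("CovariateDesign", matrix = m, kind = kind, s = ncol(m) - 1L)
}

#' @param x,object a `CovariateDesign`.
#' @rdname CovariateDesign
#' @export
designMatrix <- function(x) {
  stopifnot(is(x, "CovariateDesign"))
  x@matrix
}

#' @rdname CovariateDesign
#' @export
designKind <- function(x) {
  stopifnot(is(x, "CovariateDesign"))
  x@kind
}

setMethod("show", "CovariateDesign", function(object) {
  cat(sprintf("CovariateDesign (%s): %d individuals, %d axes + intercept\n",
              object@kind, nrow(object@matrix), object@s))
  invisible(NULL)
})

#' Generalized chi-square surrogate parameters
#'
#' Parameters of the surrogate null law a * chisq_d + b used for a
#' truncated quadratic-form statistic, obtained by matching the first
#' three cumulants of parametric-bootstrap samples. `dist = "normal"`
#' marks the optional moment-matched normal fallback (then `a` is the
#' standard deviation and `b` the mean).
#'
#' @slot a scale (> 0 for the chi-square law; sd for the normal fallback).
#' @slot b location shift (mean for the normal fallback).
#' @slot d degrees of freedom (> 0; unused for the normal fallback).
#' @slot dist `"genchi2"` or `"normal"`.
#'
#' @aliases GenChi2Params-class
#' @name GenChi2Params
#' @rdname GenChi2Params
#' @exportClass GenChi2Params
setClass("GenChi2Params",
         representation(a = "numeric", b = "numeric", d = "numeric",
                        dist = "character"),
         prototype(dist = "genchi2"))

setValidity("GenChi2Params", function(object) {
  msgs <- character()
  if (!object@dist %in% c("genchi2", "normal"))
    msgs <- c(msgs, "dist must be 'genchi2' or 'normal'")
  if (object@dist == "genchi2") {
    if (!isTRUE(object@a > 0)) msgs <- c(msgs, "scale 'a' must be > 0")
    if (!isTRUE(object@d > 0))
      msgs <- c(msgs, "degrees of freedom 'd' must be > 0")
  } else if (!isTRUE(object@a > 0)) {
    msgs <- c(msgs, "normal fallback needs sd 'a' > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param a,b,d numeric parameters.
#' @param dist distribution tag.
#' @return `genChi2Params()` returns a validated `GenChi2Params`.
#' @examples
#' genChi2Params(2, 1, 3)
#' @rdname GenChi2Params
#' @export
genChi2Params <- function(a, b, d = NA_real_, dist = "genchi2") {
  new("GenChi2Params", a = as.numeric(a), b = as.numeric(b),
      d = as.numeric(d), dist = dist)
}

setMethod("show", "GenChi2Params", function(object) {
  if (object@dist == "genchi2")
    cat(sprintf("GenChi2Params: %.4g * chisq(%.4g) + %.4g\n",
                object@a, object@d, object@b))
  else
    cat(sprintf("GenChi2Params (normal fallback): N(%.4g, %.4g^2)\n",
                object@b, object@a))
  invisible(NULL)
})

#' Calibration table for truncated statistics
#'
#' Maps each truncation level eta < 1 to its fitted [GenChi2Params].
#' The eta = 1 statistic has the exact chi-square M reference and needs no
#' calibration. Produced by [calibrateTruncated()]; serializable with
#' [writeCalibration()] / [readCalibration()].
#'
#' @slot eta truncation levels covered (all < 1).
#' @slot params named list of [GenChi2Params], names `as.character(eta)`.
#' @slot B parametric-bootstrap sample size used.
#' @slot seed RNG seed recorded for provenance.
#'
#' @aliases CalibrationTable-class
#' @name CalibrationTable
#' @rdname CalibrationTable
#' @exportClass CalibrationTable
setClass("CalibrationTable",
         representation(eta = "numeric", params = "list", B = "integer",
                        seed = "integer"))

setValidity("CalibrationTable", function(object) {
  msgs <- character()
  if (any(object@eta >= 1 | object@eta <= 0))
    msgs <- c(msgs, "calibrated eta levels must lie in (0, 1)")
  if (length(object@params) != length(object@eta))
    msgs <- c(msgs, "one parameter set per eta is required")
  if (!all(vapply(object@params, is, TRUE, class2 = "GenChi2Params")))
    msgs <- c(msgs, "params must all be GenChi2Params")
  if (length(msgs)) msgs else TRUE
})

#' @param x,object a `CalibrationTable`.
#' @param eta truncation level to look up.
#' @return `calibrationParams()` returns the [GenChi2Params] for `eta`.
#' @rdname CalibrationTable
#' @export
calibrationParams <- function(x, eta) {
  stopifnot(is(x, "CalibrationTable"))
  key <- sprintf("%g", eta)
  if (!key %in% names(x@params))
    stop("no calibration available for eta = ", key)
  x@params[[key]]
}

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf("CalibrationTable: %d eta levels, B = %d, seed = %d\n",
              length(object@eta), object@B, object@seed))
  for (key in names(object@params)) {
    p <- object@params[[key]]
    cat(sprintf("  eta = %-4s  a = %8.4f  b = %8.4f  d = %8.3f%s\n",
                key, p@a, p@b, p@d,
                if (p@dist == "normal") "  [normal fallback]" else ""))
  }
  invisible(NULL)
})

#' Result of the Three-Way Test
#'
#' Component p-values and the combined Three-Way Test p-value for one Z
#' matrix (typically one gene). All p-values are clipped to the numerical
#' floor (default 1e-14) imposed by the tan/arctan transforms.
#'
#' @slot traitPvalues per-trait p-values from row quadratic forms.
#' @slot snpPvalues per-SNP p-values from column quadratic forms.
#' @slot etaPvalues per-truncation-level p-values (named by eta).
#' @slot P1,P2,P3 the three combined component p-values.
#' @slot statistic the final Cauchy-combination statistic t0.
#' @slot pvalue the Three-Way Test p-value 0.5 - arctan(t0)/pi.
#' @slot pFloor numerical floor applied to reported p-values.
#'
#' @aliases TWTResult-class
#' @name TWTResult
#' @rdname TWTResult
#' @exportClass TWTResult
setClass("TWTResult",
         representation(traitPvalues = "numeric", snpPvalues = "numeric",
                        etaPvalues = "numeric", P1 = "numeric",
                        P2 = "numeric", P3 = "numeric",
                        statistic = "numeric", pvalue = "numeric",
                        pFloor = "numeric"))

setValidity("TWTResult", function(object) {
  ps <- c(object@traitPvalues, object@snpPvalues, object@etaPvalues,
          object@P1, object@P2, object@P3, object@pvalue)
  if (any(ps < object@pFloor - 1e-300 | ps > 1))
    return("p-values must lie in [pFloor, 1]")
  TRUE
})

#' @param x,object a `TWTResult`.
#' @return `twtPvalue()` returns the combined p-value; `componentPvalues()`
#'   the named vector (P1, P2, P3).
#' @rdname TWTResult
#' @export
twtPvalue <- function(x) {
  stopifnot(is(x, "TWTResult"))
  x@pvalue
}

#' @rdname TWTResult
#' @export
componentPvalues <- function(x) {
  stopifnot(is(x, "TWTResult"))
  c(P1 = x@P1, P2 = x@P2, P3 = x@P3)
}

setMethod("show", "TWTResult", function(object) {
  cat("Three-Way Test result\n")
  cat(sprintf("  P1 (per-trait rows):    %.4g\n", object@P1))
  cat(sprintf("  P2 (per-SNP columns):   %.4g\n", object@P2))
  cat(sprintf("  P3 (truncated grid):    %.4g\n", object@P3))
  cat(sprintf("  TWT p-value:            %.4g\n", object@pvalue))
  invisible(NULL)
})

#' Gene-level test unit
#'
#' Bundles the Z matrix and the SNP correlation matrix for one gene, with
#' consistent SNP ordering, ready for [twtTest()].
#'
#' @slot gene gene identifier.
#' @slot z the [ZMatrix] (traits x gene SNPs).
#' @slot snpCorr the gene's [SnpCorrMatrix].
#'
#' @aliases GeneTestUnit-class
#' @name GeneTestUnit
#' @rdname GeneTestUnit
#' @exportClass GeneTestUnit
setClass("GeneTestUnit",
         representation(gene = "character", z = "ZMatrix",
                        snpCorr = "SnpCorrMatrix"))

setValidity("GeneTestUnit", function(object) {
  if (!identical(zSnps(object@z), corrLabels(object@snpCorr)))
    return("SNP order differs between ZMatrix and SnpCorrMatrix")
  TRUE
})

setMethod("show", "GeneTestUnit", function(object) {
  cat(sprintf("GeneTestUnit %s: %d traits x %d SNPs\n", object@gene,
              nrow(zValues(object@z)), ncol(zValues(object@z))))
  invisible(NULL)
})
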