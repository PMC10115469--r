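# Independent brute-force oracles used to freeze expected values.

# textbook Pearson correlation, written out
pearsonOracle <- function(x, y) {
  xb <- sum(x) / length(x)
  yb <- sum(y) / length(y)
  sum((x - xb) * (y - yb)) /
    sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# Cauchy combination by direct evaluation of the two printed formulas
cctOracle <- function(p, w = rep(1 / length(p), length(p))) {
  0.5 - atan(sum(w * tan((0.5 - p) * pi))) / pi
}

# truncated statistic by brute force: integer-arithmetic kept count
# (eta = i/10 on the grid), explicit subset, explicit matrix inverse
truncOracle <- function(z, kron, etaTenths) {
  M <- length(z)
  k <- (etaTenths * M + 9L) %/% 10L
  ord <- order(-abs(z), seq_along(z))
  idx <- ord[seq_len(k)]
  zs <- z[idx]
  drop(t(zs) %*% solve(kron[idx, idx, drop = FALSE]) %*% zs)
}

# per-regression Wald t-statistics via lm()
lmWaldOracle <- function(Y, G, covs = NULL) {
  q <- ncol(Y); m <- ncol(G)
  out <- matrix(NA_real_, q, m)
  for (j in seq_len(q)) for (k in seq_len(m)) {
    fit <- if (is.null(covs)) lm(Y[, j] ~ G[, k]) else
      lm(Y[, j] ~ G[, k] + covs)
    out[j, k] <- summary(fit)$coefficients[2, "t value"]
  }
  out
}

# random positive-definite correlation matrix
randomCorr <- function(p, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(p * (p + 2)), p + 2, p)
  s <- crossprod(a)
  d <- sqrt(diag(s))
  r <- s / tcrossprod(d)
  diag(r) <- 1
  r
}

# brute-force sampler of the truncated statistic under N(0, kron):
# plain R, explicit per-draw subset and solve (independent of the
# package's nested-Cholesky path and of its C++ sampler)
truncSamplerOracle <- function(kron, etaTenths, B, seed) {
  set.seed(seed)
  M <- ncol(kron)
  L <- t(chol(kron))
  k <- (etaTenths * M + 9L) %/% 10L
  vapply(seq_len(B), function(i) {
    z <- drop(L %*% rnorm(M))
    idx <- order(-abs(z), seq_along(z))[seq_len(k)]
    zs <- z[idx]
    drop(t(zs) %*% solve(kron[idx, idx, drop = FALSE]) %*% zs)
  }, 0)
}

# latent-Gaussian threshold genotype sampler, written independently:
# returns dosage draws for exactly two adjacent SNPs with AR(1) latent rho
adjacentDosageOracle <- function(rho, maf, B, seed) {
  set.seed(seed)
  thr <- qnorm(maf)
  draw <- function() {
    l1 <- rnorm(B)
    l2 <- rho * l1 + sqrt(1 - rho^2) * rnorm(B)
    cbind((l1 < thr) + 0, (l2 < thr) + 0)
  }
  draw() + draw()
}
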