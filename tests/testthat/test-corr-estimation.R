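test_that("trait correlation from null-SNP Z-scores matches the Pearson formula", {
  z <- cbind(t1 = c(1, 2, 3, 4), t2 = c(1, 3, 2, 4))
  est <- estimateTraitCorrelation(z, minSnps = 2L)
  expect_s4_class(est, "TraitCorrMatrix")
  expect_equal(corrValues(est)["t1", "t2"],
               pearsonOracle(z[, 1], z[, 2]), tolerance = 1e-12)
  expect_identical(diag(corrValues(est)), c(t1 = 1, t2 = 1))

  dup <- cbind(a = rnorm(60), b = 0)
  dup[, 2] <- dup[, 1]
  expect_equal(corrValues(estimateTraitCorrelation(dup))["a", "b"], 1)
  neg <- cbind(a = dup[, 1], b = -dup[, 1])
  expect_equal(corrValues(estimateTraitCorrelation(neg))["a", "b"], -1)
})

test_that("trait correlation estimation rejects degenerate input", {
  z <- cbind(t1 = rnorm(60), flat = rep(2, 60))
  expect_error(estimateTraitCorrelation(z), "flat")
  expect_error(estimateTraitCorrelation(matrix(rnorm(20), 10, 2)),
               "null SNPs")
})

test_that("genotype Pearson correlation matches the direct formula", {
  g <- cbind(rs1 = c(0, 1, 1, 2, 0, 2), rs2 = c(0, 1, 2, 2, 0, 1))
  est <- pearsonGenotypeCorrelation(g)
  expect_equal(corrValues(est)["rs1", "rs2"],
               pearsonOracle(g[, 1], g[, 2]), tolerance = 1e-12)

  dup <- cbind(a = g[, 1], b = g[, 1])
  expect_equal(corrValues(pearsonGenotypeCorrelation(dup))["a", "b"], 1)
  comp <- cbind(a = g[, 1], b = 2 - g[, 1])
  expect_equal(corrValues(pearsonGenotypeCorrelation(comp))["a", "b"], -1)
})

test_that("genotype correlation guards monomorphic SNPs and missingness", {
  g <- cbind(rs1 = c(0, 1, 2, 1), mono = c(1, 1, 1, 1))
  expect_error(pearsonGenotypeCorrelation(g), "mono")
  gm <- cbind(rs1 = c(0, 1, 2, 1, 0, 2, 1, 2, 0, 1),
              rs2 = c(NA, NA, NA, 1, 0, 2, 1, 2, 0, 1))
  expect_error(pearsonGenotypeCorrelation(gm), "rs2")
  # a single missing value (10%) is imputed under a looser threshold
  gm2 <- gm
  gm2[1:2, 2] <- c(1, 2)
  expect_s4_class(pearsonGenotypeCorrelation(gm2, maxMissing = 0.2),
                  "SnpCorrMatrix")
})

test_that("residualization projects out the covariate space", {
  set.seed(42)
  n <- 30
  g <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  x <- rnorm(n)

  d0 <- covariateDesign(NULL, kind = "environment_only", n = n)
  expect_equal(residualizeGenotypes(g, d0), scale(g, scale = FALSE),
               ignore_attr = TRUE)

  d1 <- covariateDesign(cbind(x = x), kind = "stratification")
  h <- residualizeGenotypes(g, d1)
  expect_lt(max(abs(crossprod(designMatrix(d1), h))), 1e-8 * n)
  expect_equal(residualizeGenotypes(h, d1), h, tolerance = 1e-10)

  dg <- covariateDesign(cbind(g1 = g[, 1]), kind = "stratification")
  expect_lt(max(abs(residualizeGenotypes(g, dg)[, 1])), 1e-10)

  expect_error(covariateDesign(cbind(x = x, x2 = 2 * x),
                               kind = "stratification"), "rank deficient")
})

test_that("partial correlation reduces to Pearson without genetic confounders", {
  set.seed(7)
  g <- matrix(rbinom(60, 2, 0.3), 20, 3,
              dimnames = list(NULL, paste0("rs", 1:3)))
  d <- covariateDesign(cbind(env = rnorm(20)), kind = "environment_only")
  expect_identical(corrValues(partialGenotypeCorrelation(g, d)),
                   corrValues(pearsonGenotypeCorrelation(g)))
})

test_that("partial correlation removes confounding by a shared covariate", {
  set.seed(11)
  n <- 20000
  c0 <- rnorm(n)
  # two 'dosages' correlated only through the shared axis
  g1 <- pmin(pmax(1 + 0.45 * c0 + 0.35 * rnorm(n), 0), 2)
  g2 <- pmin(pmax(1 + 0.45 * c0 + 0.35 * rnorm(n), 0), 2)
  g <- cbind(a = g1, b = g2)
  d <- covariateDesign(cbind(axis = c0), kind = "stratification")
  marginal <- corrValues(pearsonGenotypeCorrelation(g))["a", "b"]
  partial <- corrValues(partialGenotypeCorrelation(g, d))["a", "b"]
  expect_gt(marginal, 0.3)
  expect_lt(abs(partial), 0.05)
})

test_that("principal coordinates recover population structure", {
  set.seed(5)
  n1 <- 25; n2 <- 25; m <- 60
  pop1 <- matrix(rbinom(n1 * m, 2, 0.15), n1, m)
  pop2 <- matrix(rbinom(n2 * m, 2, 0.45), n2, m)
  panel <- rbind(pop1, pop2)
  d <- principalCoordinates(panel, s = 2)
  expect_s4_class(d, "CovariateDesign")
  axis1 <- designMatrix(d)[, 2]
  expect_true(max(axis1[1:n1]) < min(axis1[(n1 + 1):(n1 + n2)]) ||
              min(axis1[1:n1]) > max(axis1[(n1 + 1):(n1 + n2)]))
  expect_s4_class(principalCoordinates(panel, s = 0), "CovariateDesign")
  expect_equal(ncol(designMatrix(principalCoordinates(panel, s = 0))), 1L)
})

test_that("principal coordinates reproduce the top eigenspace of the double-centered distances", {
  set.seed(6)
  panel <- matrix(rbinom(200, 2, 0.3), 20, 10)
  s <- 3
  d <- principalCoordinates(panel, s = s)
  coords <- designMatrix(d)[, -1, drop = FALSE]
  # oracle: eigendecomposition of -0.5 * J D^2 J
  D2 <- as.matrix(dist(panel))^2
  n <- nrow(panel)
  J <- diag(n) - matrix(1 / n, n, n)
  Bmat <- -0.5 * J %*% D2 %*% J
  es <- eigen(Bmat, symmetric = TRUE)
  expect_equal(tcrossprod(coords),
               es$vectors[, 1:s] %*% diag(es$values[1:s]) %*%
                 t(es$vectors[, 1:s]),
               tolerance = 1e-8)
})

test_that("regularization enforces the eigenvalue floor and is a no-op on good input", {
  id <- diag(3)
  expect_identical(regularizeCorrelation(id), id)

  sing <- matrix(c(1, 1, 1, 1), 2, 2)
  fixed <- regularizeCorrelation(sing, epsPd = 1e-4)
  expect_equal(diag(fixed), c(1, 1))
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 1e-4 * 0.99)

  r5 <- randomCorr(5, seed = 3)
  stopifnot(min(eigen(r5)$values) > 0.05)
  expect_identical(regularizeCorrelation(r5, epsPd = 1e-4), r5)

  asym <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(regularizeCorrelation(asym), "symmetric")

  est <- regularizeCorrelation(SnpCorrMatrix(sing, labels = c("a", "b")),
                               epsPd = 1e-4)
  expect_s4_class(est, "SnpCorrMatrix")
})

test_that("null-SNP selection applies the p-value filter and LD pruning", {
  set.seed(9)
  n <- 400
  base <- rbinom(n, 2, 0.3)
  panel <- cbind(s1 = base,
                 s2 = pmin(pmax(base + rbinom(n, 1, 0.05) -
                                  rbinom(n, 1, 0.05), 0), 2),  # high LD
                 s3 = rbinom(n, 2, 0.3),
                 s4 = rbinom(n, 2, 0.4))
  z <- rbind(s1 = c(0.1, -0.4), s2 = c(0.3, 0.2),
             s3 = c(5.0, 0.1), s4 = c(-1.0, 0.5))
  kept <- selectNullSnps(z, panel)
  expect_false("s3" %in% kept)         # significant somewhere
  expect_true("s1" %in% kept)
  expect_false("s2" %in% kept)         # pruned: r2 with s1 above 0.1
  expect_true("s4" %in% kept)
})
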