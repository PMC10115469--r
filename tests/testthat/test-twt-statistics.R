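test_that("Cauchy combination matches the printed transform pair", {
  expect_equal(cauchyCombine(rep(0.5, 4))$pvalue, 0.5, tolerance = 1e-12)
  expect_equal(cauchyCombine(0.01)$pvalue, 0.01, tolerance = 1e-12)
  expect_equal(cauchyCombine(c(0.01, 0.5))$pvalue,
               cctOracle(c(0.01, 0.5)), tolerance = 1e-12)
  expect_equal(cauchyCombine(c(0.01, 0.5))$pvalue, 0.0200,
               tolerance = 1e-3)
  # order invariance with uniform weights
  p <- c(0.03, 0.2, 0.77, 0.41)
  expect_equal(cauchyCombine(p)$pvalue, cauchyCombine(rev(p))$pvalue,
               tolerance = 1e-14)
})

test_that("Cauchy combination validates its inputs", {
  expect_error(cauchyCombine(numeric(0)), "no p-values")
  expect_error(cauchyCombine(c(0.1, 0.2), weights = 1), "length")
  expect_error(cauchyCombine(c(0.1, 0.2), weights = c(0.3, 0.3)),
               "sum to 1")
  expect_error(cauchyCombine(c(0.1, 0.2), weights = c(-0.5, 1.5)),
               "nonnegative")
})

test_that("row quadratic forms give chi-square m p-values", {
  # m = 1: statistic Z^2 against chi-square 1
  expect_equal(unname(rowQuadraticPvalues(matrix(2, 1, 1), diag(1))),
               pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(rowQuadraticPvalues(matrix(2, 1, 1), diag(1))),
               0.04550, tolerance = 1e-4)
  # m = 2, correlated: (1,1)' with off-diagonal 0.5 gives 4/3, tail exp(-2/3)
  th <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(unname(rowQuadraticPvalues(matrix(c(1, 1), 1, 2), th)),
               exp(-2 / 3), tolerance = 1e-12)
  # zero row
  expect_equal(unname(rowQuadraticPvalues(matrix(0, 1, 3), diag(3))), 1)
})

test_that("factorized quadratic forms agree with explicit inversion", {
  set.seed(21)
  for (rep in 1:5) {
    q <- sample(2:5, 1); m <- sample(2:6, 1)
    z <- matrix(rnorm(q * m), q, m)
    th <- randomCorr(m, seed = rep)
    rho <- randomCorr(q, seed = rep + 100)
    pj <- rowQuadraticPvalues(z, th)
    stats <- sapply(seq_len(q), function(j)
      drop(t(z[j, ]) %*% solve(th) %*% z[j, ]))
    expect_equal(unname(pj), pchisq(stats, m, lower.tail = FALSE),
                 tolerance = 1e-8)
    pk <- colQuadraticPvalues(z, rho)
    statsC <- sapply(seq_len(m), function(k)
      drop(t(z[, k]) %*% solve(rho) %*% z[, k]))
    expect_equal(unname(pk), pchisq(statsC, q, lower.tail = FALSE),
                 tolerance = 1e-8)
    # transposition symmetry: columns of Z are rows of t(Z)
    expect_equal(unname(colQuadraticPvalues(z, rho)),
                 unname(rowQuadraticPvalues(t(z), rho)), tolerance = 1e-12)
  }
})

test_that("column quadratic forms handle degenerate dimensions", {
  z <- matrix(c(1.3, -0.7, 2.1), 1, 3)
  expect_equal(unname(colQuadraticPvalues(z, diag(1))),
               pchisq(z[1, ]^2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(colQuadraticPvalues(matrix(0, 2, 1), diag(2))), 1)
})

test_that("truncated statistic selects by |Z| with deterministic ties", {
  expect_equal(truncatedStatistic(c(1, 2, 3), diag(3), eta = 1), 14)
  z6 <- c(3, -2, 1, 0.5, -0.2, 0.1)
  expect_equal(truncatedStatistic(z6, diag(6), eta = 0.4), 14)  # keeps 3
  # M = 2, eta = 0.5 keeps only the larger entry; 1x1 submatrix
  kron2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(truncatedStatistic(c(1, 2), kron2, eta = 0.5), 4)
  # tie on |z|: ascending index wins, deterministic
  kron3 <- randomCorr(3, seed = 2)
  expect_equal(truncatedStatistic(c(2, -2, 1), kron3, eta = 0.4),
               truncOracle(c(2, -2, 1), kron3, 4L))
})

test_that("kept counts use exact-integer ceilings across grid and M", {
  expect_identical(truncationSize(0.4, 6L), 3L)
  expect_identical(truncationSize(0.1, 60L), 6L)   # fp-hazard product
  expect_identical(truncationSize(1, 54L), 54L)
  expect_identical(truncationSize((1:10) / 10, 54L),
                   as.integer((((1:10) * 54) + 9) %/% 10))
  expect_error(truncationSize(0, 10L), "eta")
})

test_that("grid evaluation agrees with single-eta brute force and C++ path", {
  set.seed(33)
  for (rep in 1:4) {
    q <- 3; m <- 4; M <- q * m
    z <- rnorm(M)
    kron <- kronecker(randomCorr(m, seed = rep), randomCorr(q, rep + 50))
    grid <- defaultTruncationGrid()
    gridStats <- truncatedStatisticGrid(z, kron, grid)
    for (i in seq_along(grid)) {
      expect_equal(unname(gridStats[i]), truncOracle(z, kron, i),
                   tolerance = 1e-8)
      expect_equal(unname(gridStats[i]),
                   truncatedStatistic(z, kron, grid[i]), tolerance = 1e-8)
    }
    ks <- truncationSize(grid, M)
    cppStats <- twtest:::cpp_trunc_stats(z, kron, ks)
    expect_equal(unname(gridStats), as.numeric(cppStats),
                 tolerance = 1e-10)
  }
})

test_that("P1/P2 collapse correctly in degenerate cases", {
  z0 <- matrix(0, 3, 4)
  expect_gt(computeP1(z0, diag(4)), 0.99)
  expect_gt(computeP2(z0, diag(3)), 0.99)
  z1 <- matrix(c(1.7, 0.2, -0.9), 1, 3)
  expect_equal(computeP1(z1, diag(3)),
               unname(rowQuadraticPvalues(z1, diag(3))), tolerance = 1e-12)
  expect_equal(cauchyCombine(rep(0.5, 3))$pvalue, 0.5, tolerance = 1e-12)
})

test_that("the full test behaves at the null and signal extremes", {
  res0 <- twtTest(matrix(0, 3, 3), diag(3), diag(3), B = 2000, seed = 4)
  expect_gt(twtPvalue(res0), 0.99)

  zsig <- matrix(0, 3, 3)
  zsig[2, 2] <- 8
  res1 <- twtTest(zsig, diag(3), diag(3), B = 2000, seed = 4)
  expect_lt(twtPvalue(res1), 1e-6)

  # closed-form cross-check of P1 under identity covariance (the all-zero
  # rows give pj = 1, capped at 1 - 1e-6 before the tan transform)
  pj <- pchisq(rowSums(zsig^2), 3, lower.tail = FALSE)
  expect_equal(componentPvalues(res1)[["P1"]],
               cctOracle(pmin(pmax(pj, 1e-14), 1 - 1e-6)),
               tolerance = 1e-10)

  # p-values never fall below the 1e-14 numerical floor
  zhuge <- matrix(40, 3, 3)
  resH <- twtTest(zhuge, diag(3), diag(3), B = 2000, seed = 4)
  expect_gte(twtPvalue(resH), 1e-14)
  expect_gte(min(resH@traitPvalues, resH@snpPvalues, resH@etaPvalues),
             1e-14)
})

test_that("scaling all Z up cannot increase the identity-covariance p-value", {
  set.seed(12)
  z <- matrix(rnorm(9), 3, 3)
  calib <- calibrateTruncated(diag(3), diag(3), B = 5000, seed = 8)
  pv <- sapply(c(1, 1.5, 2.5, 4), function(s)
    twtPvalue(twtTest(s * z, diag(3), diag(3), calibration = calib)))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("eta = 1 p-value is the exact chi-square tail of the full quadratic form", {
  set.seed(3)
  z <- matrix(rnorm(12), 3, 4)
  calib <- calibrateTruncated(diag(4), diag(3), B = 2000, seed = 2)
  res <- twtTest(z, diag(4), diag(3), calibration = calib)
  expect_equal(unname(res@etaPvalues["1"]),
               pchisq(sum(z^2), 12, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("results serialize to a flat record", {
  res <- twtTest(matrix(rnorm(6), 2, 3), diag(3), diag(2), B = 2000,
                 seed = 9)
  rec <- resultRecord(res, gene = "GENE1")
  expect_identical(rec$gene, "GENE1")
  expect_identical(rec$q, 2L)
  expect_identical(rec$m, 3L)
  expect_equal(rec$twt_pvalue, twtPvalue(res))
})
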