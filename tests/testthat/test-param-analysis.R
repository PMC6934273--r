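# Connectivity, convexity bookkeeping, correlations and polynomial
# variance decomposition.

test_that("interior neighbor counts match brute-force enumeration", {
  expect_equal(neighborCountInterior(1), 12)
  # brute force on a 3^6 grid around the center point
  center <- rep(2L, 6)
  pts <- as.matrix(expand.grid(rep(list(1:3), 6)))
  dist <- abs(sweep(pts, 2, center))
  nDiff <- rowSums(dist > 0)
  within1 <- apply(dist <= 1, 1, all)
  for (n in 1:3) {
    brute <- sum(within1 & nDiff >= 1 & nDiff <= n)
    expect_equal(neighborCountInterior(n), brute)
  }
})

test_that("connected components follow the neighbor order", {
  g <- deskGrid()
  expect_equal(connectedComponents(5, g, 1)$nClusters, 1)
  # two instances differing by one step in each of two dimensions
  i1 <- instanceId(g, c(1, 1, 1, 1, 1, 1))
  i2 <- instanceId(g, c(2, 2, 1, 1, 1, 1))
  expect_equal(connectedComponents(c(i1, i2), g, 1)$nClusters, 2)
  expect_equal(connectedComponents(c(i1, i2), g, 2)$nClusters, 1)
})

test_that("component count is non-increasing in neighbor order", {
  g <- deskGrid()
  set.seed(14)
  ids <- sample(gridSize(g), 120)
  counts <- vapply(1:4, function(n)
    connectedComponents(ids, g, n)$nClusters, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("convexity bookkeeping produces nPairs x 3 children", {
  g <- deskGrid()
  set.seed(2)
  acc <- as.data.frame(instanceIndices(g, sample(729, 50)))
  for (d in gbcpop:::GRID_DIMS) acc[[d]] <- gridValues(g)[[d]][acc[[d]]]
  res <- convexityTest(acc, evaluator = function(p) TRUE, nPairs = 40,
                       seed = 4)
  expect_equal(res$nChildren, 120)
  expect_equal(res$fraction, 1.0)
  expect_true(all(res$children$mE == round(res$children$mE)))
  # interpolants lie between their parents
  expect_true(all(res$children$wE >= min(acc$wE) &
                    res$children$wE <= max(acc$wE)))
  # identical parents give children identical to the parents
  two <- acc[c(1, 1), ]
  two[2, ] <- two[1, ]
  resSame <- convexityTest(two, evaluator = function(p) TRUE, nPairs = 5,
                           seed = 4)
  for (d in gbcpop:::GRID_DIMS)
    expect_true(all(resSame$children[[d]] == two[1, d]))
  expect_error(convexityTest(acc[1, ], function(p) TRUE, nPairs = 2), "2")
})

test_that("parameter correlations recover constructed dependence", {
  set.seed(31)
  X <- as.data.frame(matrix(runif(6 * 10000), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  indep <- pairwiseCorrelations(X)
  off <- indep$r[upper.tri(indep$r)]
  expect_true(all(abs(off) < 0.1))
  expect_false(any(indep$flagged))
  X$wE <- X$mE                      # duplicated column
  X$aE <- -X$mE                     # anticorrelated
  dep <- pairwiseCorrelations(X)
  expect_equal(dep$r["mE", "wE"], 1)
  expect_equal(dep$r["mE", "aE"], -1)
  expect_true(dep$flagged["mE", "wE"])
  X$tR <- 1                         # zero variance
  degen <- pairwiseCorrelations(X)
  expect_true(is.na(degen$r["tR", "mE"]))
})

test_that("polynomial bases have 6, 27 and 83 terms", {
  set.seed(5)
  X <- as.data.frame(matrix(rnorm(6 * 200), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  y <- rnorm(200)
  expect_equal(polynomialFit(X, y, 1)$nTerms, 6)
  expect_equal(polynomialFit(X, y, 2)$nTerms, 27)
  expect_equal(polynomialFit(X, y, 3)$nTerms, 83)
})

test_that("fits agree with lm and respect nesting", {
  set.seed(17)
  X <- as.data.frame(matrix(rnorm(6 * 400), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  Z <- scale(as.matrix(X))
  y <- 2 * Z[, 1] - Z[, 4] + 0.5 * Z[, 2] * Z[, 6] + rnorm(400, 0, 0.3)
  r2 <- vapply(1:3, function(d) polynomialFit(X, y, d)$r2, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))            # nested models
  # independent oracle: lm on the same design
  D1 <- as.data.frame(Z)
  expect_equal(r2[1], summary(lm(y ~ ., data = D1))$r.squared,
               tolerance = 1e-10)
  D2 <- as.data.frame(gbcpop:::polyDesign(Z, 2))
  names(D2) <- paste0("t", seq_len(ncol(D2)))
  expect_equal(r2[2], summary(lm(y ~ ., data = D2))$r.squared,
               tolerance = 1e-10)
})

test_that("exact polynomial relationships are recovered", {
  set.seed(23)
  X <- as.data.frame(matrix(runif(6 * 300, 1, 3), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  Z <- scale(as.matrix(X))
  lin <- 3 * Z[, 2] - Z[, 5]
  expect_equal(polynomialFit(X, lin, 1)$r2, 1, tolerance = 1e-10)
  prod2 <- Z[, 1] * Z[, 3]
  expect_lt(polynomialFit(X, prod2, 1)$r2, 0.2)
  expect_equal(polynomialFit(X, prod2, 2)$r2, 1, tolerance = 1e-10)
})

test_that("transform domains and rank deficiency are enforced", {
  set.seed(3)
  X <- as.data.frame(matrix(rnorm(6 * 100), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  y <- c(-1, abs(rnorm(99)) + 0.1)
  fit <- polynomialFit(X, y, 1, transform = "log")
  expect_equal(fit$nExcluded, 1)
  expect_equal(fit$nUsed, 99)
  vs <- c(1.0, runif(99, 0.5, 0.99))
  expect_equal(polynomialFit(X, vs, 1, transform = "log1m")$nExcluded, 1)
  X$wE <- X$mE    # collinear design
  expect_error(polynomialFit(X, rnorm(100), 1), "rank-deficient")
})

test_that("linear variance contributions are the Shapley values of R2", {
  set.seed(41)
  X <- as.data.frame(matrix(rnorm(6 * 300), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  Z <- scale(as.matrix(X))
  y <- 2 * Z[, 1] + Z[, 3] + rnorm(300, 0, 0.5)
  vc <- varianceContribution(X, y, degree = 1)
  expect_equal(vc$nOrderings, 720)
  expect_equal(sum(vc$gain), polynomialFit(X, y, 1)$r2, tolerance = 1e-10)
  # direct Shapley computation over all subsets via lm R2
  r2sub <- function(S) {
    if (!length(S)) return(0)
    summary(lm(y ~ Z[, S, drop = FALSE]))$r.squared
  }
  shap <- numeric(6)
  vars <- 1:6
  for (k in vars) {
    others <- setdiff(vars, k)
    for (m in 0:5) {
      for (S in if (m == 0) list(integer(0)) else
           asplit(utils::combn(others, m), 2)) {
        w <- factorial(m) * factorial(6 - m - 1) / factorial(6)
        shap[k] <- shap[k] + w * (r2sub(c(S, k)) - r2sub(S))
      }
    }
  }
  expect_equal(unname(vc$gain), shap, tolerance = 1e-8)
})

test_that("a single-parameter output credits nearly all gain to that term", {
  set.seed(43)
  X <- as.data.frame(matrix(rnorm(6 * 400), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  y <- 5 * scale(as.matrix(X))[, 4] + rnorm(400, 0, 0.05)
  vc <- varianceContribution(X, y, degree = 1)
  expect_gt(vc$gain[["tR"]] / sum(vc$gain), 0.98)
})

test_that("quadratic contributions start from the linear fit and telescope", {
  set.seed(47)
  X <- as.data.frame(matrix(rnorm(6 * 300), ncol = 6))
  names(X) <- gbcpop:::GRID_DIMS
  Z <- scale(as.matrix(X))
  y <- Z[, 1] + Z[, 2] * Z[, 3] + rnorm(300, 0, 0.2)
  vc <- varianceContribution(X, y, degree = 2, nOrderings = 50, seed = 6)
  expect_equal(vc$r2Base, polynomialFit(X, y, 1)$r2, tolerance = 1e-10)
  expect_equal(vc$r2Total, polynomialFit(X, y, 2)$r2, tolerance = 1e-10)
  expect_equal(sum(vc$gain), vc$r2Total - vc$r2Base, tolerance = 1e-10)
  expect_equal(names(which.max(vc$gain)), "wE*aE")
})
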