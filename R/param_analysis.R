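# Analyses of the accepted parameter set: connectivity in the grid,
# convexity by interpolation, pairwise parameter correlations, and
# polynomial input-output variance decomposition.

# ---- connectivity ------------------------------------------------------

#' Closed-form neighbor count of an interior grid point
#'
#' An order-n neighbor differs in at most n of the six dimensions by one
#' grid step. An interior point has \eqn{\sum_{k=1}^{n} \binom{6}{k} 2^k}
#' such neighbors: 12 for n = 1, 72 for n = 2, 232 for n = 3.
#'
#' @param order n in 1..6.
#' @param nDim number of grid dimensions.
#' @return integer neighbor count.
#' @export
neighborCountInterior <- function(order, nDim = 6) {
  stopifnot(order >= 1, order <= nDim)
  sum(choose(nDim, seq_len(order)) * 2^seq_len(order))
}

# All index offsets in {-1,0,1}^nDim with 1..order nonzero entries.
neighborOffsets <- function(order, nDim = 6) {
  g <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), nDim)))
  nz <- rowSums(g != 0L)
  g[nz >= 1 & nz <= order, , drop = FALSE]
}

#' Connected components of an accepted instance set
#'
#' Two instances are connected when a path of order-\code{order} neighbor
#' steps exists between them with every intermediate instance also in the
#' accepted set. The component count is weakly decreasing in the neighbor
#' order.
#'
#' @param ids accepted instance ids.
#' @param grid the \code{ParameterGrid}.
#' @param order neighbor order (1..6).
#' @return list with \code{nClusters} and \code{labels} (component label
#'   per id, in the order of \code{ids}).
#' @export
connectedComponents <- function(ids, grid, order = 1) {
  if (!length(ids)) return(list(nClusters = 0L, labels = integer(0)))
  ids <- as.numeric(ids)
  n <- vapply(gridValues(grid), length, integer(1))
  idx <- instanceIndices(grid, ids)
  offs <- neighborOffsets(order)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    shifted <- sweep(idx, 2, offs[k, ], `+`)
    ok <- rowSums(shifted >= 1L) == 6L &
      rowSums(shifted <= rep(n, each = nrow(shifted))) == 6L
    if (!any(ok)) next
    nid <- instanceId(grid, shifted[ok, , drop = FALSE])
    pos <- match(nid, ids)
    hit <- !is.na(pos)
    if (any(hit))
      edges[[k]] <- cbind(which(ok)[hit], pos[hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (!is.null(em) && nrow(em))
    g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)
  list(nClusters = as.integer(comp$no),
       labels = as.integer(comp$membership))
}

# ---- convexity ---------------------------------------------------------

#' Convexity of the accepted set by interpolation
#'
#' Samples random pairs of accepted instances ("parents") and evaluates
#' intermediate ("child") instances at interpolation fractions 1/4, 1/2 and
#' 3/4 between the parent parameter vectors (mE rounded to the nearest
#' integer, other parameters continuous). If the accepted region were
#' convex, every child would be accepted.
#'
#' @param accepted data.frame (or matrix) of accepted parameter vectors
#'   with columns mE, wE, aE, tR, tA, sA.
#' @param evaluator function taking a \code{GBCParameters} and returning
#'   TRUE/FALSE (accepted). For a full analysis pass a closure around
#'   [evaluateInstance()]; the default of NULL must then be overridden.
#' @param nPairs number of parent pairs (3500 for the full analysis).
#' @param fractions interpolation fractions.
#' @param seed sampling seed.
#' @return list with \code{fraction} accepted, \code{nChildren}
#'   (nPairs * length(fractions)) and the per-child records.
#' @export
convexityTest <- function(accepted, evaluator, nPairs = 3500,
                          fractions = c(0.25, 0.5, 0.75), seed = 1) {
  accepted <- as.data.frame(accepted)[, GRID_DIMS, drop = FALSE]
  if (nrow(accepted) < 2) stop("need at least 2 accepted instances")
  set.seed(childSeed(seed, stream = 77L))
  i1 <- sample.int(nrow(accepted), nPairs, replace = TRUE)
  i2 <- sample.int(nrow(accepted) - 1L, nPairs, replace = TRUE)
  i2 <- ifelse(i2 >= i1, i2 + 1L, i2)   # distinct parents
  rows <- vector("list", nPairs * length(fractions))
  k <- 0L
  for (p in seq_len(nPairs)) {
    a <- as.numeric(accepted[i1[p], ])
    b <- as.numeric(accepted[i2[p], ])
    for (f in fractions) {
      child <- a + f * (b - a)
      params <- GBCParameters(mE = round(child[1]), wE = child[2],
                              aE = child[3], tR = child[4], tA = child[5],
                              sA = child[6])
      k <- k + 1L
      rows[[k]] <- data.frame(pair = p, fraction = f,
                              mE = params@mE, wE = params@wE,
                              aE = params@aE, tR = params@tR,
                              tA = params@tA, sA = params@sA,
                              accepted = isTRUE(evaluator(params)))
    }
  }
  children <- do.call(rbind, rows)
  list(fraction = mean(children$accepted), nChildren = nrow(children),
       children = children)
}

# ---- correlations ------------------------------------------------------

#' Pairwise parameter correlations of the accepted set
#'
#' Pearson correlation coefficients between each pair of the six model
#' parameters over the accepted instances, with per-pair p-values.
#' Correlations with |r| > 0.2 and p below the significance threshold
#' (default 1e-9) are flagged.
#'
#' @param accepted data.frame with columns mE, wE, aE, tR, tA, sA.
#' @param rThreshold,pThreshold flagging thresholds.
#' @return list with symmetric \code{r} and \code{p} matrices (unit
#'   diagonal; NA where a dimension has zero variance) and the logical
#'   \code{flagged} matrix.
#' @export
pairwiseCorrelations <- function(accepted, rThreshold = 0.2,
                                 pThreshold = 1e-9) {
  X <- as.matrix(as.data.frame(accepted)[, GRID_DIMS, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 accepted instances")
  p <- ncol(X)
  r <- matrix(NA_real_, p, p, dimnames = list(GRID_DIMS, GRID_DIMS))
  pv <- r
  diag(r) <- 1; diag(pv) <- 0
  sds <- apply(X, 2, stats::sd)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (sds[i] == 0 || sds[j] == 0) next
    ct <- stats::cor.test(X[, i], X[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  flagged <- !is.na(r) & abs(r) > rThreshold & pv < pThreshold
  diag(flagged) <- FALSE
  list(r = r, p = pv, flagged = flagged)
}

# ---- polynomial input-output regressions ------------------------------

# Polynomial term list over 6 z-scored inputs: degree-1 terms are the six
# variables; degree-2 adds the 21 products x_i x_j (i <= j); degree-3 adds
# the 56 products x_i x_j x_k (i <= j <= k), for 6, 27 and 83 terms.
polyTermIndices <- function(degree, nVar = 6) {
  terms <- lapply(seq_len(nVar), function(i) i)
  if (degree >= 2)
    for (i in 1:nVar) for (j in i:nVar)
      terms[[length(terms) + 1L]] <- c(i, j)
  if (degree >= 3)
    for (i in 1:nVar) for (j in i:nVar) for (k in j:nVar)
      terms[[length(terms) + 1L]] <- c(i, j, k)
  terms
}

polyTermNames <- function(terms, varNames) {
  vapply(terms, function(ix) paste(varNames[ix], collapse = "*"),
         character(1))
}

polyDesign <- function(Z, degree) {
  terms <- polyTermIndices(degree, ncol(Z))
  X <- vapply(terms, function(ix) {
    col <- Z[, ix[1]]
    for (m in ix[-1]) col <- col * Z[, m]
    col
  }, numeric(nrow(Z)))
  colnames(X) <- polyTermNames(terms, colnames(Z))
  X
}

zscore <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) stop("zero-variance input dimension")
  scale(X, center = mu, scale = sd)
}

#' Transform an output measure for regression
#'
#' Applies the regression-scale transform: \code{log} for rates (values
#' must be positive), \code{log1m} (\eqn{\log(1 - x)}) for VS/EI (values
#' must be below 1), or none. Natural logarithms; the base does not affect
#' R-squared. Rows outside the transform domain are marked for exclusion.
#'
#' @param x numeric output values.
#' @param type "log", "log1m" or "none".
#' @return list with \code{y} (transformed, NA where excluded) and
#'   \code{nExcluded}.
#' @export
transformOutput <- function(x, type = c("none", "log", "log1m")) {
  type <- match.arg(type)
  y <- rep(NA_real_, length(x))
  ok <- switch(type, none = !is.na(x), log = !is.na(x) & x > 0,
               log1m = !is.na(x) & x < 1)
  y[ok] <- switch(type, none = x[ok], log = log(x[ok]),
                  log1m = log(1 - x[ok]))
  bad <- is.na(y) & !is.na(x)
  list(y = y, nExcluded = sum(bad))
}

# Symmetric sweep operator on a moment matrix; sweeping predictor pivots
# turns the bottom-right element into the residual sum of squares of the
# regression on the swept set.
sweepOp <- function(A, k, tol = 1e-12) {
  d <- A[k, k]
  if (!is.finite(d) || d < tol)
    stop("rank-deficient design (pivot ", k, " ~ 0); ",
         "remove collinear terms")
  B <- A - outer(A[, k], A[k, ]) / d
  B[k, ] <- A[k, ] / d
  B[, k] <- A[, k] / d
  B[k, k] <- -1 / d
  B
}

# Centered moment matrix [X'X, X'y; y'X, y'y] of complete rows.
momentMatrix <- function(X, y) {
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  M <- crossprod(cbind(Xc, yc))
  list(M = M, n = length(y), tss = sum(yc^2))
}

#' Polynomial input-output fit
#'
#' Ordinary least squares of one (optionally transformed) output measure on
#' polynomial terms of the z-scored model parameters. Degree 1 uses the six
#' parameters, degree 2 adds 21 quadratic terms and degree 3 another 56
#' cubic terms (83 in total). A rank-deficient design raises an error.
#'
#' @param params data.frame of the six parameters (mE, wE, aE, tR, tA, sA).
#' @param output numeric vector of the output measure (one per row).
#' @param degree 1, 2 or 3.
#' @param transform output transform passed to [transformOutput()].
#' @return a fit report: list with \code{degree}, \code{nTerms},
#'   \code{r2}, \code{nUsed}, \code{nExcluded} and the term names.
#' @export
polynomialFit <- function(params, output, degree = 1,
                          transform = c("none", "log", "log1m")) {
  stopifnot(degree %in% 1:3)
  Z <- zscore(as.data.frame(params)[, GRID_DIMS, drop = FALSE])
  X <- polyDesign(Z, degree)
  tr <- transformOutput(output, match.arg(transform))
  mm <- momentMatrix(X, tr$y)
  A <- mm$M
  for (k in seq_len(ncol(X))) A <- sweepOp(A, k)
  rss <- A[ncol(X) + 1L, ncol(X) + 1L]
  list(degree = degree, nTerms = ncol(X), r2 = 1 - rss / mm$tss,
       nUsed = mm$n, nExcluded = tr$nExcluded, terms = colnames(X))
}

#' Per-term variance contributions by ordered addition
#'
#' Starting from a constant, adds one regression term at a time and
#' records the gain in explained variance, averaged over orderings of the
#' terms. Degree 1 enumerates all 720 orderings of the six parameters, so
#' the mean gains are exactly the Shapley values of R-squared and sum to
#' the full linear R-squared. Degree 2 starts every ordering from the
#' complete linear fit (no quadratic term is added without its linear
#' components) and samples random orderings of the 21 quadratic terms;
#' the mean gains then sum to R2(quadratic) - R2(linear).
#'
#' @param params data.frame of the six parameters.
#' @param output numeric output vector.
#' @param degree 1 or 2.
#' @param nOrderings number of sampled orderings in degree-2 mode (40000
#'   for the full analysis).
#' @param seed sampling seed for degree-2 mode.
#' @param transform output transform, see [transformOutput()].
#' @return list with \code{gain} (named mean incremental R-squared per
#'   term), \code{nOrderings}, \code{r2Total} (of the full fit at this
#'   degree) and \code{r2Base} (0 for degree 1, linear R-squared for
#'   degree 2).
#' @export
varianceContribution <- function(params, output, degree = 1,
                                 nOrderings = 40000, seed = 1,
                                 transform = c("none", "log", "log1m")) {
  stopifnot(degree %in% 1:2)
  Z <- zscore(as.data.frame(params)[, GRID_DIMS, drop = FALSE])
  X <- polyDesign(Z, degree)
  tr <- transformOutput(output, match.arg(transform))
  mm <- momentMatrix(X, tr$y)
  p <- ncol(X)
  yPos <- p + 1L
  r2At <- function(A) 1 - A[yPos, yPos] / mm$tss

  if (degree == 1) {
    ords <- permutations(6L)
    gains <- matrix(0, nrow(ords), 6)
    for (o in seq_len(nrow(ords))) {
      A <- mm$M
      prev <- 0
      for (s in seq_len(6)) {
        k <- ords[o, s]
        A <- sweepOp(A, k)
        r2 <- r2At(A)
        gains[o, k] <- r2 - prev
        prev <- r2
      }
    }
    g <- colMeans(gains)
    names(g) <- colnames(X)
    return(list(gain = g, nOrderings = nrow(ords), r2Total = sum(g),
                r2Base = 0))
  }

  # degree 2: linear terms first (order immaterial for the totals), then
  # sampled orderings of the 21 quadratic terms
  Alin <- mm$M
  for (k in 1:6) Alin <- sweepOp(Alin, k)
  r2Lin <- r2At(Alin)
  qTerms <- 7:p
  set.seed(childSeed(seed, stream = 88L))
  gains <- matrix(0, nOrderings, length(qTerms))
  for (o in seq_len(nOrderings)) {
    ord <- sample(qTerms)
    A <- Alin
    prev <- r2Lin
    for (k in ord) {
      A <- sweepOp(A, k)
      r2 <- r2At(A)
      gains[o, k - 6L] <- r2 - prev
      prev <- r2
    }
  }
  g <- colMeans(gains)
  names(g) <- colnames(X)[qTerms]
  list(gain = g, nOrderings = nOrderings, r2Total = r2Lin + sum(g),
       r2Base = r2Lin)
}

# All permutations of 1..n as a matrix (n! rows).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[r, ]])
    }
  }
  out
}
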