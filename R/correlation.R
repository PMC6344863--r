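#' Spearman's rank correlation of two profiles
#'
#' Pearson correlation of average-tie (fractional) ranks. Constant input is
#' an undefined correlation, signalled as a classed error
#' (\code{coexatlas_constant_profile}) rather than returned as 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @examples
#' spearmanRho(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(structure(class = c("coexatlas_constant_profile", "error",
                             "condition"),
                   list(message = "correlation undefined for a constant profile",
                        call = sys.call(-1))))
  stats::cor(rank(x), rank(y))
}

# average-tie ranks of each matrix row
.rankRows <- function(mat) {
  rk <- mat
  for (i in seq_len(nrow(mat))) rk[i, ] <- rank(mat[i, ])
  rk
}

# rows scaled to zero mean / unit sum of squares; constant rows -> NA flag
.standardizeRankRows <- function(rk) {
  ctr <- rk - rowMeans(rk)
  ss <- sqrt(rowSums(ctr^2))
  valid <- ss > 0
  ctr[valid, ] <- ctr[valid, , drop = FALSE] / ss[valid]
  list(z = ctr, valid = valid)
}

#' All-pairs Spearman correlation with sparse thresholded storage
#'
#' Evaluates every unordered pair of non-constant gene profiles exactly once
#' using blocked cross-products of standardized ranks, keeping working
#' memory bounded by the block size; only pairs with \code{|rho| >=
#' reportThreshold} are stored. The result is deterministic and independent
#' of the block size. Constant-profile genes are excluded from pairing (an
#' undefined correlation) and reported via \code{\link{validGenes}}.
#'
#' @param mat numeric matrix, genes as rows (typically the condition-level
#'   log2 matrix from \code{\link{conditionLog2}}).
#' @param reportThreshold storage threshold in (0, 1].
#' @param blockSize number of genes per block.
#' @return A \linkS4class{CorrelationResult}.
#' @export
allPairsCorrelation <- function(mat, reportThreshold = 0.5, blockSize = 512L) {
  if (ncol(mat) < 3)
    stop("all-pairs correlation requires at least 3 conditions")
  if (reportThreshold <= 0 || reportThreshold > 1)
    stop("reportThreshold must lie in (0, 1]")
  if (is.null(rownames(mat)))
    rownames(mat) <- .syntheticGeneIds(nrow(mat))
  std <- .standardizeRankRows(.rankRows(mat))
  ids <- rownames(mat)
  valid <- which(std$valid)
  if (!length(valid))
    warning("all gene profiles are constant; empty correlation result")
  z <- std$z[valid, , drop = FALSE]
  v <- length(valid)
  starts <- seq(1L, max(v, 1L), by = blockSize)
  ea <- eb <- rho <- list()
  k <- 0L
  for (si in seq_along(starts)) {
    bi <- starts[si]:min(starts[si] + blockSize - 1L, v)
    for (sj in si:length(starts)) {
      bj <- starts[sj]:min(starts[sj] + blockSize - 1L, v)
      R <- tcrossprod(z[bi, , drop = FALSE], z[bj, , drop = FALSE])
      if (si == sj) R[lower.tri(R, diag = TRUE)] <- 0
      hit <- which(abs(R) >= reportThreshold, arr.ind = TRUE)
      if (nrow(hit)) {
        k <- k + 1L
        ea[[k]] <- ids[valid[bi[hit[, 1L]]]]
        eb[[k]] <- ids[valid[bj[hit[, 2L]]]]
        rho[[k]] <- pmin(1, pmax(-1, R[hit]))
      }
    }
  }
  if (k) {
    a <- unlist(ea); b <- unlist(eb); r <- unlist(rho)
    swap <- a > b
    edges <- data.frame(gene_a = ifelse(swap, b, a),
                        gene_b = ifelse(swap, a, b),
                        rho = r, stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  }
  new("CorrelationResult", edges = edges, reportThreshold = reportThreshold,
      validGenes = ids[valid], allGenes = ids,
      nPairsTotal = v * (v - 1) / 2, nConditions = ncol(mat))
}

.substreamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %% 2147483629)
}

#' Permute each gene profile independently across columns
#'
#' Destroys all between-gene correlation while preserving each gene's value
#' multiset exactly. Each row uses its own random substream keyed by the
#' master seed and the row index, so the output does not depend on
#' iteration order.
#'
#' @param mat numeric matrix, genes as rows.
#' @param seed master seed.
#' @return matrix of the same shape and dimnames.
#' @export
permuteMatrix <- function(mat, seed = 1L) {
  out <- mat
  nc <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    set.seed(.substreamSeed(seed, i))
    out[i, ] <- mat[i, sample.int(nc)]
  }
  out
}

#' Calibrate the co-expression threshold against a permutation null
#'
#' Computes all-pairs |rho| on a row-permuted copy of the matrix (a
#' pseudo-random compendium with identically distributed but independent
#' profiles), counts exceedances of each candidate threshold, and selects
#' the smallest candidate with zero null exceedances. If no candidate
#' qualifies the calibration is returned with an explicit
#' \code{"uncalibrated"} status; no silent default is ever applied.
#'
#' @param mat numeric matrix, genes as rows.
#' @param candidates strictly increasing candidate thresholds.
#' @param seed master permutation seed.
#' @param blockSize genes per block.
#' @return A \linkS4class{NullCalibration}.
#' @export
calibrateThreshold <- function(mat, candidates = c(0.3, 0.4, 0.5, 0.6, 0.7),
                               seed = 1L, blockSize = 512L) {
  if (is.unsorted(candidates, strictly = TRUE))
    stop("candidates must be sorted strictly ascending")
  perm <- permuteMatrix(mat, seed)
  # the internal kernel runs even in the degenerate 2-column geometry,
  # where every defined null rho is +/-1 and no candidate can qualify
  std <- .standardizeRankRows(.rankRows(perm))
  z <- std$z[std$valid, , drop = FALSE]
  v <- nrow(z)
  exceed <- numeric(length(candidates))
  maxAbs <- 0
  starts <- seq(1L, max(v, 1L), by = blockSize)
  for (si in seq_along(starts)) {
    bi <- starts[si]:min(starts[si] + blockSize - 1L, v)
    for (sj in si:length(starts)) {
      bj <- starts[sj]:min(starts[sj] + blockSize - 1L, v)
      R <- abs(tcrossprod(z[bi, , drop = FALSE], z[bj, , drop = FALSE]))
      if (si == sj) R[lower.tri(R, diag = TRUE)] <- 0
      maxAbs <- max(maxAbs, max(R, 0))
      for (ci in seq_along(candidates))
        exceed[ci] <- exceed[ci] + sum(R >= candidates[ci])
    }
  }
  zero <- candidates[exceed == 0]
  status <- if (length(zero)) "calibrated" else "uncalibrated"
  if (status == "uncalibrated")
    warning("no candidate threshold has zero null exceedances; ",
            "calibration left unresolved for the caller to decide")
  new("NullCalibration", candidates = candidates, exceedance = exceed,
      maxAbsRhoNull = maxAbs,
      chosenThreshold = if (length(zero)) min(zero) else NA_real_,
      status = status, nNullPairs = v * (v - 1) / 2,
      seed = as.integer(seed))
}
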