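# Independent brute-force oracles used to cross-check the implementation.

# Union-find connected-component labelling of a 3D logical array.
# offsets: n x 3 integer matrix of neighbour displacements.
unionFindLabel <- function(mask, offsets) {
  d <- dim(mask)
  n <- length(mask)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(mask)
  co <- arrayInd(idx, d)
  for (t in seq_along(idx)) {
    r <- co[t, 1]; c <- co[t, 2]; s <- co[t, 3]
    for (o in seq_len(nrow(offsets))) {
      r2 <- r + offsets[o, 1]; c2 <- c + offsets[o, 2]; s2 <- s + offsets[o, 3]
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2] || s2 < 1 || s2 > d[3])
        next
      j <- as.integer(r2 + d[1] * ((c2 - 1) + d[2] * (s2 - 1)))
      if (mask[j]) {
        ri <- find(idx[t]); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(idx, find, integer(1))
  lab <- array(0L, dim = d)
  lab[idx] <- as.integer(factor(roots))
  lab
}

# Two label arrays describe the same partition of the foreground?
samePartition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  fg <- which(a > 0L)
  if (!length(fg)) return(TRUE)
  byA <- split(b[fg], a[fg])
  byB <- split(a[fg], b[fg])
  all(vapply(byA, function(v) length(unique(v)) == 1L, logical(1))) &&
    all(vapply(byB, function(v) length(unique(v)) == 1L, logical(1)))
}

# Percentile by explicit sort + linear interpolation at rank p*(n-1)+1.
percentileOracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- p * (n - 1) + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Spearman's rho by explicit mid-ranks then the Pearson formula.
spearmanOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Trapezoid AUC by direct summation over explicitly ordered points.
aucOracle <- function(sens, spec) {
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  total <- 0
  for (i in seq_len(length(fpr) - 1)) {
    total <- total + (fpr[i + 1] - fpr[i]) * (tpr[i] + tpr[i + 1]) / 2
  }
  total
}

# Offsets for the oracle labeller, mirroring the adjacency definitions.
oracleOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    "4" = rowSums(abs(g)) == 1 & g[, 3] == 0,
    "8" = g[, 3] == 0)
  g[keep, , drop = FALSE]
}

# Small random test mask.
randomMask <- function(dim, density, seed) {
  set.seed(seed)
  new("RegionMask",
      voxels = array(stats::runif(prod(dim)) < density, dim = dim),
      id = "rand")
}

# A compact phantom configuration for fast property tests (not the
# default study-scale geometry).
smallPhantomConfig <- function(...) {
  phantomConfig(dim = c(32L, 32L, 10L), boneBox = c(9L, 24L, 9L, 24L, 2L, 9L),
                roiCenter = c(16, 16), roiRadius = 6.5, roiSlices = 2:3, ...)
}
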