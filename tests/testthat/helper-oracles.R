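# Independent oracles used across the suite. These deliberately avoid the
# package's compiled kernels: plain-R breadth-first flood fill, all-pairs
# distance matrices, and exhaustive assignment enumeration.

# flood-fill connected-component count (26- or 6-connectivity), plain R
oracleComponentCount <- function(mask, connectivity = 26) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  count <- 0
  fg <- which(mask != 0)
  for (start in fg) {
    if (visited[start]) next
    count <- count + 1
    queue <- list(arrayInd(start, d)[1, ])
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        n <- v + offs[r, ]
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] != 0 && !visited[n[1], n[2], n[3]]) {
          visited[n[1], n[2], n[3]] <- TRUE
          queue[[length(queue) + 1]] <- n
        }
      }
    }
  }
  count
}

# brute-force ASSD: all-pairs distance matrix between surface voxel centres
oracleASSD <- function(a, b, spacing) {
  surface <- function(m) {
    d <- dim(m)
    idx <- which(m != 0)
    keep <- vapply(idx, function(i) {
      v <- arrayInd(i, d)[1, ]
      for (ax in 1:3) for (s in c(-1, 1)) {
        n <- v
        n[ax] <- n[ax] + s
        if (any(n < 1) || any(n > d)) return(TRUE)
        if (m[n[1], n[2], n[3]] == 0) return(TRUE)
      }
      FALSE
    }, logical(1))
    (arrayInd(idx[keep], d) - 1) %*% diag(spacing)
  }
  sa <- surface(a)
  sb <- surface(b)
  dmat <- sqrt(outer(sa[, 1], sb[, 1], "-")^2 +
                 outer(sa[, 2], sb[, 2], "-")^2 +
                 outer(sa[, 3], sb[, 3], "-")^2)
  (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) / (nrow(sa) + nrow(sb))
}

# pooled-variance two-sample t statistic and two-tailed p, by the textbook
# formula
oracleStudentT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), n1 + n2 - 2)
  c(t = t, p = p)
}

# random small binary mask with a few blobs, for metric cross-checks
randomBlobMask <- function(d = c(12, 12, 12), nBlobs = 2, rmax = 3) {
  m <- array(0, d)
  for (i in seq_len(nBlobs)) {
    c0 <- runif(3, 3, d - 2)
    r <- runif(1, 1, rmax)
    idx <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
    inside <- colSums((t(idx) - c0)^2) <= r^2
    m[idx[inside, , drop = FALSE]] <- 1
  }
  m
}

# small deterministic phantom shared across tests (memoised per session)
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateStudy(phantomConfig(
        grid_shape = c(48, 48, 48), n_existing = 2, n_new = 1,
        n_disappeared = 1, diameter_range_mm = c(6, 12), seed = 7))
    cache
  }
})
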