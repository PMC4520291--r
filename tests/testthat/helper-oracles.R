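# Independent brute-force oracles. Deliberately naive (explicit loops,
# no shared code with the package internals) so they can certify the
# vectorized implementations.

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# equal-width binning over each vector's own range, top value in last bin
naive_bin <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(1L, length(v)))
  idx <- floor((v - lo) / ((hi - lo) / bins)) + 1L
  idx[idx > bins] <- bins
  idx
}

naive_mi <- function(x, y, bins) {
  bx <- naive_bin(x, bins)
  by <- naive_bin(y, bins)
  n <- length(x)
  joint <- matrix(0, bins, bins)
  for (i in seq_len(n)) joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1 / n
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    if (joint[a, b] > 0)
      mi <- mi + joint[a, b] * log2(joint[a, b] / (px[a] * py[b]))
  }
  mi
}

naive_chamfer <- function(X, Y) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    best <- Inf
    for (j in seq_len(nrow(Y))) {
      d <- sqrt(sum((X[i, ] - Y[j, ])^2))
      if (d < best) best <- d
    }
    tot <- tot + best
  }
  tot / nrow(X)
}

clampi <- function(i, n) min(max(i, 1L), n)

naive_laplacian <- function(g) {
  d <- dim(g)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    out[i, j, k] <- g[clampi(i - 1L, d[1]), j, k] + g[clampi(i + 1L, d[1]), j, k] +
      g[i, clampi(j - 1L, d[2]), k] + g[i, clampi(j + 1L, d[2]), k] +
      g[i, j, clampi(k - 1L, d[3])] + g[i, j, clampi(k + 1L, d[3])] -
      6 * g[i, j, k]
  }
  out
}

# full 3x3x3 separable Sobel kernels applied by direct triple loop with
# edge-replicating padding; returns the three responses
naive_sobel <- function(g) {
  d <- dim(g)
  deriv <- c(-1, 0, 1)   # response at offset -1, 0, +1
  smooth <- c(1, 2, 1)
  kern <- function(axis) {
    k <- array(0, c(3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (c_ in 1:3) {
      w <- c(a, b, c_)
      k[a, b, c_] <- prod(ifelse(seq_len(3) == axis, deriv[w], smooth[w]))
    }
    k
  }
  resp <- lapply(1:3, function(axis) {
    k <- kern(axis)
    out <- array(0, d)
    for (kk in 1:d[3]) for (jj in 1:d[2]) for (ii in 1:d[1]) {
      acc <- 0
      for (a in -1:1) for (b in -1:1) for (c_ in -1:1) {
        acc <- acc + k[a + 2, b + 2, c_ + 2] *
          g[clampi(ii + a, d[1]), clampi(jj + b, d[2]), clampi(kk + c_, d[3])]
      }
      out[ii, jj, kk] <- acc
    }
    out
  })
  list(gx = resp[[1]], gy = resp[[2]], gz = resp[[3]])
}

# 6-neighbour surface scan; rows ordered x fastest (column-major order)
naive_surface <- function(g, thr) {
  d <- dim(g)
  pts <- NULL
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (g[i, j, k] < thr) next
    nb_below <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          g[ii, jj, kk] < thr) {
        nb_below <- TRUE
        break
      }
    }
    if (nb_below) pts <- rbind(pts, c(i, j, k))
  }
  pts
}

# x-fastest reordering so point sets compare row-wise
order_points <- function(p) p[order(p[, 3], p[, 2], p[, 1]), , drop = FALSE]

# naive complete-linkage agglomeration: repeatedly merge the pair of
# clusters with the smallest maximum inter-point distance, lowest-index
# pair first, while that distance is <= cutoff
naive_complete_linkage <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    if (!is.finite(best) || best > cutoff) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  labels <- integer(n)
  for (c_ in seq_along(clusters)) labels[clusters[[c_]]] <- c_
  labels
}

same_partition <- function(a, b) {
  identical(unname(as.integer(factor(a, levels = unique(a)))),
            unname(as.integer(factor(b, levels = unique(b)))))
}

# Borda totals by explicit enumeration from a matrix of ranks
# (fits x scores, 1 = best)
naive_borda <- function(rank_mat) {
  n <- nrow(rank_mat)
  total <- numeric(n)
  for (j in seq_len(n)) for (s in seq_len(ncol(rank_mat)))
    total[j] <- total[j] + (n - rank_mat[j, s])
  total
}

# per-voxel double loop Gaussian blur without truncation
naive_blur <- function(xyz, masses, sigma, map) {
  d <- dim(map$grid)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    pos <- map$origin + map$apix * c(i - 1, j - 1, k - 1)
    acc <- 0
    for (a in seq_len(nrow(xyz))) {
      r2 <- sum((pos - xyz[a, ])^2)
      acc <- acc + masses[a] * exp(-r2 / (2 * sigma^2))
    }
    out[i, j, k] <- acc
  }
  out
}

# naive normal-vector score: naive surface + central-difference normals
# computed per point with clamped indices + O(n^2) nearest neighbour
naive_nv <- function(gp, gt, thr_p, thr_t) {
  normals_at <- function(g, pts) {
    d <- dim(g)
    out <- NULL; keep <- NULL
    for (r in seq_len(nrow(pts))) {
      i <- pts[r, 1]; j <- pts[r, 2]; k <- pts[r, 3]
      gr <- c((g[clampi(i + 1, d[1]), j, k] - g[clampi(i - 1, d[1]), j, k]) / 2,
              (g[i, clampi(j + 1, d[2]), k] - g[i, clampi(j - 1, d[2]), k]) / 2,
              (g[i, j, clampi(k + 1, d[3])] - g[i, j, clampi(k - 1, d[3])]) / 2)
      nr <- sqrt(sum(gr^2))
      if (nr > 1e-12) {
        out <- rbind(out, -gr / nr)
        keep <- c(keep, r)
      }
    }
    list(normals = out, keep = keep)
  }
  pt <- naive_surface(gt, thr_t)
  pp <- naive_surface(gp, thr_p)
  nt <- normals_at(gt, pt)
  np <- normals_at(gp, pp)
  pt <- pt[nt$keep, , drop = FALSE]
  pp <- pp[np$keep, , drop = FALSE]
  tot <- 0
  for (r in seq_len(nrow(pt))) {
    best <- Inf; bidx <- 0
    for (s in seq_len(nrow(pp))) {
      d2 <- sum((pt[r, ] - pp[s, ])^2)
      if (d2 < best) { best <- d2; bidx <- s }
    }
    dotp <- sum(nt$normals[r, ] * np$normals[bidx, ])
    tot <- tot + acos(min(max(dotp, -1), 1))
  }
  tot / nrow(pt)
}
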