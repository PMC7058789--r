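# Brute-force texture oracles, independent of the package's C++ kernels.
# All operate on an integer 3D array `lev` with 0 = outside the ROI.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm <- function(lev, ng, distance = 1, dirs = 1:13) {
  d <- dim(lev)
  m <- matrix(0, ng, ng)
  for (dd in dirs) {
    off <- DIRS13[dd, ] * distance
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- lev[x, y, z]
      if (i == 0) next
      p2 <- c(x, y, z) + off
      if (!in_bounds(p2, d)) next
      j <- lev[p2[1], p2[2], p2[3]]
      if (j == 0) next
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
  }
  m
}

# Runs via rle() on each grid line (non-ROI voxels break runs).
oracle_glrlm <- function(lev, ng, dirs = 1:13) {
  d <- dim(lev)
  m <- matrix(0, ng, sum(d))
  for (dd in dirs) {
    off <- DIRS13[dd, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      if (in_bounds(c(x, y, z) - off, d)) next  # not a line start
      p <- c(x, y, z)
      seqv <- integer(0)
      while (in_bounds(p, d)) {
        seqv <- c(seqv, lev[p[1], p[2], p[3]])
        p <- p + off
      }
      r <- rle(seqv)
      for (k in seq_along(r$values))
        if (r$values[k] > 0)
          m[r$values[k], r$lengths[k]] <- m[r$values[k], r$lengths[k]] + 1
    }
  }
  keep <- max(which(colSums(m) > 0), 1)
  m[, 1:keep, drop = FALSE]
}

# Zones via breadth-first flood fill over 26-neighbourhoods.
oracle_glszm <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- NULL
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  coords <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    p0 <- coords[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    val <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (!in_bounds(q, d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == val) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones <- rbind(zones, c(val, size))
  }
  zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng); n <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lev[x, y, z]
    if (i == 0) next
    vals <- numeric(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(p, d)) next
      j <- lev[p[1], p[2], p[3]]
      if (j > 0) vals <- c(vals, j)
    }
    if (length(vals)) s[i] <- s[i] + abs(i - mean(vals))
    n[i] <- n[i] + 1
  }
  cbind(s = s, n = n)
}

# Build a quantized_roi directly from an integer level array.
make_qroi <- function(lev, ng = max(lev)) {
  lev <- array(as.integer(lev), dim(lev))
  structure(list(levels = lev, n_levels = as.integer(ng), dims = dim(lev),
                 bin_range = c(0, 1)), class = "quantized_roi")
}

# Random ROI: levels 1..ng on a random subset of a random small box.
random_qroi <- function(ng = 6, max_dim = c(8, 8, 6), p_roi = 0.7) {
  d <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
         sample(2:max_dim[3], 1))
  lev <- array(sample(0:ng, prod(d), replace = TRUE,
                      prob = c(1 - p_roi, rep(p_roi / ng, ng))), d)
  if (sum(lev > 0) < 2) lev[1:2] <- c(1L, ng)
  make_qroi(lev, ng)
}

samp_skew <- function(x) {
  m2 <- mean((x - mean(x))^2)
  mean((x - mean(x))^3) / m2^1.5
}

# 2D binary disc dilation/erosion by direct offset scan (morphology oracle).
oracle_dilate <- function(sl, r) {
  d <- dim(sl)
  out <- matrix(FALSE, d[1], d[2])
  offs <- which(disk_kernel(r) > 0, arr.ind = TRUE) - (r + 1)
  fg <- which(sl, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    pts <- sweep(offs, 2, fg[k, ], "+")
    keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2]
    out[pts[keep, , drop = FALSE]] <- TRUE
  }
  out
}

oracle_erode <- function(sl, r) {
  d <- dim(sl)
  out <- matrix(FALSE, d[1], d[2])
  offs <- which(disk_kernel(r) > 0, arr.ind = TRUE) - (r + 1)
  fg <- which(sl, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    pts <- sweep(offs, 2, fg[k, ], "+")
    inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
      pts[, 2] >= 1 & pts[, 2] <= d[2]
    if (all(inside) && all(sl[pts])) out[fg[k, 1], fg[k, 2]] <- TRUE
  }
  out
}

# Small well-separated specs for fast plant-and-recover runs.
test_specs <- function() default_class_specs()

small_tumor <- function(seed = 1, label = "SCA") {
  generate_tumor(test_specs()[[label]], shape_mm = c(30, 30, 40),
                 spacing = c(1, 1, 5), seed = seed)
}
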