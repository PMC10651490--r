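# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms/structure than the package
# code paths they verify.

# Exhaustive stack-based flood fill for connected-component labelling.
floodFillLabels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextLab <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] && lab[i, j, k] == 0L) {
      nextLab <- nextLab + 1L
      stack <- list(c(i, j, k))
      lab[i, j, k] <- nextLab
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (r in seq_len(nrow(offs))) {
          q <- p + offs[r, ]
          if (all(q >= 1L) && all(q <= d) && mask[q[1], q[2], q[3]] &&
              lab[q[1], q[2], q[3]] == 0L) {
            lab[q[1], q[2], q[3]] <- nextLab
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# Canonical form of a labelling: relabel by first occurrence so two
# labelings can be compared as partitions.
canonicalLabels <- function(lab) {
  ids <- lab[lab > 0L]
  remap <- integer(max(c(0L, ids)))
  seen <- unique(ids)
  remap[seen] <- seq_along(seen)
  lab[lab > 0L] <- remap[ids]
  lab
}

# Brute-force reimplementation of the two-pass RRI cleaning rules,
# structured as explicit index bookkeeping rather than a growing vector.
bruteCleanRRI <- function(rri, lo = 0.5, hi = 1.5, relLo = 0.6, relHi = 1.4) {
  status <- rep("kept", length(rri))
  status[rri < lo | rri > hi] <- "absolute"
  for (i in seq_along(rri)) {
    if (status[i] != "kept") next
    prior <- which(status[seq_len(i - 1)] == "kept")
    if (length(prior) < 10) next
    m <- mean(rri[prior[(length(prior) - 9):length(prior)]])
    if (rri[i] < relLo * m || rri[i] > relHi * m) status[i] <- "relative"
  }
  status
}

# Same rules applied in the wrong order (relative pass first) to show the
# stated order matters.
bruteCleanRRIWrongOrder <- function(rri, lo = 0.5, hi = 1.5,
                                    relLo = 0.6, relHi = 1.4) {
  status <- rep("kept", length(rri))
  for (i in seq_along(rri)) {
    prior <- which(status[seq_len(i - 1)] == "kept")
    if (length(prior) < 10) next
    m <- mean(rri[prior[(length(prior) - 9):length(prior)]])
    if (rri[i] < relLo * m || rri[i] > relHi * m) status[i] <- "relative"
  }
  status[status == "kept" & (rri < lo | rri > hi)] <- "absolute"
  status
}

# Numeric FWHM of a log-normal density via uniroot on each side of the mode.
numericLognormFWHM <- function(mu, sigma) {
  mode <- exp(mu - sigma^2)
  half <- stats::dlnorm(mode, mu, sigma) / 2
  f <- function(a) stats::dlnorm(a, mu, sigma) - half
  lowRoot <- stats::uniroot(f, c(mode * 1e-6, mode), tol = 1e-12)$root
  hiRoot <- stats::uniroot(f, c(mode, mode * 1e6), tol = 1e-12)$root
  c(lowRoot, hiRoot)
}

# Brute-force voxelisation of an axis-aligned circular tube along z:
# counts voxel centres inside the circle, slice by slice.
bruteTubeSliceCounts <- function(shape, spacing, centre, radius) {
  counts <- integer(shape[3])
  for (k in seq_len(shape[3])) {
    n <- 0L
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
      x <- (i - 0.5) * spacing[1] - centre[1]
      y <- (j - 0.5) * spacing[2] - centre[2]
      if (x * x + y * y <= radius^2) n <- n + 1L
    }
    counts[k] <- n
  }
  counts
}

# Mask with near-exact slice centroids: for each slice along y, a 20-voxel
# column plus the best single nudge voxel reproduces a target physical
# z-centroid to ~1/40 voxel, so curve-recovery tests have tight ground truth
# (unit spacing assumed; physical coordinate = index - 0.5).
maskWithCentroids <- function(d, zTargets, xTargets) {
  m <- array(FALSE, d)
  for (j in seq_along(zTargets)) {
    mz <- zTargets[j] + 0.5        # target mean voxel index
    L <- 20L
    a <- round(mz - (L - 1) / 2)
    run <- a:(a + L - 1L)
    xi <- round(xTargets[j] + 0.5)
    m[xi, j, run] <- TRUE
    cand <- setdiff(seq_len(d[3]), run)
    means <- (sum(run) + cand) / (L + 1)
    best <- cand[which.min(abs(means - mz))]
    if (abs(means[which.min(abs(means - mz))] - mz) < abs(mean(run) - mz))
      m[xi, j, best] <- TRUE
  }
  m
}
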