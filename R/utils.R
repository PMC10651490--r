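# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched, so generators have no global side effects.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Physical coordinates of voxel centres along one axis (1-based indices).
voxelCenters <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# Coordinates (n x 3) of voxel-centre positions for index matrix `idx`.
indexToPhysical <- function(idx, spacing) {
  sweep(idx - 0.5, 2, spacing, `*`)
}

# Bring `axis` first, apply f to the array, restore order.
withAxisFirst <- function(arr, axis, f) {
  perm <- c(axis, setdiff(1:3, axis))
  out <- f(aperm(arr, perm))
  aperm(out, order(perm))
}

#' Label connected components of a 3D binary mask
#'
#' Vectorised connected-component labelling: neighbour edges are built by
#' shifting the foreground index set along each connectivity offset and the
#' components are found with \code{igraph}. Labels are assigned in first-voxel
#' (column-major) order starting at 1; background is 0.
#'
#' @param mask 3D logical (or 0/1 numeric) array.
#' @param connectivity 26 (vertex/edge/face neighbours, default) or 6
#'   (face neighbours only).
#' @return 3D integer array of component labels.
#' @examples
#' m <- array(FALSE, c(3, 3, 1)); m[1, 1, 1] <- m[3, 3, 1] <- TRUE
#' table(labelComponents(m, 26))
#' @export
labelComponents <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  fg <- which(mask != 0)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  if (connectivity == 6) {
    offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[offs[, 1] != 0 | offs[, 2] != 0 | offs[, 3] != 0, , drop = FALSE]
    # keep one of each +/- pair
    keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0)))
    offs <- offs[keep, , drop = FALSE]
  }
  pos <- integer(prod(d))
  pos[fg] <- seq_along(fg)
  ai <- arrayInd(fg, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ni <- ai[, 1] + offs[r, 1]
    nj <- ai[, 2] + offs[r, 2]
    nk <- ai[, 3] + offs[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    lin <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
    tgt <- pos[lin]
    src <- seq_along(fg)[ok]
    hit <- tgt > 0L
    edges[[r]] <- cbind(src[hit], tgt[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel components in order of first occurrence so labelling is stable
  first <- !duplicated(comp)
  remap <- integer(max(comp))
  remap[comp[first]] <- seq_len(sum(first))
  lab[fg] <- remap[comp]
  lab
}

# Build a ClusterSet from a label array + the intensity volume it came from.
clusterSetFromLabels <- function(lab, vol, spacing) {
  ids <- sort(unique(lab[lab > 0L]))
  cl <- lapply(ids, function(id) {
    lin <- which(lab == id)
    list(id = as.integer(id), voxels = arrayInd(lin, dim(lab)),
         intensities = as.numeric(vol[lin]), size = length(lin))
  })
  new("ClusterSet", labels = lab, clusters = cl, spacing = as.numeric(spacing))
}
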