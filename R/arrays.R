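# Internal 3D array primitives: zero-padded shifts, structuring elements,
# binary morphology, and connected-component labeling. These back the
# component-geometry operations; voxel connectivity is 26 by default.

# out[x] = a[x - d], zero/FALSE outside the grid
shift3d <- function(a, d) {
  dm <- dim(a)
  out <- array(vector(typeof(a), 1L), dm)
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      if (d[ax] >= dm[ax]) return(out)
      dst[[ax]] <- seq.int(1L + d[ax], dm[ax])
      src[[ax]] <- seq.int(1L, dm[ax] - d[ax])
    } else {
      if (-d[ax] >= dm[ax]) return(out)
      dst[[ax]] <- seq.int(1L, dm[ax] + d[ax])
      src[[ax]] <- seq.int(1L - d[ax], dm[ax])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# integer offsets within Euclidean distance `radius` (3D ball, centre included)
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# 2D disk applied per axial (third-axis) slice
disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = 0L))
  g[rowSums(g[, 1:2, drop = FALSE]^2) <= radius^2, , drop = FALSE]
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26", call. = FALSE)
  g
}

# Dilation/erosion work on the sparse voxel set: component masks are small
# relative to the grid, so touching only the set and its neighbourhood is
# much cheaper than shifting full arrays.
binary_dilate <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  idx <- which(mask)
  if (!length(idx)) return(out)
  coords <- arrayInd(idx, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2L, offsets[i, ], "+")
    nb <- nb[in_grid(dim(mask), nb), , drop = FALSE]
    out[nb] <- TRUE
  }
  out
}

binary_erode <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  idx <- which(mask)
  if (!length(idx)) return(out)
  coords <- arrayInd(idx, dim(mask))
  keep <- rep(TRUE, nrow(coords))
  for (i in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2L, offsets[i, ], "+")
    ok <- in_grid(dim(mask), nb)
    inside <- logical(nrow(coords))
    inside[ok] <- mask[nb[ok, , drop = FALSE]]
    keep <- keep & inside
  }
  out[coords[keep, , drop = FALSE]] <- TRUE
  out
}

binary_open <- function(mask, offsets) binary_dilate(binary_erode(mask, offsets), offsets)

# closing runs on a padded copy: clipping the dilation at the array edge
# would lose mass and break the (infinite-background) closing semantics,
# including the idempotence of the open-close filter
binary_close <- function(mask, offsets) {
  r <- max(abs(offsets))
  dm <- dim(mask)
  ix <- lapply(dm, function(d) r + seq_len(d))
  big <- array(FALSE, dm + 2L * r)
  big[ix[[1L]], ix[[2L]], ix[[3L]]] <- mask
  out <- binary_erode(binary_dilate(big, offsets), offsets)
  out[ix[[1L]], ix[[2L]], ix[[3L]]]
}

# Label connected regions of a binary 3D mask. Returns an integer array with
# 0 for background and 1..k region labels (label order is arbitrary but
# deterministic). Adjacency edges are built by array shifts; components come
# from igraph.
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L)
  lab <- array(0L, dim(mask))
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  pos <- array(0L, dim(mask))
  pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dim(mask))
  offs <- neighbor_offsets(connectivity)
  # half the offsets suffice: each undirected edge is seen once
  offs <- offs[offs[, 1L] > 0L |
                 (offs[, 1L] == 0L & offs[, 2L] > 0L) |
                 (offs[, 1L] == 0L & offs[, 2L] == 0L & offs[, 3L] > 0L), ,
               drop = FALSE]
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[i, ], "+")
    ok <- in_grid(dim(mask), nb)
    hit <- logical(n)
    tovox <- integer(n)
    if (any(ok)) {
      tovox[ok] <- pos[nb[ok, , drop = FALSE]]
      hit <- tovox > 0L
    }
    if (any(hit)) {
      from <- c(from, seq_len(n)[hit])
      to <- c(to, tovox[hit])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

region_sizes <- function(lab) {
  v <- lab[lab > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v)
}

# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
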