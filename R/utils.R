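# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Shift an array along one margin by `s` voxels, replicating edge values.
shift_array <- function(a, s, along) {
  if (s == 0L) return(a)
  d <- dim(a)
  n <- d[along]
  idx <- seq_len(n) - s
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  args <- rep(list(quote(expr = )), length(d))
  args[[along]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# Separable Gaussian smoothing of a 2D or 3D array; sigma per dimension, in
# voxels. sigma of 0 skips the corresponding axis.
gaussian_smooth <- function(a, sigma) {
  d <- dim(a)
  stopifnot(length(sigma) == length(d))
  for (ax in seq_along(d)) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    out <- array(0, d)
    for (j in seq_along(w)) out <- out + w[j] * shift_array(a, j - r - 1L, ax)
    a <- out
  }
  a
}

# Global Otsu threshold on the full intensity distribution of an array.
# Returns a threshold on the original intensity scale; Inf for flat input.
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  mn <- min(x)
  mx <- max(x)
  if (!is.finite(mn) || !is.finite(mx) || mx <= mn) return(Inf)
  xn <- (x - mn) / (mx - mn)
  img <- EBImage::Image(matrix(xn, nrow = length(xn), ncol = 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  mn + as.numeric(th[1L]) * (mx - mn)
}

# 26-connected (3D) / 8-connected (2D) component labelling of a logical
# array via graph components over voxel adjacency.
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, d))
  pos <- arrayInd(idx, d)
  # forward half of the neighbourhood offsets
  offs <- as.matrix(expand.grid(rep(list(-1L:1L), nd)))
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0L)
    length(nz) > 0L && o[nz[1L]] > 0L
  })
  offs <- offs[keep, , drop = FALSE]
  strides <- cumprod(c(1L, d[-nd]))
  edges_from <- integer(0)
  edges_to <- integer(0)
  id_of <- integer(prod(d))
  id_of[idx] <- seq_along(idx)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- rep(TRUE, length(idx))
    for (ax in seq_len(nd)) {
      np <- pos[, ax] + o[ax]
      ok <- ok & np >= 1L & np <= d[ax]
    }
    if (!any(ok)) next
    nidx <- idx[ok] + as.integer(sum(o * strides))
    hit <- id_of[nidx] > 0L
    if (!any(hit)) next
    edges_from <- c(edges_from, id_of[idx[ok]][hit])
    edges_to <- c(edges_to, id_of[nidx][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges_from) > 0L) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  memb <- igraph::components(g)$membership
  # relabel so labels are contiguous and ordered by first voxel occurrence
  first <- tapply(seq_along(idx), memb, min)
  relab <- integer(max(memb))
  relab[as.integer(names(sort(first)))] <- seq_along(first)
  lab <- array(0L, d)
  lab[idx] <- relab[memb]
  lab
}

# Voxel-centre coordinates (µm) along each axis of an array with the given
# voxel size; axis order matches the array's dim order.
axis_coords <- function(d, voxel_size) {
  lapply(seq_along(d), function(ax) (seq_len(d[ax]) - 0.5) * voxel_size[ax])
}

# All voxel-centre coordinates (µm) for linear indices `idx` of an array of
# dim `d`; returns a length(idx) x length(d) matrix.
voxel_centres_um <- function(idx, d, voxel_size) {
  pos <- arrayInd(idx, d)
  sweep(pos - 0.5, 2L, voxel_size[seq_along(d)], `*`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
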