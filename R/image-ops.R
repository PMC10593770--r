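# Low-level raster operations on plain R matrices/arrays.
#
# No raster-image package ships with this environment, so the handful of
# primitives the morphometry and densitometry layers need are implemented
# here directly: Otsu thresholding, connected-component labelling, binary
# morphology with a disk structuring element, Zhang-Suen skeletonization and
# geodesic path lengths on the skeleton pixel graph. Pixel coordinates are
# 0-based row-major in all user-facing output; internally R's 1-based
# matrix indexing is used.

#' Otsu threshold of an intensity image
#'
#' Computes the threshold that maximises between-class variance of the
#' two-class split of the intensity histogram (256 equal-width bins over the
#' observed range). Pixels strictly above the returned value are foreground.
#'
#' @param x Numeric matrix or array of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return A single numeric threshold. For a constant image the constant
#'   itself is returned (so `x > otsu_threshold(x)` is empty) with a warning.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) abort("no finite pixels to threshold")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warn("constant-intensity image: threshold equals the constant, mask will be empty")
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                           nbins = n_bins))
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  total_w <- w[n_bins]
  total_mu <- mu[n_bins]
  w0 <- w[-n_bins]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-n_bins] / w0
  m1 <- (total_mu - mu[-n_bins]) / w1
  between <- w0 * w1 * (m0 - m1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  # threshold at the upper edge of bin k: foreground = strictly above
  breaks[k + 1L]
}

# neighbour offsets (dr, dc) for 2D connectivity
.neigh2d <- function(connectivity = 8L) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      as.matrix() |>
      (\(m) m[!(m[, 1] == 0 & m[, 2] == 0), , drop = FALSE])()
  }
}

#' Label connected components of a binary mask
#'
#' Foreground pixels (`TRUE`/nonzero) are grouped into connected components
#' (8-connectivity in 2D, 26-connectivity in 3D by default) and labelled
#' 1..k in decreasing component size. Implemented on the pixel adjacency
#' graph via igraph.
#'
#' @param mask Logical (or 0/1 numeric) matrix or 3D array.
#' @param connectivity 4 or 8 for matrices, 6 or 26 for 3D arrays.
#' @return Integer matrix/array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = NULL) {
  dims <- dim(mask)
  stopifnot(length(dims) %in% c(2L, 3L))
  fg <- which(mask != 0)
  lab <- array(0L, dim = dims)
  if (length(fg) == 0L) return(lab)
  if (length(dims) == 2L) {
    connectivity <- connectivity %||% 8L
    offs <- .neigh2d(connectivity)
    idx <- arrayInd(fg, dims)
    edges <- .mask_edges(fg, idx, dims, offs)
  } else {
    connectivity <- connectivity %||% 26L
    g <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
    g <- as.matrix(g[!(g$dr == 0 & g$dc == 0 & g$dz == 0), , drop = FALSE])
    if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
    idx <- arrayInd(fg, dims)
    edges <- .mask_edges(fg, idx, dims, g)
  }
  # map linear indices to 1..n vertex ids
  vid <- integer(prod(dims))
  vid[fg] <- seq_along(fg)
  gr <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L) {
    gr <- igraph::add_edges(gr, rbind(vid[edges[, 1L]], vid[edges[, 2L]]))
  }
  comp <- igraph::components(gr)
  # relabel by decreasing size, ties by first pixel
  ord <- order(-comp$csize, seq_along(comp$csize))
  relab <- integer(length(comp$csize))
  relab[ord] <- seq_along(ord)
  lab[fg] <- relab[comp$membership]
  lab
}

# undirected edges (linear index pairs) between foreground pixels under offsets
.mask_edges <- function(fg, idx, dims, offs) {
  inmask <- logical(prod(dims))
  inmask[fg] <- TRUE
  out <- vector("list", nrow(offs))
  nd <- length(dims)
  for (k in seq_len(nrow(offs))) {
    shifted <- idx
    for (d in seq_len(nd)) shifted[, d] <- idx[, d] + offs[k, d]
    ok <- rep(TRUE, nrow(shifted))
    for (d in seq_len(nd)) ok <- ok & shifted[, d] >= 1L & shifted[, d] <= dims[d]
    if (!any(ok)) next
    lin <- .lin_index(shifted[ok, , drop = FALSE], dims)
    hit <- inmask[lin]
    if (!any(hit)) next
    a <- fg[ok][hit]
    b <- lin[hit]
    keep <- a < b   # each undirected edge once
    out[[k]] <- cbind(a[keep], b[keep])
  }
  do.call(rbind, c(out, list(matrix(integer(), ncol = 2L))))
}

.lin_index <- function(sub, dims) {
  lin <- sub[, 1L]
  mult <- 1L
  for (d in seq_len(length(dims) - 1L)) {
    mult <- mult * dims[d]
    lin <- lin + (sub[, d + 1L] - 1L) * mult
  }
  lin
}

# disk structuring-element offsets of pixel radius r (r = 0 -> identity)
.disk_offsets <- function(r) {
  r <- as.integer(round(r))
  if (r <= 0L) return(cbind(dr = 0L, dc = 0L))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

.shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Binary dilation, erosion and opening with a disk
#'
#' @param mask Logical matrix.
#' @param radius Structuring-element radius in pixels (integer; 0 = no-op).
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, radius) {
  mask <- mask != 0
  offs <- .disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | .shift_mat(mask, offs[k, 1L], offs[k, 2L], fill = FALSE)
  }
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius) {
  mask <- mask != 0
  offs <- .disk_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & .shift_mat(mask, offs[k, 1L], offs[k, 2L], fill = FALSE)
  }
  out
}

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, radius) {
  dilate_mask(erode_mask(mask, radius), radius)
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels while preserving connectivity and
#' endpoints until no pixel can be removed, yielding a 1-pixel-wide medial
#' skeleton. 2D only; project stacks before calling.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- .shift_mat(m, -1L, 0L); p3 <- .shift_mat(m, -1L, 1L)
      p4 <- .shift_mat(m, 0L, 1L);  p5 <- .shift_mat(m, 1L, 1L)
      p6 <- .shift_mat(m, 1L, 0L);  p7 <- .shift_mat(m, 1L, -1L)
      p8 <- .shift_mat(m, 0L, -1L); p9 <- .shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0->1 transitions in the circular sequence p2..p9,p2
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Weighted pixel graph of a 2D skeleton: 4-neighbours weight 1, diagonals
# sqrt(2). Returns list(graph, fg linear indices).
.skeleton_graph <- function(skel) {
  dims <- dim(skel)
  fg <- which(skel)
  if (length(fg) == 0L) {
    return(list(graph = igraph::make_empty_graph(0, directed = FALSE), fg = fg))
  }
  idx <- arrayInd(fg, dims)
  offs <- .neigh2d(8L)
  wts <- sqrt(offs[, 1L]^2 + offs[, 2L]^2)
  inmask <- logical(prod(dims))
  inmask[fg] <- TRUE
  vid <- integer(prod(dims))
  vid[fg] <- seq_along(fg)
  eds <- list(); ws <- list()
  for (k in seq_len(nrow(offs))) {
    shifted <- cbind(idx[, 1L] + offs[k, 1L], idx[, 2L] + offs[k, 2L])
    ok <- shifted[, 1L] >= 1L & shifted[, 1L] <= dims[1L] &
      shifted[, 2L] >= 1L & shifted[, 2L] <= dims[2L]
    lin <- .lin_index(shifted[ok, , drop = FALSE], dims)
    hit <- inmask[lin]
    a <- fg[ok][hit]; b <- lin[hit]
    keep <- a < b
    eds[[k]] <- cbind(vid[a[keep]], vid[b[keep]])
    ws[[k]] <- rep(wts[k], sum(keep))
  }
  em <- do.call(rbind, eds)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0L) {
    g <- igraph::add_edges(g, t(em))
    igraph::E(g)$weight <- unlist(ws)
  }
  list(graph = g, fg = fg)
}
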