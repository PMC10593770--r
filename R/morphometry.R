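# Cell-density and glial-morphology metrics: areal / per-length neuron
# densities, microglial soma area (morphological opening), skeleton process
# lengths (geodesic, sqrt(2) diagonals), 3D volume, and the
# Purkinje-contact fraction.

#' Areal cell density
#'
#' @param count Number of cells counted in the region of interest.
#' @param area_mm2 ROI surface area in mm² (> 0).
#' @return Cells per mm².
#' @examples
#' areal_density(10, 0.5)  # 20 per mm2
#' @export
areal_density <- function(count, area_mm2) {
  if (any(area_mm2 <= 0)) abort("`area_mm2` must be > 0")
  count / area_mm2
}

#' Linear (per-length) Purkinje cell density
#'
#' Cells per mm of the Purkinje cell layer. Callers must restrict counts to
#' single-lamina segments; pooling concatenated segments is the pooled
#' count over the pooled length.
#'
#' @param count Number of cells counted along the layer.
#' @param length_mm Layer length in mm (> 0).
#' @return Cells per mm.
#' @export
linear_density <- function(count, length_mm) {
  if (any(length_mm <= 0)) abort("`length_mm` must be > 0")
  count / length_mm
}

#' Microglial soma area from a 2D object mask
#'
#' The soma is the morphologically opened core of the object: opening with
#' a disk of `opening_radius_um` removes thin processes, what survives is
#' the soma. Radius 0 returns the full-object area (an upper bound).
#'
#' @param mask Logical 2D mask of one object.
#' @param scale_xy µm per pixel.
#' @param opening_radius_um Disk radius for the opening (µm, default 2).
#' @return Soma area in µm².
#' @export
soma_area <- function(mask, scale_xy, opening_radius_um = 2) {
  if (!any(mask != 0)) abort("empty object mask")
  core <- soma_core(mask, scale_xy, opening_radius_um)
  sum(core) * scale_xy^2
}

#' @rdname soma_area
#' @return `soma_core()`: the logical core mask itself.
#' @export
soma_core <- function(mask, scale_xy, opening_radius_um = 2) {
  r_px <- round(opening_radius_um / scale_xy)
  open_mask(mask != 0, r_px)
}

#' Per-process skeleton lengths of a microglial object
#'
#' Skeletonizes the object with the soma core removed; every skeleton
#' endpoint contributes the geodesic path length (4-neighbour steps 1 px,
#' diagonal steps sqrt(2) px) from the nearest skeleton pixel touching the
#' soma boundary. Skeleton components not connected to the soma are
#' measured from their own far end (whole-component diameter path).
#'
#' @param mask Logical 2D mask of the full object. 3D arrays are
#'   maximum-projected first (2D skeleton metrics on projections).
#' @param soma Logical core mask, e.g. from [soma_core()]; must be a subset
#'   of `mask`.
#' @param scale_xy µm per pixel.
#' @param min_length_um Branches shorter than this are discarded (boundary
#'   crumbs left over from the soma opening, default 2 µm).
#' @return Numeric vector of process lengths in µm (one per endpoint;
#'   empty if nothing lies outside the soma).
#' @export
process_lengths <- function(mask, soma, scale_xy, min_length_um = 2) {
  if (length(dim(mask)) == 3L) mask <- apply(mask != 0, c(1L, 2L), max) > 0
  if (length(dim(soma)) == 3L) soma <- apply(soma != 0, c(1L, 2L), max) > 0
  mask <- mask != 0; soma <- soma != 0
  if (any(soma & !mask)) abort("`soma` must be contained in `mask`")
  outside <- mask & !soma
  if (!any(outside)) return(numeric())
  skel <- skeletonize_mask(outside)
  if (!any(skel)) return(numeric())
  sg <- .skeleton_graph(skel)
  deg <- igraph::degree(sg$graph)
  ends <- which(deg <= 1L)
  if (length(ends) == 0L) ends <- seq_along(sg$fg)
  if (!any(soma)) {
    # no soma core at all: report each component's diameter path
    d <- igraph::distances(sg$graph, v = ends, to = ends)
    d[!is.finite(d)] <- 0
    return(unname(max(d) * scale_xy))
  }
  # root per skeleton component: the pixel nearest the soma core (boundary
  # rounding can leave a small gap, so plain adjacency is too brittle)
  comp <- igraph::components(sg$graph)$membership
  idx <- arrayInd(sg$fg, dim(skel))
  core_idx <- which(soma, arr.ind = TRUE)
  d2core <- vapply(seq_along(sg$fg), function(v) {
    min((core_idx[, 1L] - idx[v, 1L])^2 + (core_idx[, 2L] - idx[v, 2L])^2)
  }, numeric(1))
  roots <- vapply(unique(comp), function(cm) {
    v <- which(comp == cm)
    v[which.min(d2core[v])]
  }, integer(1))
  d <- igraph::distances(sg$graph, v = roots, to = ends)
  len_px <- apply(d, 2L, min)
  len_px <- len_px[is.finite(len_px) & len_px > 0]
  lens <- unname(len_px * scale_xy)
  lens[lens >= min_length_um]
}

#' Object volume from a 3D mask
#'
#' @param mask Logical 3D array (one object).
#' @param voxel_um3 Physical voxel volume in µm³ (e.g.
#'   `scale_xy^2 * scale_z`).
#' @return Volume in µm³ (voxel count x voxel volume).
#' @export
object_volume <- function(mask, voxel_um3) {
  if (!any(mask != 0)) abort("empty mask")
  sum(mask != 0) * voxel_um3
}

#' Fraction of microglia in contact with Purkinje neurons
#'
#' A microglial object "contacts" the Purkinje mask if its mask, dilated by
#' `dilation_px`, intersects it. Dilation 1 operationalises "touching";
#' objects already overlapping the Purkinje mask count regardless.
#'
#' @param microglia_labels Integer label mask (2D) of microglial objects.
#'   3D label arrays are maximum-projected.
#' @param purkinje_mask Logical mask, co-registered with the labels.
#' @param dilation_px Contact radius in pixels (default 1).
#' @return List: `fraction`, `n_contact`, `n_total`, and per-object tibble
#'   `objects` (`object_id`, `contacts_purkinje`).
#' @export
contact_fraction <- function(microglia_labels, purkinje_mask, dilation_px = 1L) {
  if (length(dim(microglia_labels)) == 3L) {
    microglia_labels <- apply(microglia_labels, c(1L, 2L), max)
  }
  if (length(dim(purkinje_mask)) == 3L) {
    purkinje_mask <- apply(purkinje_mask != 0, c(1L, 2L), max) > 0
  }
  if (!identical(dim(microglia_labels), dim(purkinje_mask))) {
    abort("masks must be co-registered (same dimensions)")
  }
  ids <- sort(unique(microglia_labels[microglia_labels > 0L]))
  if (length(ids) == 0L) abort("no microglial objects in label mask")
  # dilate the purkinje mask once instead of every object: symmetric SE
  near <- dilate_mask(purkinje_mask != 0, dilation_px)
  hit <- vapply(ids, function(id) any(near[microglia_labels == id]), logical(1))
  list(
    fraction = mean(hit),
    n_contact = sum(hit),
    n_total = length(ids),
    objects = tibble(object_id = ids, contacts_purkinje = hit)
  )
}

#' Morphometry table for a labelled microglia stack
#'
#' Convenience wrapper running [soma_area()], [process_lengths()] and
#' [object_volume()] per labelled object of a 3D stack (2D metrics on the
#' maximum projection).
#'
#' @param labels Integer 3D label array (e.g. from [sim_microglia_stack()]).
#' @param scale_xy,scale_z Physical scales (µm).
#' @param opening_radius_um Soma opening radius (µm).
#' @return Tibble: `object_id`, `soma_area_um2`, `n_processes`,
#'   `mean_process_length_um`, `total_process_length_um`, `volume_um3`.
#' @export
measure_microglia <- function(labels, scale_xy, scale_z,
                              opening_radius_um = 2) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) abort("no objects in label array")
  pad <- ceiling(opening_radius_um / scale_xy) + 2L
  rows <- lapply(ids, function(id) {
    m3 <- labels == id
    m2full <- apply(m3, c(1L, 2L), max) > 0
    # crop to the object's bounding box (+pad) before any morphology
    rr <- range(which(rowSums(m2full) > 0))
    cc <- range(which(colSums(m2full) > 0))
    ri <- max(1L, rr[1] - pad):min(nrow(m2full), rr[2] + pad)
    ci <- max(1L, cc[1] - pad):min(ncol(m2full), cc[2] + pad)
    m2 <- m2full[ri, ci, drop = FALSE]
    core <- soma_core(m2, scale_xy, opening_radius_um)
    lens <- process_lengths(m2, core, scale_xy)
    tibble(
      object_id = id,
      soma_area_um2 = sum(core) * scale_xy^2,
      n_processes = length(lens),
      mean_process_length_um = if (length(lens)) mean(lens) else NA_real_,
      total_process_length_um = sum(lens),
      volume_um3 = object_volume(m3, scale_xy^2 * scale_z)
    )
  })
  bind_rows(rows)
}
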