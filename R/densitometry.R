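# Per-cell and per-object mean signal densities from channel stacks.
# Automated stand-in for the manual freehand-ROI densitometry used in the
# modelled study: threshold the marker-of-interest channel, label connected
# components, area-filter, and average every channel over each object.

#' Segment marker-positive cells
#'
#' Otsu-thresholds the marker channel, labels connected components
#' (8-connectivity) and keeps components whose physical area lies in
#' `[min_area, max_area]` µm². Touching cells may merge: no watershed split
#' is attempted, matching the granularity limitation documented for this
#' pipeline.
#'
#' @param stack A [channel_stack()] (2D).
#' @param marker Channel/marker name to segment on.
#' @param min_area,max_area Area filter in µm².
#' @return Integer label mask (relabelled 1..k after filtering). A
#'   constant-intensity channel yields an empty mask with a warning.
#' @export
segment_marker_positive <- function(stack, marker,
                                    min_area = 20, max_area = Inf) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!marker %in% names(stack$channels)) {
    abort(sprintf("marker '%s' not in stack channels (%s)", marker,
                  paste(names(stack$channels), collapse = ", ")))
  }
  img <- stack$channels[[marker]]
  if (length(dim(img)) != 2L) abort("segment_marker_positive is 2D-only")
  thr <- otsu_threshold(img)
  fg <- img > thr
  lab <- label_components(fg)
  if (max(lab) == 0L) return(lab)
  px_area <- stack$scale_xy^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * px_area >= min_area & sizes * px_area <= max_area)
  out <- array(0L, dim = dim(lab))
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  sel <- lab > 0L
  out[sel] <- relab[lab[sel]]
  out
}

#' Measure per-cell mean densities over a label mask
#'
#' For every labelled object and every channel, the mean intensity over the
#' object's pixels; area (2D) or volume (3D) from the pixel/voxel count and
#' the physical scales. Whole-mask means, no background subtraction by
#' default (`background` subtracts a constant first).
#'
#' @param stack A [channel_stack()].
#' @param mask Integer label mask with the same dimensions as the channels.
#' @param mouse_id,group,region Metadata stamped onto every row.
#' @param background Constant offset subtracted from every channel before
#'   averaging (default 0, i.e. none).
#' @return Tibble: `cell_id` (label id as `"<image_id>_<label>"`),
#'   `mouse_id`, `group`, `region`, `area_um2` (or `volume_um3` for 3D),
#'   one mean-density column per channel.
#' @export
measure_cells <- function(stack, mask, mouse_id = NA_character_,
                          group = NA_character_, region = NA_character_,
                          background = 0) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!identical(dim(mask), dim(stack$channels[[1]]))) {
    abort("mask dimensions must match the stack")
  }
  labs <- sort(unique(as.integer(mask[mask > 0L])))
  three_d <- is_3d(stack)
  px <- if (three_d) stack$scale_xy^2 * stack$scale_z else stack$scale_xy^2
  if (length(labs) == 0L) {
    out <- tibble(cell_id = character(), mouse_id = character(),
                  group = character(), region = character())
    out[[if (three_d) "volume_um3" else "area_um2"]] <- numeric()
    for (ch in names(stack$channels)) out[[ch]] <- numeric()
    return(out)
  }
  fac <- factor(as.integer(mask[mask > 0L]), levels = labs)
  counts <- as.integer(table(fac))
  means <- lapply(stack$channels, function(ch) {
    as.numeric(tapply(ch[mask > 0L] - background, fac, mean))
  })
  out <- tibble(
    cell_id = sprintf("%s_%d", stack$image_id, labs),
    mouse_id = mouse_id, group = group, region = region
  )
  out[[if (three_d) "volume_um3" else "area_um2"]] <- counts * px
  for (ch in names(means)) out[[ch]] <- means[[ch]]
  out
}

#' Measure terminal-level objects
#'
#' Mitochondrial content within marker-positive "objects" (e.g. GAD1-2
#' positive inhibitory axonal terminals): thresholds the object channel
#' (Otsu by default or an absolute value), labels connected components in
#' 2D or 3D, drops objects below `min_voxels`, and returns one measurement
#' row per object with mean densities for every channel.
#'
#' @param stack A [channel_stack()] (2D or 3D).
#' @param object_marker Channel defining the objects.
#' @param threshold Either `"otsu"` or a numeric absolute threshold
#'   (foreground is strictly above it).
#' @param min_voxels Minimum component size in pixels/voxels.
#' @param ... Metadata passed to [measure_cells()] (`mouse_id`, `group`,
#'   `region`).
#' @return A measurement tibble as from [measure_cells()], one row per
#'   object, with an `object_role = "terminal"` column.
#' @export
measure_terminal_objects <- function(stack, object_marker,
                                     threshold = "otsu",
                                     min_voxels = 4L, ...) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!object_marker %in% names(stack$channels)) {
    abort(sprintf("object marker '%s' not in stack", object_marker))
  }
  img <- stack$channels[[object_marker]]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(img) else threshold
  fg <- img > thr
  lab <- label_components(fg)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_voxels)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    sel <- lab > 0L
    lab[sel] <- relab[lab[sel]]
  }
  out <- measure_cells(stack, lab, ...)
  out$object_role <- rep("terminal", nrow(out))
  out
}
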