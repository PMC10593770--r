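#' Multi-channel image stack
#'
#' Container for a multi-channel fluorescence image: one 2D matrix (or 3D
#' array) per channel, a channel-to-marker mapping implied by the list
#' names, and physical pixel scales. All densitometry operates on this
#' object; the synthetic renderer produces it, so measured and simulated
#' data flow through identical code paths.
#'
#' @param channels Named list of numeric matrices (2D) or arrays (3D), all
#'   with identical dimensions. Names are marker labels (e.g. `"NDUFA13"`).
#' @param scale_xy Pixel size in µm (x and y assumed isotropic). Must be > 0.
#' @param scale_z Plane spacing in µm for 3D stacks; `NULL` for 2D.
#' @param image_id Optional identifier carried into measurement tables.
#' @return An object of class `channel_stack`.
#' @examples
#' img <- matrix(rnorm(64, 100, 5), 8, 8)
#' channel_stack(list(PV = img), scale_xy = 0.25)
#' @export
channel_stack <- function(channels, scale_xy, scale_z = NULL, image_id = "image") {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a non-empty named list of arrays")
  }
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort("all channels must share dimensions")
  }
  nd <- length(dims[[1]])
  if (!nd %in% c(2L, 3L)) abort("channels must be 2D matrices or 3D arrays")
  if (!is.numeric(scale_xy) || length(scale_xy) != 1L || scale_xy <= 0) {
    abort("`scale_xy` must be a single positive number (µm per pixel)")
  }
  if (nd == 3L) {
    if (is.null(scale_z) || scale_z <= 0) abort("3D stacks need a positive `scale_z`")
  } else {
    scale_z <- NULL
  }
  structure(
    list(channels = channels, scale_xy = scale_xy, scale_z = scale_z,
         image_id = image_id),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_stack> ", x$image_id, "\n", sep = "")
  cat("  channels: ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  cat("  dims: ", paste(d, collapse = " x "),
      "  scale: ", x$scale_xy, " µm/px",
      if (!is.null(x$scale_z)) paste0(", ", x$scale_z, " µm/plane"), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$channels[[1]])

is_3d <- function(stack) length(dim(stack$channels[[1]])) == 3L
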