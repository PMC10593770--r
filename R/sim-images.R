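# Rendering synthetic measurement scenes: 2D multi-channel cell images with
# a ground-truth label mask (so densitometry can be tested against known
# intensities) and 3D microglia stacks with known soma geometry and
# process polylines (so morphometry can be tested against known lengths).

# draw a line segment into a matrix by supercover stepping; returns the
# lattice points visited (including both endpoints, rounded)
.trace_segment <- function(p0, p1) {
  n <- max(abs(p1 - p0)) * 2 + 1
  t <- seq(0, 1, length.out = max(2, ceiling(n)))
  pts <- cbind(round(p0[1] + t * (p1[1] - p0[1])),
               round(p0[2] + t * (p1[2] - p0[2])))
  pts[!duplicated(pts), , drop = FALSE]
}

#' Render a per-cell table as a multi-channel image
#'
#' Each cell becomes a disk whose area matches its `area_um2` at the given
#' pixel scale, placed without overlap by rejection sampling. Every marker
#' column of `cells` becomes one channel whose mean intensity over the
#' cell's pixels equals the cell's density value; i.i.d. Gaussian noise is
#' added per pixel. The returned label mask maps pixels to rows of `cells`.
#'
#' @param cells Tibble with `cell_id`, `area_um2` and one column per marker
#'   (as produced by [sim_cell_table()]).
#' @param image_px Image side length in pixels (square image).
#' @param scale_xy µm per pixel.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param background Background intensity.
#' @param max_tries Placement retries per cell before failing.
#' @param seed Optional seed (local to this call).
#' @return List: `stack` ([channel_stack()]), `mask` (integer label matrix,
#'   0 = background, label i = row i of `cells`), `cells` (the input with
#'   pixel centres appended).
#' @export
sim_cell_image <- function(cells, image_px = 512L, scale_xy = 0.5,
                           noise_sd = 0, background = 0,
                           max_tries = 200L, seed = NULL) {
  marker_cols <- setdiff(names(cells),
                         c("cell_id", "mouse_id", "group", "region", "area_um2"))
  if (nrow(cells) > 0L && length(marker_cols) == 0L) {
    abort("`cells` has no marker columns to render")
  }
  with_seed(seed, {
    mask <- matrix(0L, image_px, image_px)
    radii_px <- if (nrow(cells)) sqrt(cells$area_um2 / pi) / scale_xy else numeric()
    centres <- matrix(NA_real_, nrow(cells), 2L)
    for (i in seq_len(nrow(cells))) {
      r <- radii_px[i]
      if (2 * r + 2 > image_px) abort("cell larger than image at this scale")
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        c_i <- runif(2, min = r + 1, max = image_px - r)
        ok <- TRUE
        if (i > 1L) {
          prev <- seq_len(i - 1L)
          d <- sqrt((centres[prev, 1L] - c_i[1L])^2 +
                    (centres[prev, 2L] - c_i[2L])^2)
          ok <- all(d > r + radii_px[prev] + 1)
        }
        if (ok) {
          centres[i, ] <- c_i
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("could not place cell %d without overlap after %d tries",
                      i, max_tries))
      }
    }
    # paint disks
    if (nrow(cells)) {
      rows <- row(mask); cols <- col(mask)
      for (i in seq_len(nrow(cells))) {
        inside <- (rows - centres[i, 1L])^2 + (cols - centres[i, 2L])^2 <=
          radii_px[i]^2
        mask[inside] <- i
      }
    }
    channels <- lapply(marker_cols, function(mk) {
      img <- matrix(background, image_px, image_px)
      if (nrow(cells)) {
        v <- cells[[mk]]
        sel <- mask > 0L
        img[sel] <- v[mask[sel]]
      }
      if (noise_sd > 0) img <- img + matrix(rnorm(image_px^2, 0, noise_sd),
                                            image_px, image_px)
      img
    })
    names(channels) <- marker_cols
    placed_cells <- cells
    placed_cells$centre_row <- centres[, 1L]
    placed_cells$centre_col <- centres[, 2L]
    list(stack = channel_stack(channels, scale_xy = scale_xy,
                               image_id = "synthetic_cells"),
         mask = mask,
         cells = placed_cells)
  })
}

#' Generate a synthetic 3D microglia stack with ground truth
#'
#' Each microglial object is an ellipsoidal soma plus `n_processes`
#' piecewise-linear processes of known polyline length, drawn one voxel
#' wide in the soma's mid-plane. Objects are placed on a grid so they never
#' touch. Ground truth records the analytic mid-plane soma area, each
#' process's polyline length measured from the soma boundary, the analytic
#' ellipsoid volume and the rendered voxel count.
#'
#' Defaults emulate quiescent cerebellar microglia: soma ~34 µm² mid-plane
#' area, 4 ramified processes of 15-30 µm, imaged at 0.25 µm/px and
#' 0.5 µm/plane.
#'
#' @param n_cells Number of microglia.
#' @param soma_radius_um Mean in-plane soma radius (µm).
#' @param soma_aspect_jitter Soma in-plane radii are `r*u` and `r/u`,
#'   `u ~ U(1, 1 + jitter)`.
#' @param n_processes Processes per cell.
#' @param process_length_um Length-2 range; each process's target length is
#'   uniform over it (µm).
#' @param n_segments Straight segments per process.
#' @param turn_sd_deg Direction jitter between segments (degrees).
#' @param scale_xy µm per pixel, `scale_z` µm per plane.
#' @param scale_z µm per plane.
#' @param seed Optional seed (local to this call).
#' @return List: `stack` (logical 3D array, the binary Iba1-like channel),
#'   `labels` (integer 3D array, voxel -> object id), `truth` (tibble:
#'   object_id, soma_area_um2, soma_volume_um3, volume_um3 (rendered),
#'   n_processes, process lengths list-column and their mean), `scale_xy`,
#'   `scale_z`.
#' @export
sim_microglia_stack <- function(n_cells = 9L,
                                soma_radius_um = 3.3,
                                soma_aspect_jitter = 0.1,
                                n_processes = 4L,
                                process_length_um = c(15, 30),
                                n_segments = 3L,
                                turn_sd_deg = 10,
                                scale_xy = 0.25,
                                scale_z = 0.5,
                                seed = NULL) {
  with_seed(seed, {
    r_px <- soma_radius_um / scale_xy
    max_len_px <- max(process_length_um) / scale_xy
    cell_extent <- 2 * (r_px * (1 + soma_aspect_jitter) + max_len_px)
    spacing <- ceiling(cell_extent + 6)
    ncol_grid <- ceiling(sqrt(n_cells))
    nrow_grid <- ceiling(n_cells / ncol_grid)
    nx <- nrow_grid * spacing
    ny <- ncol_grid * spacing
    rz_px <- max(2, round(0.7 * soma_radius_um / scale_z))
    nz <- 2L * rz_px + 5L
    kz <- rz_px + 3L  # mid-plane

    labels <- array(0L, dim = c(nx, ny, nz))
    truth <- vector("list", n_cells)

    for (i in seq_len(n_cells)) {
      gi <- (i - 1L) %/% ncol_grid
      gj <- (i - 1L) %% ncol_grid
      ci <- gi * spacing + spacing / 2
      cj <- gj * spacing + spacing / 2
      u <- runif(1, 1, 1 + soma_aspect_jitter)
      rx <- r_px * u
      ry <- r_px / u

      # ellipsoid soma
      ii <- max(1, floor(ci - rx)):min(nx, ceiling(ci + rx))
      jj <- max(1, floor(cj - ry)):min(ny, ceiling(cj + ry))
      kk <- max(1, kz - rz_px):min(nz, kz + rz_px)
      grid <- expand.grid(i = ii, j = jj, k = kk)
      inside <- ((grid$i - ci) / rx)^2 + ((grid$j - cj) / ry)^2 +
        ((grid$k - kz) / rz_px)^2 <= 1
      sel <- grid[inside, , drop = FALSE]
      labels[cbind(sel$i, sel$j, sel$k)] <- i

      # processes from the soma boundary, drawn in the mid-plane
      base_angles <- seq(0, 2 * pi, length.out = n_processes + 1L)[-(n_processes + 1L)] +
        runif(1, 0, 2 * pi / n_processes)
      lens_um <- numeric(n_processes)
      for (p in seq_len(n_processes)) {
        theta <- base_angles[p]
        target_len_px <- runif(1, process_length_um[1], process_length_um[2]) /
          scale_xy
        seg_len <- target_len_px / n_segments
        # start on the ellipse boundary in direction theta
        rb <- 1 / sqrt((cos(theta) / rx)^2 + (sin(theta) / ry)^2)
        pt <- c(ci + rb * cos(theta), cj + rb * sin(theta))
        pts_all <- matrix(round(pt), ncol = 2L)
        dir <- theta
        for (s in seq_len(n_segments)) {
          dir <- dir + rnorm(1, 0, turn_sd_deg * pi / 180)
          nxt <- pt + seg_len * c(cos(dir), sin(dir))
          seg_pts <- .trace_segment(round(pt), round(nxt))
          pts_all <- rbind(pts_all, seg_pts[-1L, , drop = FALSE])
          pt <- nxt
        }
        # true length = polyline length over drawn lattice points
        dpts <- diff(pts_all)
        lens_um[p] <- sum(sqrt(dpts[, 1L]^2 + dpts[, 2L]^2)) * scale_xy
        keep <- pts_all[, 1L] >= 1 & pts_all[, 1L] <= nx &
          pts_all[, 2L] >= 1 & pts_all[, 2L] <= ny
        pts_all <- pts_all[keep, , drop = FALSE]
        labels[cbind(pts_all[, 1L], pts_all[, 2L], kz)] <- i
      }

      truth[[i]] <- tibble(
        object_id = i,
        soma_area_um2 = pi * rx * ry * scale_xy^2,
        soma_volume_um3 = 4 / 3 * pi * rx * ry * rz_px *
          scale_xy^2 * scale_z,
        n_processes = n_processes,
        process_lengths_um = list(lens_um),
        mean_process_length_um = mean(lens_um)
      )
    }
    truth <- bind_rows(truth)
    counts <- tabulate(labels[labels > 0L], nbins = n_cells)
    truth$volume_um3 <- counts * scale_xy^2 * scale_z

    list(stack = labels > 0L, labels = labels, truth = truth,
         scale_xy = scale_xy, scale_z = scale_z, mid_plane = kz)
  })
}
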