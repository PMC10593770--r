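# Segmentation and per-cell/per-object densitometry against the renderer's
# ground truth and a per-pixel brute-force oracle.

# brute-force oracle: per-label mean by explicit pixel loop
oracle_means <- function(img, mask) {
  ids <- sort(unique(mask[mask > 0]))
  vapply(ids, function(id) {
    total <- 0; cnt <- 0
    for (k in seq_along(mask)) {
      if (mask[k] == id) { total <- total + img[k]; cnt <- cnt + 1 }
    }
    total / cnt
  }, numeric(1))
}

test_that("segmentation recovers rendered disks with centroid accuracy", {
  set.seed(31)
  cells <- make_cells(target_density = runif(20, 80, 150),
                      mass_density = runif(20, 80, 150))
  cells$area_um2 <- runif(20, 60, 140)
  img <- sim_cell_image(cells, image_px = 360, scale_xy = 0.5,
                        noise_sd = 1, seed = 31)
  seg <- segment_marker_positive(img$stack, "NDUFA13", min_area = 20)
  expect_identical(max(seg), 20L)
  # centroid of each segmented component within 1 px of the placed centre
  for (lab in seq_len(20)) {
    idx <- which(seg == lab, arr.ind = TRUE)
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    d <- sqrt((img$cells$centre_row - cr)^2 + (img$cells$centre_col - cc)^2)
    expect_lt(min(d), 1)
  }
})

test_that("blank and touching-cell edge cases behave as documented", {
  blank <- channel_stack(list(PV = matrix(3, 30, 30)), scale_xy = 0.5)
  expect_warning(seg <- segment_marker_positive(blank, "PV"), "constant")
  expect_identical(max(seg), 0L)
  # two touching disks may merge: component count <= n_true
  m <- matrix(0, 40, 60)
  m[disk_mask(40, 60, 20, 20, 8)] <- 100
  m[disk_mask(40, 60, 20, 35, 8)] <- 100
  st <- channel_stack(list(PV = m), scale_xy = 0.5)
  seg <- segment_marker_positive(st, "PV", min_area = 1)
  expect_lte(max(seg), 2L)
  expect_gte(max(seg), 1L)
})

test_that("measure_cells reports exact means, physical areas, bijection", {
  cells <- make_cells(target_density = c(100, 55), mass_density = c(70, 90))
  cells$area_um2 <- c(100, 80)
  img <- sim_cell_image(cells, image_px = 100, scale_xy = 0.25,
                        noise_sd = 0, seed = 8)
  m <- measure_cells(img$stack, img$mask, mouse_id = "m1",
                     group = "control", region = "cortex")
  expect_identical(nrow(m), 2L)                       # one row per object
  expect_equal(m$NDUFA13, cells$NDUFA13)              # noiseless: exact
  expect_equal(m$SDHA, cells$SDHA)
  # area = pixel count x scale^2; pixel accounting conserved
  expect_equal(m$area_um2, as.numeric(table(img$mask[img$mask > 0])) * 0.25^2)
  expect_equal(sum(m$area_um2) / 0.25^2, sum(img$mask > 0))
  # 100-px object at 0.25 um/px is 6.25 um2
  mask1 <- matrix(0L, 20, 20); mask1[1:10, 1:10] <- 1L
  st <- channel_stack(list(X = matrix(7, 20, 20)), scale_xy = 0.25)
  m1 <- measure_cells(st, mask1)
  expect_equal(m1$area_um2, 100 * 0.0625)
  # empty mask -> empty tibble with schema
  m0 <- measure_cells(st, matrix(0L, 20, 20))
  expect_identical(nrow(m0), 0L)
  expect_true(all(c("cell_id", "area_um2", "X") %in% names(m0)))
  expect_error(measure_cells(st, matrix(0L, 5, 5)), "dimensions")
})

test_that("batch densitometry matches the per-pixel brute-force oracle", {
  set.seed(44)
  for (rep in 1:3) {
    cells <- make_cells(target_density = runif(6, 50, 200),
                        mass_density = runif(6, 50, 200))
    cells$area_um2 <- runif(6, 50, 120)
    img <- sim_cell_image(cells, image_px = 200, scale_xy = 0.5,
                          noise_sd = 4, seed = 44 + rep)
    m <- measure_cells(img$stack, img$mask)
    expect_equal(m$NDUFA13, oracle_means(img$stack$channels$NDUFA13, img$mask))
    expect_equal(m$SDHA, oracle_means(img$stack$channels$SDHA, img$mask))
  }
})

test_that("terminal-object measurement finds planted objects, oracle means", {
  set.seed(7)
  # plant 12 small square "terminals" with known GAD and NDUFA13 signal
  gad <- matrix(rnorm(150 * 150, 5, 0.5), 150, 150)
  nd <- matrix(rnorm(150 * 150, 2, 0.2), 150, 150)
  centers <- expand.grid(r = c(20, 60, 100, 140) - 10, c = c(30, 70, 110))
  for (i in seq_len(nrow(centers))) {
    rr <- centers$r[i] + 0:3; cc <- centers$c[i] + 0:3
    gad[rr, cc] <- 100 + i
    nd[rr, cc] <- 50 + i
  }
  st <- channel_stack(list(GAD = gad, NDUFA13 = nd), scale_xy = 0.2,
                      image_id = "dcn")
  obj <- measure_terminal_objects(st, "GAD", min_voxels = 4)
  expect_identical(nrow(obj), 12L)
  expect_true(all(obj$object_role == "terminal"))
  expect_true(all(obj$GAD > 90))
  # oracle check of masked means via an absolute threshold
  obj2 <- measure_terminal_objects(st, "GAD", threshold = 50, min_voxels = 4)
  lab <- label_components(gad > 50)
  expect_equal(sort(obj2$NDUFA13), sort(oracle_means(nd, lab)))
  # threshold above the max -> no rows
  expect_identical(nrow(measure_terminal_objects(st, "GAD", threshold = 1e6)), 0L)
})
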