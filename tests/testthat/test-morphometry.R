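# Densities, soma/process/volume morphometry and the contact criterion.

test_that("areal and linear densities are ratios with pooling additivity", {
  expect_equal(areal_density(10, 0.5), 20)
  expect_equal(areal_density(0, 2), 0)
  expect_error(areal_density(5, 0), "> 0")
  expect_equal(linear_density(35, 1), 35)
  expect_error(linear_density(5, -1), "> 0")
  # tiling invariance: pooled counts over pooled measure = whole-field value
  counts <- c(12, 7, 21); areas <- c(0.2, 0.1, 0.45)
  expect_equal(areal_density(sum(counts), sum(areas)),
               sum(counts) / sum(areas))
  lens <- c(0.8, 1.3); cts <- c(30, 41)
  expect_equal(linear_density(sum(cts), sum(lens)), 71 / 2.1)
})

test_that("soma area via opening: disk recovery and radius-0 upper bound", {
  m <- disk_mask(60, 60, 30, 30, 10)
  # radius-10 disk at 0.5 um/px: ~ pi * 25 um^2
  a <- soma_area(m, scale_xy = 0.5, opening_radius_um = 1)
  expect_equal(a, pi * 25, tolerance = 0.06)
  # opening radius 0 returns the full object area (monotone upper bound)
  m2 <- m; m2[30, 41:58] <- TRUE
  a_full <- soma_area(m2, 0.5, opening_radius_um = 0)
  expect_equal(a_full, sum(m2) * 0.25)
  expect_lt(soma_area(m2, 0.5, opening_radius_um = 2), a_full)
  expect_error(soma_area(matrix(FALSE, 4, 4), 0.5), "empty")
})

test_that("a straight process measures its geometric length", {
  m <- disk_mask(60, 120, 30, 25, 8)
  m[30, 34:83] <- TRUE   # 50 px straight horizontal process
  core <- soma_core(m, scale_xy = 0.2, opening_radius_um = 1)
  lens <- process_lengths(m, core, scale_xy = 0.2)
  expect_identical(length(lens), 1L)
  expect_gte(lens, 9.8)
  expect_lte(lens, 10.2)
  # nothing outside the soma -> empty list
  expect_identical(process_lengths(m & !m | core, core, 0.2), numeric())
  expect_error(process_lengths(core, m, 0.2), "contained")
})

test_that("object volume: voxel arithmetic, translation invariance, phantom", {
  a <- array(FALSE, c(10, 10, 10)); a[1:10, 1:10, 1:10] <- TRUE
  expect_equal(object_volume(a, 0.01), 10)
  b <- array(FALSE, c(30, 30, 12)); b[2:11, 2:11, 2:11] <- TRUE
  b2 <- array(FALSE, c(30, 30, 12)); b2[15:24, 12:21, 2:11] <- TRUE
  expect_equal(object_volume(b, 0.125), object_volume(b2, 0.125))
  # ellipsoid phantom within 5% of 4/3 pi abc * voxel volume
  dims <- c(61, 61, 41); ra <- 20; rb <- 15; rc <- 12
  g <- expand.grid(i = 1:61, j = 1:61, k = 1:41)
  ell <- array(((g$i - 31) / ra)^2 + ((g$j - 31) / rb)^2 +
                 ((g$k - 21) / rc)^2 <= 1, dim = dims)
  vox <- 0.25^2 * 0.5
  expect_equal(object_volume(ell, vox), 4 / 3 * pi * ra * rb * rc * vox,
               tolerance = 0.05)
})

test_that("contact fraction recovers planted contacts exactly", {
  lab <- matrix(0L, 80, 80)
  lab[disk_mask(80, 80, 15, 15, 6)] <- 1L   # far from purkinje
  lab[disk_mask(80, 80, 15, 60, 6)] <- 2L   # touching (1 px gap)
  lab[disk_mask(80, 80, 60, 70, 6)] <- 3L   # overlapping
  pk <- matrix(FALSE, 80, 80)
  pk[, 67:80] <- TRUE
  res <- contact_fraction(lab, pk, dilation_px = 1)
  expect_equal(res$fraction, 2 / 3)
  expect_identical(res$objects$contacts_purkinje, c(FALSE, TRUE, TRUE))
  # disjoint far-apart masks never contact at dilation 1
  res0 <- contact_fraction(lab * (lab == 1L), pk, dilation_px = 1)
  expect_equal(res0$fraction, 0)
  # overlap counts regardless of dilation radius
  res_ov <- contact_fraction(lab * (lab == 3L), pk, dilation_px = 0)
  expect_equal(res_ov$fraction, 1)
  expect_error(contact_fraction(matrix(0L, 4, 4), pk), "co-registered|objects")
})

test_that("physical outputs scale correctly with pixel size", {
  m <- disk_mask(60, 60, 30, 30, 10)
  expect_equal(soma_area(m, 1, 0) / soma_area(m, 0.5, 0), 4)
  mm <- disk_mask(60, 120, 30, 25, 8); mm[30, 34:83] <- TRUE
  core <- soma_core(mm, 0.2, 1)
  expect_equal(process_lengths(mm, core, 0.4) / process_lengths(mm, core, 0.2), 2)
  a <- array(FALSE, c(5, 5, 5)); a[2:4, 2:4, 2:4] <- TRUE
  expect_equal(object_volume(a, 0.8^3) / object_volume(a, 0.4^3), 8)
})

test_that("synthetic microglia morphometry recovers generator truth", {
  mg <- sim_microglia_stack(n_cells = 6, seed = 101)
  mm <- measure_microglia(mg$labels, mg$scale_xy, mg$scale_z,
                          opening_radius_um = 2)
  tr <- mg$truth
  # soma areas within 10% of analytic truth (per cell)
  expect_true(all(abs(mm$soma_area_um2 - tr$soma_area_um2) /
                    tr$soma_area_um2 < 0.10))
  # mean process length within 15% of truth at default branch config
  expect_lt(abs(mean(mm$mean_process_length_um) -
                  mean(tr$mean_process_length_um)) /
              mean(tr$mean_process_length_um), 0.15)
  # volumes equal the rendered voxel truth exactly
  expect_equal(mm$volume_um3, tr$volume_um3)
  # process removal only removes skeleton length
  expect_true(all(mm$total_process_length_um >= 0))
})
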