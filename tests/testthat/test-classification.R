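# The z-score deficiency classifier: reference fitting, scoring, the
# five-class bins, breakdown aggregation and the summary statistics.

test_that("control reference is the pooled mean/SD of log10 ratios", {
  # densities 10^{1,2,3} over unity mass: log-ratios {1,2,3} -> mean 2, SD 1
  cells <- make_cells(target_density = 10^c(1, 2, 3), mass = "unity_dummy")
  cells$unity_dummy <- NULL
  ref <- fit_control_reference(cells, "NDUFA13", "unity")
  expect_equal(ref$mean_log_ratio, 2)
  expect_equal(ref$sd_log_ratio, 1)
  expect_identical(ref$n_cells, 3L)
  # one usable cell -> calibration error
  expect_error(fit_control_reference(make_cells(10), "NDUFA13", "unity"),
               ">= 2")
  # non-positive densities are excluded with a message
  cells2 <- make_cells(target_density = c(10, 100, -5, 0), mass_density = 1)
  expect_message(ref2 <- fit_control_reference(cells2, "NDUFA13", "SDHA"),
                 "excluded 2")
  expect_identical(ref2$n_cells, 2L)
})

test_that("reference matches a brute-force oracle on a synthetic set", {
  sim <- small_cohort(seed = 41)
  ref <- fit_control_reference(sim$cells, "NDUFA13", "SDHA")
  ctrl <- sim$cells[sim$cells$group == "control", ]
  lr <- log10(ctrl$NDUFA13 / ctrl$SDHA)
  expect_equal(ref$mean_log_ratio, sum(lr) / length(lr), tolerance = 1e-12)
  expect_equal(ref$sd_log_ratio,
               sqrt(sum((lr - mean(lr))^2) / (length(lr) - 1)),
               tolerance = 1e-12)
})

test_that("z-scores are exact and control cells self-calibrate to N(0,1) moments", {
  ref <- tibble::tibble(region = "Purkinje", target = "NDUFA13",
                        mass = "unity", mean_log_ratio = 2, sd_log_ratio = 0.5,
                        n_cells = 10L)
  class(ref) <- c("mito_reference", class(ref))
  cells <- make_cells(target_density = 10^c(2, 1, 3))  # log-ratios 2,1,3
  rec <- zscore_cells(cells, ref)
  expect_equal(rec$z, c(0, -2, 2))
  sim <- small_cohort(seed = 19)
  ref2 <- fit_control_reference(sim$cells, "NDUFA13", "SDHA")
  rec2 <- zscore_cells(sim$cells, ref2)
  zc <- rec2$z[rec2$group == "control"]
  expect_equal(mean(zc), 0, tolerance = 1e-12)
  expect_equal(sd(zc), 1, tolerance = 1e-12)
})

test_that("classification bins are exclusive, total and as printed", {
  expect_identical(as.character(classify_z(-4.425)), "severely_deficient")
  expect_identical(as.character(classify_z(-1.753)), "normal")
  expect_identical(as.character(classify_z(0)), "normal")
  expect_identical(as.character(classify_z(2.5)), "overexpressed")
  # boundaries fall to the less-severe class
  expect_identical(as.character(classify_z(c(-4, -3, -2, 2))),
                   c("deficient", "low", "normal", "normal"))
  # totality and exclusivity over a sweep
  z <- seq(-6, 4, by = 0.01)
  cl <- classify_z(z)
  expect_false(anyNA(cl))
  counts <- table(cl)
  expect_identical(sum(counts), length(z))
  expect_error(classify_z(NaN), "finite")
})

test_that("deficiency never decreases as target density drops (monotone)", {
  ref <- tibble::tibble(region = "Purkinje", target = "NDUFA13",
                        mass = "SDHA", mean_log_ratio = 0, sd_log_ratio = 0.2,
                        n_cells = 10L)
  class(ref) <- c("mito_reference", class(ref))
  dens <- 10^seq(1, -2, length.out = 40)   # decreasing target, mass fixed
  cells <- make_cells(target_density = dens, mass_density = 10)
  rec <- zscore_cells(cells, ref)
  severity <- as.integer(rec$class)  # level 1 = severely_deficient
  expect_true(all(diff(severity) <= 0))
})

test_that("z-scores are invariant to a common rescaling of both channels", {
  sim <- small_cohort(seed = 23)
  ref_a <- fit_control_reference(sim$cells, "NDUFA13", "SDHA")
  rec_a <- zscore_cells(sim$cells, ref_a)
  scaled <- sim$cells
  scaled$NDUFA13 <- scaled$NDUFA13 * 37.5
  scaled$SDHA <- scaled$SDHA * 37.5
  ref_b <- fit_control_reference(scaled, "NDUFA13", "SDHA")
  rec_b <- zscore_cells(scaled, ref_b)
  expect_equal(rec_a$z, rec_b$z, tolerance = 1e-9)
  expect_identical(as.character(rec_a$class), as.character(rec_b$class))
})

test_that("breakdown aggregation matches a brute-force tally", {
  rec <- tibble::tibble(
    cell_id = sprintf("c%d", 1:4), mouse_id = "m1", group = "knockout",
    region = "DCN", target = "NDUFA13", mass = "SDHA",
    log_ratio = 0, z = c(-5, -3.5, -2.5, 0))
  rec$class <- classify_z(rec$z)
  bd <- aggregate_breakdown(rec)
  expect_equal(bd$percentage[match(c("severely_deficient", "deficient",
                                     "low", "normal", "overexpressed"),
                                   as.character(bd$class))],
               c(25, 25, 25, 25, 0))
  # all normal
  rec2 <- rec; rec2$z <- c(0, 1, -1, 0.5); rec2$class <- classify_z(rec2$z)
  bd2 <- aggregate_breakdown(rec2)
  expect_equal(bd2$percentage[as.character(bd2$class) == "normal"], 100)
  # randomized cohort vs independent tally oracle
  sim <- small_cohort(seed = 29, regions = c("Purkinje", "TRN"))
  ref <- fit_control_reference(sim$cells, "NDUFA13", "SDHA")
  recs <- zscore_cells(sim$cells, ref)
  bd3 <- aggregate_breakdown(recs)
  for (i in sample(nrow(bd3), 20)) {
    row <- bd3[i, ]
    sel <- recs$region == row$region & recs$group == row$group
    oracle <- 100 * sum(as.character(recs$class[sel]) ==
                          as.character(row$class)) / sum(sel)
    expect_equal(row$percentage, oracle)
    expect_identical(row$n_cells, sum(sel))
    expect_identical(row$n_mice,
                     length(unique(recs$mouse_id[sel])))
  }
  # percentages sum to 100 per stratum
  sums <- tapply(bd3$percentage, paste(bd3$region, bd3$group), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("overall reduction and median z summarise records", {
  rec <- tibble::tibble(
    cell_id = sprintf("c%d", 1:4), mouse_id = "m1", group = "ko",
    region = "DCN", target = "N", mass = "S", log_ratio = 0,
    z = c(-5, -2.5, 0, 1), class = classify_z(c(-5, -2.5, 0, 1)))
  expect_equal(overall_reduction_fraction(rec), 0.5)
  expect_equal(overall_reduction_fraction(
    dplyr::mutate(rec, z = c(0, 1, -1, -1.9))), 0)
  # boundary inclusion: z = -2 counts as reduced
  expect_equal(overall_reduction_fraction(dplyr::mutate(rec, z = rep(-2, 4))), 1)
  # identity with the breakdown away from the z = -2 boundary
  sim <- small_cohort(seed = 47)
  recs <- zscore_cells(sim$cells,
                       fit_control_reference(sim$cells, "NDUFA13", "SDHA"))
  bd <- aggregate_breakdown(recs)
  ko <- bd[bd$group == "knockout", ]
  via_classes <- 1 - sum(ko$percentage[as.character(ko$class) %in%
                                         c("normal", "overexpressed")]) / 100
  direct <- overall_reduction_fraction(recs[recs$group == "knockout" &
                                              !recs$z == -2, ])
  expect_equal(direct, via_classes, tolerance = 1e-12)
  # medians: odd and even n, stratified vs sort oracle
  expect_equal(median_z(rec), mean(c(-2.5, 0)))
  expect_equal(median_z(dplyr::slice(rec, 1:3)), -2.5)
  strat <- median_z(recs, group)
  for (g in strat$group) {
    zs <- sort(recs$z[recs$group == g])
    n <- length(zs)
    oracle <- if (n %% 2 == 1) zs[(n + 1) / 2] else mean(zs[n / 2 + 0:1])
    expect_equal(strat$median_z[strat$group == g], oracle)
  }
})
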