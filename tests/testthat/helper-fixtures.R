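# Shared fixture builders for the test suite. All data is generated in
# code; seeds are fixed so runs are reproducible.

# minimal wide cell table with explicit densities (one region unless given)
make_cells <- function(target_density, mass_density = 1,
                       group = "control", region = "Purkinje",
                       mouse_id = "m01", target = "NDUFA13",
                       mass = "SDHA") {
  n <- length(target_density)
  out <- tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(n)),
    mouse_id = rep_len(mouse_id, n),
    group = rep_len(group, n),
    region = rep_len(region, n),
    area_um2 = 250
  )
  out[[target]] <- target_density
  out[[mass]] <- rep_len(mass_density, n)
  out
}

# a small default cohort reused across classification tests
small_cohort <- function(seed = 17, regions = "Purkinje",
                         cells = 30, effects = NULL) {
  d <- cohort_design(regions = regions, cells_per_mouse_per_region = cells,
                     ratios = "NDUFA13:SDHA", seed = seed)
  if (is.null(effects)) effects <- default_region_effects(d)
  sim_cell_table(d, effects)
}

# draw a filled disk into a logical matrix
disk_mask <- function(nrow, ncol, cr, cc, r) {
  m <- matrix(FALSE, nrow, ncol)
  rows <- row(m); cols <- col(m)
  m[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- TRUE
  m
}
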