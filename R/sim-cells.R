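# Synthetic per-cell densitometry tables with the hierarchical structure the
# analysis assumes: mouse-level random intercepts, a shared cell-size factor
# correlating channels, and a two-component mixture in the knockout group
# (an affected subpopulation with the target channel shifted down, the mass
# channel untouched).

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort design for the synthetic cell-table generator
#'
#' Describes the sampling structure: how many mice per group, how many cells
#' per mouse in each region, which regions, and which target/mass marker
#' ratios are measured. Defaults follow the quadruple-immunofluorescence
#' panel design of the knockout study this package models: 6 knockout vs 3
#' control mice, ~45 cells per mouse per region (276 knockout Purkinje
#' neurons from 6 mice), complex I and IV subunits (NDUFA13, COXIV)
#' normalised to the mass marker SDHA.
#'
#' @param n_control_mice,n_knockout_mice Mice per group (>= 1).
#' @param cells_per_mouse_per_region Cells sampled per mouse per region.
#' @param regions Character vector of unique region labels.
#' @param ratios Data frame with columns `target`, `mass` (one row per
#'   measured ratio), or a character vector like `"NDUFA13:SDHA"`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_control_mice = 3L,
                          n_knockout_mice = 6L,
                          cells_per_mouse_per_region = 45L,
                          regions = c("Purkinje", "TRN", "cerebellar_ML",
                                      "DCN", "cortex", "hippocampus"),
                          ratios = c("NDUFA13:SDHA", "COXIV:SDHA"),
                          seed = 1L) {
  if (is.character(ratios)) {
    parts <- strsplit(ratios, ":", fixed = TRUE)
    if (any(lengths(parts) != 2L)) abort("ratios strings must be 'TARGET:MASS'")
    ratios <- tibble(target = vapply(parts, `[[`, "", 1L),
                     mass = vapply(parts, `[[`, "", 2L))
  }
  ratios <- as_tibble(ratios)
  stopifnot(all(c("target", "mass") %in% names(ratios)))
  counts <- c(n_control_mice, n_knockout_mice, cells_per_mouse_per_region)
  if (any(counts < 1L)) abort("all design counts must be >= 1")
  if (anyDuplicated(regions)) abort("region labels must be unique")
  structure(
    list(n_control_mice = as.integer(n_control_mice),
         n_knockout_mice = as.integer(n_knockout_mice),
         cells_per_mouse_per_region = as.integer(cells_per_mouse_per_region),
         regions = as.character(regions),
         ratios = ratios,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Region-specific deficiency effects for the knockout group
#'
#' One row per (region, ratio): the fraction of knockout cells in the
#' affected (deficient) mixture component, the mean downward shift of their
#' log10 target/mass ratio in units of the control log-ratio SD, and the
#' between-mouse and within-mouse SDs of the log10 ratio.
#'
#' `default_region_effects()` returns presets named after the study's
#' regions with monotonically decreasing affected fractions (Purkinje worst,
#' hippocampus mildest) and a severe shift of -4.5 control SDs; the numbers
#' are illustrative generator knobs emulating the region-dependent
#' deficiency hierarchy, not measured constants.
#'
#' @param region,target,mass Labels (vectorised).
#' @param affected_fraction Proportion in \[0, 1\].
#' @param deficiency_shift Mean log-ratio shift of affected cells, in
#'   control-SD units (negative = deficient).
#' @param mouse_sd Between-mouse SD of the log10 ratio (>= 0).
#' @param cell_sd Within-mouse SD of the log10 ratio (> 0).
#' @return A tibble of effects.
#' @export
region_effect <- function(region, target, mass,
                          affected_fraction,
                          deficiency_shift = -4.5,
                          mouse_sd = 0.5 * cell_sd,
                          cell_sd = 0.15) {
  out <- tibble(region = region, target = target, mass = mass,
                affected_fraction = affected_fraction,
                deficiency_shift = deficiency_shift,
                mouse_sd = mouse_sd, cell_sd = cell_sd)
  if (any(out$cell_sd <= 0)) abort("cell_sd must be > 0")
  if (any(out$mouse_sd < 0)) abort("mouse_sd must be >= 0")
  if (any(out$affected_fraction < 0 | out$affected_fraction > 1)) {
    abort("affected_fraction must be in [0, 1]")
  }
  out
}

#' @rdname region_effect
#' @param design A [cohort_design()].
#' @export
default_region_effects <- function(design) {
  fractions <- c(Purkinje = 0.97, TRN = 0.90, cerebellar_ML = 0.75,
                 DCN = 0.55, cortex = 0.30, hippocampus = 0.20)
  grid <- tidyr::expand_grid(region = design$regions, design$ratios)
  f <- unname(fractions[grid$region])
  f[is.na(f)] <- 0.5
  region_effect(grid$region, grid$target, grid$mass, affected_fraction = f)
}

#' Generate a synthetic per-cell measurement table with ground truth
#'
#' Draws per-cell log10 densities for every marker in the design. Control
#' cells: baseline + mouse random intercept + shared cell-size factor +
#' cell-level noise per channel. Knockout cells are a two-component mixture:
#' with probability `affected_fraction` a cell's target-channel log density
#' is shifted down by `deficiency_shift` control-SDs of the log ratio, the
#' mass channel is untouched. Affected status is nested across ratios via a
#' shared per-cell uniform, so a cell affected for a mildly-hit ratio is
#' also affected for severely-hit ones (deficiencies in complexes I and IV
#' co-occur in the same cells).
#'
#' @param design A [cohort_design()].
#' @param effects Tibble from [region_effect()]; must cover every
#'   (region, ratio) in the design. Defaults to [default_region_effects()].
#' @param baseline_log10 Baseline log10 density shared by all markers
#'   (arbitrary fluorescence units per µm²).
#' @param size_sd SD of the shared log10 cell-size factor.
#' @param mean_area_um2,area_sd_um2 Cell soma area distribution (truncated
#'   normal, µm²).
#' @return A list with `cells` (wide tibble: cell_id, mouse_id, group,
#'   region, area_um2, one density column per marker) and `truth` (long
#'   tibble per cell x ratio: affected flag, true log10 ratio).
#' @examples
#' d <- cohort_design(regions = "Purkinje", cells_per_mouse_per_region = 10)
#' sim <- sim_cell_table(d)
#' head(sim$cells)
#' @export
sim_cell_table <- function(design,
                           effects = default_region_effects(design),
                           baseline_log10 = 2,
                           size_sd = 0.1,
                           mean_area_um2 = 250,
                           area_sd_um2 = 50) {
  stopifnot(inherits(design, "cohort_design"))
  effects <- as_tibble(effects)
  need <- tidyr::expand_grid(region = design$regions, design$ratios)
  missing <- dplyr::anti_join(need, effects, by = c("region", "target", "mass"))
  if (nrow(missing) > 0L) {
    abort(paste0("missing effect entry for (region, ratio): ",
                 paste(sprintf("%s %s:%s", missing$region, missing$target,
                               missing$mass), collapse = "; ")))
  }

  with_seed(design$seed, {
    mice <- tibble(
      mouse_id = c(sprintf("ctrl_m%02d", seq_len(design$n_control_mice)),
                   sprintf("ko_m%02d", seq_len(design$n_knockout_mice))),
      group = rep(c("control", "knockout"),
                  c(design$n_control_mice, design$n_knockout_mice))
    )
    markers <- unique(c(design$ratios$target, design$ratios$mass))

    cells <- tidyr::expand_grid(mice, region = design$regions) |>
      group_by(.data$mouse_id, .data$region) |>
      tidyr::uncount(design$cells_per_mouse_per_region) |>
      ungroup() |>
      mutate(cell_id = sprintf("cell_%05d", dplyr::row_number()),
             area_um2 = pmax(50, rnorm(n(), mean_area_um2, area_sd_um2)),
             size_factor = rnorm(n(), 0, size_sd),
             u_affected = runif(n()))

    # the mass channel is drawn once per (cell, mass marker) so that ratios
    # sharing a denominator stay consistent; its own noise/mouse terms only
    # shape raw-channel realism, the classifier sees the log-ratio model
    mass_sd <- 0.1
    masses <- unique(design$ratios$mass)
    mouse_mass <- tidyr::expand_grid(mouse_id = mice$mouse_id, mass = masses) |>
      mutate(mouse_mass_eff = rnorm(n(), 0, mass_sd / 2))
    mass_draws <- tidyr::expand_grid(
      cells |> select("cell_id", "mouse_id", "size_factor"),
      mass = masses
    ) |>
      left_join(mouse_mass, by = c("mouse_id", "mass")) |>
      mutate(log_mass = baseline_log10 + .data$size_factor +
               .data$mouse_mass_eff + rnorm(n(), 0, mass_sd)) |>
      select("cell_id", "mass", "log_mass")

    # per-mouse random intercepts on the log-ratio scale, one per ratio
    mouse_ratio <- tidyr::expand_grid(mouse_id = mice$mouse_id, effects) |>
      mutate(mouse_lr = rnorm(n(), 0, .data$mouse_sd))

    per_ratio <- cells |>
      tidyr::expand_grid(design$ratios) |>
      left_join(mouse_ratio,
                by = c("mouse_id", "region", "target", "mass")) |>
      left_join(mass_draws, by = c("cell_id", "mass")) |>
      mutate(
        sigma_ref = sqrt(.data$mouse_sd^2 + .data$cell_sd^2),
        affected = .data$group == "knockout" &
          .data$u_affected < .data$affected_fraction,
        log_ratio = rnorm(n(), 0, .data$cell_sd) + .data$mouse_lr +
          ifelse(.data$affected, .data$deficiency_shift * .data$sigma_ref, 0),
        log_target = .data$log_mass + .data$log_ratio
      )

    # assemble wide marker columns (a target reused across panels keeps its
    # first draw)
    dens <- bind_rows(
      per_ratio |> select("cell_id", marker = "target", value = "log_target"),
      per_ratio |> select("cell_id", marker = "mass", value = "log_mass")
    ) |>
      distinct(.data$cell_id, .data$marker, .keep_all = TRUE) |>
      mutate(value = 10^.data$value) |>
      tidyr::pivot_wider(names_from = "marker", values_from = "value")

    cells_out <- cells |>
      select("cell_id", "mouse_id", "group", "region", "area_um2") |>
      left_join(dens, by = "cell_id")

    truth <- per_ratio |>
      select("cell_id", "mouse_id", "group", "region", "target", "mass",
             "affected", true_log_ratio = "log_ratio")

    list(cells = cells_out, truth = truth)
  })
}
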