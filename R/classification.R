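# The core computation: control-referenced z-scores of log10
# mitochondrial-protein / mass-marker ratios and the five-class deficiency
# assignment, with region x group class-breakdown surfaces.
#
# Transform order: z-scores are computed on log10(target/mass). This makes
# them invariant to any common rescaling of both channels (acquisition
# gain), which z-scores of a ratio of separately-logged densities would not
# be. The alternative (difference of logs) is algebraically identical.

DEFICIENCY_CLASSES <- c("severely_deficient", "deficient", "low",
                        "normal", "overexpressed")

#' Classify a z-score into the five deficiency classes
#'
#' SD-limit bins on the control-referenced z-score of the log10 ratio:
#' overexpressed if z > 2; normal if -2 <= z <= 2; low if -3 <= z < -2;
#' deficient if -4 <= z < -3; severely deficient if z < -4. Bins are
#' exclusive and total; boundary values fall to the less-severe class.
#'
#' @param z Numeric vector of finite z-scores.
#' @return Factor with levels severely_deficient, deficient, low, normal,
#'   overexpressed.
#' @examples
#' classify_z(c(-4.425, -1.753, 0, 2.5))
#' @export
classify_z <- function(z) {
  if (any(!is.finite(z))) abort("z-scores must be finite")
  cls <- dplyr::case_when(
    z < -4 ~ "severely_deficient",
    z < -3 ~ "deficient",
    z < -2 ~ "low",
    z <= 2 ~ "normal",
    TRUE   ~ "overexpressed"
  )
  factor(cls, levels = DEFICIENCY_CLASSES)
}

.log_ratio <- function(cells, target, mass) {
  if (!target %in% names(cells)) abort(sprintf("no '%s' column in cells", target))
  mass_v <- if (identical(mass, "unity")) rep(1, nrow(cells)) else {
    if (!mass %in% names(cells)) abort(sprintf("no '%s' column in cells", mass))
    cells[[mass]]
  }
  t_v <- cells[[target]]
  usable <- is.finite(t_v) & is.finite(mass_v) & t_v > 0 & mass_v > 0
  lr <- rep(NA_real_, length(t_v))
  lr[usable] <- log10(t_v[usable] / mass_v[usable])
  list(log_ratio = lr, usable = usable)
}

#' Fit the control reference for a target/mass ratio
#'
#' Per region, the sample mean and SD (n-1 denominator) of
#' log10(target/mass) over pooled control cells — the calibration the
#' z-score classifier is referenced against. Cells with non-positive or
#' missing density in either channel are excluded and their count reported
#' via a message.
#'
#' @param cells Measurement tibble with `group`, `region` and marker
#'   density columns.
#' @param target,mass Marker column names; `mass = "unity"` scores the raw
#'   (unnormalised) target channel.
#' @param control_label Value of `group` identifying control cells.
#' @return Tibble (class `mito_reference`): `region`, `target`, `mass`,
#'   `mean_log_ratio`, `sd_log_ratio`, `n_cells`.
#' @export
fit_control_reference <- function(cells, target, mass = "unity",
                                  control_label = "control") {
  ctrl <- cells |> filter(.data$group == control_label)
  if (nrow(ctrl) == 0L) abort("no control cells found")
  lr <- .log_ratio(ctrl, target, mass)
  n_excluded <- sum(!lr$usable)
  if (n_excluded > 0L) {
    inform(sprintf(
      "fit_control_reference: excluded %d control cell(s) with non-positive density",
      n_excluded))
  }
  ref <- ctrl |>
    mutate(.lr = lr$log_ratio, .ok = lr$usable) |>
    filter(.data$.ok) |>
    group_by(.data$region) |>
    summarise(mean_log_ratio = mean(.data$.lr),
              sd_log_ratio = sd(.data$.lr),
              n_cells = n(), .groups = "drop") |>
    mutate(target = target, mass = mass) |>
    select("region", "target", "mass", "mean_log_ratio", "sd_log_ratio",
           "n_cells")
  bad <- ref |> filter(.data$n_cells < 2L)
  missing_regions <- setdiff(unique(ctrl$region), ref$region)
  if (nrow(bad) > 0L || length(missing_regions) > 0L) {
    abort(paste0("control reference needs >= 2 usable cells per region; ",
                 "failing regions: ",
                 paste(c(bad$region, missing_regions), collapse = ", ")))
  }
  class(ref) <- c("mito_reference", class(ref))
  ref
}

#' Score cells against a control reference
#'
#' z = (log10(target/mass) - reference mean) / reference SD, applied to
#' cells of both groups (control cells are scored against their own pooled
#' reference), then binned with [classify_z()]. Cells with non-positive
#' density in either channel are excluded with a message.
#'
#' @param cells Measurement tibble.
#' @param reference A `mito_reference` from [fit_control_reference()]
#'   matching the ratio.
#' @return z-score record tibble: `cell_id`, `mouse_id`, `group`, `region`,
#'   `target`, `mass`, `log_ratio`, `z`, `class`.
#' @export
zscore_cells <- function(cells, reference) {
  stopifnot(inherits(reference, "mito_reference"))
  target <- reference$target[1L]
  mass <- reference$mass[1L]
  lr <- .log_ratio(cells, target, mass)
  n_excluded <- sum(!lr$usable)
  if (n_excluded > 0L) {
    inform(sprintf("zscore_cells: excluded %d cell(s) with non-positive density",
                   n_excluded))
  }
  scored <- cells |>
    mutate(log_ratio = lr$log_ratio, .ok = lr$usable) |>
    filter(.data$.ok) |>
    left_join(reference |> select("region", "mean_log_ratio", "sd_log_ratio"),
              by = "region")
  if (anyNA(scored$mean_log_ratio)) {
    abort(paste0("no reference for region(s): ",
                 paste(unique(scored$region[is.na(scored$mean_log_ratio)]),
                       collapse = ", ")))
  }
  scored |>
    mutate(z = (.data$log_ratio - .data$mean_log_ratio) / .data$sd_log_ratio,
           class = classify_z(.data$z),
           target = target, mass = mass) |>
    select(dplyr::any_of(c("cell_id", "mouse_id", "group", "region")),
           "target", "mass", "log_ratio", "z", "class")
}

#' Region x group x ratio class breakdown
#'
#' The stacked-bar surface: for every (region, group, target/mass ratio),
#' the percentage of cells in each of the five deficiency classes, with
#' cell and mouse counts. Percentages sum to 100 per stratum.
#'
#' @param records z-score record tibble from [zscore_cells()].
#' @return Tibble (class `mito_breakdown`): `region`, `group`, `target`,
#'   `mass`, `class`, `n`, `percentage`, `n_cells`, `n_mice` (long form,
#'   all five classes present per stratum, zero-filled).
#' @export
aggregate_breakdown <- function(records) {
  if (nrow(records) == 0L) abort("no z-score records to aggregate")
  sizes <- records |>
    group_by(.data$region, .data$group, .data$target, .data$mass) |>
    summarise(n_cells = n(), n_mice = n_distinct(.data$mouse_id),
              .groups = "drop")
  out <- records |>
    mutate(class = factor(.data$class, levels = DEFICIENCY_CLASSES)) |>
    count(.data$region, .data$group, .data$target, .data$mass, .data$class) |>
    group_by(.data$region, .data$group, .data$target, .data$mass) |>
    tidyr::complete(class = factor(DEFICIENCY_CLASSES,
                                   levels = DEFICIENCY_CLASSES),
                    fill = list(n = 0L)) |>
    ungroup() |>
    left_join(sizes, by = c("region", "group", "target", "mass")) |>
    mutate(percentage = 100 * .data$n / .data$n_cells) |>
    arrange(.data$region, .data$group, .data$target, .data$mass, .data$class)
  class(out) <- c("mito_breakdown", class(out))
  out
}

#' Fraction of cells with overall reduction (z <= -2)
#'
#' The "combined overall reduction" summary: the fraction of cells whose
#' z-score is at or below -2 (inclusive, so the low + deficient + severely
#' deficient mass plus the boundary point).
#'
#' @param records z-score record tibble.
#' @param ... Optional grouping columns (unquoted), e.g. `region, group`.
#' @return With grouping: a tibble with `fraction` and `n_cells` per
#'   stratum; without: a single proportion.
#' @export
overall_reduction_fraction <- function(records, ...) {
  if (nrow(records) == 0L) abort("no z-score records")
  dots <- rlang::enquos(...)
  if (length(dots) == 0L) return(mean(records$z <= -2))
  records |>
    group_by(!!!dots) |>
    summarise(fraction = mean(.data$z <= -2), n_cells = n(),
              .groups = "drop")
}

#' Median z-score within strata
#'
#' Sample median (even n: mean of the central pair) of z within each
#' stratum, e.g. Purkinje somata vs GAD+ terminals.
#'
#' @param records z-score record tibble.
#' @param ... Optional grouping columns (unquoted).
#' @return With grouping: tibble with `median_z` and `n_cells`; without: a
#'   single number.
#' @export
median_z <- function(records, ...) {
  if (nrow(records) == 0L) abort("no z-score records")
  dots <- rlang::enquos(...)
  if (length(dots) == 0L) return(median(records$z))
  records |>
    group_by(!!!dots) |>
    summarise(median_z = median(.data$z), n_cells = n(), .groups = "drop")
}
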