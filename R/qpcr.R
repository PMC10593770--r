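# Absolute mtDNA copy-number quantification: standard-curve least squares,
# inverse prediction from mean replicate Cq, and normalisation to the
# cumulative dissected cell area.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over the standard dilution
#' series: Cq = intercept + slope * log10(copies). Amplification efficiency
#' is 10^(-1/slope) - 1 (1.0 = perfect doubling, slope -1/log10(2) ≈
#' -3.3219).
#'
#' @param standards Data frame with columns `known_copies` (> 0) and `cq`,
#'   one row per standard well (replicates included as rows).
#' @return Object of class `standard_curve`: list with `intercept`,
#'   `slope`, `r_squared`, `efficiency`, `n_points`, `fit` (the lm).
#' @examples
#' std <- data.frame(known_copies = 10^(2:6),
#'                   cq = 40 - 1 / log10(2) * (2:6))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standards) {
  standards <- as_tibble(standards)
  stopifnot(all(c("known_copies", "cq") %in% names(standards)))
  standards <- standards |>
    filter(is.finite(.data$cq), is.finite(.data$known_copies))
  if (any(standards$known_copies <= 0)) abort("standard copies must be > 0")
  if (n_distinct(standards$known_copies) < 3L) {
    abort("need >= 3 distinct standard concentrations")
  }
  fit <- lm(cq ~ log10(known_copies), data = standards)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) abort("assay failure: standard-curve slope is not negative")
  structure(
    list(intercept = unname(coef(fit)[1L]),
         slope = slope,
         # exact standards trip summary.lm's perfect-fit warning; harmless here
         r_squared = suppressWarnings(summary(fit)$r.squared),
         efficiency = 10^(-1 / slope) - 1,
         n_points = nrow(standards),
         fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.3f %+.4f * log10(copies)  (r² = %.4f, eff = %.1f%%, n = %d)\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency, x$n_points))
  invisible(x)
}

#' Absolute copies from Cq via inverse prediction
#'
#' copies = 10^((cq - intercept) / slope). Vectorised; monotone decreasing
#' in Cq.
#'
#' @param cq Numeric Cq values.
#' @param curve A [fit_standard_curve()] object.
#' @return Copy numbers.
#' @export
quantify_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Quantify a qPCR plate
#'
#' Fits the standard curve from the plate's `standard` wells, averages each
#' sample's replicate Cqs on the Cq scale, inverse-predicts absolute copies
#' and (when `area_um2` is present) normalises to the cumulative dissected
#' area. Undetermined (NA) Cqs within a sample triplicate are dropped when
#' at least `min_replicates` remain, otherwise the sample is flagged
#' unquantifiable. NTC wells with a detectable Cq raise a QC warning.
#'
#' @param plate Plate tibble as from [sim_qpcr_plate()] (`well`, `role`,
#'   `sample_id`, `cq`, `known_copies`, `area_um2`).
#' @param min_replicates Minimum usable replicates per sample (default 2).
#' @return List: `curve` (the [fit_standard_curve()] object) and `samples`
#'   tibble (`sample_id`, `n_replicates`, `mean_cq`, `cq_cv`, `copies`,
#'   `area_um2`, `copies_per_um2`, `quantifiable`).
#' @export
quantify_plate <- function(plate, min_replicates = 2L) {
  plate <- as_tibble(plate)
  stopifnot(all(c("role", "sample_id", "cq") %in% names(plate)))
  ntc <- plate |> filter(.data$role == "ntc")
  if (any(is.finite(ntc$cq))) {
    warn(sprintf("QC: %d no-template well(s) show amplification",
                 sum(is.finite(ntc$cq))))
  }
  curve <- fit_standard_curve(plate |> filter(.data$role == "standard"))
  samples <- plate |>
    filter(.data$role == "sample") |>
    group_by(.data$sample_id) |>
    summarise(
      n_replicates = sum(is.finite(.data$cq)),
      mean_cq = mean(.data$cq[is.finite(.data$cq)]),
      cq_cv = sd(.data$cq[is.finite(.data$cq)]) /
        mean(.data$cq[is.finite(.data$cq)]),
      area_um2 = .data$area_um2[1L],
      .groups = "drop") |>
    mutate(
      quantifiable = .data$n_replicates >= min_replicates,
      copies = ifelse(.data$quantifiable,
                      quantify_copies(.data$mean_cq, curve), NA_real_),
      copies_per_um2 = ifelse(is.finite(.data$area_um2),
                              normalize_to_area(.data$copies, .data$area_um2),
                              NA_real_)
    ) |>
    select("sample_id", "n_replicates", "mean_cq", "cq_cv", "copies",
           "area_um2", "copies_per_um2", "quantifiable")
  list(curve = curve, samples = samples)
}

#' Normalise copies to cumulative dissected area
#'
#' @param copies Absolute copy numbers.
#' @param cumulative_area_um2 Cumulative surface area of the pooled
#'   dissected cells (µm², > 0).
#' @return Copies per µm².
#' @export
normalize_to_area <- function(copies, cumulative_area_um2) {
  if (any(cumulative_area_um2 <= 0, na.rm = TRUE)) {
    abort("`cumulative_area_um2` must be > 0")
  }
  copies / cumulative_area_um2
}
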