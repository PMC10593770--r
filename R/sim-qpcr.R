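# Synthetic qPCR plates from a log-linear standard model, emulating
# absolute mtDNA copy-number quantification of laser-captured Purkinje cell
# pools: Cq = intercept + slope * log10(copies) + noise, standards and
# samples in triplicate, no-template controls without Cq.

#' Simulate a qPCR plate
#'
#' @param true_copies Numeric vector of true template copies per sample
#'   (> 0). Names, if present, become sample ids.
#' @param curve Length-2 numeric `c(intercept, slope)` of the Cq model;
#'   slope must be negative. The default slope `-1/log10(2)` is a perfect
#'   doubling assay.
#' @param noise_sd Gaussian Cq noise SD (cycles).
#' @param standards Known copy numbers of the standard dilution series.
#' @param n_replicates Wells per sample/standard/NTC group.
#' @param areas_um2 Optional cumulative dissected area per sample (µm²),
#'   carried into the plate table for downstream normalisation.
#' @param target Assay label stored in the table (documentation only).
#' @param seed Optional seed (local to this call).
#' @return Plate tibble: `well`, `role` (standard/sample/ntc), `sample_id`,
#'   `target`, `cq` (NA for NTC), `known_copies` (standards only),
#'   `area_um2` (samples only).
#' @examples
#' sim_qpcr_plate(c(A = 100), noise_sd = 0)
#' @export
sim_qpcr_plate <- function(true_copies,
                           curve = c(intercept = 40, slope = -1 / log10(2)),
                           noise_sd = 0.15,
                           standards = 10^(2:7),
                           n_replicates = 3L,
                           areas_um2 = NULL,
                           target = "MT-ND5",
                           seed = NULL) {
  if (length(curve) != 2L || curve[2L] >= 0) {
    abort("`curve` must be c(intercept, slope) with slope < 0")
  }
  if (any(true_copies <= 0) || any(standards <= 0)) {
    abort("copy numbers must be > 0")
  }
  ids <- names(true_copies) %||% sprintf("sample_%02d", seq_along(true_copies))
  if (!is.null(areas_um2) && length(areas_um2) != length(true_copies)) {
    abort("`areas_um2` must match `true_copies` in length")
  }
  with_seed(seed, {
    grp <- bind_rows(
      tibble(role = "standard", sample_id = sprintf("std_%02d", seq_along(standards)),
             copies = as.numeric(standards), area_um2 = NA_real_),
      tibble(role = "sample", sample_id = ids, copies = as.numeric(true_copies),
             area_um2 = if (is.null(areas_um2)) NA_real_ else as.numeric(areas_um2)),
      tibble(role = "ntc", sample_id = "NTC", copies = NA_real_,
             area_um2 = NA_real_)
    )
    plate <- grp |>
      tidyr::uncount(n_replicates) |>
      mutate(
        well = sprintf("w%03d", dplyr::row_number()),
        target = target,
        cq = ifelse(.data$role == "ntc", NA_real_,
                    curve[1L] + curve[2L] * log10(.data$copies) +
                      rnorm(n(), 0, noise_sd)),
        known_copies = ifelse(.data$role == "standard", .data$copies, NA_real_)
      ) |>
      select("well", "role", "sample_id", "target", "cq", "known_copies",
             "area_um2")
    plate
  })
}
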