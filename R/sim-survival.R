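# Synthetic survival cohorts emulating the knockout lifespan endpoint
# (median survival 94 days in the modelled study).

#' Simulate a survival cohort
#'
#' Event times are exponential (default) or Weibull, scaled so the
#' theoretical median equals `median_days`; times beyond `censor_day` are
#' administratively censored at it. `fixed_day` replaces the draw with a
#' deterministic "all die at day d" cohort, useful as a degenerate check.
#'
#' @param n Number of animals.
#' @param median_days Theoretical median survival (> 0).
#' @param censor_day Administrative censoring time (default `Inf`: none).
#' @param shape Weibull shape; `NULL` or 1 gives exponential.
#' @param group Group label stored in the table.
#' @param fixed_day If non-NULL, all animals die at this day exactly.
#' @param seed Optional seed (local to this call).
#' @return Tibble: `id`, `group`, `days`, `event` (1 = death, 0 = censored).
#' @examples
#' sim_survival(12, median_days = 94, seed = 1)
#' @export
sim_survival <- function(n, median_days = 94, censor_day = Inf,
                         shape = NULL, group = "knockout",
                         fixed_day = NULL, seed = NULL) {
  if (median_days <= 0) abort("`median_days` must be > 0")
  with_seed(seed, {
    if (!is.null(fixed_day)) {
      t_raw <- rep(fixed_day, n)
    } else if (is.null(shape) || shape == 1) {
      t_raw <- rexp(n, rate = log(2) / median_days)
    } else {
      t_raw <- stats::rweibull(n, shape = shape,
                               scale = median_days / log(2)^(1 / shape))
    }
    tibble(
      id = sprintf("%s_%03d", group, seq_len(n)),
      group = group,
      days = pmin(t_raw, censor_day),
      event = as.integer(t_raw <= censor_day)
    )
  })
}
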