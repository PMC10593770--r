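# Behavioural indices and small descriptive helpers.

#' Novel-object discrimination index
#'
#' (t_novel - t_familiar) / (t_novel + t_familiar): the difference in time
#' spent exploring the novel and familiar objects divided by the total
#' exploration time. Ranges over \[-1, 1\]; 0 means no preference.
#'
#' @param t_novel,t_familiar Exploration times (seconds); their sum must be
#'   positive. Vectorised.
#' @return Index in \[-1, 1\].
#' @examples
#' discrimination_index(3, 1)  # 0.5
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  if (any(t_novel + t_familiar <= 0)) abort("total exploration time must be > 0")
  (t_novel - t_familiar) / (t_novel + t_familiar)
}

#' Elevated-plus-maze open-arm entry percentage
#'
#' @param open,closed Entry counts; total must be positive. Vectorised.
#' @return Percentage of entries into open arms.
#' @examples
#' open_arm_percentage(5, 5)  # 50
#' @export
open_arm_percentage <- function(open, closed) {
  if (any(open + closed <= 0)) abort("total entries must be > 0")
  100 * open / (open + closed)
}

#' Percent change from control to test
#'
#' 100 * (control - test) / control: positive values are reductions
#' relative to control.
#'
#' @param control,test Values; `control` must be nonzero. Vectorised.
#' @return Percent change.
#' @examples
#' percent_change(35.8, 28.5)  # ~20.4
#' @export
percent_change <- function(control, test) {
  if (any(control == 0)) abort("`control` must be nonzero")
  100 * (control - test) / control
}

#' Mean event rate across independent raters
#'
#' Each rater's count over the common observation window, averaged over
#' raters: `mean(counts / duration_min)`.
#'
#' @param counts Event counts, one per rater (>= 1 rater).
#' @param duration_min Observation duration in minutes (> 0).
#' @return Events per minute.
#' @examples
#' rater_mean_rate(c(10, 14), 10)  # 1.2
#' @export
rater_mean_rate <- function(counts, duration_min) {
  if (length(counts) < 1L) abort("need >= 1 rater")
  if (duration_min <= 0) abort("`duration_min` must be > 0")
  mean(counts / duration_min)
}
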