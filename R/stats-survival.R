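# Kaplan-Meier survival and the Mantel-Cox log-rank comparison, via the
# survival package behind this module's tabular surface.

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator per group; the median is the earliest time at
#' which S(t) <= 0.5 (NA when never reached, e.g. all censored); two-group
#' Mantel-Cox log-rank chi-square when two groups are present.
#'
#' @param data Survival table with columns `days` (> 0), `event` (1 death,
#'   0 censored) and `group`.
#' @return Object of class `mito_km`: list with `curves` (tibble: `group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `medians` (tibble: `group`,
#'   `median_days`, `n`, `n_events`), `logrank_chisq`, `logrank_p` (NA
#'   unless exactly two groups).
#' @export
km_logrank <- function(data) {
  stopifnot(all(c("days", "event", "group") %in% names(data)))
  if (any(data$days <= 0)) abort("`days` must be > 0")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1")
  data <- as_tibble(data) |> mutate(group = as.character(.data$group))
  sf <- survival::survfit(survival::Surv(days, event) ~ group, data = data)
  smry <- summary(sf)
  strata <- if (is.null(smry$strata)) {
    rep(unique(data$group), length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  curves <- tibble(group = strata, time = smry$time, n_risk = smry$n.risk,
                   n_event = smry$n.event, surv = smry$surv)
  med_tab <- summary(sf)$table
  if (is.null(dim(med_tab))) med_tab <- t(as.matrix(med_tab))
  medians <- tibble(
    group = sub("^group=", "", rownames(med_tab) %||% unique(data$group)),
    median_days = unname(med_tab[, "median"]),
    n = unname(med_tab[, "records"]),
    n_events = unname(med_tab[, "events"])
  )
  lr_chisq <- NA_real_; lr_p <- NA_real_
  if (n_distinct(data$group) == 2L) {
    sd2 <- survival::survdiff(survival::Surv(days, event) ~ group, data = data)
    lr_chisq <- sd2$chisq
    lr_p <- stats::pchisq(sd2$chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, medians = medians,
                 logrank_chisq = lr_chisq, logrank_p = lr_p),
            class = "mito_km")
}

#' @export
print.mito_km <- function(x, ...) {
  cat("<mito_km>\n")
  for (i in seq_len(nrow(x$medians))) {
    cat(sprintf("  %s: median %s days (%d/%d events)\n",
                x$medians$group[i],
                format(x$medians$median_days[i]),
                x$medians$n_events[i], x$medians$n[i]))
  }
  if (is.finite(x$logrank_chisq)) {
    cat(sprintf("  log-rank chi-sq = %.3f, p = %.4g\n",
                x$logrank_chisq, x$logrank_p))
  }
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `mito_km` object.
#' @param ... Unused.
#' @export
tidy.mito_km <- function(x, ...) x$curves

#' @rdname km_logrank
#' @export
glance.mito_km <- function(x, ...) {
  out <- x$medians |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("median_days", "n", "n_events"))
  out$logrank_chisq <- x$logrank_chisq
  out$logrank_p <- x$logrank_p
  out
}

#' Step-function survival plot
#'
#' @param object A `mito_km` object.
#' @param ... Unused.
#' @return A ggplot: Kaplan-Meier step curves per group.
#' @export
autoplot.mito_km <- function(object, ...) {
  d <- object$curves |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, surv = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
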