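# Cell-in-animal inference: linear mixed-effects model with the group as a
# fixed effect and the mouse/case as a random intercept, fitted by REML via
# nlme (the framework the modelled study used). The fixed-effect p-value
# uses nlme's containment (between-cluster) degrees of freedom, which is
# what keeps per-cell pseudo-replication from inflating significance.

#' Mixed-model group comparison of cell-level values
#'
#' Fits `value ~ group` with a random intercept per cluster (mouse or
#' case). `method = "reml"` (default) reports the group-contrast t-test on
#' between-cluster df; `method = "lrt"` refits by ML and reports the
#' likelihood-ratio chi-square against the no-group model. A singular fit
#' (cluster variance collapsing to ~0) is reported via the `singular`
#' flag, not an error. A Shapiro-Wilk p-value on the within-cluster
#' residuals is attached as a diagnostic.
#'
#' @param data Data frame of cell-level observations.
#' @param value,group,cluster Column names (strings).
#' @param method `"reml"` or `"lrt"`.
#' @return Object of class `mito_lmm`: list with `estimate` (group
#'   contrast, second level minus first), `se`, `df`, `statistic`,
#'   `p_value`, `ranef_sd`, `resid_sd`, `n_obs`, `n_clusters`, `singular`,
#'   `resid_shapiro_p`, `group_levels`, `method`, `fit`.
#' @export
lmm_group_test <- function(data, value, group, cluster,
                           method = c("reml", "lrt")) {
  method <- match.arg(method)
  d <- tibble(value = data[[value]],
              group = factor(data[[group]]),
              cluster = factor(data[[cluster]]))
  d <- d[complete.cases(d) & is.finite(d$value), ]
  d$group <- droplevels(d$group); d$cluster <- droplevels(d$cluster)
  if (nlevels(d$group) != 2L) abort("`group` must have exactly 2 levels")
  per_group <- d |> distinct(.data$group, .data$cluster) |> count(.data$group)
  if (any(per_group$n < 2L)) abort("need >= 2 clusters per group")
  fit <- nlme::lme(value ~ group, random = ~ 1 | cluster, data = d,
                   method = "REML")
  tt <- summary(fit)$tTable
  vc <- nlme::VarCorr(fit)
  ranef_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  resid_sd <- fit$sigma
  singular <- is.finite(ranef_sd) && ranef_sd < 1e-4 * resid_sd
  res <- stats::resid(fit, type = "pearson")
  shap <- if (length(res) >= 3L && length(res) <= 5000L && sd(res) > 0) {
    shapiro.test(res)$p.value
  } else NA_real_
  out <- list(
    estimate = unname(tt[2L, "Value"]),
    se = unname(tt[2L, "Std.Error"]),
    df = unname(tt[2L, "DF"]),
    statistic = unname(tt[2L, "t-value"]),
    p_value = unname(tt[2L, "p-value"]),
    ranef_sd = ranef_sd,
    resid_sd = resid_sd,
    n_obs = nrow(d),
    n_clusters = nlevels(d$cluster),
    singular = singular,
    resid_shapiro_p = shap,
    group_levels = levels(d$group),
    method = method,
    fit = fit
  )
  if (method == "lrt") {
    full_ml <- nlme::lme(value ~ group, random = ~ 1 | cluster, data = d,
                         method = "ML")
    null_ml <- nlme::lme(value ~ 1, random = ~ 1 | cluster, data = d,
                         method = "ML")
    lr <- 2 * (stats::logLik(full_ml) - stats::logLik(null_ml))
    out$statistic <- as.numeric(lr)
    out$df <- 1
    out$p_value <- stats::pchisq(as.numeric(lr), df = 1, lower.tail = FALSE)
  }
  structure(out, class = "mito_lmm")
}

#' @export
print.mito_lmm <- function(x, ...) {
  cat(sprintf(
    "<mito_lmm> %s vs %s: estimate %.4g (SE %.3g), %s = %.3f (df %.0f), p = %.4g\n",
    x$group_levels[2L], x$group_levels[1L], x$estimate, x$se,
    if (x$method == "lrt") "LR chi-sq" else "t", x$statistic, x$df, x$p_value))
  cat(sprintf("  random-intercept SD %.3g, residual SD %.3g, %d cells in %d clusters%s\n",
              x$ranef_sd, x$resid_sd, x$n_obs, x$n_clusters,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' @rdname lmm_group_test
#' @param x A `mito_lmm` object.
#' @param ... Unused.
#' @export
tidy.mito_lmm <- function(x, ...) {
  tibble(term = paste0("group", x$group_levels[2L]),
         estimate = x$estimate, std.error = x$se,
         statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' @rdname lmm_group_test
#' @export
glance.mito_lmm <- function(x, ...) {
  tibble(nobs = x$n_obs, n_clusters = x$n_clusters,
         ranef_sd = x$ranef_sd, resid_sd = x$resid_sd,
         singular = x$singular, resid_shapiro_p = x$resid_shapiro_p,
         method = x$method)
}
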