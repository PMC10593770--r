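# Orchestration: a configured, seeded run through simulate -> classify ->
# aggregate -> stats (+ qPCR and survival side-channels), each stage
# persisting a CSV so every reported number traces to a file, plus a
# manifest of checksums for reproducibility audits.

#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. The
#' config round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character subset of
#'   `c("simulate", "classify", "aggregate", "stats", "qpcr", "survival")`.
#'   Disabling `"simulate"` requires `cells_csv`.
#' @param design A [cohort_design()] (its seed is overridden by `seed`).
#' @param effects Region effects tibble; default [default_region_effects()].
#' @param cells_csv Optional path to an existing cells CSV consumed
#'   directly when the simulate stage is disabled.
#' @param control_label Group label of control cells.
#' @param qpcr List: `control_copies`, `knockout_copies` (per-sample true
#'   copies), `noise_sd`, `area_um2` per pool.
#' @param survival_cfg List: `n_control`, `n_knockout`, `median_control`,
#'   `median_knockout`, `censor_day`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = c("simulate", "classify", "aggregate",
                                  "stats", "qpcr", "survival"),
                       design = cohort_design(),
                       effects = default_region_effects(design),
                       cells_csv = NULL,
                       control_label = "control",
                       qpcr = list(control_copies = rep(2000, 4),
                                   knockout_copies = rep(300, 6),
                                   noise_sd = 0.15,
                                   area_um2 = 15000),
                       survival_cfg = list(n_control = 4, n_knockout = 12,
                                           median_control = 700,
                                           median_knockout = 94,
                                           censor_day = 180)) {
  known <- c("simulate", "classify", "aggregate", "stats", "qpcr", "survival")
  if (!all(stages %in% known)) {
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", ")))
  }
  if (!"simulate" %in% stages && any(c("classify") %in% stages) &&
      is.null(cells_csv)) {
    abort("classify without simulate requires `cells_csv`")
  }
  if (!is.null(cells_csv) && !file.exists(cells_csv)) {
    abort(sprintf("`cells_csv` does not exist: %s", cells_csv))
  }
  design$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         design = design, effects = as_tibble(effects),
         cells_csv = cells_csv, control_label = control_label,
         qpcr = qpcr, survival_cfg = survival_cfg),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$design <- c(unclass(x$design)[setdiff(names(x$design), "ratios")],
                list(ratios = as.data.frame(x$design$ratios)))
  x$effects <- as.data.frame(x$effects)
  yaml::write_yaml(x, path, column.major = FALSE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  design <- cohort_design(
    n_control_mice = x$design$n_control_mice,
    n_knockout_mice = x$design$n_knockout_mice,
    cells_per_mouse_per_region = x$design$cells_per_mouse_per_region,
    regions = unlist(x$design$regions),
    ratios = dplyr::bind_rows(x$design$ratios),
    seed = x$design$seed
  )
  run_config(out_dir = x$out_dir, seed = x$seed,
             stages = unlist(x$stages), design = design,
             effects = dplyr::bind_rows(x$effects),
             cells_csv = x$cells_csv,
             control_label = x$control_label,
             qpcr = x$qpcr, survival_cfg = x$survival_cfg)
}

.stage_file <- function(config, name) file.path(config$out_dir, name)

#' Execute a configured pipeline run
#'
#' Runs the enabled stages in order, persisting each stage's outputs as CSV
#' under `config$out_dir`. On a stage failure the completed outputs persist
#' and the manifest marks the failure point; subsequent stages are skipped.
#'
#' @param config A [run_config()].
#' @return Invisible list of class `mito_run`: `manifest` (tibble: stage,
#'   status, files, md5 checksums), `results` (in-memory stage results),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list()
  failed <- FALSE

  record <- function(stage, status, files = character()) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, status = status,
      file = if (length(files)) basename(files) else NA_character_,
      md5 = if (length(files)) unname(tools::md5sum(files)) else NA_character_
    )
  }
  run_stage <- function(stage, fn) {
    if (failed || !stage %in% config$stages) return(invisible())
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      failed <<- TRUE
      record(stage, paste0("failed: ", conditionMessage(out)))
    } else {
      results[[stage]] <<- out$result
      record(stage, "ok", out$files)
    }
  }

  run_stage("simulate", function() {
    sim <- sim_cell_table(config$design, config$effects)
    f_cells <- .stage_file(config, "cells.csv")
    f_truth <- .stage_file(config, "ground_truth.csv")
    readr::write_csv(sim$cells, f_cells)
    readr::write_csv(sim$truth, f_truth)
    list(result = sim, files = c(f_cells, f_truth))
  })

  run_stage("classify", function() {
    cells <- if (!is.null(results$simulate)) results$simulate$cells else {
      readr::read_csv(config$cells_csv, show_col_types = FALSE)
    }
    ratios <- config$design$ratios
    records <- purrr::pmap(ratios, function(target, mass) {
      ref <- fit_control_reference(cells, target, mass,
                                   control_label = config$control_label)
      zscore_cells(cells, ref)
    }) |> bind_rows()
    f <- .stage_file(config, "zscores.csv")
    readr::write_csv(records, f)
    list(result = records, files = f)
  })

  run_stage("aggregate", function() {
    records <- results$classify %||% abort("classify stage output missing")
    breakdown <- aggregate_breakdown(records)
    reduction <- overall_reduction_fraction(records, .data$region,
                                            .data$group, .data$target)
    f_b <- .stage_file(config, "breakdown.csv")
    f_r <- .stage_file(config, "overall_reduction.csv")
    readr::write_csv(breakdown, f_b)
    readr::write_csv(reduction, f_r)
    list(result = list(breakdown = breakdown, reduction = reduction),
         files = c(f_b, f_r))
  })

  run_stage("stats", function() {
    records <- results$classify %||% abort("classify stage output missing")
    per_stratum <- records |>
      group_by(.data$region, .data$target, .data$mass) |>
      dplyr::group_split()
    rows <- purrr::map(per_stratum, function(d) {
      fit <- lmm_group_test(d, "z", "group", "mouse_id")
      tibble(region = d$region[1L], target = d$target[1L], mass = d$mass[1L],
             estimate = fit$estimate, se = fit$se, df = fit$df,
             statistic = fit$statistic, p_value = fit$p_value,
             n_cells = fit$n_obs, n_mice = fit$n_clusters,
             singular = fit$singular)
    }) |> bind_rows()
    rows <- rows |>
      group_by(.data$target, .data$mass) |>
      mutate(p_adjusted = bh_adjust(.data$p_value)) |>
      ungroup()
    f <- .stage_file(config, "stats.csv")
    readr::write_csv(rows, f)
    list(result = rows, files = f)
  })

  run_stage("qpcr", function() {
    q <- config$qpcr
    copies <- c(q$control_copies, q$knockout_copies)
    names(copies) <- c(sprintf("ctrl_%02d", seq_along(q$control_copies)),
                       sprintf("ko_%02d", seq_along(q$knockout_copies)))
    plate <- sim_qpcr_plate(copies, noise_sd = q$noise_sd,
                            areas_um2 = rep(q$area_um2, length(copies)),
                            seed = config$seed + 1L)
    quant <- quantify_plate(plate)
    quant$samples$group <- rep(c("control", "knockout"),
                               c(length(q$control_copies),
                                 length(q$knockout_copies)))
    f_p <- .stage_file(config, "qpcr_plate.csv")
    f_q <- .stage_file(config, "copynumber.csv")
    readr::write_csv(plate, f_p)
    readr::write_csv(quant$samples, f_q)
    list(result = quant, files = c(f_p, f_q))
  })

  run_stage("survival", function() {
    s <- config$survival_cfg
    surv <- bind_rows(
      sim_survival(s$n_control, s$median_control, s$censor_day,
                   group = "control", seed = config$seed + 2L),
      sim_survival(s$n_knockout, s$median_knockout, s$censor_day,
                   group = "knockout", seed = config$seed + 3L)
    )
    km <- km_logrank(surv)
    f_s <- .stage_file(config, "survival.csv")
    f_m <- .stage_file(config, "survival_summary.csv")
    readr::write_csv(surv, f_s)
    readr::write_csv(glance(km), f_m)
    list(result = km, files = c(f_s, f_m))
  })

  manifest <- bind_rows(manifest)
  run <- structure(
    list(manifest = manifest, results = results, config = config),
    class = "mito_run"
  )
  invisible(run)
}

#' @export
print.mito_run <- function(x, ...) {
  cat("<mito_run> out_dir:", x$config$out_dir, "\n")
  print(x$manifest |> distinct(.data$stage, .data$status))
  invisible(x)
}

#' Render a human-readable + machine-readable run report
#'
#' Writes `report.md` (tables of class breakdowns, overall-reduction
#' fractions, mixed-model stats, copy-number and survival summaries; empty
#' optional sections are omitted) and `summary.json`. Every number is read
#' back from the stage CSVs so the report is traceable to files.
#'
#' @param run A `mito_run` from [run_pipeline()].
#' @return Invisible named character vector of the files written.
#' @export
report_run <- function(run) {
  stopifnot(inherits(run, "mito_run"))
  cfg <- run$config
  lines <- c("# Pipeline run report", "",
             sprintf("- seed: %d", cfg$seed),
             sprintf("- stages: %s",
                     paste(cfg$stages, collapse = ", ")), "")
  summary_json <- list(seed = cfg$seed, stages = cfg$stages)

  fmt_tbl <- function(d, digits = 3) {
    d[] <- lapply(d, function(col) if (is.numeric(col)) signif(col, digits) else col)
    header <- paste0("| ", paste(names(d), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
    body <- apply(d, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body, "")
  }

  f_breakdown <- .stage_file(cfg, "breakdown.csv")
  if (file.exists(f_breakdown)) {
    b <- readr::read_csv(f_breakdown, show_col_types = FALSE)
    lines <- c(lines, "## Deficiency class breakdown (% of cells)", "",
               fmt_tbl(b |> select("region", "group", "target", "mass",
                                   "class", "percentage", "n_cells",
                                   "n_mice")))
    summary_json$breakdown <- b
  }
  f_red <- .stage_file(cfg, "overall_reduction.csv")
  if (file.exists(f_red)) {
    r <- readr::read_csv(f_red, show_col_types = FALSE)
    lines <- c(lines, "## Overall reduction (fraction of cells with z <= -2)",
               "", fmt_tbl(r))
    summary_json$overall_reduction <- r
  }
  f_stats <- .stage_file(cfg, "stats.csv")
  if (file.exists(f_stats)) {
    s <- readr::read_csv(f_stats, show_col_types = FALSE)
    lines <- c(lines, "## Mixed-model group contrasts (z ~ group, mouse random intercept)",
               "", fmt_tbl(s))
    summary_json$stats <- s
  }
  f_cn <- .stage_file(cfg, "copynumber.csv")
  if (file.exists(f_cn)) {
    cn <- readr::read_csv(f_cn, show_col_types = FALSE)
    lines <- c(lines, "## mtDNA copy number", "",
               fmt_tbl(cn |> select("sample_id", "group", "mean_cq",
                                    "copies", "copies_per_um2")))
    summary_json$copynumber <- cn
  }
  f_surv <- .stage_file(cfg, "survival_summary.csv")
  if (file.exists(f_surv)) {
    sv <- readr::read_csv(f_surv, show_col_types = FALSE)
    lines <- c(lines, "## Survival", "", fmt_tbl(sv))
    summary_json$survival <- sv
  }

  f_md <- .stage_file(cfg, "report.md")
  f_json <- .stage_file(cfg, "summary.json")
  writeLines(lines, f_md)
  jsonlite::write_json(summary_json, f_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(report = f_md, summary = f_json))
}
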