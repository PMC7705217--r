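# Config-driven orchestration: scoring/descriptives -> difference scores ->
# robust fits with the remediation ladder -> effect sizes and ROPE
# decisions -> report tables, with full seeding and a manifest.

#' Configure a pipeline run
#'
#' @param simulate a [cohort_config()] to generate the cohort, or `NULL`
#'   when reading from `input`.
#' @param input path to a cohort CSV (ignored when `simulate` is given).
#' @param plan list of analysis entries; each entry is a list with
#'   `variable`, `model` (`"multi_group"` or `"single_group"`), optional
#'   `groups` (default: all groups present) and `contrast` (logical,
#'   multi-group only: add the pooled mental-disorder vs healthy-control
#'   row).
#' @param regression optional list with `variable` and `covariates`
#'   (column names) for the covariate regression on that variable's change
#'   score.
#' @param rope a [rope_spec()].
#' @param hdi_mass HDI mass for all summaries.
#' @param model_args named list of overrides passed to [model_spec()]
#'   (e.g. `chains`, `draws_per_chain`).
#' @param ess_target,psrf_threshold convergence gates (see
#'   [diagnostics_report()]).
#' @param contrast_hc label of the control group for contrast rows.
#' @param seed integer master seed; every stage derives its own substream.
#' @param out_dir output directory (created if needed).
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, input = NULL,
                       plan = list(list(variable = "stress",
                                        model = "multi_group",
                                        contrast = TRUE)),
                       regression = NULL,
                       rope = rope_spec(), hdi_mass = 0.95,
                       model_args = list(),
                       ess_target = 10000, psrf_threshold = 1.05,
                       contrast_hc = "HC",
                       seed = 1L, out_dir = tempfile("ropebest_run_")) {
  if (is.null(simulate) && is.null(input)) {
    stop("either 'simulate' or 'input' must be given", call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "cohort_config"))
  stopifnot(inherits(rope, "rope_spec"))
  assert_number(hdi_mass, "hdi_mass", lower = 1e-6, upper = 1)
  assert_number(seed, "seed")
  structure(
    list(simulate = simulate, input = input, plan = plan,
         regression = regression, rope = rope, hdi_mass = hdi_mass,
         model_args = model_args, ess_target = ess_target,
         psrf_threshold = psrf_threshold, contrast_hc = contrast_hc,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

report_columns <- function() {
  c("row", "mu", "sigma", "mu_hdi_ll", "mu_hdi_ul",
    "delta", "delta_hdi_ll", "delta_hdi_ul",
    "pct_delta_gt_0", "pct_below_rope", "pct_in_rope", "pct_above_rope",
    "verdict")
}

empty_report <- function() {
  df <- data.frame(row = character(0), mu = numeric(0), sigma = numeric(0),
                   mu_hdi_ll = numeric(0), mu_hdi_ul = numeric(0),
                   delta = numeric(0), delta_hdi_ll = numeric(0),
                   delta_hdi_ul = numeric(0), pct_delta_gt_0 = numeric(0),
                   pct_below_rope = numeric(0), pct_in_rope = numeric(0),
                   pct_above_rope = numeric(0), verdict = character(0),
                   stringsAsFactors = FALSE)
  df
}

report_row <- function(label, mu_draws, sigma_draws, rope, mass) {
  mu_h <- hdi(mu_draws, mass)
  delta <- effect_size_single(mu_draws, sigma_draws, mass)
  dec <- rope_decision(delta, rope)
  data.frame(row = label,
             mu = median(as.numeric(mu_draws)),
             sigma = median(as.numeric(sigma_draws)),
             mu_hdi_ll = mu_h$lower, mu_hdi_ul = mu_h$upper,
             delta = delta$median,
             delta_hdi_ll = delta$hdi$lower, delta_hdi_ul = delta$hdi$upper,
             pct_delta_gt_0 = dec$pct_above_zero,
             pct_below_rope = dec$pct_below_rope,
             pct_in_rope = dec$pct_in_rope,
             pct_above_rope = dec$pct_above_rope,
             verdict = dec$verdict,
             stringsAsFactors = FALSE)
}

#' Summarize a multi-group fit as report rows
#'
#' One row per group (posterior medians of the cell mean and group scale,
#' their HDIs, standardized effect size and ROPE decision), optionally
#' followed by the pooled mental-disorder vs control contrast row.
#'
#' @param fit a multi-group `posterior_samples`.
#' @param rope a [rope_spec()].
#' @param mass HDI mass.
#' @param contrast logical: append the contrast row.
#' @param hc_group control-group label used for the contrast.
#' @return unrounded data frame in the report column layout.
#' @export
summarize_multi_group <- function(fit, rope = rope_spec(), mass = 0.95,
                                  contrast = TRUE, hc_group = "HC") {
  stopifnot(inherits(fit, "posterior_samples"),
            fit$model_kind == "multi_group")
  rows <- do.call(rbind, lapply(fit$groups, function(gl) {
    report_row(gl, fit$draws[[paste0("mu_", gl)]],
               fit$draws[[paste0("sigma_", gl)]], rope, mass)
  }))
  if (contrast && hc_group %in% fit$groups && length(fit$groups) > 1) {
    ct <- contrast_md_vs_hc(fit, hc_group = hc_group, rope = rope, mass = mass)
    ct_h <- hdi(ct$contrast_draws, mass)
    rows <- rbind(rows, data.frame(
      row = paste0("Contrast MD vs. ", hc_group),
      mu = median(as.numeric(ct$contrast_draws)),
      sigma = NA_real_,
      mu_hdi_ll = ct_h$lower, mu_hdi_ul = ct_h$upper,
      delta = ct$delta$median,
      delta_hdi_ll = ct$delta$hdi$lower, delta_hdi_ul = ct$delta$hdi$upper,
      pct_delta_gt_0 = ct$decision$pct_above_zero,
      pct_below_rope = ct$decision$pct_below_rope,
      pct_in_rope = ct$decision$pct_in_rope,
      pct_above_rope = ct$decision$pct_above_rope,
      verdict = ct$decision$verdict,
      stringsAsFactors = FALSE))
  }
  rows
}

#' Round report rows for emission
#'
#' Rounds all numeric report columns half-up to 2 decimals.  Decisions and
#' verdicts are computed upstream on unrounded values; only the printed
#' table is rounded.
#'
#' @param rows unrounded report data frame (or a named list of them).
#' @return rounded data frame(s) in the fixed column order.
#' @export
render_reports <- function(rows) {
  if (is.data.frame(rows)) {
    if (!nrow(rows)) return(empty_report())
    out <- rows[, report_columns(), drop = FALSE]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, digits = 2)
    rownames(out) <- NULL
    return(out)
  }
  lapply(rows, render_reports)
}

write_report_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

pipeline_spec <- function(config, kind, key) {
  args <- config$model_args
  args$model_kind <- kind
  args$seed <- derive_seed(config$seed, key)
  do.call(model_spec, args)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or CSV input), group
#' frequency descriptives, per-variable difference scores, robust Bayesian
#' fits with the nu-floor remediation ladder, effect sizes, ROPE decisions
#' and the pooled-disorders-vs-controls contrast, the optional covariate
#' regression, and report emission.  All randomness derives from the config
#' seed; the same config and seed reproduce byte-identical report files.
#'
#' Emitted files (under `config$out_dir`): `cohort.csv`,
#' `group_frequencies.csv`, one `report_<variable>.csv` per plan entry,
#' `regression_<variable>.csv` when configured, one
#' `diagnostics_<variable>.json` per fit, `manifest.json` and `log.txt`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `dir`, `cohort`, `reports` (unrounded),
#'   `rendered` (rounded, as written), `fits`, `diagnostics` and
#'   `regression`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # --- stage: cohort ---
  cohort <- if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- derive_seed(config$seed, "cohort")
    say("stage cohort: simulating %d participants", sum(cfg$group_sizes))
    generate_cohort(cfg)
  } else {
    say("stage cohort: reading %s", config$input)
    read_cohort(config$input)
  }
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  # --- stage: descriptives ---
  freq <- frequency_table(cohort, "group",
                          denominator = nrow(cohort),
                          denominator_definition = "all cohort rows")
  write_report_csv(freq, file.path(config$out_dir, "group_frequencies.csv"))
  say("stage descriptives: %d groups, n = %d", nrow(freq), nrow(cohort))

  reports <- list()
  fits <- list()
  diags <- list()

  # --- stage: per-variable fits ---
  for (entry in config$plan) {
    v <- entry$variable
    model <- entry$model %||% "multi_group"
    say("stage fit: variable '%s' (%s)", v, model)
    diffs <- difference_scores(cohort, v)
    keep_groups <- entry$groups %||% levels(droplevels(cohort$group))
    sel <- cohort$group %in% keep_groups
    rows <- if (model == "multi_group") {
      res <- fit_with_remediation(
        function(sp) fit_multi_group(diffs[sel], cohort$group[sel], sp),
        pipeline_spec(config, "multi_group", paste0("fit|", v)),
        parameters = as.vector(outer(c("mu_", "sigma_"), keep_groups, paste0)),
        ess_target = config$ess_target,
        psrf_threshold = config$psrf_threshold)
      fits[[v]] <- res$fit
      diags[[v]] <- res$report
      if (!is.null(res$nu_floor_used)) {
        say("  remediation: refit with nu floor %g", res$nu_floor_used)
      }
      summarize_multi_group(res$fit, config$rope, config$hdi_mass,
                            contrast = isTRUE(entry$contrast %||% TRUE),
                            hc_group = config$contrast_hc)
    } else if (model == "single_group") {
      do.call(rbind, lapply(keep_groups, function(gl) {
        res <- fit_with_remediation(
          function(sp) fit_single_group(diffs[cohort$group == gl], sp,
                                        label = paste(v, gl)),
          pipeline_spec(config, "single_group", paste0("fit|", v, "|", gl)),
          parameters = c("mu", "sigma"),
          ess_target = config$ess_target,
          psrf_threshold = config$psrf_threshold)
        fits[[paste(v, gl, sep = ".")]] <<- res$fit
        diags[[paste(v, gl, sep = ".")]] <<- res$report
        report_row(gl, res$fit$draws$mu, res$fit$draws$sigma,
                   config$rope, config$hdi_mass)
      }))
    } else {
      stop(sprintf("stage fit: unknown model '%s' for variable '%s'", model, v),
           call. = FALSE)
    }
    reports[[v]] <- rows
  }

  # --- stage: regression ---
  regression <- NULL
  if (!is.null(config$regression)) {
    v <- config$regression$variable
    covars <- config$regression$covariates
    say("stage regression: %s ~ %s", v, paste(covars, collapse = " + "))
    y <- difference_scores(cohort, v)
    X <- as.matrix(cohort[, covars, drop = FALSE])
    fit <- fit_regression(y, X, pipeline_spec(config, "regression",
                                              paste0("reg|", v)))
    regression <- coef_summary(fit, config$hdi_mass)
    out <- regression
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, digits = 3)
    write_report_csv(out, file.path(config$out_dir,
                                    paste0("regression_", v, ".csv")))
    fits[[paste0("regression.", v)]] <- fit
  }

  # --- stage: reports ---
  rendered <- render_reports(reports)
  if (!length(rendered)) {
    rendered <- list()
  }
  for (v in names(rendered)) {
    write_report_csv(rendered[[v]],
                     file.path(config$out_dir, paste0("report_", v, ".csv")))
  }
  if (!length(config$plan)) {
    write_report_csv(empty_report(),
                     file.path(config$out_dir, "report_empty.csv"))
  }
  for (v in names(diags)) {
    d <- diags[[v]]
    jsonlite::write_json(
      list(variable = v, converged = isTRUE(attr(d, "converged")),
           ess_target = attr(d, "ess_target"),
           psrf_threshold = attr(d, "psrf_threshold"),
           notes = attr(d, "notes"),
           parameters = as.data.frame(d)),
      file.path(config$out_dir,
                paste0("diagnostics_", gsub("[^A-Za-z0-9_.-]", "_", v), ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "ropebest",
    version = as.character(utils::packageVersion("ropebest")),
    seed = config$seed,
    config_hash = derive_seed(0L, paste(deparse(config[setdiff(names(config),
                                                               "out_dir")]),
                                        collapse = "")),
    n_participants = nrow(cohort),
    plan_variables = vapply(config$plan, function(e) e$variable, ""),
    ess_target = config$ess_target,
    rope = c(config$rope$lower, config$rope$upper),
    hdi_mass = config$hdi_mass
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  say("run complete: %s", config$out_dir)

  invisible(list(dir = config$out_dir, cohort = cohort, reports = reports,
                 rendered = rendered, fits = fits, diagnostics = diags,
                 regression = regression))
}
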