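# Synthetic cohorts with the statistical structure the change analysis
# assumes: 11 diagnostic groups at the study's sizes, two time points,
# heavy-tailed individual change (location-scale t), group-specific spread,
# and sociodemographic covariates.

#' Canonical diagnostic group labels
#'
#' The eleven cohort labels: ten self-identified mental-disorder groups
#' (generalized anxiety, panic/agoraphobia, illness anxiety, social anxiety,
#' depression, obsessive-compulsive, body dysmorphic, eating, schizophrenia
#' spectrum, other non-specified) and healthy controls.
#'
#' @return character vector of group labels.
#' @export
group_levels <- function() {
  c("GAD", "PA", "IA", "SAD", "DP", "OCD", "BDD", "ED", "SP", "other", "HC")
}

default_group_sizes <- function() {
  stats::setNames(c(135L, 83L, 30L, 86L, 586L, 47L, 16L, 62L, 6L, 156L, 1026L),
                  group_levels())
}

# Per-group true change for the default "stress" variable: locations and
# spreads at the magnitudes typical of a 0-20 stress sum score, with
# moderately heavy tails (nu = 30).
default_true_change <- function() {
  mu <- c(GAD = 1.58, PA = 1.49, IA = 1.24, SAD = 1.03, DP = 1.55,
          OCD = 0.92, BDD = 1.64, ED = 1.38, SP = 1.35, other = 0.83,
          HC = 1.56)
  sigma <- c(GAD = 2.98, PA = 2.68, IA = 2.69, SAD = 2.73, DP = 3.10,
             OCD = 2.79, BDD = 2.62, ED = 2.75, SP = 2.62, other = 2.43,
             HC = 2.66)
  data.frame(group = names(mu), variable = "stress", mu = unname(mu),
             sigma = unname(sigma), nu = 30, stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' Describes everything the generator needs: group sizes, bounded score
#' variables, per-(group, variable) true change distributions, baseline
#' distributions, covariate marginals and a seed.  The default configuration
#' is an eleven-group cohort at the study's group sizes with a single
#' "stress" sum score (range 0-20) whose true per-group change follows a
#' location-scale t distribution.
#'
#' @param group_sizes named integer vector, group label -> n (all >= 1).
#' @param variables data frame with columns `name`, `score_min`, `score_max`.
#' @param true_change data frame with columns `group`, `variable`, `mu`,
#'   `sigma` (> 0), `nu` (> 0): the location, scale and normality parameter
#'   of the t-distributed individual change, in raw score units.  The
#'   implied true effect size is `delta_true = mu / sigma`.
#' @param baseline data frame with columns `variable`, `location`, `spread`:
#'   T0 scores are drawn from a normal truncated to the score range.
#' @param covariates list with `age_mean`, `age_sd` (truncated at 18),
#'   `p_female`, `p_relationship`.
#' @param seed integer; one seed expands into independent per-group,
#'   per-variable substreams, so adding a variable does not perturb
#'   existing draws.
#' @param clamp logical; clamp scores to the variable range and round to the
#'   integer score grid (questionnaire sums are integers).  Disable for
#'   calibration studies, since clamping biases effect-size recovery near
#'   range edges.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = default_group_sizes(),
                          variables = data.frame(name = "stress",
                                                 score_min = 0, score_max = 20),
                          true_change = default_true_change(),
                          baseline = data.frame(variable = "stress",
                                                location = 8, spread = 4),
                          covariates = list(age_mean = 33.2, age_sd = 12.7,
                                            p_female = 0.81,
                                            p_relationship = 0.64),
                          seed = 1L,
                          clamp = TRUE) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector", call. = FALSE)
  }
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1", call. = FALSE)
  stopifnot(is.data.frame(variables),
            all(c("name", "score_min", "score_max") %in% names(variables)))
  if (any(variables$score_min >= variables$score_max)) {
    stop("score_min must be < score_max for every variable", call. = FALSE)
  }
  stopifnot(is.data.frame(true_change),
            all(c("group", "variable", "mu", "sigma", "nu") %in% names(true_change)))
  if (any(true_change$sigma <= 0)) stop("sigma_true must be > 0", call. = FALSE)
  if (any(true_change$nu <= 0)) stop("nu_true must be > 0", call. = FALSE)
  bad_g <- setdiff(true_change$group, names(group_sizes))
  if (length(bad_g)) {
    stop("unknown group in true_change: ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  bad_v <- setdiff(true_change$variable, variables$name)
  if (length(bad_v)) {
    stop("unknown variable in true_change: ", paste(bad_v, collapse = ", "),
         call. = FALSE)
  }
  assert_number(seed, "seed")
  assert_flag(clamp, "clamp")
  structure(
    list(group_sizes = group_sizes, variables = variables,
         true_change = true_change, baseline = baseline,
         covariates = covariates, seed = as.integer(seed), clamp = clamp),
    class = "cohort_config"
  )
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws T0 from a truncated-normal baseline, individual change from a
#' location-scale t distribution `t(nu_true, mu_true, sigma_true)`, sets
#' `T1 = T0 + change`, and (by default) clamps both to the score range and
#' rounds to the integer grid.  Difference columns `<var>_diff` hold exactly
#' `t1 - t0` on the final (clamped) scale.  Groups or variables without an
#' entry in `true_change` get zero change apart from noise-free baseline
#' carry-over (mu = 0, sigma = 1, nu = 30 is NOT assumed; instead a missing
#' entry is an error, so ground truth is always explicit).
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `cohort_table` with one row per
#'   participant: `participant_id`, `group`, per variable `<var>_t0`,
#'   `<var>_t1`, `<var>_diff`, and covariates `age`, `gender` (1 = female),
#'   `relationship` (1 = in a relationship).  Deterministic given the
#'   config's seed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_sizes)
  vars <- config$variables
  n_total <- sum(config$group_sizes)

  key <- function(...) paste(..., sep = "|")
  tc <- config$true_change
  has_change <- function(g, v) any(tc$group == g & tc$variable == v)

  rows <- vector("list", length(groups))
  id0 <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$group_sizes[[g]]
    df <- data.frame(
      participant_id = sprintf("P%05d", id0 + seq_len(n)),
      group = g, stringsAsFactors = FALSE
    )
    id0 <- id0 + n
    for (vi in seq_len(nrow(vars))) {
      v <- vars$name[vi]
      lo <- vars$score_min[vi]
      hi <- vars$score_max[vi]
      if (!has_change(g, v)) {
        stop(sprintf("no true_change entry for group '%s', variable '%s'", g, v),
             call. = FALSE)
      }
      b <- config$baseline[config$baseline$variable == v, , drop = FALSE]
      if (nrow(b) != 1L) {
        stop(sprintf("baseline must have exactly one row for variable '%s'", v),
             call. = FALSE)
      }
      p <- tc[tc$group == g & tc$variable == v, , drop = FALSE]
      t0 <- with_seed(derive_seed(config$seed, key("t0", g, v)),
                      rtruncnorm(n, b$location, b$spread, lo, hi))
      change <- with_seed(derive_seed(config$seed, key("change", g, v)),
                          p$mu + p$sigma * rt(n, df = p$nu))
      t1 <- t0 + change
      if (config$clamp) {
        t0 <- round(pmin(pmax(t0, lo), hi))
        t1 <- round(pmin(pmax(t1, lo), hi))
      }
      df[[paste0(v, "_t0")]] <- t0
      df[[paste0(v, "_t1")]] <- t1
      df[[paste0(v, "_diff")]] <- t1 - t0
    }
    cov <- config$covariates
    df$age <- with_seed(derive_seed(config$seed, key("age", g)),
                        round(rtruncnorm(n, cov$age_mean, cov$age_sd, lower = 18)))
    df$gender <- with_seed(derive_seed(config$seed, key("gender", g)),
                           rbinom(n, 1, cov$p_female))
    df$relationship <- with_seed(derive_seed(config$seed, key("relationship", g)),
                                 rbinom(n, 1, cov$p_relationship))
    rows[[gi]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = groups)
  structure(out, variables = vars$name,
            class = c("cohort_table", "data.frame"))
}

#' Write a cohort table to CSV
#'
#' The on-disk format stores `participant_id`, `group`, `<var>_t0`,
#' `<var>_t1` per variable and the covariates; difference columns are
#' derived data and are recomputed on read.
#'
#' @param table a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table") || is.data.frame(table))
  keep <- !grepl("_diff$", names(table))
  write.csv(table[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates required columns, numeric scores and group labels, recomputes
#' `<var>_diff = <var>_t1 - <var>_t0`, and returns a `cohort_table`.
#' `read_cohort(write_cohort(x))` round-trips losslessly.
#'
#' @param path CSV path.
#' @param groups allowed group labels (default [group_levels()]); unknown
#'   labels are rejected with the offending row number.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, groups = group_levels()) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "age", "gender", "relationship")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  t0_cols <- grep("_t0$", names(raw), value = TRUE)
  vars <- sub("_t0$", "", t0_cols)
  missing_t1 <- vars[!paste0(vars, "_t1") %in% names(raw)]
  if (length(missing_t1)) {
    stop("cohort file has _t0 but no _t1 column for: ",
         paste(missing_t1, collapse = ", "), call. = FALSE)
  }
  if (!length(vars)) {
    stop("cohort file contains no <variable>_t0/_t1 score columns", call. = FALSE)
  }
  bad <- which(!raw$group %in% groups)
  if (length(bad)) {
    stop(sprintf("unknown group label '%s' at row %d", raw$group[bad[1]], bad[1]),
         call. = FALSE)
  }
  for (v in vars) {
    for (suff in c("_t0", "_t1")) {
      col <- paste0(v, suff)
      vals <- raw[[col]]
      if (!is.numeric(vals)) {
        nonnum <- which(is.na(suppressWarnings(as.numeric(vals))))
        stop(sprintf("non-numeric score in column '%s' at row %d", col,
                     if (length(nonnum)) nonnum[1] else 1L), call. = FALSE)
      }
      if (anyNA(vals)) {
        stop(sprintf("missing score in column '%s' at row %d", col,
                     which(is.na(vals))[1]), call. = FALSE)
      }
    }
    raw[[paste0(v, "_diff")]] <- raw[[paste0(v, "_t1")]] - raw[[paste0(v, "_t0")]]
  }
  ord <- c("participant_id", "group",
           as.vector(t(outer(vars, c("_t0", "_t1", "_diff"), paste0))),
           "age", "gender", "relationship")
  extra <- setdiff(names(raw), ord)
  raw <- raw[, c(ord, extra), drop = FALSE]
  raw$group <- factor(raw$group, levels = groups)
  structure(raw, variables = vars, class = c("cohort_table", "data.frame"))
}
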