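#' Highest-density interval
#'
#' The narrowest contiguous interval containing at least `mass` of the
#' draws: with `m = ceiling(mass * n)` sorted points per window, the window
#' of minimal width is returned (ties broken toward the lowest window, so
#' the result is deterministic).
#'
#' @param draws numeric vector (or chains x draws matrix) of posterior
#'   draws; at least 2 finite values.
#' @param mass interval mass in (0, 1]; `mass = 1` gives `[min, max]`.
#' @return an object of class `hdinterval`: list with `lower`, `upper`,
#'   `mass`.
#' @export
hdi <- function(draws, mass = 0.95) {
  x <- as.numeric(draws)
  if (!length(x) || anyNA(x) || any(!is.finite(x))) {
    stop("draws must be non-empty and finite", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 draws", call. = FALSE)
  assert_number(mass, "mass", lower = 1e-12, upper = 1)
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) {
    out <- list(lower = x[1], upper = x[n], mass = mass)
  } else {
    starts <- seq_len(n - m + 1)
    widths <- x[starts + m - 1] - x[starts]
    i <- which.min(widths)
    out <- list(lower = x[i], upper = x[i + m - 1], mass = mass)
  }
  class(out) <- "hdinterval"
  out
}

#' @export
print.hdinterval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI [%.4f, %.4f]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Region of practical equivalence
#'
#' An interval of standardized effect sizes treated as practically zero.
#' The default, `-0.2 < delta < 0.2`, is deliberately wider than half a
#' small effect so that negligible effects do not trigger false alarms.
#'
#' @param lower,upper ROPE bounds in effect-size units, `lower < upper`.
#' @return an object of class `rope_spec`.
#' @export
rope_spec <- function(lower = -0.2, upper = 0.2) {
  assert_number(lower, "lower")
  assert_number(upper, "upper")
  if (lower >= upper) stop("rope lower must be < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "rope_spec")
}

new_effect_size <- function(delta_draws, mass = 0.95) {
  d <- as.numeric(delta_draws)
  structure(
    list(delta_draws = delta_draws, median = median(d), hdi = hdi(d, mass)),
    class = "effect_size_posterior"
  )
}

#' @export
print.effect_size_posterior <- function(x, ...) {
  cat(sprintf("delta: median %.3f, %.0f%% HDI [%.3f, %.3f]\n",
              x$median, 100 * x$hdi$mass, x$hdi$lower, x$hdi$upper))
  invisible(x)
}

#' Single-group standardized effect size
#'
#' Per-draw `delta = mu / sigma` (the standardized departure of the change
#' from zero), summarized by the median of the per-draw ratios and its HDI.
#' Propagating the ratio through every draw keeps the uncertainty in sigma
#' in the effect-size posterior.
#'
#' @param mu_draws,sigma_draws equal-shape vectors or matrices of draws;
#'   all sigma draws must be > 0.
#' @param mass HDI mass for the summary.
#' @return an `effect_size_posterior` with `delta_draws`, `median`, `hdi`.
#' @export
effect_size_single <- function(mu_draws, sigma_draws, mass = 0.95) {
  if (!identical(dim(mu_draws), dim(sigma_draws)) ||
      length(mu_draws) != length(sigma_draws)) {
    stop("mu_draws and sigma_draws must have identical shape", call. = FALSE)
  }
  if (any(sigma_draws <= 0)) stop("sigma draws must be > 0", call. = FALSE)
  new_effect_size(mu_draws / sigma_draws, mass)
}

#' Two-group standardized effect size
#'
#' Per-draw `delta = (mu2 - mu1) / sqrt((sigma1^2 + sigma2^2) / 2)`: the
#' group difference standardized by the root mean of the two variances.
#' Swapping the groups negates delta exactly.
#'
#' @param mu1_draws,mu2_draws,sigma1_draws,sigma2_draws equal-shape draws;
#'   sigma draws > 0.
#' @param mass HDI mass.
#' @return an `effect_size_posterior`.
#' @export
effect_size_two <- function(mu1_draws, mu2_draws, sigma1_draws, sigma2_draws,
                            mass = 0.95) {
  lens <- lengths(list(mu1_draws, mu2_draws, sigma1_draws, sigma2_draws))
  if (length(unique(lens)) != 1) {
    stop("all draw arrays must have identical shape", call. = FALSE)
  }
  if (any(sigma1_draws <= 0) || any(sigma2_draws <= 0)) {
    stop("sigma draws must be > 0", call. = FALSE)
  }
  delta <- (mu2_draws - mu1_draws) /
    sqrt((sigma1_draws^2 + sigma2_draws^2) / 2)
  new_effect_size(delta, mass)
}

#' Posterior mass fractions relative to zero and a ROPE
#'
#' Percentages (indicator means x 100) of draws above the reference value
#' and below / inside / above the ROPE.  The ROPE is treated as closed, so
#' the three ROPE fractions always sum to 100.
#'
#' @param delta_draws numeric draws.
#' @param rope a [rope_spec()].
#' @param reference comparison value for the "above" fraction (default 0).
#' @return named numeric vector: `pct_above_zero`, `pct_below_rope`,
#'   `pct_in_rope`, `pct_above_rope`.
#' @export
posterior_fractions <- function(delta_draws, rope = rope_spec(), reference = 0) {
  d <- as.numeric(delta_draws)
  if (!length(d)) stop("empty draws", call. = FALSE)
  c(pct_above_zero = 100 * mean(d > reference),
    pct_below_rope = 100 * mean(d < rope$lower),
    pct_in_rope = 100 * mean(d >= rope$lower & d <= rope$upper),
    pct_above_rope = 100 * mean(d > rope$upper))
}

#' Three-way ROPE decision
#'
#' The null hypothesis is accepted when the HDI of delta lies completely
#' within the (closed) ROPE; the alternative is accepted when the HDI lies
#' completely outside it; any overlap is inconclusive.  The closed-interval
#' reading means an HDI endpoint touching a ROPE bound still counts as
#' contained.  Decisions are computed on unrounded values.
#'
#' @param delta an `effect_size_posterior`, or a numeric vector of delta
#'   draws.
#' @param rope a [rope_spec()].
#' @param mass HDI mass used when `delta` is a raw draw vector.
#' @return an object of class `rope_decision`: `hdi`, `rope`, `verdict`
#'   (one of `"accept_null"`, `"accept_alternative"`, `"inconclusive"`)
#'   and the four posterior-mass fractions.
#' @export
rope_decision <- function(delta, rope = rope_spec(), mass = 0.95) {
  if (inherits(delta, "effect_size_posterior")) {
    h <- delta$hdi
    d <- as.numeric(delta$delta_draws)
  } else {
    d <- as.numeric(delta)
    h <- hdi(d, mass)
  }
  verdict <- if (h$lower >= rope$lower && h$upper <= rope$upper) {
    "accept_null"
  } else if (h$upper < rope$lower || h$lower > rope$upper) {
    "accept_alternative"
  } else {
    "inconclusive"
  }
  fr <- posterior_fractions(d, rope)
  structure(
    list(hdi = h, rope = rope, verdict = verdict,
         pct_above_zero = fr[["pct_above_zero"]],
         pct_below_rope = fr[["pct_below_rope"]],
         pct_in_rope = fr[["pct_in_rope"]],
         pct_above_rope = fr[["pct_above_rope"]]),
    class = "rope_decision"
  )
}

#' @export
print.rope_decision <- function(x, ...) {
  cat(sprintf("%s: %.0f%% HDI [%.3f, %.3f] vs ROPE [%.2f, %.2f]\n",
              x$verdict, 100 * x$hdi$mass, x$hdi$lower, x$hdi$upper,
              x$rope$lower, x$rope$upper))
  cat(sprintf("  %% > 0: %.2f | < ROPE: %.2f | in ROPE: %.2f | > ROPE: %.2f\n",
              x$pct_above_zero, x$pct_below_rope, x$pct_in_rope,
              x$pct_above_rope))
  invisible(x)
}

#' Contrast pooled mental-disorder groups against healthy controls
#'
#' From a multi-group fit, forms the per-draw contrast
#' `mu_MD - mu_HC`, where `mu_MD` is the (by default unweighted) mean of
#' the mental-disorder groups' cell means and the pooled MD scale is the
#' root mean of the MD group variances (optionally weighted by group size).
#' The standardized contrast uses [effect_size_two()] with HC as group 1,
#' so a positive delta means the MD pool changed more than HC.
#'
#' @param fit a `posterior_samples` from [fit_multi_group()].
#' @param md_groups labels of the mental-disorder groups; default all
#'   groups except `hc_group`.
#' @param hc_group label of the control group.
#' @param weights `"unweighted"` (default) or `"by_n"` pooling of MD cell
#'   means and variances.
#' @param rope a [rope_spec()].
#' @param mass HDI mass.
#' @return list with `contrast_draws` (raw-score `mu_MD - mu_HC`), `delta`
#'   (an `effect_size_posterior`) and `decision` (a `rope_decision`).
#' @export
contrast_md_vs_hc <- function(fit, md_groups = NULL, hc_group = "HC",
                              weights = c("unweighted", "by_n"),
                              rope = rope_spec(), mass = 0.95) {
  stopifnot(inherits(fit, "posterior_samples"),
            fit$model_kind == "multi_group")
  weights <- match.arg(weights)
  labels <- fit$groups
  if (!hc_group %in% labels) {
    stop(sprintf("unknown control group '%s'", hc_group), call. = FALSE)
  }
  md_groups <- md_groups %||% setdiff(labels, hc_group)
  unknown <- setdiff(md_groups, labels)
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!length(md_groups)) stop("md_groups must be non-empty", call. = FALSE)
  w <- if (weights == "by_n") {
    n <- fit$group_n[match(md_groups, labels)]
    n / sum(n)
  } else {
    rep(1 / length(md_groups), length(md_groups))
  }
  mu_md <- 0
  var_md <- 0
  for (i in seq_along(md_groups)) {
    mu_md <- mu_md + w[i] * fit$draws[[paste0("mu_", md_groups[i])]]
    var_md <- var_md + w[i] * fit$draws[[paste0("sigma_", md_groups[i])]]^2
  }
  sigma_md <- sqrt(var_md)
  mu_hc <- fit$draws[[paste0("mu_", hc_group)]]
  sigma_hc <- fit$draws[[paste0("sigma_", hc_group)]]
  delta <- effect_size_two(mu_hc, mu_md, sigma_hc, sigma_md, mass)
  list(contrast_draws = mu_md - mu_hc,
       delta = delta,
       decision = rope_decision(delta, rope))
}
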