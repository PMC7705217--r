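#' Specify a robust model and its MCMC settings
#'
#' All models share the same noise family: observations are t-distributed
#' with normality parameter nu under an exponential prior with rate
#' `nu_rate` (default 1/30, i.e. prior mean 30, allowing both near-normal
#' and heavy-tailed data).  `nu_floor` truncates that prior from below; it
#' is the remediation lever for fits where nu collapses toward zero and the
#' scale estimate collapses with it (outlier overcompensation).
#'
#' Priors default to non-committal, data-scaled choices: the location prior
#' is normal centered at the sample mean with scale 100 x the sample sd;
#' the single-group scale prior is uniform on (sd/1000, sd x 1000); group
#' scales in the multi-group model get a gamma prior whose mode and sd have
#' broad uniform hyperpriors on the same range; deflections and regression
#' coefficients get normal priors (deflections: scale 10 x the pooled sd;
#' regression: scale `beta_prior_scale` on standardized predictors).
#'
#' @param model_kind one of `"single_group"`, `"two_group"`,
#'   `"multi_group"`, `"regression"`.
#' @param nu_rate rate of the exponential prior on nu (> 0).
#' @param nu_floor optional lower truncation for nu (e.g. 1 or 2); `NULL`
#'   means no floor.
#' @param mu_prior optional `c(center, scale)` for the location prior;
#'   `NULL` = data-scaled default.
#' @param sigma_prior_single optional `c(lower, upper)` of the uniform scale
#'   prior (lower > 0); `NULL` = data-scaled default.
#' @param sigma_prior_multi optional `c(lower, upper)` of the uniform
#'   hyperpriors on the gamma mode and sd; `NULL` = data-scaled default.
#' @param beta_prior_scale normal-prior scale for standardized regression
#'   coefficients.
#' @param chains number of independent chains (>= 2).
#' @param draws_per_chain retained draws per chain.
#' @param warmup burn-in iterations discarded before sampling.
#' @param adapt sampler adaptation iterations.
#' @param seed integer seed; expanded into per-chain RNG streams, so the
#'   same spec + data + seed reproduces identical draws.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model_kind = c("single_group", "two_group",
                                      "multi_group", "regression"),
                       nu_rate = 1 / 30, nu_floor = NULL,
                       mu_prior = NULL, sigma_prior_single = NULL,
                       sigma_prior_multi = NULL, beta_prior_scale = 10,
                       chains = 4, draws_per_chain = 12500,
                       warmup = 500, adapt = 500, seed = 1L) {
  model_kind <- match.arg(model_kind)
  assert_number(nu_rate, "nu_rate", lower = 1e-12)
  if (!is.null(nu_floor)) assert_number(nu_floor, "nu_floor", lower = 0)
  assert_number(chains, "chains", lower = 2)
  assert_number(draws_per_chain, "draws_per_chain", lower = 1)
  assert_number(warmup, "warmup", lower = 1)
  assert_number(adapt, "adapt", lower = 0)
  assert_number(beta_prior_scale, "beta_prior_scale", lower = 1e-12)
  assert_number(seed, "seed")
  if (!is.null(mu_prior)) {
    stopifnot(length(mu_prior) == 2, is.finite(mu_prior), mu_prior[2] > 0)
  }
  if (!is.null(sigma_prior_single)) {
    stopifnot(length(sigma_prior_single) == 2, sigma_prior_single[1] > 0,
              sigma_prior_single[1] < sigma_prior_single[2])
  }
  if (!is.null(sigma_prior_multi)) {
    stopifnot(length(sigma_prior_multi) == 2, sigma_prior_multi[1] > 0,
              sigma_prior_multi[1] < sigma_prior_multi[2])
  }
  structure(
    list(model_kind = model_kind, nu_rate = nu_rate, nu_floor = nu_floor,
         mu_prior = mu_prior, sigma_prior_single = sigma_prior_single,
         sigma_prior_multi = sigma_prior_multi,
         beta_prior_scale = beta_prior_scale,
         chains = as.integer(chains),
         draws_per_chain = as.integer(draws_per_chain),
         warmup = as.integer(warmup), adapt = as.integer(adapt),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

spec_nu_floor <- function(spec) spec$nu_floor %||% 0

# place an initial value strictly inside a support interval
init_in_interval <- function(x, bounds) {
  lo <- bounds[1]
  hi <- bounds[2]
  pmin(pmax(x, lo + 0.01 * (hi - lo)), hi - 0.01 * (hi - lo))
}

new_posterior_samples <- function(draws, model_kind, spec, extra = list()) {
  structure(
    c(list(draws = draws, model_kind = model_kind, spec = spec), extra),
    class = "posterior_samples"
  )
}

#' Extract posterior draws
#'
#' @param fit a `posterior_samples` object.
#' @param parameter parameter name (e.g. `"mu"`, `"sigma"`, `"nu"`).
#' @param flatten if `TRUE` (default) return a single vector pooling all
#'   chains; otherwise a chains x draws matrix.
#' @return numeric vector or matrix of draws.
#' @export
posterior_draws <- function(fit, parameter, flatten = TRUE) {
  stopifnot(inherits(fit, "posterior_samples"))
  if (!parameter %in% names(fit$draws)) {
    stop(sprintf("unknown parameter '%s'; available: %s", parameter,
                 paste(names(fit$draws), collapse = ", ")), call. = FALSE)
  }
  m <- fit$draws[[parameter]]
  if (flatten) as.numeric(t(m)) else m
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %s model: %d chains x %d draws\n",
              x$model_kind, nrow(x$draws[[1]]), ncol(x$draws[[1]])))
  cat("  parameters:", paste(names(x$draws), collapse = ", "), "\n")
  for (p in names(x$draws)) {
    d <- as.numeric(x$draws[[p]])
    h <- hdi(d)
    cat(sprintf("  %-10s median %8.3f  95%% HDI [%8.3f, %8.3f]\n",
                p, median(d), h$lower, h$upper))
  }
  invisible(x)
}

check_change_vector <- function(y, label = "data", min_n = 5) {
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) {
    stop(sprintf("%s contains missing or non-finite values", label), call. = FALSE)
  }
  if (length(y) < min_n) {
    stop(sprintf("%s needs at least %d observations (got %d)", label, min_n,
                 length(y)), call. = FALSE)
  }
  if (sd(y) == 0) {
    stop(sprintf("degenerate data: '%s' has zero variance", label), call. = FALSE)
  }
  y
}

#' Fit the robust single-group model
#'
#' `y_i ~ t(nu, mu, sigma)` with a normal prior on mu, a uniform prior on
#' sigma and an exponential prior (rate `nu_rate`, optionally truncated at
#' `nu_floor`) on nu.  Used for per-group change scores: is the central
#' change mu different from zero?
#'
#' @param diffs numeric vector of change scores (n >= 5, non-degenerate).
#' @param spec a [model_spec()]; its `model_kind` is ignored.
#' @param label name used in error messages and reports.
#' @return a `posterior_samples` with parameters `mu`, `sigma`, `nu`.
#' @export
fit_single_group <- function(diffs, spec = model_spec("single_group"),
                             label = "diffs") {
  y <- check_change_vector(diffs, label)
  s <- sd(y)
  mu_prior <- spec$mu_prior %||% c(mean(y), 100 * s)
  sig_prior <- spec$sigma_prior_single %||% c(s / 1000, s * 1000)
  data <- list(y = y, N = length(y),
               muMean = mu_prior[1], muPrec = 1 / mu_prior[2]^2,
               sigmaLo = sig_prior[1], sigmaHi = sig_prior[2],
               nuRate = spec$nu_rate, nuLo = spec_nu_floor(spec))
  inits <- list(mu = mean(y),
                sigma = init_in_interval(s, sig_prior),
                nu = spec_nu_floor(spec) + 5)
  draws <- run_jags(jags_model_single, data, inits, c("mu", "sigma", "nu"), spec)
  new_posterior_samples(draws, "single_group", spec,
                        list(n = length(y), label = label))
}

#' Fit the robust two-group model (Bayesian analog to a t test)
#'
#' Each group gets its own location and scale; the normality parameter nu is
#' shared.  The quantity of interest is usually `mu2 - mu1` and its
#' standardized version via [effect_size_two()].
#'
#' @param y1,y2 numeric vectors (each n >= 5).
#' @param spec a [model_spec()].
#' @return a `posterior_samples` with parameters `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `nu`.
#' @export
fit_two_group <- function(y1, y2, spec = model_spec("two_group")) {
  y1 <- check_change_vector(y1, "y1")
  y2 <- check_change_vector(y2, "y2")
  pooled <- c(y1, y2)
  s <- sd(pooled)
  mu_prior <- spec$mu_prior %||% c(mean(pooled), 100 * s)
  sig_prior <- spec$sigma_prior_single %||% c(s / 1000, s * 1000)
  data <- list(y1 = y1, y2 = y2, N1 = length(y1), N2 = length(y2),
               muMean = mu_prior[1], muPrec = 1 / mu_prior[2]^2,
               sigmaLo = sig_prior[1], sigmaHi = sig_prior[2],
               nuRate = spec$nu_rate, nuLo = spec_nu_floor(spec))
  inits <- list(mu = c(mean(y1), mean(y2)),
                sigma = init_in_interval(c(sd(y1), sd(y2)), sig_prior),
                nu = spec_nu_floor(spec) + 5)
  draws <- run_jags(jags_model_two, data, inits,
                    c("mu", "sigma", "nu"), spec)
  draws <- list(mu1 = draws[["mu[1]"]], mu2 = draws[["mu[2]"]],
                sigma1 = draws[["sigma[1]"]], sigma2 = draws[["sigma[2]"]],
                nu = draws[["nu"]])
  new_posterior_samples(draws, "two_group", spec,
                        list(n = c(length(y1), length(y2))))
}

#' Fit the robust multi-group (ANOVA-like) model
#'
#' Change scores from all groups are modelled jointly:
#' `y_i ~ t(nu, beta0 + beta_g[i], sigma_g[i])` with a grand mean `beta0`,
#' per-group deflections `beta_g` under normal priors, per-group scales
#' `sigma_g` under a gamma prior with broad mode/sd hyperpriors (partial
#' pooling of spreads), and a shared nu.  Deflections are identified by
#' sum-to-zero recentering applied to every draw; cell means
#' `mu_g = beta0 + beta_g` are invariant to that choice and are returned
#' directly.
#'
#' @param diffs numeric vector of change scores.
#' @param groups factor (or coercible) of the same length; >= 2 levels,
#'   each with n >= 2.
#' @param spec a [model_spec()].
#' @return a `posterior_samples` with `beta0`, per-group `mu_<group>`,
#'   `beta_<group>`, `sigma_<group>`, and `nu`; group labels and sizes are
#'   stored in `$groups` and `$group_n`.
#' @export
fit_multi_group <- function(diffs, groups, spec = model_spec("multi_group")) {
  y <- as.numeric(diffs)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("diffs contain missing or non-finite values", call. = FALSE)
  }
  g <- droplevels(as.factor(groups))
  if (length(g) != length(y)) stop("diffs and groups lengths differ", call. = FALSE)
  tab <- table(g)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  if (sd(y) == 0) stop("degenerate data: zero variance", call. = FALSE)
  s <- sd(y)
  labels <- levels(g)
  J <- length(labels)
  sig_prior <- spec$sigma_prior_multi %||% c(s / 1000, s * 1000)
  a0_prior <- spec$mu_prior %||% c(mean(y), 10 * s)
  defl_scale <- 10 * s
  data <- list(y = y, g = as.integer(g), N = length(y), J = J,
               yMean = a0_prior[1], a0Prec = 1 / a0_prior[2]^2,
               aPrec = 1 / defl_scale^2,
               sigmaLo = sig_prior[1], sigmaHi = sig_prior[2],
               nuRate = spec$nu_rate, nuLo = spec_nu_floor(spec))
  group_sd <- pmax(tapply(y, g, sd), s / 100)
  inits <- list(a0 = mean(y), a = rep(0, J),
                sigma = init_in_interval(as.numeric(group_sd), sig_prior),
                sigmaMode = init_in_interval(s, sig_prior),
                sigmaSD = init_in_interval(s, sig_prior),
                nu = spec_nu_floor(spec) + 5)
  raw <- run_jags(jags_model_multi, data, inits,
                  c("a0", "a", "sigma", "nu"), spec)
  a0 <- raw[["a0"]]
  a <- lapply(seq_len(J), function(j) raw[[sprintf("a[%d]", j)]])
  a_mean <- Reduce(`+`, a) / J
  draws <- list(beta0 = a0 + a_mean)
  for (j in seq_len(J)) {
    draws[[paste0("mu_", labels[j])]] <- a0 + a[[j]]
  }
  for (j in seq_len(J)) {
    draws[[paste0("beta_", labels[j])]] <- a[[j]] - a_mean
  }
  for (j in seq_len(J)) {
    draws[[paste0("sigma_", labels[j])]] <- raw[[sprintf("sigma[%d]", j)]]
  }
  draws$nu <- raw$nu
  new_posterior_samples(draws, "multi_group", spec,
                        list(groups = labels, group_n = as.integer(tab)))
}

#' Fit a robust Bayesian linear regression
#'
#' `y_i ~ t(nu, intercept + X b, sigma)` with normal priors on the
#' coefficients.  Predictors and outcome are standardized internally (the
#' prior scale `beta_prior_scale` applies on that scale) and draws are
#' back-transformed to raw units.  The same t noise family as the other
#' models is used so outliers do not drive the coefficients.
#'
#' @param y numeric outcome (e.g. change in perceived stress).
#' @param X numeric matrix of covariates with column names (no intercept
#'   column); must be full column rank.
#' @param spec a [model_spec()].
#' @return a `posterior_samples` with `intercept`, one `b_<name>` per
#'   column of `X`, `sigma`, `nu`.
#' @seealso [coef_summary()] for medians, HDIs and posterior sign masses.
#' @export
fit_regression <- function(y, X, spec = model_spec("regression")) {
  y <- check_change_vector(y, "y", min_n = 5)
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  if (length(y) <= ncol(X) + 1) {
    stop("need more observations than coefficients", call. = FALSE)
  }
  if (ncol(X) == 0) {
    # intercept-only design: the model nests to the single-group location fit
    f <- fit_single_group(y, spec, label = "y")
    draws <- list(intercept = f$draws$mu, sigma = f$draws$sigma,
                  nu = f$draws$nu)
    return(new_posterior_samples(draws, "regression", spec,
                                 list(n = length(y), covariates = character(0))))
  }
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[dropped[dropped > 0]], collapse = ", "),
         call. = FALSE)
  }
  sd_x <- apply(X, 2, sd)
  if (any(sd_x == 0)) {
    stop("constant covariate column(s): ",
         paste(colnames(X)[sd_x == 0], collapse = ", "), call. = FALSE)
  }
  mean_x <- colMeans(X)
  mean_y <- mean(y)
  sd_y <- sd(y)
  zx <- sweep(sweep(X, 2, mean_x), 2, sd_x, `/`)
  zy <- (y - mean_y) / sd_y
  data <- list(zy = zy, zx = zx, N = length(y), K = ncol(X),
               bPrec = 1 / spec$beta_prior_scale^2,
               nuRate = spec$nu_rate, nuLo = spec_nu_floor(spec))
  inits <- list(zb0 = 0, zb = rep(0, ncol(X)), sigma = 1,
                nu = spec_nu_floor(spec) + 5)
  raw <- run_jags(jags_model_regression, data, inits,
                  c("zb0", "zb", "sigma", "nu"), spec)
  # coda drops the index on length-1 vector nodes
  zb <- lapply(seq_len(ncol(X)), function(k) {
    raw[[if (ncol(X) == 1) "zb" else sprintf("zb[%d]", k)]]
  })
  b <- lapply(seq_len(ncol(X)), function(k) zb[[k]] * sd_y / sd_x[k])
  intercept <- mean_y + sd_y * raw$zb0
  for (k in seq_len(ncol(X))) intercept <- intercept - b[[k]] * mean_x[k]
  draws <- c(list(intercept = intercept),
             stats::setNames(b, paste0("b_", colnames(X))),
             list(sigma = raw$sigma * sd_y, nu = raw$nu))
  new_posterior_samples(draws, "regression", spec,
                        list(n = length(y), covariates = colnames(X)))
}

#' Summarize regression coefficients
#'
#' Per-coefficient posterior median, 95% HDI, and the percentage of
#' posterior mass below and above zero — the reporting convention for
#' sociodemographic effects on change scores.
#'
#' @param fit a regression `posterior_samples`.
#' @param mass HDI mass.
#' @return data frame with one row per coefficient.
#' @export
coef_summary <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "posterior_samples"),
            fit$model_kind == "regression")
  terms <- c("intercept", paste0("b_", fit$covariates))
  do.call(rbind, lapply(terms, function(p) {
    d <- posterior_draws(fit, p)
    h <- hdi(d, mass)
    data.frame(term = p, median = median(d), hdi_ll = h$lower,
               hdi_ul = h$upper,
               pct_below_0 = 100 * mean(d < 0),
               pct_above_0 = 100 * mean(d > 0),
               stringsAsFactors = FALSE)
  }))
}
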