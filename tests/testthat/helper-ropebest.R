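# Shared fixtures: fast MCMC settings and small cohorts used across tests.

fast_spec <- function(kind = "single_group", seed = 1L, chains = 2,
                      draws = 800, warmup = 300, adapt = 300, ...) {
  model_spec(kind, chains = chains, draws_per_chain = draws,
             warmup = warmup, adapt = adapt, seed = seed, ...)
}

small_cohort_config <- function(seed = 42L, clamp = TRUE,
                                mu = c(GAD = 1.5, DP = 1.5, HC = 0),
                                sigma = 3, nu = 30) {
  cohort_config(
    group_sizes = c(GAD = 40, DP = 60, HC = 80),
    true_change = data.frame(group = names(mu), variable = "stress",
                             mu = unname(mu), sigma = sigma, nu = nu),
    seed = seed, clamp = clamp
  )
}

# Hand-built multi-group posterior with known draw content, for testing the
# posterior post-processing layer without running MCMC.
fake_multi_fit <- function(labels, mu_values, sigma_values, group_n = NULL,
                           chains = 2, draws = 200) {
  stopifnot(length(labels) == length(mu_values),
            length(labels) == length(sigma_values))
  d <- list(beta0 = matrix(mean(mu_values), chains, draws))
  for (i in seq_along(labels)) {
    d[[paste0("mu_", labels[i])]] <- matrix(mu_values[i], chains, draws)
  }
  for (i in seq_along(labels)) {
    d[[paste0("beta_", labels[i])]] <-
      matrix(mu_values[i] - mean(mu_values), chains, draws)
  }
  for (i in seq_along(labels)) {
    d[[paste0("sigma_", labels[i])]] <- matrix(sigma_values[i], chains, draws)
  }
  d$nu <- matrix(30, chains, draws)
  structure(list(draws = d, model_kind = "multi_group",
                 spec = fast_spec("multi_group"),
                 groups = labels,
                 group_n = group_n %||% rep(100L, length(labels))),
            class = "posterior_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
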