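# Internal JAGS plumbing: model strings, seeded per-chain initial values,
# and conversion of coda output to chains x draws matrices.

jags_model_single <- "
model {
  for (i in 1:N) { y[i] ~ dt(mu, tau, nu) }
  tau <- pow(sigma, -2)
  mu ~ dnorm(muMean, muPrec)
  sigma ~ dunif(sigmaLo, sigmaHi)
  nu ~ dexp(nuRate) T(nuLo, )
}
"

jags_model_two <- "
model {
  for (i in 1:N1) { y1[i] ~ dt(mu[1], tau[1], nu) }
  for (i in 1:N2) { y2[i] ~ dt(mu[2], tau[2], nu) }
  for (j in 1:2) {
    mu[j] ~ dnorm(muMean, muPrec)
    sigma[j] ~ dunif(sigmaLo, sigmaHi)
    tau[j] <- pow(sigma[j], -2)
  }
  nu ~ dexp(nuRate) T(nuLo, )
}
"

# ANOVA-like model: grand intercept plus per-group deflections, per-group
# scales under a gamma prior whose mode and sd get broad uniform hyperpriors.
jags_model_multi <- "
model {
  for (i in 1:N) { y[i] ~ dt(a0 + a[g[i]], tau[g[i]], nu) }
  for (j in 1:J) {
    a[j] ~ dnorm(0, aPrec)
    sigma[j] ~ dgamma(gSh, gRa)
    tau[j] <- pow(sigma[j], -2)
  }
  gSh <- 1 + sigmaMode * gRa
  gRa <- (sigmaMode + sqrt(sigmaMode^2 + 4 * sigmaSD^2)) / (2 * sigmaSD^2)
  sigmaMode ~ dunif(sigmaLo, sigmaHi)
  sigmaSD ~ dunif(sigmaLo, sigmaHi)
  a0 ~ dnorm(yMean, a0Prec)
  nu ~ dexp(nuRate) T(nuLo, )
}
"

# Regression on standardized predictors and outcome; coefficients are
# back-transformed to the raw scale after sampling.
jags_model_regression <- "
model {
  for (i in 1:N) {
    zy[i] ~ dt(zb0 + inprod(zb[1:K], zx[i, 1:K]), tau, nu)
  }
  zb0 ~ dnorm(0, bPrec)
  for (k in 1:K) { zb[k] ~ dnorm(0, bPrec) }
  sigma ~ dunif(1.0E-3, 1.0E+3)
  tau <- pow(sigma, -2)
  nu ~ dexp(nuRate) T(nuLo, )
}
"

run_jags <- function(model_string, data, inits_values, monitor, spec) {
  inits <- lapply(seq_len(spec$chains), function(ch) {
    c(inits_values,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = derive_seed(spec$seed, paste0("chain", ch))))
  })
  fit <- tryCatch({
    model <- rjags::jags.model(textConnection(model_string), data = data,
                               inits = inits, n.chains = spec$chains,
                               n.adapt = spec$adapt, quiet = TRUE)
    stats::update(model, spec$warmup, progress.bar = "none")
    rjags::coda.samples(model, monitor, n.iter = spec$draws_per_chain,
                        progress.bar = "none")
  }, error = function(e) {
    stop(structure(
      class = c("ropebest_sampler_error", "error", "condition"),
      list(message = paste0("MCMC sampler failure: ", conditionMessage(e)),
           call = sys.call(-1), data_summary = summary(unlist(data[1])))))
  })
  # chains x draws matrix per monitored scalar node
  vars <- colnames(fit[[1]])
  draws <- lapply(vars, function(v) {
    do.call(rbind, lapply(fit, function(ch) as.numeric(ch[, v])))
  })
  names(draws) <- vars
  draws
}
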