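test_that("model specs validate their fields", {
  expect_error(model_spec(chains = 1), "chains")
  expect_error(model_spec(nu_rate = -1), "nu_rate")
  expect_error(model_spec(sigma_prior_single = c(0, 1)))
  expect_s3_class(model_spec(nu_floor = 2), "model_spec")
})

test_that("single-group fits are seed-deterministic and respect support", {
  set.seed(101)
  y <- rnorm(60, 0.4, 1)
  sp <- fast_spec(seed = 11, draws = 400)
  f1 <- fit_single_group(y, sp)
  f2 <- fit_single_group(y, sp)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws$sigma > 0))
  expect_true(all(f1$draws$nu > 0))
  f3 <- fit_single_group(y, fast_spec(seed = 12, draws = 400))
  expect_false(identical(f1$draws$mu, f3$draws$mu))
})

test_that("a nu floor constrains every retained draw", {
  set.seed(102)
  y <- c(rnorm(50), 8, -9, 12)  # outliers pull nu low
  f <- fit_single_group(y, fast_spec(seed = 2, draws = 400, nu_floor = 2))
  expect_gte(min(f$draws$nu), 2)
})

test_that("single-group HDIs cover a known location", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    y <- rnorm(200, 0.5, 1)
    f <- fit_single_group(y, fast_spec(seed = s, draws = 600))
    h <- hdi(f$draws$mu)
    if (h$lower <= 0.5 && 0.5 <= h$upper) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("degenerate single-group data are rejected with the label", {
  expect_error(fit_single_group(rep(2, 10), label = "stress DP"),
               "stress DP")
  expect_error(fit_single_group(c(1, 2)), "at least 5")
  expect_error(fit_single_group(c(1, 2, NA, 4, 5)), "missing")
})

test_that("two-group fit recovers a known separation and is symmetric", {
  set.seed(103)
  y1 <- rnorm(500, 0, 1)
  y2 <- rnorm(500, 1, 1)
  f <- fit_two_group(y1, y2, fast_spec("two_group", seed = 3, draws = 600))
  dmed <- median(posterior_draws(f, "mu2") - posterior_draws(f, "mu1"))
  expect_gt(dmed, 0.8)
  expect_lt(dmed, 1.2)

  fs <- fit_two_group(y2, y1, fast_spec("two_group", seed = 3, draws = 600))
  dmed_swapped <- median(posterior_draws(fs, "mu2") - posterior_draws(fs, "mu1"))
  expect_lt(abs(dmed + dmed_swapped), 0.1)
})

test_that("identical two-group inputs give a difference HDI containing 0", {
  set.seed(104)
  y <- rnorm(80)
  f <- fit_two_group(y, y, fast_spec("two_group", seed = 4, draws = 600))
  h <- hdi(posterior_draws(f, "mu2") - posterior_draws(f, "mu1"))
  expect_lte(h$lower, 0)
  expect_gte(h$upper, 0)
})

test_that("multi-group fit recovers cell means and enforces sum-to-zero", {
  set.seed(105)
  truth <- c(a = 0, b = 0, c = 1)
  y <- rnorm(900, rep(truth, each = 300), 1)
  g <- factor(rep(names(truth), each = 300))
  f <- fit_multi_group(y, g, fast_spec("multi_group", seed = 5, draws = 800))
  for (gl in names(truth)) {
    expect_lt(abs(median(posterior_draws(f, paste0("mu_", gl))) - truth[[gl]]),
              0.15)
  }
  defl_sum <- f$draws$beta_a + f$draws$beta_b + f$draws$beta_c
  expect_lt(max(abs(defl_sum)), 1e-10)
  # identity beta0 + beta_g = mu_g at every draw
  expect_equal(f$draws$beta0 + f$draws$beta_c, f$draws$mu_c,
               tolerance = 1e-12)
})

test_that("null multi-group data leave all deflection HDIs covering 0", {
  set.seed(106)
  y <- rnorm(600)
  g <- factor(rep(c("a", "b", "c"), each = 200))
  f <- fit_multi_group(y, g, fast_spec("multi_group", seed = 6, draws = 600))
  for (gl in levels(g)) {
    h <- hdi(posterior_draws(f, paste0("beta_", gl)))
    expect_lte(h$lower, 0)
    expect_gte(h$upper, 0)
  }
})

test_that("multi-group cell means agree with separate single-group fits", {
  set.seed(107)
  y <- rnorm(800, rep(c(0.3, 0.9), each = 400), 1)
  g <- factor(rep(c("a", "b"), each = 400))
  fm <- fit_multi_group(y, g, fast_spec("multi_group", seed = 7, draws = 800))
  for (gl in c("a", "b")) {
    fs <- fit_single_group(y[g == gl], fast_spec(seed = 7, draws = 800))
    m_multi <- median(posterior_draws(fm, paste0("mu_", gl)))
    m_single <- median(fs$draws$mu)
    # both posteriors have sd ~ 1/sqrt(400); agree within 3 such SEs
    expect_lt(abs(m_multi - m_single), 3 / sqrt(400))
  }
})

test_that("small groups are rejected by name", {
  y <- rnorm(12)
  g <- factor(c(rep("big", 11), "tiny"))
  expect_error(fit_multi_group(y, g, fast_spec("multi_group")), "tiny")
})

test_that("regression recovers slopes and reduces to the intercept-only model", {
  set.seed(108)
  x <- rnorm(500)
  y <- 2 * x + rnorm(500, 0, 0.5)
  f <- fit_regression(y, cbind(slope = x),
                      fast_spec("regression", seed = 8, draws = 600))
  b <- median(posterior_draws(f, "b_slope"))
  expect_gt(b, 1.8)
  expect_lt(b, 2.2)

  # intercept-only: same inference as the single-group model
  y0 <- rnorm(300, 0.7, 1)
  f0 <- fit_regression(y0, matrix(numeric(0), 300, 0),
                       fast_spec("regression", seed = 9, draws = 600))
  fs <- fit_single_group(y0, fast_spec(seed = 9, draws = 600))
  expect_lt(abs(median(posterior_draws(f0, "intercept")) -
                  median(fs$draws$mu)), 3 / sqrt(300))
})

test_that("a negative binary effect is detected in the posterior sign mass", {
  set.seed(109)
  z <- rbinom(2000, 1, 0.5)
  y <- -0.3 * z + rnorm(2000, 0, 1)
  f <- fit_regression(y, cbind(flag = z),
                      fast_spec("regression", seed = 10, draws = 600))
  cs <- coef_summary(f)
  expect_gte(cs$pct_below_0[cs$term == "b_flag"], 95)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  set.seed(110)
  x <- rnorm(50)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_regression(rnorm(50), X, fast_spec("regression")),
               "rank deficient")
})

test_that("with diffuse data the location posterior stays near the prior scale", {
  # five wildly spread points: the posterior sd of mu must be within an
  # order of magnitude of the prior scale, not collapsed or exploded
  y <- c(-1000, -500, 0, 500, 1000)
  sp <- fast_spec(seed = 20, draws = 600,
                  mu_prior = c(0, 2000), nu_floor = 30)
  f <- fit_single_group(y, sp)
  expect_gt(sd(posterior_draws(f, "mu")), 200)
  expect_lt(sd(posterior_draws(f, "mu")), 20000)
})
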