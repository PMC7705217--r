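test_that("hdi handles degenerate, full-mass and ordinary inputs", {
  expect_equal(unclass(hdi(rep(3.2, 10)))[c("lower", "upper")],
               list(lower = 3.2, upper = 3.2))
  x <- c(5, 1, 9, 3, 7)
  h <- hdi(x, mass = 1)
  expect_equal(c(h$lower, h$upper), c(1, 9))
  expect_error(hdi(numeric(0)), "non-empty")
  expect_error(hdi(c(1, NA, 3)), "finite")
  expect_error(hdi(1), "at least 2")
})

test_that("hdi finds the narrowest window and narrows as mass drops", {
  # a draw set with a tight cluster and a far outlier: the 80% window must
  # exclude the outlier
  x <- c(seq(0, 1, length.out = 9), 50)
  h <- hdi(x, 0.8)
  expect_lte(h$upper, 1)
  set.seed(1)
  d <- rnorm(5000)
  w95 <- with(hdi(d, 0.95), upper - lower)
  w80 <- with(hdi(d, 0.80), upper - lower)
  w50 <- with(hdi(d, 0.50), upper - lower)
  expect_gt(w95, w80)
  expect_gt(w80, w50)
})

test_that("single-group delta reproduces printed mu/sigma/delta triples", {
  # point-mass posteriors at printed medians must give the printed delta
  triples <- list(c(2.34, 5.87, 0.40),   # depression scale
                  c(1.58, 2.98, 0.53),   # stress, generalized anxiety
                  c(2.45, 2.04, 1.20))   # hand washing, controls
  for (tr in triples) {
    es <- effect_size_single(rep(tr[1], 100), rep(tr[2], 100))
    expect_lt(abs(es$median - tr[3]), 0.015)
  }
  expect_equal(effect_size_single(rep(0, 50), rep(2, 50))$median, 0)
})

test_that("per-draw delta matches an elementwise ratio oracle", {
  set.seed(41)
  mu <- rnorm(1000, 1, 0.3)
  sigma <- exp(rnorm(1000, 0.5, 0.2))
  es <- effect_size_single(mu, sigma)
  oracle <- median(vapply(seq_along(mu), function(i) mu[i] / sigma[i],
                          numeric(1)))
  expect_equal(es$median, oracle, tolerance = 1e-12)
  expect_error(effect_size_single(mu, sigma[-1]), "shape")
  expect_error(effect_size_single(mu, -sigma), "> 0")
})

test_that("two-group delta uses the root mean of variances and is antisymmetric", {
  n <- 200
  es <- effect_size_two(rep(0, n), rep(1, n), rep(1, n), rep(1, n))
  expect_equal(unique(as.numeric(es$delta_draws)), 1.0)
  es2 <- effect_size_two(rep(0, n), rep(5, n), rep(3, n), rep(4, n))
  expect_equal(unique(as.numeric(es2$delta_draws)), 5 / sqrt(12.5),
               tolerance = 1e-12)
  set.seed(42)
  mu1 <- rnorm(500); mu2 <- rnorm(500)
  s1 <- exp(rnorm(500)); s2 <- exp(rnorm(500))
  a <- effect_size_two(mu1, mu2, s1, s2)
  b <- effect_size_two(mu2, mu1, s2, s1)
  expect_equal(as.numeric(a$delta_draws), -as.numeric(b$delta_draws))
})

test_that("posterior fractions count mass as constructed", {
  rope <- rope_spec(-0.2, 0.2)
  fr <- posterior_fractions(rep(0.5, 100), rope)
  expect_equal(unname(fr), c(100, 0, 0, 100))

  # constructed 25/50/25 placement relative to the ROPE
  d <- c(rep(-1, 25), rep(0, 50), rep(1, 25))
  fr <- posterior_fractions(d, rope)
  expect_equal(unname(fr[c("pct_below_rope", "pct_in_rope", "pct_above_rope")]),
               c(25, 50, 25))
  expect_equal(sum(fr[2:4]), 100)

  set.seed(43)
  sym <- rnorm(200000)
  expect_lt(abs(posterior_fractions(sym, rope)[["pct_above_zero"]] - 50), 0.5)
})

test_that("the three-way ROPE rule is correct on all six HDI configurations", {
  rope <- rope_spec(-0.2, 0.2)
  mk <- function(lo, hi) {
    # 1000 draws whose 95% HDI is essentially [lo, hi]
    c(seq(lo, hi, length.out = 980), seq(lo - 2, hi + 2, length.out = 20))
  }
  cases <- list(
    list(-3.0, -0.5, "accept_alternative"),  # disjoint left
    list(-0.5,  0.0, "inconclusive"),        # overlaps left edge
    list(-0.1,  0.1, "accept_null"),         # contained
    list(-0.5,  0.5, "inconclusive"),        # contains the ROPE
    list( 0.0,  0.5, "inconclusive"),        # overlaps right edge
    list( 0.5,  3.0, "accept_alternative")   # disjoint right
  )
  for (cs in cases) {
    dec <- rope_decision(mk(cs[[1]], cs[[2]]), rope)
    expect_equal(dec$verdict, cs[[3]],
                 label = sprintf("HDI [%g, %g]", cs[[1]], cs[[2]]))
  }
})

test_that("an HDI touching the ROPE bound still accepts the null (closed rope)", {
  rope <- rope_spec(-0.2, 0.2)
  d <- seq(-0.20, 0.01, length.out = 1000)  # HDI endpoints exactly on/inside
  dec <- rope_decision(d, rope, mass = 1)
  expect_equal(dec$verdict, "accept_null")
})

test_that("verdicts are invariant to joint affine rescaling", {
  set.seed(44)
  for (i in 1:10) {
    d <- rnorm(2000, runif(1, -0.5, 0.5), runif(1, 0.05, 0.5))
    a <- runif(1, 0.1, 10)
    b <- runif(1, -2, 2)
    v1 <- rope_decision(d, rope_spec(-0.2, 0.2))$verdict
    v2 <- rope_decision(a * d + b, rope_spec(a * -0.2 + b, a * 0.2 + b))$verdict
    expect_equal(v1, v2)
  }
})

test_that("constructed in-rope mass is reported exactly", {
  rope <- rope_spec(-0.2, 0.2)
  n_in <- 598; n_out <- 402
  d <- c(runif(n_in, -0.19, 0.19), runif(n_out, 0.3, 1))
  dec <- rope_decision(d, rope)
  expect_equal(dec$pct_in_rope, 59.8)
})

test_that("pooled-disorders contrast recovers constructed truth", {
  labels <- c("GAD", "DP", "ED", "HC")
  fit <- fake_multi_fit(labels, mu_values = c(1, 1, 1, 0),
                        sigma_values = c(1, 1, 1, 1))
  ct <- contrast_md_vs_hc(fit)
  expect_equal(unique(as.numeric(ct$contrast_draws)), 1)
  expect_lt(abs(ct$delta$median - 1.0), 0.1)
  expect_equal(ct$decision$verdict, "accept_alternative")

  # all groups identical: HDI of the contrast contains 0
  fit0 <- fake_multi_fit(labels, mu_values = rep(0.3, 4),
                         sigma_values = rep(1, 4))
  ct0 <- contrast_md_vs_hc(fit0)
  expect_equal(unique(as.numeric(ct0$contrast_draws)), 0)
  expect_error(contrast_md_vs_hc(fit, hc_group = "XX"), "unknown")
})

test_that("weighted and unweighted pooling agree on balanced groups", {
  labels <- c("a", "b", "HC")
  fit <- fake_multi_fit(labels, mu_values = c(0.4, 0.8, 0),
                        sigma_values = c(1, 2, 1),
                        group_n = c(250L, 250L, 500L))
  un <- contrast_md_vs_hc(fit, weights = "unweighted")
  by_n <- contrast_md_vs_hc(fit, weights = "by_n")
  expect_equal(as.numeric(un$contrast_draws), as.numeric(by_n$contrast_draws))
})
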