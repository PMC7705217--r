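test_that("scale definitions validate their invariants", {
  expect_error(scale_definition("x", 5, 3, 1), "item_min")
  expect_error(scale_definition("x", 5, 1, 3, dichotomous = TRUE), "dichotomous")
  expect_error(scale_definition("x", 5, 0, 3, subscales = list(a = c(1, 9))),
               "outside")
  reg <- default_scale_registry()
  expect_named(reg)
  for (s in reg) {
    expect_s3_class(s, "scale_definition")
    expect_lt(s$item_min, s$item_max)
    if (s$dichotomous) expect_equal(c(s$item_min, s$item_max), c(0L, 1L))
    for (idx in s$subscales) expect_true(all(idx >= 1 & idx <= s$n_items))
  }
})

test_that("sum scores match brute-force totals and respect the score range", {
  reg <- default_scale_registry()
  # all-zero responses on the 10-item stress scale
  expect_equal(score_scale(matrix(0, 4, 10), reg$phq_stress), rep(0, 4))
  # single respondent at the ceiling of the 16-item worry scale (range 1-5)
  expect_equal(score_scale(matrix(5, 1, 16), reg$pswq), 80)
  # random depression-shaped matrix vs an element-by-element oracle
  set.seed(11)
  m <- matrix(sample(0:3, 35, replace = TRUE), 5, 7)
  oracle <- vapply(1:5, function(i) sum(m[i, ]), numeric(1))
  scores <- score_scale(m, reg$dass_d)
  expect_identical(scores, oracle)
  expect_true(all(scores >= 0 & scores <= 21))
})

test_that("scoring is respondent-permutation equivariant and item-order invariant", {
  reg <- default_scale_registry()
  set.seed(21)
  m <- matrix(sample(0:4, 8 * 18, replace = TRUE), 8, 18)
  p <- sample(8)
  expect_equal(score_scale(m[p, ], reg$fks), score_scale(m, reg$fks)[p])
  expect_equal(score_scale(m[, sample(18)], reg$fks), score_scale(m, reg$fks))
})

test_that("subscale scoring selects the right items", {
  reg <- default_scale_registry()
  set.seed(31)
  m <- matrix(sample(0:4, 6 * 10, replace = TRUE), 6, 10)
  expect_equal(score_scale(m, reg$ybocs, subset = "obsessions"),
               rowSums(m[, 1:5]))
  expect_equal(score_scale(m, reg$ybocs, subset = "compulsions"),
               rowSums(m[, 6:10]))
  # panic severity: 11 physical-symptom items of the 15-item module
  b <- matrix(rbinom(15 * 4, 1, 0.5), 4, 15)
  expect_equal(score_scale(b, reg$phq_panic, subset = "severity"),
               rowSums(b[, 5:15]))
  expect_error(score_scale(m, reg$ybocs, subset = "nope"), "unknown subscale")
})

test_that("reverse-keyed items are reflected before summing", {
  s <- scale_definition("rev", 3, 1, 5, reverse_items = 2L)
  m <- rbind(c(1, 1, 1), c(5, 5, 5))
  # middle item maps 1 -> 5 and 5 -> 1
  expect_equal(score_scale(m, s), c(1 + 5 + 1, 5 + 1 + 5))
})

test_that("invalid responses are rejected with coordinates", {
  reg <- default_scale_registry()
  m <- matrix(0, 3, 10)
  m[2, 4] <- 7
  expect_error(score_scale(m, reg$phq_stress), "respondent 2, item 4")
  m[2, 4] <- NA
  expect_error(score_scale(m, reg$phq_stress), "respondent 2, item 4")
  expect_error(score_scale(matrix(0, 3, 9), reg$phq_stress), "expected 10")
})

test_that("Cronbach's alpha matches an independent covariance-formula oracle", {
  # duplicated column: variance ratio 1/2, k/(k-1) = 2 => alpha = 1
  x <- c(1, 2, 3, 4, 2)
  expect_equal(cronbach_alpha(cbind(x, x))$value, 1.0)

  # seeded integer matrix vs the covariance-matrix formulation
  set.seed(1234)
  m <- matrix(sample(0:4, 20 * 5, replace = TRUE), 20, 5)
  C <- cov(m)  # independent path: alpha from the full covariance matrix
  k <- ncol(m)
  oracle <- k / (k - 1) * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbach_alpha(m)$value, oracle, tolerance = 1e-12)

  # mutually independent items: alpha near 0 in large samples
  set.seed(99)
  ind <- matrix(rnorm(10000 * 5), 10000, 5)
  expect_lt(abs(cronbach_alpha(ind)$value), 0.05)
})

test_that("alpha never exceeds 1 and never drops when an item is duplicated", {
  # the duplication property is a statement about internally consistent
  # batteries (positively correlated items), so simulate a common factor
  set.seed(7)
  for (rep in 1:20) {
    f <- rnorm(40)
    m <- vapply(1:4, function(j) round(2 + f + rnorm(40)), numeric(40))
    a <- cronbach_alpha(m)$value
    expect_lte(a, 1)
    a_dup <- cronbach_alpha(cbind(m, m[, sample(4, 1)]))$value
    expect_gte(a_dup + 1e-12, a)
  }
})

test_that("alpha rejects degenerate input", {
  expect_error(cronbach_alpha(matrix(2, 5, 3)), "zero")
  expect_error(cronbach_alpha(matrix(1:10, 10, 1)), "2 items")
  expect_error(cronbach_alpha(matrix(0:3, 2, 2)), "3 respondents")
})

test_that("KR-20 is exactly Cronbach's alpha on binary data", {
  set.seed(55)
  for (rep in 1:10) {
    b <- matrix(rbinom(14 * 25, 1, runif(1, 0.2, 0.8)), 25, 14)
    if (var(rowSums(b)) == 0) next
    expect_equal(kr20(b)$value, cronbach_alpha(b)$value, tolerance = 1e-12)
  }
})

test_that("KR-20 matches the p*q item-variance oracle on a 14-item matrix", {
  set.seed(77)
  b <- matrix(rbinom(14 * 30, 1, 0.4), 30, 14)
  n <- nrow(b)
  p <- colMeans(b)
  oracle <- 14 / 13 * (1 - sum(p * (1 - p)) * n / (n - 1) / var(rowSums(b)))
  expect_equal(kr20(b)$value, oracle, tolerance = 1e-12)
})

test_that("perfectly consistent binary responses give KR-20 = 1", {
  # each respondent answers every item identically; respondents differ
  b <- matrix(rep(c(0, 1, 1, 0, 1), times = 14), 5, 14)
  expect_equal(kr20(b)$value, 1.0)
})

test_that("KR-20 rejects non-binary data", {
  expect_error(kr20(matrix(sample(0:2, 30, TRUE), 10, 3)), "dichotomous")
})
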