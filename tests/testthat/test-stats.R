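test_that("two-sample t: textbook fixture, symmetry, and error contracts", {
  res <- independentT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6),
                      variant = "student")
  ## pooled sd = 1.5811, se = 1.5811 * sqrt(2/5) = 1.0, t = -1/1 = -1
  expect_equal(res@statistic, -1, tolerance = 1e-12)
  expect_equal(res@df, 8)
  ## identical samples: t = 0, p = 1
  same <- independentT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)
  expect_error(independentT(1, c(1, 2)), "n >= 2")
  expect_error(independentT(c(2, 2, 2), c(3, 3, 3)), "zero variance")
})

test_that("paired t: antisymmetry, degenerate cases, patient alignment", {
  d0 <- pairedT(c(5, 7), c(6, 6))  # differences {1, -1}
  expect_equal(d0@statistic, 0)
  expect_equal(d0@pValue, 1)
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(2.0, 3.0, 4.4, 4.1)
  expect_equal(pairedT(a, b)@statistic, -pairedT(b, a)@statistic)
  ## constant shift: zero-variance differences have no t statistic
  expect_error(pairedT(c(1, 2, 3), c(3, 4, 5)), "zero variance")
  ## ids realign the after sample
  ids <- list(c("p1", "p2", "p3", "p4"), c("p4", "p3", "p2", "p1"))
  aligned <- pairedT(a, rev(b), ids = ids)
  expect_equal(aligned@statistic, pairedT(a, b)@statistic)
  expect_error(pairedT(a, b, ids = list(ids[[1]], c("p1", "p2", "p3", "px"))),
               "ids")
})

test_that("chi-square: hand-computed 2x2, null table, and margins", {
  res <- chiSquareTest(matrix(c(10, 20, 20, 10), nrow = 2))
  expect_equal(res@statistic, 100 / 15, tolerance = 1e-12)  # 6.6667
  expect_equal(res@df, 1)
  flat <- chiSquareTest(matrix(c(5, 10, 5, 10), nrow = 2))
  expect_equal(flat@statistic, 0)
  expect_equal(flat@pValue, 1)
  expect_error(chiSquareTest(matrix(c(0, 0, 5, 5), nrow = 2)),
               "expected")
  ## 2x2 chi-square equals the squared two-proportion z statistic
  tab <- matrix(c(34, 16, 21, 29), nrow = 2, byrow = TRUE)
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
  pp <- sum(tab[, 1]) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(chiSquareTest(tab)@statistic, z^2, tolerance = 1e-12)
})

test_that("one-way ANOVA: hand fixture and degenerate input", {
  res <- anovaOneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res@statistic, 3, tolerance = 1e-12)
  expect_equal(res@df, c(2, 6))
  expect_error(anovaOneway(list(c(1, 2, 3))), "at least 2")
  expect_error(anovaOneway(list(c(2, 2), c(2, 2), c(2, 2))),
               "zero within-group variance")
})

test_that("p-values match the reference implementations to 1e-6", {
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(4:12, 1), mean = runif(1, -1, 1))
    expect_equal(independentT(x, y, "welch")@pValue,
                 t.test(x, y)$p.value, tolerance = 1e-6)
    expect_equal(independentT(x, y, "student")@pValue,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-6)
    tab <- matrix(rpois(6, 30) + 1, nrow = 2)
    expect_equal(chiSquareTest(tab)@pValue,
                 suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                 tolerance = 1e-6)
    g <- list(rnorm(5), rnorm(6, 1), rnorm(7, -1))
    expect_equal(anovaOneway(g)@pValue,
                 oneway.test(v ~ f,
                             data.frame(v = unlist(g),
                                        f = rep(letters[1:3], lengths(g))),
                             var.equal = TRUE)$p.value,
                 tolerance = 1e-6)
  }
  ## paired t against the reference, separately drawn
  for (i in 1:20) {
    before <- rnorm(8)
    after <- before + rnorm(8, 0.3)
    expect_equal(pairedT(before, after)@pValue,
                 t.test(after, before, paired = TRUE)$p.value,
                 tolerance = 1e-6)
    expect_equal(pairedT(before, after)@statistic,
                 unname(t.test(after, before, paired = TRUE)$statistic),
                 tolerance = 1e-9)
  }
})
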