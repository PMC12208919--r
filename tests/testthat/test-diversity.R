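test_that("Hill diversity matches closed forms and limits", {
  expect_equal(hill_diversity(c(1, 1, 1, 1)), 4)
  expect_equal(hill_diversity(7), 1)
  expect_equal(hill_diversity(c(2, 1, 1), q = 1), 2^1.5)        # exp entropy
  expect_equal(hill_diversity(c(2, 1, 1), q = 2), 1 / 0.375)    # inv Simpson
  expect_equal(hill_diversity(c(5, 0, 3), q = 0), 2)            # richness
  # continuity at q = 1
  expect_equal(hill_diversity(c(5, 3, 2), q = 1 + 1e-9),
               hill_diversity(c(5, 3, 2), q = 1), tolerance = 1e-6)
  expect_error(hill_diversity(numeric(0)), "undefined")
  expect_error(hill_diversity(c(0, 0)), "undefined")
})

test_that("Hill diversity is nonincreasing in q and scale invariant", {
  set.seed(11)
  for (i in 1:20) {
    x <- rpois(15, 4) + c(rep(20, 3), rep(0, 12))
    x <- x[x > 0]
    qs <- c(0, 0.5, 1, 1.5, 2, 3)
    d <- vapply(qs, function(q) hill_diversity(x, q), numeric(1))
    expect_true(all(diff(d) <= 1e-8))
    expect_equal(d[1], sum(x > 0))
    expect_equal(hill_diversity(7 * x), hill_diversity(x))
  }
})

test_that("rarefied diversity agrees with the exhaustive-enumeration oracle", {
  cases <- list(c(3, 1), c(5, 3, 2), c(2, 2, 2, 2), c(6, 3, 1), c(4, 4, 4))
  for (x in cases) {
    n <- sum(x)
    for (m in c(2L, n %/% 2L, n - 1L)) {
      exact <- exact_rarefied_diversity(x, m)
      mc <- rarefied_diversity(x, m, reps = 2000, seed = 99)
      tol <- max(3 * mc$se, 1e-10)
      expect_lt(abs(mc$mean - exact), tol + 1e-12)
    }
  }
  # hand-enumerated case: counts (3,1), m = 2 -> E[D] = 1.5
  expect_equal(exact_rarefied_diversity(c(3, 1), 2), 1.5)
})

test_that("rarefaction endpoints and errors behave", {
  x <- c(5, 3, 2, 1, 1)
  full <- rarefied_diversity(x, sum(x), reps = 10, seed = 1)
  expect_equal(full$mean, hill_diversity(x))
  expect_equal(full$se, 0)
  one <- rarefied_diversity(c(1, 1), 1, reps = 25, seed = 1)
  expect_equal(one$mean, 1)
  expect_error(rarefied_diversity(x, sum(x) + 1, seed = 1), "exceeds")
  expect_error(rarefied_diversity(x, 0, seed = 1), "m")

  curve <- rarefaction_curve(x, grid = c(2, 6, sum(x)), reps = 400, seed = 5)
  expect_equal(curve$m, c(2, 6, 12))
  expect_equal(curve$mean[3], hill_diversity(x))
  # expected rarefied diversity is nondecreasing in depth (within MC noise)
  expect_true(all(diff(curve$mean) > -3 * (curve$se[-1] + curve$se[-3])))
  expect_error(rarefaction_curve(x, grid = c(6, 2)), "sorted")
  expect_error(rarefaction_curve(x, grid = c(2, 50), seed = 1), "exceeds")
})

test_that("rarefaction is bit-identical under a fixed seed", {
  x <- c(9, 5, 3, 2, 1)
  c1 <- rarefaction_curve(x, c(3, 8, 15), reps = 50, seed = 123)
  c2 <- rarefaction_curve(x, c(3, 8, 15), reps = 50, seed = 123)
  expect_identical(c1, c2)
  c3 <- rarefaction_curve(x, c(3, 8, 15), reps = 50, seed = 124)
  expect_false(identical(c1$mean, c3$mean))
})

test_that("sample coverage follows the Good-Turing form", {
  expect_equal(sample_coverage(c(2, 2, 2)), 1)      # no singletons
  expect_equal(sample_coverage(c(1, 1, 1, 1)), 0)   # all singletons
  expect_equal(sample_coverage(c(3, 1)), 0.75)      # f1=1, f2=0, n=4
  # f1 and f2 both present: formula by hand for (2,1): n=3, f1=1, f2=1
  expect_equal(sample_coverage(c(2, 1)), 1 - (1 / 3) * (2 / (2 + 2)))
  expect_error(sample_coverage(integer(0)), "undefined")
  expect_true(sample_coverage(rpois(50, 3) + 1) >= 0)
})

test_that("relative diversity normalises by the reference mean", {
  v <- c(a = 4, b = 4, c = 2)
  expect_equal(relative_diversity(v, c("a", "b")), c(a = 1, b = 1, c = 0.5))
  expect_equal(unname(relative_diversity(c(s = 5), "s")), 1)
  expect_equal(unname(relative_diversity(c(a = 3, b = 6), c("a", "b"))),
               c(3, 6) / 4.5)
  expect_error(relative_diversity(v, character(0)), "nonempty")
  expect_error(relative_diversity(v, "zzz"), "not found")
})

test_that("per-sample summaries agree with an independent implementation", {
  skip_if_not_installed("vegan")
  tab <- make_table(matrix(c(12, 5, 0, 3, 7, 7, 7, 1), 4), )
  res <- diversity_summary(tab)
  for (i in 1:2) {
    x <- tab$counts[, i]
    expect_equal(res$summary$D_obs[i],
                 exp(vegan::diversity(x, index = "shannon")))
  }
  expect_equal(hill_diversity(c(12, 5, 3), q = 2),
               vegan::diversity(c(12, 5, 3), index = "invsimpson"))
})
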