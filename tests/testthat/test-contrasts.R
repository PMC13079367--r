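test_that("contrast definition on a two-tip tree", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  u <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(abs(as.numeric(u)), 2 / sqrt(2))
  expect_equal(unname(attr(u, "variance")), 2)
})

test_that("identical tip values give all-zero contrasts", {
  tr <- random_tree(8)
  u <- pic_contrasts(tr, stats::setNames(rep(3.3, 8), tr$tip.label))
  expect_equal(as.numeric(u), rep(0, 7))
})

test_that("contrasts agree with ape's reference implementation", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    tr <- random_tree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    mine <- pic_contrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr)
    # same multiset up to sign and ordering
    expect_equal(sort(abs(as.numeric(mine))), sort(abs(unname(ref))),
                 tolerance = 1e-12)
  }
})

test_that("through-origin contrast regression equals the Brownian GLS slope", {
  set.seed(32)
  for (i in 1:30) {
    n <- sample(5:8, 1)
    tr <- random_tree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    y <- stats::setNames(-1.2 * x + rnorm(n, sd = 0.5), tr$tip.label)
    slope <- fit_scaling(as.numeric(pic_contrasts(tr, x)),
                         as.numeric(pic_contrasts(tr, y)),
                         method = "pic")$slope
    expect_equal(slope, gls_slope(tr, x, y), tolerance = 1e-8)
  }
})

test_that("star phylogeny reduces contrasts regression to OLS", {
  n <- 10
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- paste0("t", 1:n)
  set.seed(33)
  x <- stats::setNames(rnorm(n), tr$tip.label)
  y <- stats::setNames(2 - 1.2 * x + rnorm(n, sd = 0.3), tr$tip.label)
  pic_slope <- fit_scaling(as.numeric(pic_contrasts(tr, x)),
                           as.numeric(pic_contrasts(tr, y)),
                           method = "pic")$slope
  ols_slope <- fit_scaling(unname(x), unname(y), method = "ols")$slope
  expect_equal(pic_slope, ols_slope, tolerance = 1e-10)
})

test_that("contrast slope is invariant to branch-length rescaling and log base", {
  tr <- random_tree(7)
  set.seed(34)
  x <- stats::setNames(runif(7, 2, 5), tr$tip.label)
  y <- stats::setNames(1.6 - 1.2 * x + rnorm(7, sd = 0.2), tr$tip.label)
  s1 <- fit_scaling(as.numeric(pic_contrasts(tr, x)),
                    as.numeric(pic_contrasts(tr, y)), "pic")$slope
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.5
  s2 <- fit_scaling(as.numeric(pic_contrasts(tr2, x)),
                    as.numeric(pic_contrasts(tr2, y)), "pic")$slope
  expect_equal(s1, s2, tolerance = 1e-12)
  # same transformation base on both axes leaves the exponent unchanged
  s3 <- fit_scaling(as.numeric(pic_contrasts(tr, x / log10(exp(1)))),
                    as.numeric(pic_contrasts(tr, y / log10(exp(1)))),
                    "pic")$slope
  expect_equal(s1, s3, tolerance = 1e-12)
})

test_that("contrast input validation: coverage, zero variance, polytomies", {
  tr <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")  # rooted polytomy
  u <- pic_contrasts(tr, c(A = 1, B = 2, C = 4, D = 0))
  expect_length(as.numeric(u), 3)
  expect_error(pic_contrasts(tr, c(A = 1, B = 2)), "cover every tip")
  z <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(pic_contrasts(z, c(A = 1, B = 2)), "zero total branch length")
})

test_that("scaling fit handles exact, orthogonal and degenerate inputs", {
  x <- c(-2, -1, 0.5, 1, 3)
  f <- fit_scaling(x, -1.2 * x, method = "pic")
  expect_equal(f$slope, -1.2)
  expect_equal(f$r2, 1)
  f0 <- fit_scaling(c(-1, 1, -2, 2), c(1, 1, -1, -1), method = "pic")
  expect_equal(f0$slope, 0)
  expect_error(fit_scaling(c(0, 0, 0), c(1, 2, 3), "pic"), "degenerate")
  expect_error(fit_scaling(1:2, 1:2, "pic"), "at least 3")
  # ols variant reports an intercept and the usual r2
  fo <- fit_scaling(x, 2 - 1.2 * x, method = "ols")
  expect_equal(unname(coef(fo)), c(2, -1.2))
  expect_equal(fo$r2, 1)
  # methods on the fit object
  expect_equal(residuals(f), rep(0, 5))
  expect_equal(predict(fo, newdata = 0), 2)
  ci <- confint(f)
  expect_true(ci[1] <= -1.2 && -1.2 <= ci[2])
  expect_output(print(f), "through origin")
})
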