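test_that("Mann-Whitney U matches hand cases and symmetries", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  x <- c(1.2, 3.4, 5.1, 0.4)
  same <- mann_whitney_u(x, x)
  expect_equal(same$u, length(x)^2 / 2)

  y <- c(2.2, 0.9, 4.4)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(b$u, length(x) * length(y) - a$u)
  expect_equal(a$p_value, b$p_value)

  expect_error(mann_whitney_u(numeric(0), y), "non-empty")
})

test_that("exact p agrees with full enumeration for small samples", {
  set.seed(4)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- rnorm(n1); y <- rnorm(n2) + 0.5
    r <- mann_whitney_u(x, y)
    expect_equal(r$p_value, oracle_mw_p(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal_tie_corrected")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(r$u, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("partial correlation reduces to Pearson with a single predictor", {
  set.seed(11)
  d <- tibble::tibble(a = rnorm(50), y = rnorm(50))
  p <- partial_correlation(d, "y", "a")
  expect_equal(p$pcr, cor(d$a, d$y), tolerance = 1e-12)

  d2 <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60))
  d2$y <- d2$x1
  p2 <- partial_correlation(d2, "y", c("x1", "x2"))
  expect_equal(p2$pcr[p2$term == "x1"], 1, tolerance = 1e-10)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(21)
  n <- 120; k <- 6
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
  y <- X %*% rnorm(k) + rnorm(n)
  d <- tibble::tibble(as.data.frame(X), y = as.numeric(y))
  p <- partial_correlation(d, "y", colnames(X))
  for (j in seq_len(k)) {
    others <- X[, -j, drop = FALSE]
    ry <- stats::lm.fit(cbind(1, others), as.numeric(y))$residuals
    rx <- stats::lm.fit(cbind(1, others), X[, j])$residuals
    expect_equal(p$pcr[j], cor(ry, rx), tolerance = 1e-10)
  }
})

test_that("partial correlation is invariant to affine predictor rescaling", {
  set.seed(31)
  d <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  d$y <- d$a - 2 * d$b + rnorm(40)
  p1 <- partial_correlation(d, "y", c("a", "b", "c"))
  d2 <- d; d2$a <- 100 * d2$a - 7
  p2 <- partial_correlation(d2, "y", c("a", "b", "c"))
  expect_equal(p1$pcr, p2$pcr, tolerance = 1e-10)
})

test_that("degenerate designs are refused with informative errors", {
  d <- tibble::tibble(a = rnorm(30), y = rnorm(30))
  d$b <- 1
  expect_error(partial_correlation(d, "y", c("a", "b")), "constant")
  d$b <- 2 * d$a
  expect_error(partial_correlation(d, "y", c("a", "b")), "collinear")
  expect_error(partial_correlation(d[1:3, ], "y", c("a", "b")), "rows")
})

test_that("group comparison flags a constructed determinant and not noise", {
  set.seed(8)
  n <- 200
  d <- tibble::tibble(!!!setNames(replicate(11, runif(n, 0, 3),
                                            simplify = FALSE),
                                  conductance_names()))
  d$sustained <- d$gNa > 1.5
  gc <- build_group_comparison(d, "sustained")
  expect_true(gc$significant[gc$term == "gNa"])
  expect_lt(sum(gc$significant), 3) # the 10 noise factors stay quiet

  # row-order invariance
  gc2 <- build_group_comparison(d[sample(n), ], "sustained")
  expect_equal(tidy(gc2), tidy(gc))

  d$all <- TRUE
  expect_error(build_group_comparison(d, "all"), "non-empty")
})

test_that("signed correlation-style coefficient is bounded and signed", {
  set.seed(2)
  x <- rnorm(80); y <- -x + rnorm(80)
  expect_lt(signed_r2(x, y), 0)
  expect_gte(signed_r2(x, y), -1)
})
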