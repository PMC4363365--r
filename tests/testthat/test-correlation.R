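test_that("pearson_binary handles identity, complement and degenerate inputs", {
  x <- c(1, 0, 1, 1, 0)
  expect_equal(pearson_binary(x, x), 1)
  expect_equal(pearson_binary(x, 1 - x), -1)
  expect_true(is.na(pearson_binary(rep(1, 5), x)))
  expect_true(is.na(pearson_binary(x, rep(0, 5))))
  expect_error(pearson_binary(c(0, 1), c(1, 0)))
})

test_that("Pearson on binary data equals the phi closed form", {
  # the worked 2x2 table: n11=20, n10=5, n01=5, n00=20 -> phi = 0.6
  v <- vectors_from_table(20, 5, 5, 20)
  expect_equal(pearson_binary(v$x, v$y), 0.6, tolerance = 1e-12)
  expect_equal(phi_oracle(v$x, v$y), 0.6)

  withr::local_seed(2)
  for (rep in 1:5) {
    m <- random_bm(50, 10, prev = runif(1, 0.2, 0.8))
    r <- correlation_matrix(m)$r
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(r[i, j], phi_oracle(m$values[, i], m$values[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("correlation_matrix flags zero-variance bands instead of leaking NaN", {
  withr::local_seed(6)
  vals <- cbind(rep(1, 10), rbinom(10, 1, 0.5), rbinom(10, 1, 0.5))
  vals[1, 2] <- 1 - vals[1, 2]  # ensure variance
  vals[1, 3] <- 1 - vals[1, 3]
  m <- band_matrix(vals)
  c <- correlation_matrix(m)
  expect_identical(c$undefined, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(c$r[1, ])))
  expect_false(any(is.nan(c$r)))
  expect_equal(diag(c$r)[2:3], c("2" = 1, "3" = 1))
  expect_error(correlation_matrix(band_matrix(matrix(0:1, 2, 2))),
               "at least 3")
})

test_that("the t statistic follows t = r sqrt(n-2)/sqrt(1-r^2)", {
  expect_equal(t_statistic(0, 50), 0)
  expect_equal(t_statistic(0.6, 50), 0.6 * sqrt(48) / sqrt(0.64),
               tolerance = 1e-12)
  expect_equal(round(t_statistic(0.6, 50), 3), 5.196)
  expect_identical(t_statistic(1, 10), Inf)
  expect_identical(t_statistic(-1, 10), -Inf)
  expect_error(t_statistic(0.5, 2), "at least 3")
  expect_error(t_statistic(1.5, 10), "exceed")
})

test_that("binarize applies the two-tailed t rule at level alpha", {
  # r = 0.6 at n = 50 is significant; r = 0.1 is not
  v <- vectors_from_table(20, 5, 5, 20)
  m <- band_matrix(cbind(v$x, v$y))
  b <- binarize(correlation_matrix(m), alpha = 0.05)
  expect_identical(b$b[1, 2], 1L)

  p_r <- function(r, n) 2 * pt(abs(t_statistic(r, n)), n - 2,
                               lower.tail = FALSE)
  expect_lt(p_r(0.6, 50), 1e-5)
  expect_gt(p_r(0.1, 50), 0.4)
  expect_error(binarize(correlation_matrix(m), alpha = 1.2), "alpha")
})

test_that("two-tailed p < alpha equals one-tailed p < alpha/2", {
  withr::local_seed(31)
  for (rep in 1:20) {
    r <- runif(1, -0.99, 0.99); n <- sample(5:100, 1)
    t <- t_statistic(r, n)
    two <- 2 * pt(abs(t), n - 2, lower.tail = FALSE) < 0.05
    one <- pt(abs(t), n - 2, lower.tail = FALSE) < 0.05 / 2
    expect_identical(two, one)
  }
})

test_that("the significance boundary in |r| sits at the inverted critical t", {
  expect_equal(critical_r(50, 0.05), 0.2787106, tolerance = 5e-7)
  eps <- 1e-9
  p_r <- function(r) 2 * pt(abs(t_statistic(r, 50)), 48, lower.tail = FALSE)
  expect_lt(p_r(critical_r(50) + eps), 0.05)
  expect_gt(p_r(critical_r(50) - eps), 0.05)
})

test_that("zero-variance bands and perfect correlations are handled in B", {
  withr::local_seed(7)
  vals <- cbind(rep(0, 20), rbinom(20, 1, 0.5))
  vals[1, 2] <- 1L
  m <- band_matrix(cbind(vals, vals[, 2]))  # col 3 duplicates col 2
  c <- correlation_matrix(m)
  b <- binarize(c)
  expect_equal(sum(b$b[1, ]), 0)         # constant band: no links
  expect_identical(b$b[2, 3], 1L)        # |r| = 1 -> p = 0 -> link
  expect_equal(b$n_zero_variance, 1L)
  expect_identical(diag(b$b), setNames(rep(0L, 3), 1:3))
  expect_identical(b$b, t(b$b))
})

test_that("negative significant correlations produce links", {
  v <- vectors_from_table(2, 23, 23, 2)  # strong negative phi
  m <- band_matrix(cbind(v$x, v$y))
  c <- correlation_matrix(m)
  expect_lt(c$r[1, 2], -0.5)
  expect_identical(binarize(c)$b[1, 2], 1L)
})

test_that("t-rule decisions track an exact-style permutation test at small n", {
  withr::local_seed(77)
  n <- 10
  agree <- logical(200)
  for (i in seq_along(agree)) {
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (var(x) == 0 || var(y) == 0) { agree[i] <- TRUE; next }
    r_obs <- cor(x, y)
    perm <- replicate(400, abs(cor(x, sample(y))))
    p_perm <- mean(perm >= abs(r_obs) - 1e-12)
    p_t <- 2 * pt(abs(t_statistic(r_obs, n)), n - 2, lower.tail = FALSE)
    agree[i] <- (p_perm < 0.05) == (p_t < 0.05)
  }
  expect_gte(mean(agree), 0.95)
})

test_that("multiplicity correction prunes links but never adds them", {
  m <- generate_cohort(synthetic_config(50, 15, rho_within = 0.45, seed = 12))
  c <- correlation_matrix(m)
  raw <- binarize(c, correction = "none")
  bonf <- binarize(c, correction = "bonferroni")
  bh <- binarize(c, correction = "BH")
  expect_true(all(bonf$b <= raw$b))
  expect_true(all(bh$b <= raw$b))
  expect_true(all(bonf$b <= bh$b))
})

test_that("edge-list export contains one row per unique link with r and p", {
  m <- generate_cohort(synthetic_config(50, 10, rho_within = 0.5, seed = 19))
  c <- correlation_matrix(m)
  b <- binarize(c)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(c, b, path)
  el <- read.delim(path)
  expect_equal(nrow(el), sum(b$b) / 2)
  expect_true(all(el$node_a < el$node_b))
  expect_true(all(el$p < b$alpha))
  g <- as_band_graph(b, c)
  expect_equal(igraph::ecount(g), nrow(el))
  expect_equal(sort(igraph::E(g)$r), sort(el$r), tolerance = 1e-12)
})
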