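test_that("identical (config, seed) reproduces the cohort bit-for-bit", {
  cfg <- synthetic_config(30, 15, rho_within = 0.4, rho_between = 0.1,
                          seed = 42)
  expect_identical(generate_cohort(cfg)$values, generate_cohort(cfg)$values)
  cfg2 <- synthetic_config(30, 15, rho_within = 0.4, rho_between = 0.1,
                           seed = 43)
  expect_false(identical(generate_cohort(cfg)$values,
                         generate_cohort(cfg2)$values))
})

test_that("invalid configurations are rejected with the offending parameters", {
  expect_error(synthetic_config(10, 5, rho_within = 0.2, rho_between = 0.3),
               "positive definite.*rho_between \\(0.3\\)")
  expect_error(synthetic_config(10, 5, rho_within = 1),
               "positive definite")
  expect_error(synthetic_config(10, 5, prevalence = c(0.5, 1, 0.5, 0.5, 0.5)),
               "strictly inside")
  expect_error(synthetic_config(10, 6, blocks = list(1:3, 5:6)),
               "partition")
})

test_that("empirical prevalence recovers the configured marginals at large n", {
  prev <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  cfg <- synthetic_config(10000, 5, blocks = list(1:5), rho_within = 0.3,
                          rho_between = 0, prevalence = prev, seed = 8)
  freq <- colMeans(generate_cohort(cfg)$values)
  expect_true(all(abs(freq - prev) < 0.02))
})

test_that("within-block dependence exceeds between-block dependence by construction", {
  cfg <- synthetic_config(200, 10, blocks = list(1:5, 6:10),
                          rho_within = 0.9, rho_between = 0,
                          prevalence = 0.5, seed = 3)
  r <- correlation_matrix(generate_cohort(cfg))$r
  same <- outer(rep(1:2, each = 5), rep(1:2, each = 5), "==")
  within <- r[same & upper.tri(r)]
  between <- r[!same & upper.tri(r)]
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.5)   # strong blocks survive thresholding
})

test_that("group scenarios share everything but rho_within and seed", {
  base <- synthetic_config(20, 12, rho_within = 0.4, rho_between = 0.05,
                           seed = 9)
  cfgs <- group_scenario(c("A", "B", "C"), base, scale = c(1, 1, 1))
  for (cfg in cfgs) {
    expect_equal(cfg$rho_within, base$rho_within)
    expect_equal(cfg$prevalence, base$prevalence)
    expect_equal(cfg$blocks, base$blocks)
  }
  expect_equal(vapply(cfgs, `[[`, 1L, "seed"), c(A = 9L, B = 10L, C = 11L))
  expect_error(group_scenario("A", base), "at least two")
  expect_error(group_scenario(c("A", "B"), base, rho_within = c(0.1, 0.2)),
               "non-increasing")
})

test_that("decreasing latent rho yields decreasing realized within-block phi at large n", {
  base <- synthetic_config(5000, 10, blocks = list(1:5, 6:10),
                           rho_between = 0, prevalence = 0.5, seed = 21,
                           rho_within = 0.6)
  cfgs <- group_scenario(c("G1", "G2", "G3"), base,
                         rho_within = c(0.6, 0.4, 0.2))
  same <- outer(rep(1:2, each = 5), rep(1:2, each = 5), "==")
  mean_phi <- vapply(names(cfgs), function(g) {
    r <- correlation_matrix(generate_cohort(cfgs[[g]], g))$r
    mean(r[same & upper.tri(r)])
  }, numeric(1))
  expect_true(all(diff(mean_phi) < 0))
})

test_that("hub ranking places strong-block members above background bands", {
  cfg <- synthetic_config(100, 20, blocks = c(list(1:6), as.list(7:20)),
                          rho_within = 0.8, rho_between = 0,
                          prevalence = 0.5, seed = 14)
  c <- correlation_matrix(generate_cohort(cfg))
  tab <- node_intensity_table(c, binarize(c))
  top6 <- tab$node[order(tab$rank)][1:6]
  expect_setequal(top6, 1:6)
})

test_that("a YAML scenario file reproduces the configured groups", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("n_participants: 25", "n_bands: 10", "rho_within: 0.5",
               "rho_between: 0.0", "seed: 6", "block_size: 5",
               "groups: [G1, G2]", "group_rho_within: [0.5, 0.25]"), path)
  cfgs <- read_scenario(path)
  expect_named(cfgs, c("G1", "G2"))
  expect_equal(cfgs$G1$rho_within, 0.5)
  expect_equal(cfgs$G2$rho_within, 0.25)
  expect_equal(cfgs$G1$n_participants, 25L)
  expect_identical(generate_cohort(cfgs$G1)$values,
                   generate_cohort(cfgs$G1)$values)
})
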