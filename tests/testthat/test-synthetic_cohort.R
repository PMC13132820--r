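test_that("default cohorts have the study dimensions, phases and group sizes", {
  co <- simulate_cohort(synthetic_config(seed = 101))
  expect_equal(dim(co$X), c(152, 35))
  expect_equal(dim(co$Y), c(152, 4))
  expect_equal(as.integer(table(attr(co$X, "phase_block"))[c("pre", "within", "post")]),
               c(17, 12, 6))
  expect_identical(attr(co$X, "role"), "predictor")
  expect_equal(as.integer(table(outcome_grouping(co$Y))), c(70, 49, 33))
})

test_that("the same seed yields bit-identical cohorts; different seeds differ", {
  a <- simulate_cohort(synthetic_config(seed = 5))
  b <- simulate_cohort(synthetic_config(seed = 5))
  d <- simulate_cohort(synthetic_config(seed = 6))
  expect_identical(as.matrix(a$X), as.matrix(b$X))
  expect_identical(as.matrix(a$Y), as.matrix(b$Y))
  expect_identical(a$truth$t, b$truth$t)
  expect_false(identical(as.matrix(a$X), as.matrix(d$X)))
})

test_that("outcome couplings hold for every generated row", {
  for (seed in c(1, 22, 333)) {
    co <- simulate_cohort(synthetic_config(seed = seed))
    Y <- as.matrix(co$Y)
    ca <- Y[, "continuous_abstinence"]
    af <- Y[, "abstinent_at_followup"]
    expect_true(all(af[ca == 1] == 1))
    expect_true(all(Y[af == 1, "daily_consumption_g"] == 0))
    expect_true(all(Y[ca == 1, "abstinent_days"] == co$config$follow_up_days))
    expect_true(all(Y[, "daily_consumption_g"] >= 0))
    expect_true(all(Y[, "abstinent_days"] >= 0 &
                      Y[, "abstinent_days"] <= co$config$follow_up_days))
  }
})

test_that("binary predictor prevalence matches its target within binomial tolerance", {
  cfg <- synthetic_config(n = 800, binary_prevalence = 0.35, seed = 13)
  co <- simulate_cohort(cfg)
  bin <- attr(co$X, "column_kind") == "binary"
  prev <- colMeans(as.matrix(co$X)[, bin])
  # empirical-quantile thresholding is exact up to rounding
  expect_true(all(abs(prev - 0.35) < 1 / cfg$n + 1e-12))
})

test_that("a rank-0 configuration leaves the blocks uncorrelated", {
  cfg <- synthetic_config(n = 500, planted_rank = 0, seed = 17)
  co <- simulate_cohort(cfg)
  # project on the default planted directions of a rank-1 sibling config
  ref <- synthetic_config(n = 500, seed = 17)
  xi <- as.matrix(co$X) %*% ref$planted_u[, 1]
  om <- as.matrix(co$Y) %*% ref$planted_v[, 1]
  expect_lt(abs(cor(xi, om)), 0.2)
})

test_that("signal_sd = 0 also removes the cross-block association", {
  cfg <- synthetic_config(n = 500, signal_sd = 0, seed = 19)
  co <- simulate_cohort(cfg)
  xi <- as.matrix(co$X) %*% cfg$planted_u[, 1]
  om <- as.matrix(co$Y) %*% cfg$planted_v[, 1]
  expect_lt(abs(cor(xi, om)), 0.2)
})

test_that("strong planted signal makes the SVD of standardized X'Y recover the loadings", {
  # u-recovery: continuous predictors, coupled observable outcomes
  cfg_u <- synthetic_config(n = 2000, binary_fraction = c(0, 0, 0),
                            ordinal_fraction = c(0, 0, 0),
                            signal_sd = 4, noise_sd = 1, seed = 23)
  co_u <- simulate_cohort(cfg_u)
  Xs <- scale(as.matrix(co_u$X)); Ys <- scale(as.matrix(co_u$Y))
  sv <- svd(crossprod(Xs, Ys))
  expect_gt(cosine(sv$u[, 1], cfg_u$planted_u[, 1]), 0.95)

  # v-recovery requires the latent linear outcome block (the observation
  # model thresholds and censors, which distorts per-column covariances)
  cfg_v <- synthetic_config(n = 2000, binary_fraction = c(0, 0, 0),
                            ordinal_fraction = c(0, 0, 0), raw_outcomes = TRUE,
                            signal_sd = 4, noise_sd = 1, seed = 23)
  co_v <- simulate_cohort(cfg_v)
  sv2 <- svd(crossprod(scale(as.matrix(co_v$X)), scale(as.matrix(co_v$Y))))
  expect_gt(cosine(sv2$v[, 1], cfg_v$planted_v[, 1]), 0.95)
})

test_that("planted dimension mismatches are rejected", {
  expect_error(synthetic_config(planted_u = matrix(1, 10, 1)), "planted_u")
  expect_error(synthetic_config(planted_v = matrix(1, 3, 1)), "planted_v")
})

test_that("the descriptive panel partitions the cohort and matches pooled identities", {
  co <- simulate_cohort(synthetic_config(seed = 29))
  t1 <- table_one_summary(co)
  g <- outcome_grouping(co$Y)
  sizes <- attr(t1, "group_sizes")
  expect_equal(sum(sizes), nrow(co$X))
  expect_equal(nrow(t1), ncol(co$X) + ncol(co$Y))
  # pooled mean equals the size-weighted mean of group means
  v <- as.matrix(co$X)[, "pre_02"]
  gm <- tapply(v, g, mean)
  expect_equal(pooled_group_mean(as.numeric(gm), as.numeric(table(g))),
               mean(v), tolerance = 1e-12)
  # q-values come from a joint BH pass over the emitted family
  ok <- !is.na(t1$p_raw)
  expect_equal(t1$q_fdr[ok], bh_fdr(t1$p_raw[ok]))
  # outcome rows separate the groups by construction
  expect_gt(t1$statistic[t1$variable == "continuous_abstinence"], 100)
})

test_that("a degenerate grouping with empty groups is reported with a warning", {
  co <- simulate_cohort(synthetic_config(seed = 31,
                                         group_props = c(1, 0, 0)))
  g <- outcome_grouping(co$Y)
  expect_equal(as.integer(table(g)), c(152, 0, 0))
  expect_warning(t1 <- table_one_summary(co, grouping = g), "empty")
  expect_true(all(is.na(t1$statistic)))
})
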