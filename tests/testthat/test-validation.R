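cfg_small <- function(...) {
  args <- list(outer_folds = 5, inner_folds = 5, grid_size = c(3, 3),
               n_permutations = 49, n_bootstraps = 0)
  do.call(cv_config, utils::modifyList(args, list(...)))
}

test_that("stratified folds partition the cohort proportionally and reproducibly", {
  labels <- factor(rep(c("a", "b", "c"), c(70, 49, 33)))
  folds <- make_stratified_folds(labels, 10, seed = 3)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), 1:152)
  expect_equal(sum(lengths(folds)), 152)  # disjoint given the union
  expect_true(all(lengths(folds) %in% c(15, 16)))
  # per-label counts within 1 of proportionality
  for (lev in levels(labels)) {
    cnt <- vapply(folds, function(f) sum(labels[f] == lev), 0L)
    expect_lte(diff(range(cnt)), 1)
  }
  expect_identical(folds, make_stratified_folds(labels, 10, seed = 3))
  expect_false(identical(folds, make_stratified_folds(labels, 10, seed = 4)))
  expect_error(make_stratified_folds(labels, 200, seed = 1), "more folds")
  expect_warning(make_stratified_folds(factor(rep(c("a", "b"), c(30, 3))), 5, 1),
                 "relaxed")
})

test_that("inner selection returns the singleton grid, is deterministic, and favors sparsity under sparse truth", {
  set.seed(61)
  n <- 100
  u <- rep(0, 20); u[c(2, 9, 15)] <- 1 / sqrt(3)
  v <- c(1, 1) / sqrt(2)
  t <- rnorm(n, sd = 2)
  X <- t %*% t(u) + matrix(rnorm(n * 20), n)
  Y <- t %*% t(v) + matrix(rnorm(n * 2), n)

  single <- sparsity_pair(2, 1.3)
  cfg1 <- cv_config(inner_folds = 5, grid = list(single), seed = 1)
  got <- inner_cv_select(X, Y, cfg1, labels_train = factor(rep(1, n)))
  expect_equal(got$c_u, 2)
  expect_equal(got$c_v, 1.3)

  cfg2 <- cfg_small(seed = 5)
  a <- inner_cv_select(X, Y, cfg2, labels_train = factor(rep(1, n)))
  b <- inner_cv_select(X, Y, cfg2, labels_train = factor(rep(1, n)))
  expect_identical(a$c_u, b$c_u)
  expect_identical(attr(a, "selection"), attr(b, "selection"))

  # constrained vs unconstrained: the sparse budget wins more often than
  # chance when the planted signature is 3-sparse and strong
  picks <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    t <- rnorm(n, sd = 2)
    Xs <- t %*% t(u) + matrix(rnorm(n * 20), n)
    Ys <- t %*% t(v) + matrix(rnorm(n * 2), n)
    cfg <- cv_config(inner_folds = 5, seed = s,
                     grid = list(sparsity_pair(1.7, sqrt(2)),
                                 sparsity_pair(sqrt(20), sqrt(2))))
    inner_cv_select(Xs, Ys, cfg, labels_train = factor(rep(1, n)))$c_u
  }, 0)
  expect_gt(sum(picks < 2), 5)
})

test_that("outer CV approaches r = 1 on noiseless planted data and stays null on independent blocks", {
  co <- simulate_cohort(synthetic_config(n = 200, signal_sd = 2,
                                         noise_sd = 1e-3, seed = 71,
                                         binary_fraction = c(0, 0, 0),
                                         ordinal_fraction = c(0, 0, 0),
                                         raw_outcomes = TRUE))
  ev <- outer_cv_evaluate(co$X, co$Y, cfg_small(seed = 2))
  expect_gte(ev$mean_r, 0.99)
  expect_equal(ev$r_squared, ev$mean_r^2)

  null_co <- simulate_cohort(synthetic_config(n = 500, planted_rank = 0,
                                              seed = 73))
  ev0 <- outer_cv_evaluate(null_co$X, null_co$Y, cfg_small(seed = 2))
  expect_lt(abs(ev0$mean_r), 0.2)

  # the fold log partitions the sample
  expect_setequal(unlist(ev$folds), seq_len(200))
})

test_that("no training information reaches held-out rows (instrumented provenance)", {
  co <- simulate_cohort(synthetic_config(seed = 79))
  ev <- outer_cv_evaluate(co$X, co$Y, cfg_small(seed = 3))
  for (pr in ev$provenance) {
    expect_length(intersect(pr$train_idx, pr$test_idx), 0)
    expect_identical(pr$sx_train_rows, pr$train_idx)
    expect_identical(pr$sy_train_rows, pr$train_idx)
  }
  expect_setequal(unlist(lapply(ev$provenance, `[[`, "test_idx")),
                  seq_len(nrow(co$X)))
})

test_that("the identity permutation reproduces the observed statistic exactly", {
  co <- simulate_cohort(synthetic_config(n = 120, seed = 83))
  ev <- outer_cv_evaluate(co$X, co$Y, cfg_small(seed = 4))
  xside <- splscv:::perm_xside(as.matrix(co$X), ev$folds, ev$fold_sp)
  expect_equal(splscv:::cv_perm_stat(xside, as.matrix(co$Y)), ev$mean_r,
               tolerance = 1e-12)
})

test_that("permutation p-values follow the add-one formula and are deterministic", {
  co <- simulate_cohort(synthetic_config(n = 100, signal_sd = 3, seed = 87))
  cfg <- cfg_small(seed = 5)
  ev <- outer_cv_evaluate(co$X, co$Y, cfg)
  pt <- permutation_test_lv(co$X, co$Y, cfg, ev)
  expect_length(pt$perm_r, 49)
  expect_equal(pt$p_perm,
               (1 + sum(pt$perm_r >= ev$mean_r)) / 50)
  expect_gte(pt$p_perm, 1 / 50)
  # strong signal beats every permutation -> the floor value
  expect_equal(pt$p_perm, 0.02)
  pt2 <- permutation_test_lv(co$X, co$Y, cfg, ev)
  expect_identical(pt$perm_r, pt2$perm_r)
})

test_that("signature extraction finds the planted component and stops on noise", {
  cfg <- cv_config(outer_folds = 5, inner_folds = 5, grid_size = c(3, 3),
                   n_permutations = 99, n_bootstraps = 25, seed = 6)
  planted <- simulate_cohort(synthetic_config(n = 200, signal_sd = 2,
                                              seed = 91))
  m <- extract_signature(planted$X, planted$Y, cfg)
  expect_gte(m$n_lv, 1)
  expect_lt(m$lvs[[1]]$p_perm, 0.05)
  expect_equal(m$lvs[[1]]$r_squared, m$lvs[[1]]$mean_r^2)

  noise <- simulate_cohort(synthetic_config(n = 120, planted_rank = 0,
                                            seed = 93))
  m0 <- extract_signature(noise$X, noise$Y, cfg)
  expect_identical(m0$n_lv, 0L)
  expect_gte(m0$p_stop, 0.05)
})

test_that("deflation inside extraction annihilates the recorded component", {
  cfg <- cv_config(outer_folds = 4, inner_folds = 4, grid_size = c(2, 2),
                   n_permutations = 39, n_bootstraps = 0, seed = 7)
  co <- simulate_cohort(synthetic_config(n = 150, signal_sd = 3, seed = 97))
  m <- extract_signature(co$X, co$Y, cfg)
  expect_gte(m$n_lv, 1)
  u1 <- m$deflation[[1]]$u
  # rebuild the deflated predictor block the second evaluation saw
  Z <- apply_standardizer(suppressWarnings(fit_standardizer(as.matrix(co$X))),
                          as.matrix(co$X))
  Xd <- Z - (Z %*% u1) %*% t(u1)
  expect_lt(max(abs(Xd %*% u1)), 1e-9)
})

test_that("Procrustes alignment handles signs and recovers a planted rotation", {
  ref <- c(0.6, -0.8)
  expect_identical(procrustes_align(ref, ref), ref)
  expect_identical(procrustes_align(ref, -ref), ref)
  expect_error(procrustes_align(ref, c(1, 2, 3)), "equal length")

  set.seed(99)
  W <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  aligned <- procrustes_align(W, W %*% R)
  expect_lt(max(abs(aligned - W)), 1e-6)
})

test_that("bootstrap ratios separate planted from null features and are seed-stable", {
  co <- simulate_cohort(synthetic_config(n = 250, signal_sd = 3,
                                         noise_sd = 0.3, seed = 103,
                                         binary_fraction = c(0, 0, 0),
                                         ordinal_fraction = c(0, 0, 0)))
  X <- as.matrix(co$X); Y <- as.matrix(co$Y)
  Xs <- scale(X); Ys <- scale(Y)
  sp <- sparsity_pair(2.4, 2)
  ref_fit <- spls_fit_pair(Xs, Ys, sp)
  cfg <- cv_config(n_bootstraps = 100, seed = 9)
  bs <- bootstrap_stability(X, Y, sp, list(u = ref_fit$u, v = ref_fit$v), cfg)
  tru <- which(co$config$planted_u[, 1] != 0)
  expect_gt(min(abs(bs$u_ratio[tru])), max(abs(bs$u_ratio[-tru])))
  expect_equal(bs$n_used, 100)

  bs2 <- bootstrap_stability(X, Y, sp, list(u = ref_fit$u, v = ref_fit$v), cfg)
  expect_identical(bs$u_ratio, bs2$u_ratio)

  # sign alignment prevents cancellation: randomly flipping half the
  # aligned draws wipes out the mean-to-sd ratio
  flipped <- bs$boot_u
  set.seed(1)
  cols <- sample(ncol(flipped), ncol(flipped) / 2)
  flipped[, cols] <- -flipped[, cols]
  ratio_flipped <- rowMeans(flipped) / apply(flipped, 1, sd)
  expect_gt(mean(abs(bs$u_ratio[tru])), mean(abs(ratio_flipped[tru])))
})

test_that("master-seed child streams are independent across stages", {
  co <- simulate_cohort(synthetic_config(n = 100, seed = 107))
  cfg_a <- cfg_small(seed = 11)
  cfg_b <- cfg_small(seed = 11, n_permutations = 19)
  ev_a <- outer_cv_evaluate(co$X, co$Y, cfg_a)
  ev_b <- outer_cv_evaluate(co$X, co$Y, cfg_b)
  # changing the permutation count does not move the folds
  expect_identical(ev_a$folds, ev_b$folds)
  expect_identical(ev_a$fold_r, ev_b$fold_r)
})
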