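#' Nested cross-validation configuration
#'
#' Holds every tunable of the inferential pipeline. Defaults follow the
#' analysis design this package implements: 10 outer folds for honest
#' generalization estimates, 10 inner folds for hyperparameter selection,
#' 5000 permutations for latent-variable significance, 500 bootstrap
#' resamples for weight stability, alpha 0.05, and a 5 x 5 log-spaced
#' sparsity grid over the feasible l1 range `[1, sqrt(dim)]` of each
#' block. One master seed drives independent child streams for folds,
#' permutations and bootstraps, so toggling one stage does not shift
#' another.
#'
#' @param outer_folds,inner_folds fold counts (>= 2).
#' @param n_permutations permutations for the LV significance test.
#' @param n_bootstraps bootstrap resamples for weight stability.
#' @param alpha significance level for continuing extraction.
#' @param grid list of [sparsity_pair()]s; `NULL` means a
#'   `grid_size[1] x grid_size[2]` log-spaced grid built from the data
#'   dimensions at fit time.
#' @param grid_size dimensions of the default grid.
#' @param stratification optional factor of group labels for stratified
#'   folds; `NULL` derives the three-level outcome grouping from the
#'   outcome block when possible.
#' @param max_lv cap on extracted latent variables.
#' @param seed master integer seed.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, inner_folds = 10L,
                      n_permutations = 5000L, n_bootstraps = 500L,
                      alpha = 0.05, grid = NULL, grid_size = c(5L, 5L),
                      stratification = NULL, max_lv = 10L, seed = 1L) {
  stopifnot(outer_folds >= 2L, inner_folds >= 2L, n_permutations >= 1L,
            n_bootstraps >= 0L, alpha > 0, alpha < 1, max_lv >= 1L)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 n_permutations = as.integer(n_permutations),
                 n_bootstraps = as.integer(n_bootstraps),
                 alpha = alpha, grid = grid,
                 grid_size = as.integer(grid_size),
                 stratification = stratification,
                 max_lv = as.integer(max_lv),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Default log-spaced sparsity grid
#'
#' @param p,q block dimensions.
#' @param sizes grid dimensions (c_u points x c_v points).
#' @return List of [sparsity_pair()]s covering
#'   `[1, sqrt(p)] x [1, sqrt(q)]` log-spaced.
#' @export
default_sparsity_grid <- function(p, q, sizes = c(5L, 5L)) {
  cu <- exp(seq(0, log(sqrt(p)), length.out = sizes[1L]))
  cv <- exp(seq(0, log(sqrt(q)), length.out = sizes[2L]))
  unlist(lapply(cu, function(a) lapply(cv, function(b) sparsity_pair(a, b))),
         recursive = FALSE)
}

resolve_grid <- function(cfg, p, q) {
  if (!is.null(cfg$grid)) cfg$grid else default_sparsity_grid(p, q, cfg$grid_size)
}

resolve_labels <- function(cfg, Y) {
  if (!is.null(cfg$stratification)) return(as.factor(cfg$stratification))
  tryCatch(outcome_grouping(Y),
           error = function(e) factor(rep("all", nrow(as.matrix(Y)))))
}

#' Stratified fold assignment
#'
#' Partitions `1..n` into `k` disjoint folds such that each label's count
#' per fold differs by at most 1 from proportionality and overall fold
#' sizes are as equal as possible. Deterministic given the seed.
#'
#' @param labels length-n vector of group labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of k integer index vectors (the held-out sets).
#' @export
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k > n) stop("more folds than observations")
  if (k > min(table(droplevels(labels))))
    warning("folds exceed the smallest class count; proportionality relaxed")
  with_seed(seed, {
    folds <- vector("list", k)
    totals <- numeric(k)
    for (lev in levels(droplevels(labels))) {
      idx <- sample(which(labels == lev))
      m <- length(idx)
      base <- m %/% k
      extra <- m %% k
      cnt <- rep(base, k)
      if (extra > 0) {
        # give the spare members to the currently smallest folds
        recipients <- order(totals, sample(k))[seq_len(extra)]
        cnt[recipients] <- cnt[recipients] + 1L
      }
      pos <- 0L
      for (f in seq_len(k)) {
        if (cnt[f] > 0L) {
          folds[[f]] <- c(folds[[f]], idx[pos + seq_len(cnt[f])])
          pos <- pos + cnt[f]
        }
      }
      totals <- totals + cnt
    }
    lapply(folds, sort)
  })
}

# standardize a (train, test) split of both blocks; constant-in-fold
# columns are zeroed quietly here (the flag is kept on the standardizer)
standardize_split <- function(X, Y, tr, te) {
  sx <- suppressWarnings(fit_standardizer(X[tr, , drop = FALSE], train_rows = tr))
  sy <- suppressWarnings(fit_standardizer(Y[tr, , drop = FALSE], train_rows = tr))
  list(sx = sx, sy = sy,
       Xtr = apply_standardizer(sx, X[tr, , drop = FALSE]),
       Ytr = apply_standardizer(sy, Y[tr, , drop = FALSE]),
       Xte = apply_standardizer(sx, X[te, , drop = FALSE]),
       Yte = apply_standardizer(sy, Y[te, , drop = FALSE]))
}

# held-out latent correlation for a fitted (u, v); degenerate -> NA
heldout_r <- function(Xte, Yte, u, v) {
  xi <- drop(Xte %*% u); om <- drop(Yte %*% v)
  if (stats::sd(xi) == 0 || stats::sd(om) == 0 ||
      !is.finite(stats::sd(xi)) || !is.finite(stats::sd(om))) return(NA_real_)
  stats::cor(xi, om)
}

#' Inner-loop hyperparameter selection
#'
#' Evaluates every sparsity pair of the grid by inner cross-validation on
#' the outer-training block: fit on inner-train, standardize inner-test
#' with the inner-train standardizer, and score by the held-out
#' latent-score correlation. Returns the pair maximizing the mean
#' held-out correlation across inner folds; ties break toward the
#' sparser pair (smaller `c_u + c_v`). If every fit is degenerate (all
#' weights zero), the sparsest pair is returned with a warning.
#'
#' @param X_train,Y_train outer-training blocks (unstandardized).
#' @param cfg a [cv_config()].
#' @param labels_train stratification labels for these rows.
#' @param seed fold seed (defaults to the config seed).
#' @return The selected [sparsity_pair()], with attribute `selection`: a
#'   data.frame of `c_u`, `c_v`, `mean_r` for the whole grid.
#' @export
inner_cv_select <- function(X_train, Y_train, cfg,
                            labels_train = NULL, seed = cfg$seed) {
  X <- as.matrix(X_train); Y <- as.matrix(Y_train)
  grid <- resolve_grid(cfg, ncol(X), ncol(Y))
  if (!length(grid)) stop("empty hyperparameter grid")
  if (is.null(labels_train)) labels_train <- resolve_labels(cfg, Y_train)
  folds <- make_stratified_folds(labels_train, cfg$inner_folds, seed)
  rmat <- matrix(NA_real_, length(folds), length(grid))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    sp_data <- standardize_split(X, Y, tr, te)
    M <- crossprod(sp_data$Xtr, sp_data$Ytr)
    for (gidx in seq_along(grid)) {
      g <- grid[[gidx]]
      fit <- cpp_spls_fit(M, g$c_u, g$c_v, 1e-10, 1e-6, 1000L)
      rmat[f, gidx] <- heldout_r(sp_data$Xte, sp_data$Yte,
                                 as.numeric(fit$u), as.numeric(fit$v))
    }
  }
  mean_r <- colMeans(rmat, na.rm = TRUE)
  cost <- vapply(grid, function(g) g$c_u + g$c_v, 0)
  sel <- data.frame(c_u = vapply(grid, `[[`, 0, "c_u"),
                    c_v = vapply(grid, `[[`, 0, "c_v"),
                    mean_r = mean_r)
  if (all(!is.finite(mean_r))) {
    warning("all grid fits degenerate; returning the sparsest pair")
    best <- which.min(cost)
  } else {
    mean_r[!is.finite(mean_r)] <- -Inf
    top <- which(mean_r == max(mean_r))
    best <- top[which.min(cost[top])]
  }
  out <- grid[[best]]
  attr(out, "selection") <- sel
  out
}

#' Outer cross-validation of one latent variable
#'
#' For each outer fold: select the sparsity pair by [inner_cv_select()]
#' on the outer-training set, refit on the full (standardized)
#' outer-training set, project the held-out set with the training
#' standardizer and weights, and record the held-out latent correlation.
#' The mean held-out r over folds is the latent variable's statistic and
#' its square the reported R-squared. A held-out fold with zero-variance
#' scores contributes r = 0 with a warning.
#'
#' Consensus weights (used for deflation and reporting) are the
#' element-wise mean of the per-fold weight vectors after Procrustes
#' (sign) alignment of the concatenated (u, v) pairs to the first fold,
#' re-projected onto the unit l2 sphere under the l1 budget of the
#' consensus sparsity pair (the pair selected most often across folds),
#' so the consensus obeys the same sparsity constraint as the per-fold
#' fits.
#'
#' @param X,Y full predictor and outcome blocks (unstandardized).
#' @param cfg a [cv_config()].
#' @return An object of class `lv_evaluation`: per-fold r, `mean_r`,
#'   `r_squared`, per-fold selected pairs, per-fold and consensus
#'   weights, fold index sets, and a provenance log of training rows
#'   seen by every standardizer.
#' @export
outer_cv_evaluate <- function(X, Y, cfg) {
  Xm <- as.matrix(X); Ym <- as.matrix(Y)
  if (nrow(Xm) != nrow(Ym)) stop("X and Y must be row-aligned")
  labels <- resolve_labels(cfg, Y)
  folds <- make_stratified_folds(labels, cfg$outer_folds,
                                 child_seed(cfg$seed, 1L))
  nf <- length(folds)
  p <- ncol(Xm); q <- ncol(Ym)
  fold_r <- numeric(nf)
  fold_u <- matrix(0, p, nf, dimnames = list(colnames(Xm), NULL))
  fold_v <- matrix(0, q, nf, dimnames = list(colnames(Ym), NULL))
  fold_sp <- vector("list", nf)
  provenance <- vector("list", nf)
  for (f in seq_len(nf)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(Xm)), te)
    sp_f <- inner_cv_select(Xm[tr, , drop = FALSE], Ym[tr, , drop = FALSE],
                            cfg, labels_train = droplevels(labels[tr]),
                            seed = child_seed(cfg$seed, 100L + f))
    sd_f <- standardize_split(Xm, Ym, tr, te)
    fit <- spls_fit_pair(sd_f$Xtr, sd_f$Ytr, sp_f)
    r <- heldout_r(sd_f$Xte, sd_f$Yte, fit$u, fit$v)
    if (is.na(r)) {
      warning(sprintf("fold %d: zero-variance held-out scores; r set to 0", f))
      r <- 0
    }
    fold_r[f] <- r
    fold_u[, f] <- fit$u
    fold_v[, f] <- fit$v
    fold_sp[[f]] <- sp_f
    provenance[[f]] <- list(train_idx = tr, test_idx = te,
                            sx_train_rows = sd_f$sx$train_rows,
                            sy_train_rows = sd_f$sy$train_rows)
  }
  cons <- consensus_weights(fold_u, fold_v, consensus_sparsity(fold_sp))
  mean_r <- mean(fold_r)
  structure(list(fold_r = fold_r, mean_r = mean_r,
                 r_squared = mean_r^2,
                 fold_sp = fold_sp, fold_u = fold_u, fold_v = fold_v,
                 consensus_u = cons$u, consensus_v = cons$v,
                 folds = folds, labels = labels,
                 provenance = provenance, seed = cfg$seed),
            class = "lv_evaluation")
}

# Consensus of per-fold weight pairs: sign-align the concatenated
# (u, v) pairs to the first fold, restrict to the majority support
# (features nonzero in >= half the folds, in the spirit of stability
# selection — averaging alone would smear mass over the union of the
# per-fold supports), average, and re-project onto the consensus
# sparsity constraint so the consensus obeys the same feasible set as
# the per-fold fits.
consensus_weights <- function(fold_u, fold_v, sp = NULL) {
  nf <- ncol(fold_u)
  ref <- c(fold_u[, 1L], fold_v[, 1L])
  for (f in seq_len(nf)) {
    cand <- c(fold_u[, f], fold_v[, f])
    if (sum(cand * ref) < 0) {
      fold_u[, f] <- -fold_u[, f]
      fold_v[, f] <- -fold_v[, f]
    }
  }
  consensus_one <- function(mat, budget) {
    keep <- rowMeans(mat != 0) >= 0.5
    w <- rowMeans(mat)
    if (any(keep)) w[!keep] <- 0
    if (all(w == 0)) return(w)
    if (is.null(budget)) return(w / sqrt(sum(w^2)))
    out <- as.numeric(l1l2_project(w, budget))
    names(out) <- rownames(mat)
    out
  }
  list(u = consensus_one(fold_u, sp$c_u),
       v = consensus_one(fold_v, sp$c_v))
}

# most frequently selected pair across folds; ties toward sparser
consensus_sparsity <- function(fold_sp) {
  key <- vapply(fold_sp, function(g) sprintf("%.10g|%.10g", g$c_u, g$c_v), "")
  tab <- table(key)
  top <- names(tab)[tab == max(tab)]
  cost <- vapply(fold_sp, function(g) g$c_u + g$c_v, 0)
  cand <- which(key %in% top)
  fold_sp[[cand[which.min(cost[cand])]]]
}

#' Permutation significance of a latent variable
#'
#' Builds the permutation null of the outer-CV statistic: for each
#' permutation the rows of `Y` are permuted jointly (preserving the
#' outcome block's internal structure, destroying the cross-block
#' association), and the mean held-out correlation is recomputed under
#' the same fold structure and per-fold sparsity pairs as the observed
#' analysis. The p-value is `(1 + #{perm >= observed}) / (1 + B)`.
#'
#' @param X,Y the blocks the observed evaluation was run on.
#' @param cfg a [cv_config()] (`n_permutations`, seed).
#' @param observed the `lv_evaluation` from [outer_cv_evaluate()].
#' @return List with `p_perm`, `observed_r`, and the vector of permuted
#'   statistics `perm_r`.
#' @export
permutation_test_lv <- function(X, Y, cfg, observed) {
  stopifnot(inherits(observed, "lv_evaluation"))
  if (cfg$n_permutations < 1L) stop("need at least one permutation")
  Xm <- as.matrix(X); Ym <- as.matrix(Y)
  n <- nrow(Xm)
  xside <- perm_xside(Xm, observed$folds, observed$fold_sp)
  perm_r <- with_seed(child_seed(cfg$seed, 2L), {
    vapply(seq_len(cfg$n_permutations), function(b) {
      cv_perm_stat(xside, Ym[sample.int(n), , drop = FALSE])
    }, 0)
  })
  p <- (1 + sum(perm_r >= observed$mean_r)) / (1 + cfg$n_permutations)
  list(p_perm = p, observed_r = observed$mean_r, perm_r = perm_r)
}

# fixed per-fold X-side of the permutation statistic: standardized
# training/held-out predictor slices and the fold's selected sparsity
perm_xside <- function(Xm, folds, fold_sp) {
  n <- nrow(Xm)
  lapply(seq_along(folds), function(f) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    sx <- suppressWarnings(fit_standardizer(Xm[tr, , drop = FALSE]))
    list(tr = tr, te = te,
         Xtr = apply_standardizer(sx, Xm[tr, , drop = FALSE]),
         Xte = apply_standardizer(sx, Xm[te, , drop = FALSE]),
         sp = fold_sp[[f]])
  })
}

# the outer-CV statistic (mean held-out r) for one outcome-block
# arrangement, reusing the observed fold structure and hyperparameters
cv_perm_stat <- function(xside, Yp) {
  r <- vapply(xside, function(fs) {
    sy <- suppressWarnings(fit_standardizer(Yp[fs$tr, , drop = FALSE]))
    Ytr <- apply_standardizer(sy, Yp[fs$tr, , drop = FALSE])
    Yte <- apply_standardizer(sy, Yp[fs$te, , drop = FALSE])
    fit <- cpp_spls_fit(crossprod(fs$Xtr, Ytr), fs$sp$c_u, fs$sp$c_v,
                        1e-10, 1e-6, 1000L)
    heldout_r(fs$Xte, Yte, as.numeric(fit$u), as.numeric(fit$v))
  }, 0)
  r[is.na(r)] <- 0
  mean(r)
}

#' Procrustes alignment of weight vectors or matrices
#'
#' For single weight vectors the orthogonal alignment reduces to a sign
#' choice: the candidate is flipped when its inner product with the
#' reference is negative. For multi-column weight matrices the
#' closed-form orthogonal Procrustes rotation is applied:
#' `Q = U V'` from the SVD `candidate' reference = U S V'`, returning
#' `candidate Q`.
#'
#' @param reference numeric vector or matrix.
#' @param candidate numeric vector or matrix of the same dimensions.
#' @return The aligned candidate.
#' @export
procrustes_align <- function(reference, candidate) {
  if (is.matrix(reference) || is.matrix(candidate)) {
    reference <- as.matrix(reference); candidate <- as.matrix(candidate)
    if (!all(dim(reference) == dim(candidate)))
      stop("reference and candidate must have identical dimensions")
    s <- svd(crossprod(candidate, reference))
    candidate %*% (s$u %*% t(s$v))
  } else {
    if (length(reference) != length(candidate))
      stop("reference and candidate must have equal length")
    if (sum(reference * candidate) < 0) -candidate else candidate
  }
}

#' Bootstrap-ratio feature stability
#'
#' Refits the sparse latent-variable pair on bootstrap resamples (rows
#' with replacement, standardization refitted within each resample),
#' sign-aligns each refit to the reference weights via
#' [procrustes_align()] so that sign-flipped draws do not cancel, and
#' reports per-feature bootstrap ratios: mean of aligned bootstrap
#' weights divided by their standard deviation. Features with zero
#' bootstrap SD and zero mean get ratio 0. Resamples in which a whole
#' block is constant are skipped with a warning count.
#'
#' @param X_train,Y_train blocks to resample (unstandardized).
#' @param sp the [sparsity_pair()] to refit at.
#' @param reference list with unit `u` and `v` reference weights.
#' @param cfg a [cv_config()] (`n_bootstraps`, seed).
#' @return List with `u_ratio`, `v_ratio` (named), `n_used`,
#'   `n_skipped`, and the aligned bootstrap weight matrices `boot_u`,
#'   `boot_v`.
#' @export
bootstrap_stability <- function(X_train, Y_train, sp, reference, cfg) {
  Xm <- as.matrix(X_train); Ym <- as.matrix(Y_train)
  n <- nrow(Xm)
  B <- cfg$n_bootstraps
  boot_u <- matrix(NA_real_, ncol(Xm), B)
  boot_v <- matrix(NA_real_, ncol(Ym), B)
  ref <- c(reference$u, reference$v)
  skipped <- 0L
  with_seed(child_seed(cfg$seed, 3L), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      Xb <- Xm[idx, , drop = FALSE]; Yb <- Ym[idx, , drop = FALSE]
      sx <- suppressWarnings(fit_standardizer(Xb))
      sy <- suppressWarnings(fit_standardizer(Yb))
      if (all(sx$constant) || all(sy$constant)) { skipped <- skipped + 1L; next }
      fit <- cpp_spls_fit(crossprod(apply_standardizer(sx, Xb),
                                    apply_standardizer(sy, Yb)),
                          sp$c_u, sp$c_v, 1e-10, 1e-6, 1000L)
      w <- c(as.numeric(fit$u), as.numeric(fit$v))
      if (all(w == 0)) { skipped <- skipped + 1L; next }
      w <- procrustes_align(ref, w)
      boot_u[, b] <- w[seq_len(ncol(Xm))]
      boot_v[, b] <- w[ncol(Xm) + seq_len(ncol(Ym))]
    }
  })
  if (skipped > 0)
    warning(sprintf("%d bootstrap resample(s) skipped (degenerate block)", skipped))
  used <- !is.na(boot_u[1L, ]) | !is.na(boot_v[1L, ])
  ratio <- function(mat) {
    m <- rowMeans(mat, na.rm = TRUE)
    s <- apply(mat, 1L, stats::sd, na.rm = TRUE)
    r <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf), m / s)
    r
  }
  u_ratio <- ratio(boot_u); v_ratio <- ratio(boot_v)
  names(u_ratio) <- colnames(Xm); names(v_ratio) <- colnames(Ym)
  list(u_ratio = u_ratio, v_ratio = v_ratio,
       n_used = sum(used), n_skipped = skipped,
       boot_u = boot_u, boot_v = boot_v)
}

#' Extract the full multivariate signature
#'
#' The top-level analysis: repeatedly evaluates a latent variable by
#' nested cross-validation ([outer_cv_evaluate()]), tests it against the
#' permutation null ([permutation_test_lv()]), and — while significant at
#' `cfg$alpha` — records it, assesses its weight stability by
#' [bootstrap_stability()], removes its covariance component from both
#' blocks by [projection_deflate()] with the consensus weights, and
#' continues on the deflated blocks. Extraction stops at the first
#' non-significant latent variable (or `cfg$max_lv`).
#'
#' @param X predictor block ([cohort_matrix()] or matrix).
#' @param Y outcome block, row-aligned.
#' @param cfg a [cv_config()].
#' @return An object of class `signature_model`: list of significant
#'   latent-variable results (consensus weights, per-fold r, mean r,
#'   R-squared, permutation p, bootstrap ratios, per-fold sparsity
#'   pairs, fold log), the first non-significant p-value
#'   (`p_stop`), stratification labels and the config echo.
#' @export
extract_signature <- function(X, Y, cfg = cv_config()) {
  Xm <- as.matrix(X); Ym <- as.matrix(Y)
  if (nrow(Xm) != nrow(Ym)) stop("X and Y must be row-aligned")
  labels <- resolve_labels(cfg, Y)
  cfg$stratification <- labels
  lvs <- list()
  p_stop <- NA_real_
  # Deflation must act in the space the weight vectors live in, i.e. on
  # z-scored columns. Since in-fold standardization is invariant to
  # per-column affine rescaling, z-scoring the blocks up front leaves
  # every cross-validated statistic unchanged while making the
  # projection deflation between successive LVs coherent.
  zscore0 <- function(m) {
    s <- suppressWarnings(fit_standardizer(m))
    out <- apply_standardizer(s, m)
    colnames(out) <- colnames(m)
    out
  }
  Xcur <- zscore0(Xm); Ycur <- zscore0(Ym)
  deflation <- list()
  for (k in seq_len(cfg$max_lv)) {
    cfg_k <- cfg
    cfg_k$seed <- child_seed(cfg$seed, 1000L * k)
    ev <- outer_cv_evaluate(Xcur, Ycur, cfg_k)
    pt <- permutation_test_lv(Xcur, Ycur, cfg_k, ev)
    if (pt$p_perm >= cfg$alpha) { p_stop <- pt$p_perm; break }
    if (all(ev$consensus_u == 0) || all(ev$consensus_v == 0)) {
      warning("significant LV with all-zero consensus weights; stopping")
      p_stop <- pt$p_perm
      break
    }
    sp_c <- consensus_sparsity(ev$fold_sp)
    boot <- if (cfg$n_bootstraps > 0L) {
      bootstrap_stability(Xcur, Ycur, sp_c,
                          list(u = ev$consensus_u, v = ev$consensus_v), cfg_k)
    } else NULL
    lvs[[k]] <- list(index = k, u = ev$consensus_u, v = ev$consensus_v,
                     fold_r = ev$fold_r, mean_r = ev$mean_r,
                     r_squared = ev$r_squared, p_perm = pt$p_perm,
                     perm_r = pt$perm_r,
                     sp_by_fold = ev$fold_sp, sp_consensus = sp_c,
                     bootstrap = boot, folds = ev$folds,
                     provenance = ev$provenance)
    defl <- projection_deflate(Xcur, Ycur, ev$consensus_u, ev$consensus_v)
    deflation[[k]] <- list(u = ev$consensus_u, v = ev$consensus_v)
    Xcur <- defl$X; Ycur <- defl$Y
  }
  structure(list(lvs = lvs, n_lv = length(lvs), p_stop = p_stop,
                 deflation = deflation, labels = labels,
                 feature_names = colnames(Xm), outcome_names = colnames(Ym),
                 phase_block = if (inherits(X, "cohort_matrix"))
                   attr(X, "phase_block") else NULL,
                 config = cfg),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d significant latent variable(s)\n", x$n_lv))
  for (lv in x$lvs)
    cat(sprintf("  LV%d: mean held-out r = %.3f, R^2 = %.3f, p_perm = %.4g\n",
                lv$index, lv$mean_r, lv$r_squared, lv$p_perm))
  if (!is.na(x$p_stop))
    cat(sprintf("  stopped at p_perm = %.4g (alpha = %g)\n",
                x$p_stop, x$config$alpha))
  invisible(x)
}
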