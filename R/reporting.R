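#' Block-wise share of feature weights
#'
#' Summarizes how a weight vector distributes over labelled blocks (the
#' pre/within/post treatment phases for predictors, or the four outcome
#' variables): per block, aggregate the absolute weights by `sum_abs` or
#' `mean_abs`, then normalize across blocks to shares summing to 1.
#' Shares are invariant to a global sign flip of the weights. Both
#' aggregation modes are provided; `mean_abs` divides by block size and
#' so is insensitive to unequal block sizes.
#'
#' @param w numeric weight vector.
#' @param block_labels per-feature block labels, same length.
#' @param mode `"mean_abs"` (default) or `"sum_abs"`.
#' @return Named numeric vector of shares in block-label order of first
#'   appearance, class `block_proportions`.
#' @examples
#' weight_proportions(c(0.2, -0.2, 0.6), c("a", "a", "b"), mode = "sum_abs")
#' @export
weight_proportions <- function(w, block_labels, mode = c("mean_abs", "sum_abs")) {
  mode <- match.arg(mode)
  if (length(w) != length(block_labels))
    stop("block_labels must have the same length as the weights")
  labs <- if (is.factor(block_labels)) block_labels
          else factor(block_labels, levels = unique(block_labels))
  agg <- if (mode == "sum_abs") {
    tapply(abs(w), labs, sum)
  } else {
    tapply(abs(w), labs, mean)
  }
  if (anyNA(agg)) {
    warning("empty block(s); share set to 0")
    agg[is.na(agg)] <- 0
  }
  total <- sum(agg)
  shares <- if (total == 0) agg else agg / total
  structure(as.numeric(shares), names = names(agg), mode = mode,
            class = c("block_proportions", "numeric"))
}

#' @export
print.block_proportions <- function(x, ...) {
  cat(sprintf("block shares (%s):\n", attr(x, "mode")))
  for (i in seq_along(x))
    cat(sprintf("  %-10s %5.1f%%\n", names(x)[i], 100 * x[i]))
  invisible(x)
}

#' Write the signature reports
#'
#' Serializes a fitted [extract_signature()] model as plain CSV files a
#' downstream reader can re-load: per-LV feature weight tables (block
#' labels and bootstrap ratios included), an LV summary (per-fold r,
#' mean r, R-squared, permutation p), the block-proportion report under
#' both aggregation modes, and a run log capturing seeds and fold
#' assignments. With zero significant LVs only the summary (stating
#' zero) and the run log are written.
#'
#' @param model a `signature_model`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of written paths.
#' @export
write_signature_report <- function(model, dir) {
  stopifnot(inherits(model, "signature_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(summary = file.path(dir, "lv_summary.csv"),
             log = file.path(dir, "run_log.txt"))
  summary_df <- if (model$n_lv == 0) {
    data.frame(lv = integer(), mean_r = numeric(), r_squared = numeric(),
               p_perm = numeric())
  } else {
    do.call(rbind, lapply(model$lvs, function(lv) {
      data.frame(lv = lv$index, mean_r = lv$mean_r,
                 r_squared = lv$r_squared, p_perm = lv$p_perm,
                 t(stats::setNames(lv$fold_r,
                                   sprintf("fold_r_%02d", seq_along(lv$fold_r)))),
                 check.names = FALSE)
    }))
  }
  utils::write.csv(summary_df, paths[["summary"]], row.names = FALSE)
  if (model$n_lv > 0) {
    paths[["weights"]] <- file.path(dir, "feature_weights.csv")
    wtab <- do.call(rbind, lapply(model$lvs, function(lv) {
      data.frame(
        lv = lv$index,
        feature = c(model$feature_names, model$outcome_names),
        block = c(if (is.null(model$phase_block))
          rep("predictor", length(lv$u)) else model$phase_block,
          rep("outcome", length(lv$v))),
        weight = c(lv$u, lv$v),
        bootstrap_ratio = if (is.null(lv$bootstrap)) NA_real_ else
          c(lv$bootstrap$u_ratio, lv$bootstrap$v_ratio))
    }))
    utils::write.csv(wtab, paths[["weights"]], row.names = FALSE)
    paths[["proportions"]] <- file.path(dir, "block_proportions.csv")
    ptab <- do.call(rbind, lapply(model$lvs, function(lv) {
      labs <- if (is.null(model$phase_block))
        rep("predictor", length(lv$u)) else model$phase_block
      rows <- lapply(c("mean_abs", "sum_abs"), function(m) {
        pu <- weight_proportions(lv$u, labs, mode = m)
        pv <- weight_proportions(lv$v, model$outcome_names, mode = m)
        data.frame(lv = lv$index, mode = m,
                   block = c(names(pu), names(pv)),
                   side = rep(c("predictor", "outcome"),
                              c(length(pu), length(pv))),
                   share = c(as.numeric(pu), as.numeric(pv)))
      })
      do.call(rbind, rows)
    }))
    utils::write.csv(ptab, paths[["proportions"]], row.names = FALSE)
  }
  log_lines <- c(
    sprintf("seed: %d", model$config$seed),
    sprintf("alpha: %g", model$config$alpha),
    sprintf("outer_folds: %d  inner_folds: %d  permutations: %d  bootstraps: %d",
            model$config$outer_folds, model$config$inner_folds,
            model$config$n_permutations, model$config$n_bootstraps),
    sprintf("significant LVs: %d", model$n_lv),
    if (!is.na(model$p_stop)) sprintf("stopping p_perm: %.6g", model$p_stop),
    unlist(lapply(model$lvs, function(lv) {
      c(sprintf("LV%d fold assignments (held-out indices):", lv$index),
        vapply(seq_along(lv$folds), function(f)
          sprintf("  fold %02d: %s", f,
                  paste(lv$folds[[f]], collapse = " ")), ""))
    })))
  writeLines(log_lines, paths[["log"]])
  invisible(paths)
}
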