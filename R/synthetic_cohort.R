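#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with the structure the signature analysis assumes: a
#' mixed binary/ordinal/continuous predictor block split into pre-,
#' within- and post-treatment phases, a four-variable abstinence outcome
#' block, and a planted low-rank cross-block covariance. Defaults mirror
#' the study scale this package is built around: 152 participants,
#' 17/12/6 predictors per phase, and a three-level outcome grouping with
#' sizes 70/49/33 (continuously abstinent / abstinent at follow-up only /
#' not abstinent).
#'
#' The generative model draws a latent factor `t_r ~ N(0, signal_sd^2)`
#' per participant and planted component; each continuous feature `j` is
#' `sum_r t_r u_rj + N(0, noise_sd^2)`. Binary features are thresholded
#' at the empirical quantile matching `binary_prevalence`; ordinal
#' features are quartile-binned to a 1-4 scale. Within each phase the
#' continuous features come first, then ordinal, then binary, so the
#' default planted support (leading features) carries exactly linear
#' signal while thresholded features carry attenuated, monotone signal.
#'
#' Outcomes: the four latent outcome columns follow the same linear
#' model through `planted_v`. A single abstinence propensity (the mean of
#' the two binary-outcome latent columns) is thresholded at empirical
#' quantiles calibrated to `group_props`, which makes the deterministic
#' couplings hold by construction: continuous abstinence implies
#' abstinence at follow-up, abstinent rows have zero daily consumption,
#' and continuously abstinent rows sit at the follow-up-window maximum of
#' abstinent days. With `raw_outcomes = TRUE` the observation model
#' (thresholding, zero-inflation, censoring) is bypassed and the latent
#' linear outcome columns are emitted directly — useful for validating
#' linear-model recovery properties.
#'
#' @param n participants.
#' @param p_pre,p_within,p_post predictor counts per treatment phase.
#' @param binary_fraction length-3 fractions of binary features per phase.
#' @param ordinal_fraction length-3 fractions of ordinal features per phase.
#' @param binary_prevalence target prevalence of binary predictors
#'   (scalar, recycled).
#' @param planted_rank number of planted cross-block components (0 =
#'   independent blocks).
#' @param planted_u p x rank matrix (or p-vector) of unit-l2 predictor
#'   loadings; default loads 4 pre, 3 within and 2 post features.
#' @param planted_v 4 x rank matrix (or 4-vector) of unit-l2 outcome
#'   loadings; default favors abstinence (negative daily-consumption
#'   loading).
#' @param signal_sd SD of each latent factor.
#' @param noise_sd SD of feature noise, > 0.
#' @param group_props target proportions of the three outcome groups
#'   (continuous abstinence, follow-up only, not abstinent); must sum
#'   to 1.
#' @param follow_up_days length of the follow-up window in days (cap for
#'   abstinent days).
#' @param consumption_mean,consumption_sd location/scale of daily alcohol
#'   consumption (g/day) among non-abstinent rows.
#' @param days_mean,days_sd location/scale of abstinent days among rows
#'   without continuous abstinence.
#' @param raw_outcomes emit latent linear outcomes instead of the coupled
#'   observables.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 152L,
                             p_pre = 17L, p_within = 12L, p_post = 6L,
                             binary_fraction = c(0.7, 0.58, 0.8),
                             ordinal_fraction = c(0.06, 0, 0),
                             binary_prevalence = 0.35,
                             planted_rank = 1L,
                             planted_u = NULL,
                             planted_v = NULL,
                             signal_sd = 1,
                             noise_sd = 1,
                             group_props = c(70, 49, 33) / 152,
                             follow_up_days = 180L,
                             consumption_mean = 92.2, consumption_sd = 88,
                             days_mean = 60, days_sd = 50,
                             raw_outcomes = FALSE,
                             seed = 1L) {
  p <- p_pre + p_within + p_post
  stopifnot(n >= 2, p >= 1, planted_rank >= 0, noise_sd > 0, signal_sd >= 0,
            length(binary_fraction) == 3L, length(ordinal_fraction) == 3L,
            abs(sum(group_props) - 1) < 1e-8, length(group_props) == 3L)
  if (planted_rank > 0) {
    if (is.null(planted_u)) planted_u <- default_planted_u(p_pre, p_within,
                                                           p_post, planted_rank)
    if (is.null(planted_v)) planted_v <- default_planted_v(planted_rank)
    planted_u <- as.matrix(planted_u); planted_v <- as.matrix(planted_v)
    if (nrow(planted_u) != p || ncol(planted_u) != planted_rank)
      stop(sprintf("planted_u must be %d x %d", p, planted_rank))
    if (nrow(planted_v) != 4L || ncol(planted_v) != planted_rank)
      stop(sprintf("planted_v must be 4 x %d", planted_rank))
    planted_u <- apply(planted_u, 2L, function(w) w / sqrt(sum(w^2)))
    planted_v <- apply(planted_v, 2L, function(w) w / sqrt(sum(w^2)))
    planted_u <- matrix(planted_u, p, planted_rank)
    planted_v <- matrix(planted_v, 4L, planted_rank)
  }
  structure(list(n = as.integer(n), p_pre = as.integer(p_pre),
                 p_within = as.integer(p_within), p_post = as.integer(p_post),
                 binary_fraction = binary_fraction,
                 ordinal_fraction = ordinal_fraction,
                 binary_prevalence = binary_prevalence,
                 planted_rank = as.integer(planted_rank),
                 planted_u = planted_u, planted_v = planted_v,
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 group_props = group_props,
                 follow_up_days = as.integer(follow_up_days),
                 consumption_mean = consumption_mean,
                 consumption_sd = consumption_sd,
                 days_mean = days_mean, days_sd = days_sd,
                 raw_outcomes = isTRUE(raw_outcomes),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# default sparse support: a 6-feature signature on the leading
# (continuous) features of each phase, alternating signs
default_planted_u <- function(p_pre, p_within, p_post, rank) {
  p <- p_pre + p_within + p_post
  U <- matrix(0, p, rank)
  picks <- c(seq_len(min(3L, p_pre)),
             p_pre + seq_len(min(2L, p_within)),
             p_pre + p_within + seq_len(min(1L, p_post)))
  for (r in seq_len(rank)) {
    idx <- ((picks + (r - 1L) * 2L - 1L) %% p) + 1L
    U[idx, r] <- rep_len(c(1, -1, 1, 1, -1), length(idx))
  }
  U
}

default_planted_v <- function(rank) {
  V <- matrix(0, 4L, rank)
  V[, 1L] <- c(1, 1, -1, 1)
  if (rank >= 2L) for (r in 2:rank) V[, r] <- c(1, -1, (-1)^r, 0)
  V
}

outcome_names <- c("continuous_abstinence", "abstinent_at_followup",
                   "daily_consumption_g", "abstinent_days")

#' Simulate a synthetic cohort
#'
#' Draws a cohort from the generative model described in
#' [synthetic_config()]. Fully reproducible from the config seed; the
#' global RNG state is left untouched.
#'
#' @param cfg a [synthetic_config()].
#' @return An object of class `synthetic_cohort`: list with `X` and `Y`
#'   ([cohort_matrix()] blocks), `truth` (planted loadings, latent factor
#'   values, abstinence propensity, latent outcome columns) and `config`.
#' @examples
#' cohort <- simulate_cohort(synthetic_config(seed = 42))
#' dim(cohort$X)  # 152 x 35
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    p <- cfg$p_pre + cfg$p_within + cfg$p_post
    R <- cfg$planted_rank
    Tmat <- matrix(stats::rnorm(n * max(R, 1L), sd = cfg$signal_sd),
                   n, max(R, 1L))
    Xlat <- matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
    Ylat <- matrix(stats::rnorm(n * 4L, sd = cfg$noise_sd), n, 4L)
    if (R > 0) {
      Xlat <- Xlat + Tmat %*% t(cfg$planted_u)
      Ylat <- Ylat + Tmat %*% t(cfg$planted_v)
    }
    phase <- rep(c("pre", "within", "post"),
                 c(cfg$p_pre, cfg$p_within, cfg$p_post))
    kind <- character(p)
    X <- Xlat
    offset <- 0L
    for (b in 1:3) {
      pb <- c(cfg$p_pre, cfg$p_within, cfg$p_post)[b]
      if (pb == 0L) next
      k_bin <- round(cfg$binary_fraction[b] * pb)
      k_ord <- round(cfg$ordinal_fraction[b] * pb)
      k_cont <- pb - k_bin - k_ord
      if (k_cont < 0L) stop("binary + ordinal fractions exceed 1 for a phase")
      kind[offset + seq_len(pb)] <-
        rep(c("continuous", "ordinal", "binary"), c(k_cont, k_ord, k_bin))
      for (j in offset + k_cont + seq_len(k_ord)) {
        X[, j] <- as.numeric(cut(Xlat[, j],
                                 breaks = stats::quantile(Xlat[, j],
                                                          c(0, .25, .5, .75, 1)),
                                 include.lowest = TRUE, labels = FALSE))
      }
      for (j in offset + k_cont + k_ord + seq_len(k_bin)) {
        thr <- stats::quantile(Xlat[, j], 1 - cfg$binary_prevalence)
        X[, j] <- as.numeric(Xlat[, j] >= thr)
      }
      offset <- offset + pb
    }
    colnames(X) <- sprintf("%s_%02d", phase, unlist(lapply(
      c(cfg$p_pre, cfg$p_within, cfg$p_post), seq_len)))

    # abstinence propensity: mean of the two binary-outcome latent columns;
    # thresholds at empirical quantiles calibrated to the target group sizes
    eta <- (Ylat[, 1L] + Ylat[, 2L]) / 2
    m_cont <- round(n * cfg$group_props[1L])
    m_abst <- round(n * (cfg$group_props[1L] + cfg$group_props[2L]))
    ord <- order(eta, decreasing = TRUE)
    cont_abst <- abst_fu <- numeric(n)
    cont_abst[ord[seq_len(m_cont)]] <- 1
    abst_fu[ord[seq_len(m_abst)]] <- 1
    zsc <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
    consumption <- ifelse(abst_fu == 1, 0,
                          pmax(0, cfg$consumption_mean +
                                 cfg$consumption_sd * zsc(Ylat[, 3L])))
    days <- ifelse(cont_abst == 1, cfg$follow_up_days,
                   round(pmin(cfg$follow_up_days - 1L,
                              pmax(0, cfg$days_mean +
                                     cfg$days_sd * zsc(Ylat[, 4L])))))
    if (cfg$raw_outcomes) {
      Y <- Ylat
      colnames(Y) <- outcome_names
      y_kind <- rep("continuous", 4L)
    } else {
      Y <- cbind(cont_abst, abst_fu, consumption, days)
      colnames(Y) <- outcome_names
      y_kind <- c("binary", "binary", "continuous", "continuous")
    }
    list(X = cohort_matrix(X, column_kind = kind, phase_block = phase,
                           role = "predictor"),
         Y = cohort_matrix(Y, column_kind = y_kind, phase_block = "outcome",
                           role = "outcome"),
         truth = list(planted_u = cfg$planted_u, planted_v = cfg$planted_v,
                      t = Tmat[, seq_len(max(R, 1L)), drop = FALSE],
                      eta = eta, Y_latent = Ylat),
         config = cfg) |>
      structure(class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, %d predictors, 4 outcomes, planted rank %d\n",
              nrow(x$X), ncol(x$X), x$config$planted_rank))
  invisible(x)
}

#' Derive the three-level outcome grouping
#'
#' Groups participants into the mutually exclusive, exhaustive categories
#' used for descriptive statistics and fold stratification: continuously
#' abstinent; abstinent at follow-up only; not abstinent at follow-up.
#'
#' @param Y outcome `cohort_matrix` (or plain matrix) containing binary
#'   columns `continuous_abstinence` and `abstinent_at_followup`.
#' @return Factor of length n with levels `continuous_abstinence`,
#'   `followup_only`, `not_abstinent`.
#' @export
outcome_grouping <- function(Y) {
  m <- as.matrix(Y)
  need <- c("continuous_abstinence", "abstinent_at_followup")
  if (!all(need %in% colnames(m)))
    stop("outcome block must contain columns ",
         paste(need, collapse = " and "))
  ca <- m[, "continuous_abstinence"]
  af <- m[, "abstinent_at_followup"]
  if (!all(ca %in% c(0, 1)) || !all(af %in% c(0, 1)))
    stop("abstinence indicators must be binary")
  if (any(ca == 1 & af == 0))
    stop("coupling violated: continuous abstinence without follow-up abstinence")
  factor(ifelse(ca == 1, "continuous_abstinence",
                ifelse(af == 1, "followup_only", "not_abstinent")),
         levels = c("continuous_abstinence", "followup_only", "not_abstinent"))
}

#' Descriptive cohort panel by outcome group
#'
#' The standard clinical "Table 1": per variable, the pooled summary and
#' per-group summaries (mean (SD) for continuous/ordinal variables,
#' percentage for binary ones), with a tie-corrected Kruskal-Wallis or
#' Pearson chi-square test across the outcome groups and
#' Benjamini-Hochberg FDR correction over the whole emitted family.
#'
#' @param cohort a `synthetic_cohort`, or any list with `X` and `Y`
#'   [cohort_matrix()] blocks.
#' @param grouping optional factor of outcome groups; defaults to
#'   [outcome_grouping()] of the outcome block.
#' @return A data.frame with one row per variable: `variable`, `phase`,
#'   `kind`, `overall`, one summary column per group, `n` per group in
#'   attributes, `statistic`, `statistic_kind`, `df`, `p_raw`, `q_fdr`.
#'   Group sizes are in `attr(, "group_sizes")`.
#' @export
table_one_summary <- function(cohort, grouping = NULL) {
  X <- cohort$X; Y <- cohort$Y
  check_cohort_pair(X, Y)
  if (is.null(grouping)) grouping <- outcome_grouping(Y)
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == nrow(X))
  sizes <- table(grouping)
  if (any(sizes == 0))
    warning("empty outcome group(s): ",
            paste(names(sizes)[sizes == 0], collapse = ", "),
            "; statistics undefined for those cells")
  vars <- data.frame(
    variable = c(colnames(X), colnames(Y)),
    phase = c(attr(X, "phase_block"), attr(Y, "phase_block")),
    kind = c(attr(X, "column_kind"), attr(Y, "column_kind")),
    stringsAsFactors = FALSE)
  all_mat <- cbind(as.matrix(X), as.matrix(Y))
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    v <- all_mat[, i]
    binary <- vars$kind[i] == "binary"
    if (binary) {
      overall <- sprintf("%.1f", 100 * mean(v))
      by_group <- vapply(levels(grouping), function(g) {
        if (sizes[[g]] == 0) return(NA_character_)
        sprintf("%.1f", 100 * mean(v[grouping == g]))
      }, "")
      res <- tryCatch({
        tab <- table(grouping[!is.na(v)], v)
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (any(dim(tab) < 2L)) NULL
        else chi_square_independence(unclass(tab), variable = vars$variable[i])
      }, error = function(e) NULL)
    } else {
      overall <- sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
      by_group <- vapply(levels(grouping), function(g) {
        if (sizes[[g]] == 0) return(NA_character_)
        sprintf("%.1f (%.1f)", mean(v[grouping == g]),
                stats::sd(v[grouping == g]))
      }, "")
      res <- tryCatch(
        kruskal_wallis(split(v, grouping)[sizes > 0],
                       variable = vars$variable[i]),
        error = function(e) NULL)
    }
    data.frame(variable = vars$variable[i], phase = vars$phase[i],
               kind = vars$kind[i], overall = overall,
               t(by_group),
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               statistic_kind = if (is.null(res)) NA_character_ else res$statistic_kind,
               df = if (is.null(res)) NA_integer_ else res$df,
               p_raw = if (is.null(res)) NA_real_ else res$p_raw,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$q_fdr[ok] <- bh_fdr(out$p_raw[ok])
  attr(out, "group_sizes") <- as.integer(sizes)
  names(attr(out, "group_sizes")) <- names(sizes)
  rownames(out) <- NULL
  out
}
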