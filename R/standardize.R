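#' Fit a column standardizer on training rows
#'
#' Records per-column mean and sample standard deviation (denominator
#' n - 1) of the training data. Binary and ordinal columns are z-scored
#' identically to continuous ones so that downstream weight magnitudes are
#' comparable across mixed variable types. Columns constant in the
#' training rows are flagged; [apply_standardizer()] maps them to zero
#' rather than dropping them, so weight-vector dimensions stay constant
#' across cross-validation folds.
#'
#' All standardizers in the nested cross-validation are fitted strictly on
#' training partitions; the object records which rows it saw
#' (`train_rows`) so leakage can be audited after the fact.
#'
#' @param train numeric matrix or `cohort_matrix` of training rows (>= 2).
#' @param train_rows optional integer vector identifying the training rows
#'   in the parent dataset (provenance only).
#' @return An object of class `standardizer` with fields `mean`, `sd`,
#'   `constant` and `train_rows`.
#' @export
fit_standardizer <- function(train, train_rows = NULL) {
  m <- as.matrix(train)
  if (nrow(m) < 2L) stop("need >= 2 training rows to fit a standardizer")
  mu <- colMeans(m)
  sd_ <- apply(m, 2L, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  if (any(const))
    warning("constant training column(s) will be zeroed: ",
            paste(colnames(m)[const], collapse = ", "))
  structure(list(mean = mu, sd = sd_, constant = const,
                 train_rows = train_rows),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Transforms columns with the training means and SDs; flagged constant
#' columns map to all-zeros. Applying a standardizer to its own training
#' data yields columns with mean 0 and sample SD 1 (non-constant columns).
#'
#' @param s a `standardizer` from [fit_standardizer()].
#' @param data numeric matrix or `cohort_matrix` with the same columns.
#' @return A numeric matrix of z-scores (metadata attributes dropped).
#' @export
apply_standardizer <- function(s, data) {
  stopifnot(inherits(s, "standardizer"))
  m <- as.matrix(data)
  if (ncol(m) != length(s$mean))
    stop("column count does not match the fitted standardizer")
  sd_safe <- ifelse(s$constant, 1, s$sd)
  out <- sweep(sweep(m, 2L, s$mean, "-"), 2L, sd_safe, "/")
  if (any(s$constant)) out[, s$constant] <- 0
  out
}

#' Fit a covariate adjuster on training rows
#'
#' Least-squares regression (with intercept) of every feature on a
#' covariate matrix; [residualize()] subtracts the fitted linear
#' predictions. Residualization is linear and idempotent on the training
#' rows, where residuals are orthogonal to the covariates. Covariate
#' correction is off by default throughout the pipeline; this is the
#' generic hook for users who need it.
#'
#' @param train numeric matrix of training feature rows.
#' @param covariates numeric matrix (same rows) of covariates, >= 1 column.
#' @param train_rows optional provenance: row indices in the parent data.
#' @return An object of class `covariate_adjuster` holding the
#'   coefficient matrix ((c+1) x features, intercept first).
#' @export
fit_covariate_adjuster <- function(train, covariates, train_rows = NULL) {
  m <- as.matrix(train)
  cv <- as.matrix(covariates)
  if (nrow(cv) != nrow(m)) stop("covariate rows must match feature rows")
  if (ncol(cv) < 1L) stop("need at least one covariate")
  design <- cbind(`(Intercept)` = 1, cv)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("rank-deficient covariate matrix (collinear or constant covariate)")
  coef <- qr.coef(qrd, m)
  structure(list(coef = coef, train_rows = train_rows),
            class = "covariate_adjuster")
}

#' Residualize features against covariates
#'
#' @param adj a `covariate_adjuster` from [fit_covariate_adjuster()].
#' @param data numeric matrix of features to adjust.
#' @param covariates numeric matrix of covariates for these rows.
#' @return Matrix of residuals, same shape as `data`.
#' @export
residualize <- function(adj, data, covariates) {
  stopifnot(inherits(adj, "covariate_adjuster"))
  m <- as.matrix(data)
  cv <- as.matrix(covariates)
  if (nrow(cv) != nrow(m)) stop("covariate rows must match feature rows")
  design <- cbind(1, cv)
  if (ncol(design) != nrow(adj$coef))
    stop("covariate count does not match the fitted adjuster")
  m - design %*% adj$coef
}
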