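# Prediction of the clinical change ratio from changes in network
# properties: feature construction, collinearity diagnostics, OLS, and
# leave-one-out cross-validation.

#' PANSS change ratio
#'
#' `(pre - post) / pre`: the fractional symptom improvement over treatment
#' on the 30-item PANSS (scale range 30-210). Positive values mean
#' improvement; a worsening (post > pre) yields a negative ratio and is
#' allowed.
#'
#' @param pre,post Total scores (>= 30, the scale minimum). Vectorized.
#' @return Numeric vector of change ratios (<= 1).
#' @export
panss_change_ratio <- function(pre, post) {
  if (any(pre <= 0)) stop("`pre` must be positive")
  if (any(pre < 30) || any(post < 30))
    stop("PANSS totals cannot fall below the scale minimum of 30")
  (pre - post) / pre
}

#' Build the change-feature table
#'
#' Per-subject changes in the four network properties across treatment
#' (`after - before`), either averaged over tasks (default) or kept per
#' task, joined with the outcome.
#'
#' @param before,after Data frames with columns `subject`, `task`, `clu`,
#'   `le`, `ge`, `path_length`; every subject must appear in both phases
#'   for every task.
#' @param outcomes Data frame with columns `subject` and `y` (the PANSS
#'   change ratio); optional.
#' @param aggregation `"mean_over_tasks"` (default) or `"per_task"` (12
#'   features; discouraged at small n, a warning is emitted).
#' @return Data frame with one row per subject: `d_clu`, `d_le`, `d_ge`,
#'   `d_l` (suffixed by task in `per_task` mode) and `y` when outcomes are
#'   supplied.
#' @export
build_features <- function(before, after, outcomes = NULL,
                           aggregation = c("mean_over_tasks", "per_task")) {
  aggregation <- match.arg(aggregation)
  props <- c("clu", "le", "ge", "path_length")
  need <- c("subject", "task", props)
  stopifnot(all(need %in% names(before)), all(need %in% names(after)))
  key_b <- paste(before$subject, before$task)
  key_a <- paste(after$subject, after$task)
  if (!setequal(key_b, key_a) || anyDuplicated(key_b) || anyDuplicated(key_a))
    stop("every subject/task must appear exactly once in each phase")
  after <- after[match(key_b, key_a), ]
  delta <- data.frame(subject = before$subject, task = before$task,
                      d_clu = after$clu - before$clu,
                      d_le = after$le - before$le,
                      d_ge = after$ge - before$ge,
                      d_l = after$path_length - before$path_length)
  if (aggregation == "mean_over_tasks") {
    feat <- stats::aggregate(delta[c("d_clu", "d_le", "d_ge", "d_l")],
                             by = list(subject = delta$subject), FUN = mean)
  } else {
    if (length(unique(delta$subject)) <= 4 * length(unique(delta$task)))
      warning("per-task features: more predictors than is prudent for n")
    feat <- stats::reshape(delta, idvar = "subject", timevar = "task",
                           direction = "wide")
    names(feat) <- sub("^d_(\\w+)\\.(\\w+)$", "d_\\1_\\2", names(feat))
  }
  if (!is.null(outcomes)) {
    stopifnot(all(c("subject", "y") %in% names(outcomes)))
    i <- match(feat$subject, outcomes$subject)
    if (anyNA(i)) stop("outcome missing for some subjects")
    feat$y <- outcomes$y[i]
    if (anyNA(feat$y)) stop("missing outcome values")
  }
  feat
}

#' Collinearity diagnostics (VIF and tolerance)
#'
#' Variance inflation factor `VIF_k = 1 / (1 - R^2_k)` from regressing each
#' column on the others; tolerance is `1/VIF`. Columns violating the
#' conventional gates (VIF < 10, tolerance > 0.1) are flagged; a perfectly
#' collinear column is flagged with infinite VIF rather than raising an
#' error.
#'
#' @param X Numeric feature matrix or data frame (rows > columns).
#' @return Data frame with `vif`, `tolerance` and logical `flagged` per
#'   column.
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) > ncol(X))
  p <- ncol(X)
  vif <- numeric(p)
  for (k in seq_len(p)) {
    if (p == 1) { vif[k] <- 1; next }
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    vif[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  data.frame(variable = colnames(X) %||% paste0("x", seq_len(p)),
             vif = vif, tolerance = 1 / vif,
             flagged = vif >= 10 | 1 / vif <= 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prune features failing the collinearity gate
#'
#' Iteratively removes the column with the largest variance inflation
#' factor until every remaining column satisfies the conventional gates
#' (VIF < `vif_max`, tolerance > `tol_min`). On dense coherence networks
#' the four property changes can be almost (or exactly) collinear --
#' e.g. raw-weight clustering and local efficiency coincide when
#' neighbourhood shortest paths are direct edges -- and an unpruned OLS fit
#' is then rank-deficient; this gate is the standard remedy and typically
#' leaves a single change feature.
#'
#' @param X Numeric feature matrix or data frame.
#' @param vif_max,tol_min Gate thresholds (defaults 10 and 0.1).
#' @return Character vector of retained column names.
#' @export
prune_collinear <- function(X, vif_max = 10, tol_min = 0.1) {
  X <- as.matrix(X)
  keep <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- keep
  repeat {
    if (length(keep) <= 1) break
    cd <- collinearity_diagnostics(X[, keep, drop = FALSE])
    bad <- cd$vif >= vif_max | cd$tolerance <= tol_min
    if (!any(bad)) break
    worst <- which.max(ifelse(is.finite(cd$vif), cd$vif,
                              .Machine$double.xmax))
    keep <- keep[-worst]
  }
  keep
}

#' Ordinary least squares fit
#'
#' @param X Numeric predictor matrix or data frame.
#' @param y Response vector (`length(y) > ncol(X) + 1`).
#' @return List with `intercept` and named `coefficients`.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) > ncol(X) + 1,
            all(is.finite(X)), all(is.finite(y)))
  fit <- stats::lm(y ~ ., data = data.frame(X, check.names = FALSE))
  if (anyNA(stats::coef(fit))) stop("rank-deficient design matrix")
  co <- stats::coef(fit)
  list(intercept = unname(co[1]), coefficients = co[-1], lm = fit)
}

#' Leave-one-out cross-validated linear regression
#'
#' Each subject is predicted from an OLS fit on the remaining `n - 1`
#' subjects; predictions are then compared with the observed outcomes
#' (Pearson r with two-sided p; RMSE). The reported model is refit on all
#' subjects.
#'
#' @param X Numeric predictor matrix or data frame.
#' @param y Outcome vector (n >= 3).
#' @return Object of class `"regression_model"`: `intercept`,
#'   `coefficients`, `vif`, `tolerance`, `loocv_predictions`, `r`, `p`,
#'   `rmse` (outcome units) and `rmse_pct` (percentage points of the
#'   change-ratio scale).
#' @export
loocv_regression <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), n >= 3)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_linear(X[-i, , drop = FALSE], y[-i])
    preds[i] <- fit$intercept + sum(fit$coefficients * X[i, ])
  }
  full <- fit_linear(X, y)
  cd <- collinearity_diagnostics(X)
  ev <- evaluate_prediction(preds, y)
  structure(list(intercept = full$intercept,
                 coefficients = full$coefficients,
                 vif = cd$vif, tolerance = cd$tolerance,
                 loocv_predictions = preds,
                 r = ev$r, p = ev$p, rmse = ev$rmse, rmse_pct = ev$rmse_pct),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> LOOCV r = %.3f (p = %.3g), RMSE = %.3g (%.2f%%)\n",
              x$r, x$p, x$rmse, x$rmse_pct))
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  cat("  coefficients:", paste(names(x$coefficients),
                               format(unname(x$coefficients), digits = 4),
                               sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate predictions against observed outcomes
#'
#' Pearson correlation (two-sided p) and root mean square error. The RMSE
#' is additionally expressed in percentage points of the change-ratio
#' scale (`100 * rmse`), the unit in which such errors are conventionally
#' quoted.
#'
#' @param predicted,actual Equal-length numeric vectors (n >= 3). Exact
#'   agreement short-circuits to `r = 1, p = 0`.
#' @return List with `r`, `p`, `rmse`, `rmse_pct`.
#' @export
evaluate_prediction <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 3)
  rmse <- sqrt(mean((predicted - actual)^2))
  if (stats::sd(actual) == 0)
    stop("observed outcomes have zero variance; r is undefined")
  if (stats::sd(predicted) == 0)
    stop("predictions have zero variance; r is undefined")
  if (isTRUE(all.equal(stats::cor(predicted, actual), 1)))
    return(list(r = 1, p = 0, rmse = rmse, rmse_pct = 100 * rmse))
  ht <- stats::cor.test(predicted, actual)
  list(r = unname(ht$estimate), p = ht$p.value, rmse = rmse,
       rmse_pct = 100 * rmse)
}
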