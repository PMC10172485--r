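# Normality-gated group comparisons, edge-wise network statistics with
# FDR correction, and correlation families.

comparison_result <- function(test_name, statistic, df, p, direction) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = if (is.null(df)) NULL else unname(df),
                 p = unname(p), direction = direction),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g%s, p = %.4g\n", x$test_name,
              x$statistic,
              if (!is.null(x$df)) sprintf(", df = %.3g", x$df) else "",
              x$p))
  invisible(x)
}

#' Choose a two-sample test by normality gating
#'
#' Shapiro-Wilk on both samples (or on the paired differences): if both
#' p-values exceed 0.05 the t family is used, otherwise the rank test.
#' Within the independent t family, the pooled-variance t is chosen when
#' the variance-ratio F test is non-significant at 0.05, else the Welch t.
#' Degenerate (constant) samples fall through to the nonparametric test.
#'
#' @param sample1,sample2 Numeric vectors (n >= 3 each).
#' @param paired Logical.
#' @param alpha Gate level (default 0.05).
#' @return One of `"pooled_t"`, `"welch_t"`, `"paired_t"`,
#'   `"mann_whitney_u"`, `"wilcoxon_signed_rank"`.
#' @export
choose_test <- function(sample1, sample2, paired = FALSE, alpha = 0.05) {
  stopifnot(length(sample1) >= 3, length(sample2) >= 3)
  sw_ok <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
  }
  if (paired) {
    stopifnot(length(sample1) == length(sample2))
    d <- sample1 - sample2
    if (sw_ok(d)) "paired_t" else "wilcoxon_signed_rank"
  } else {
    if (sw_ok(sample1) && sw_ok(sample2)) {
      f <- stats::var.test(sample1, sample2)
      if (f$p.value < alpha) "welch_t" else "pooled_t"
    } else "mann_whitney_u"
  }
}

#' Two-sample t test from summary statistics
#'
#' Pooled or Welch-Satterthwaite independent-samples t from group means,
#' standard deviations and sizes, so that printed summary tables can be
#' re-tested without raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`sd >= 0`, `n >= 2`).
#' @param variant `"pooled"` or `"welch"`.
#' @return A `"comparison_result"` with the t statistic, degrees of
#'   freedom, two-sided p and the sign of `mean1 - mean2`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) stop("both samples have zero variance")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  comparison_result(paste0(variant, "_t"), t, df,
                    2 * stats::pt(-abs(t), df), sign(mean1 - mean2))
}

#' Paired t test
#'
#' @param values1,values2 Equal-length numeric vectors (n >= 2).
#' @return A `"comparison_result"`.
#' @export
paired_t <- function(values1, values2) {
  stopifnot(length(values1) == length(values2), length(values1) >= 2)
  d <- values1 - values2
  if (stats::sd(d) == 0)
    stop("paired differences have zero variance; t is undefined")
  ht <- stats::t.test(values1, values2, paired = TRUE)
  comparison_result("paired_t", ht$statistic, ht$parameter, ht$p.value,
                    sign(mean(d)))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples; the statistic is reported as
#' `min(U1, U2)`, the conventional scale of printed tables. The p-value
#' follows `stats::wilcox.test` (exact when feasible without ties, normal
#' approximation with tie correction otherwise).
#'
#' @param values1,values2 Numeric vectors.
#' @return A `"comparison_result"`.
#' @export
mann_whitney_u <- function(values1, values2) {
  stopifnot(length(values1) >= 1, length(values2) >= 1)
  ht <- suppressWarnings(stats::wilcox.test(values1, values2))
  u1 <- unname(ht$statistic)
  u <- min(u1, length(values1) * length(values2) - u1)
  comparison_result("mann_whitney_u", u, NULL, ht$p.value,
                    sign(stats::median(values1) - stats::median(values2)))
}

#' Wilcoxon signed-rank test
#'
#' @param values1,values2 Equal-length paired numeric vectors.
#' @return A `"comparison_result"`.
#' @export
wilcoxon_signed_rank <- function(values1, values2) {
  stopifnot(length(values1) == length(values2))
  if (all(values1 == values2))
    stop("all paired differences are ties; the signed-rank test is undefined")
  ht <- suppressWarnings(stats::wilcox.test(values1, values2, paired = TRUE))
  comparison_result("wilcoxon_signed_rank", ht$statistic, NULL, ht$p.value,
                    sign(stats::median(values1 - values2)))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up rule: reject the `k` smallest p-values where
#' `k = max{ i : p_(i) <= i * q / m }`; adjusted values via the standard
#' monotone formula (`stats::p.adjust`, method `"BH"`).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical) and `adjusted` (numeric), both in
#'   input order.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  ord <- order(pvals)
  ok <- pvals[ord] <= seq_len(m) * q / m
  k <- if (any(ok)) max(which(ok)) else 0L
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  list(reject = reject, adjusted = stats::p.adjust(pvals, method = "BH"))
}

#' Edge-wise group comparison of coherence networks
#'
#' For every unique off-diagonal edge (210 for 21 nodes) an independent
#' two-sample t-test across subjects, with Benjamini-Hochberg FDR over the
#' edge family. The direction is the sign of `mean(groupA) - mean(groupB)`
#' per edge.
#'
#' @param groupA,groupB Lists of `"coherence_matrix"` objects (>= 3
#'   subjects each) sharing labels and band.
#' @param alpha FDR level (default 0.05).
#' @param variant `"welch"` (default) or `"pooled"` t statistic.
#' @return Object of class `"edge_comparison"`: symmetric matrices `t`,
#'   `p`, `q`, logical `mask` (significant after FDR; diagonal `FALSE`),
#'   `direction`, `alpha`, `labels`.
#' @export
edgewise_compare <- function(groupA, groupB, alpha = 0.05,
                             variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(groupA) >= 3, length(groupB) >= 3)
  labels <- groupA[[1]]$labels
  for (m in c(groupA, groupB))
    if (!identical(m$labels, labels)) stop("label mismatch across groups")
  N <- length(labels)
  ut <- upper.tri(matrix(0, N, N))
  stack <- function(grp)
    t(vapply(grp, function(m) m$values[ut], numeric(sum(ut))))
  A <- stack(groupA)
  B <- stack(groupB)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  n1 <- nrow(A); n2 <- nrow(B)
  if (variant == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(v1))
  }
  tt <- (m1 - m2) / se
  tt[se == 0] <- 0
  pp <- 2 * stats::pt(-abs(tt), df)
  pp[se == 0] <- 1
  fdr <- bh_fdr(pp, alpha)
  unpack <- function(v, diag_val = 0) {
    M <- matrix(diag_val, N, N, dimnames = list(labels, labels))
    M[ut] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  mask <- unpack(as.numeric(fdr$reject)) > 0
  diag(mask) <- FALSE
  structure(list(t = unpack(tt), p = unpack(pp, 1), q = unpack(fdr$adjusted, 1),
                 mask = mask, direction = unpack(sign(m1 - m2)),
                 alpha = alpha, labels = labels, variant = variant),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf("<edge_comparison> %d nodes, %d significant edges at q <= %g\n",
              length(x$labels), sum(x$mask[upper.tri(x$mask)]), x$alpha))
  invisible(x)
}

#' Pearson correlations with FDR correction across a family
#'
#' @param pairs List of `list(x =, y =)` pairs (equal-length vectors,
#'   n >= 3).
#' @return Data frame with `r`, `p` (two-sided) and BH-adjusted `q` per
#'   pair.
#' @export
correlate_with_fdr <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  res <- lapply(pairs, function(pr) {
    stopifnot(length(pr$x) == length(pr$y), length(pr$x) >= 3)
    if (stats::sd(pr$x) == 0 || stats::sd(pr$y) == 0)
      stop("zero variance in a correlation input")
    ht <- stats::cor.test(pr$x, pr$y)
    c(r = unname(ht$estimate), p = ht$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
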