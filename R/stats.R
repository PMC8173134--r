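# The study's statistical battery, implemented from first principles:
# one-sample Kolmogorov-Smirnov normality check with estimated parameters,
# one-way ANOVA from sums of squares, Duncan's multiple range post hoc
# test (studentized-range critical values at Duncan's protection levels),
# and the two-sample Wilcoxon rank-sum test with exact enumeration for
# small samples.

#' Kolmogorov-Smirnov normality test (estimated parameters)
#'
#' One-sample KS statistic `D = sup |Fn(x) - Phi((x - mean)/sd)|` with the
#' mean and SD estimated from the sample; the p-value uses the asymptotic
#' Kolmogorov distribution, which is anti-conservative when parameters
#' are estimated (the classical caveat of this procedure).
#'
#' @param sample numeric vector, n >= 4, non-degenerate.
#' @return List: `statistic` (D), `p_value`, `n`.
#' @export
ks_normality <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 4) stop("ks_normality: need at least 4 observations")
  s <- stats::sd(sample)
  if (s < 1e-12) stop("ks_normality: degenerate (zero-variance) sample")
  z <- sort((sample - mean(sample)) / s)
  p <- stats::pnorm(z)
  D <- max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
  t <- sqrt(n) * D
  k <- 1:100
  p_val <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  list(statistic = D, p_value = p_val, n = n)
}

#' One-way analysis of variance
#'
#' F statistic from between/within sums of squares; p-value from the F
#' distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return Object of class `anova_result`: `group_labels`, `group_means`,
#'   `F`, `df_between`, `df_within`, `ms_error`, `p_value`, `n_per_group`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("one_way_anova: need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("one_way_anova: each group needs n >= 2")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- sum(ns) - length(groups)
  msw <- ssw / dfw
  if (msw < 1e-300)
    stop("one_way_anova: degenerate (all observations identical within groups)")
  F <- (ssb / dfb) / msw
  structure(list(group_labels = labels, group_means = means, F = F,
                 df_between = dfb, df_within = dfw, ms_error = msw,
                 p_value = stats::pf(F, dfb, dfw, lower.tail = FALSE),
                 n_per_group = ns),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Duncan's multiple range post hoc test
#'
#' Means are ordered; a stretch of `p` consecutive ordered means is
#' compared against the critical range
#' `R_p = q(1 - alpha_p, p, df_within) * sqrt(MS_within / n)`, where
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` is Duncan's protection level and
#' `q` the studentized-range quantile.  Testing proceeds outside-in with
#' the standard constraint that no pair inside a non-significant stretch
#' may be declared significant; harmonic-mean n is used for unbalanced
#' groups (warning beyond a 2:1 imbalance).
#'
#' @param groups list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return Object of class `duncan_result`: `ordered_means`,
#'   `pairwise_decisions` (matrix, `TRUE` = significantly different),
#'   `homogeneous_subsets` (list of group-label vectors), `alpha`,
#'   `critical_ranges`.
#' @export
duncan_posthoc <- function(groups, alpha = 0.05) {
  fit <- one_way_anova(groups)
  if (fit$df_within < 2) stop("duncan_posthoc: df_within < 2")
  ns <- fit$n_per_group
  if (max(ns) / min(ns) > 2)
    warning("duncan_posthoc: imbalance beyond 2:1; harmonic-mean n is approximate")
  n_h <- length(ns) / sum(1 / ns)
  k <- length(groups)
  ord <- order(fit$group_means)
  means <- fit$group_means[ord]
  labels <- fit$group_labels[ord]
  se <- sqrt(fit$ms_error / n_h)
  crit <- vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, fit$df_within) * se
  }, 0)
  names(crit) <- paste0("R", 2:k)
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  blocked <- matrix(FALSE, k, k)   # inside a non-significant stretch
  # outside-in: widest stretches first
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      if (blocked[i, j]) next
      if (means[j] - means[i] > crit[span - 1]) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        # whole stretch homogeneous: protect all inner pairs
        for (a in i:j) for (b in i:j) blocked[a, b] <- TRUE
      }
    }
  }
  # homogeneous subsets: maximal stretches of ordered means with no
  # significant pair inside
  subsets <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    subsets[[length(subsets) + 1]] <- labels[i:j]
    i <- if (j >= k) k + 1 else i + 1
  }
  # drop subsets fully contained in another
  keep <- vapply(seq_along(subsets), function(a) {
    !any(vapply(seq_along(subsets), function(b)
      b != a && all(subsets[[a]] %in% subsets[[b]]), logical(1)))
  }, logical(1))
  structure(list(ordered_means = stats::setNames(means, labels),
                 pairwise_decisions = sig,
                 homogeneous_subsets = subsets[keep], alpha = alpha,
                 critical_ranges = crit, df_within = fit$df_within,
                 ms_error = fit$ms_error, n_harmonic = n_h),
            class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("<duncan_result> alpha = %g; subsets: %s\n", x$alpha,
              paste(vapply(x$homogeneous_subsets, paste, "",
                           collapse = ","), collapse = " | ")))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided.  Exact p by full enumeration of the rank assignments (with
#' midranks for ties) when `n_x + n_y <= 12` in `auto` mode; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List: `statistic` (rank sum of `x`), `p_value`, `mode`.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("rank_sum_test: empty sample")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))            # midranks
  W <- sum(r[seq_len(nx)])
  if (mode == "auto") mode <- if (N <= 12) "exact" else "approx"
  if (mode == "exact") {
    combs <- utils::combn(N, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    tol <- 1e-9
    p <- 2 * min(mean(sums <= W + tol), mean(sums >= W - tol))
    list(statistic = W, p_value = min(1, p), mode = "exact")
  } else {
    mu <- nx * (N + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(statistic = W, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         mode = "approx")
  }
}
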