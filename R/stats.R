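#' Five-number summary
#'
#' Minimum, lower quartile, median, upper quartile, maximum. Quartiles use
#' linear interpolation between order statistics (the inclusive convention,
#' `quantile(type = 7)`), matching how descriptive tables of small clinical
#' groups are usually produced.
#'
#' @param values numeric vector (>= 1 value).
#' @return Named numeric: `min`, `q25`, `median`, `q75`, `max`.
#' @export
five_number_summary <- function(values) {
  if (length(values) < 1L || any(!is.finite(values)))
    stop_vamorph("need at least one finite value", class = "vamorph_data_error")
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  setNames(q, c("min", "q25", "median", "q75", "max"))
}

rank_pooled <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  list(r = rank(x), g = g, x = x, n = lengths(groups), N = length(x))
}

kw_statistic <- function(r, g, n, N) {
  mr <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (mr - (N + 1) / 2)^2)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr <= 0) return(NA_real_)
  H / tie_corr
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square upper-tail p on (groups - 1) degrees
#' of freedom. For pooled n <= 8 an exact permutation p (proportion of
#' group reassignments with H at least as large) is also computed and
#' reported as `p_exact`.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty groups,
#'   pooled n >= 3).
#' @return List: `statistic` (H), `df`, `p_value`, `p_exact` (NA unless
#'   pooled n <= 8), `method`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- validate_groups(groups, min_pooled = 3L)
  pp <- rank_pooled(groups)
  if (length(unique(pp$x)) == 1L)
    stop_vamorph("all pooled values identical; test degenerate",
                 class = "vamorph_degenerate_error")
  H <- kw_statistic(pp$r, pp$g, pp$n, pp$N)
  df <- length(groups) - 1L
  p <- pchisq(H, df, lower.tail = FALSE)
  p_exact <- NA_real_
  if (pp$N <= 8L) {
    perms <- group_assignments(pp$n)
    Hs <- vapply(perms, function(gg) kw_statistic(pp$r, gg, pp$n, pp$N), numeric(1))
    p_exact <- mean(Hs >= H - 1e-12)
  }
  list(statistic = H, df = df, p_value = p, p_exact = p_exact,
       method = "Kruskal-Wallis (tie-corrected)")
}

validate_groups <- function(groups, min_pooled = 2L) {
  if (!is.list(groups) || length(groups) < 2L || any(lengths(groups) == 0L))
    stop_vamorph("need >= 2 non-empty groups", class = "vamorph_data_error")
  if (sum(lengths(groups)) < min_pooled)
    stop_vamorph("too few pooled observations", class = "vamorph_data_error")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.double)
}

# all distinct assignments of N pooled slots to groups of sizes n (used for
# the exact permutation path; N <= 8 keeps this <= 2520 combinations times
# duplicates bounded by multinomial count)
group_assignments <- function(n) {
  N <- sum(n)
  slots <- seq_len(N)
  out <- list()
  assign_rec <- function(remaining, gi, acc) {
    if (gi == length(n)) {
      g <- integer(N); for (j in seq_along(acc)) g[acc[[j]]] <- j
      g[remaining] <- length(n)
      out[[length(out) + 1L]] <<- g
      return(invisible())
    }
    cmb <- utils::combn(remaining, n[gi], simplify = FALSE)
    for (cc in cmb) assign_rec(setdiff(remaining, cc), gi + 1L, c(acc, list(cc)))
  }
  assign_rec(slots, 1L, list())
  out
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each group pair, `z = (mean rank_i - mean rank_j) / sqrt(sigma2 *
#' (1/n_i + 1/n_j))` with the tie-corrected `sigma2 = N(N+1)/12 -
#' sum(t^3 - t) / (12 (N - 1))`. Raw two-sided normal p-values are
#' adjusted by Bonferroni multiplication over all pairs (the convention of
#' common biostatistics software for "Dunn's multiple comparisons");
#' `holm` and `none` are available.
#'
#' @param groups named list of numeric vectors.
#' @param adjust `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return data.frame: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`,
#'   `adjustment`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  groups <- validate_groups(groups, min_pooled = 3L)
  pp <- rank_pooled(groups)
  if (length(unique(pp$x)) == 1L)
    stop_vamorph("all pooled values identical; test degenerate",
                 class = "vamorph_degenerate_error")
  N <- pp$N
  ties <- table(pp$r)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(pp$r, pp$g, mean)
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / pp$n[i] + 1 / pp$n[j]))
    z[k] <- (mr[i] - mr[j]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  p_adj <- switch(adjust,
                  bonferroni = pmin(1, p_raw * ncol(pairs)),
                  holm = p.adjust(p_raw, "holm"),
                  none = p_raw)
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p_raw = p_raw, p_adjusted = p_adj,
             adjustment = adjust, stringsAsFactors = FALSE)
}

#' Hodges-Lehmann location difference with Moses CI
#'
#' Point estimate: median of all pairwise differences `b - a`. Confidence
#' interval: the Moses order-statistic bracket — the k-th smallest and
#' k-th largest pairwise differences with k from the Wilcoxon rank-sum
#' null quantile, so both endpoints are elements of the pairwise
#' difference multiset.
#'
#' @param a,b numeric samples (the difference is `b - a`).
#' @param confidence nominal two-sided coverage.
#' @return List: `estimate`, `ci_lower`, `ci_upper`, `confidence`.
#' @export
hodges_lehmann <- function(a, b, confidence = 0.95) {
  if (length(a) == 0L || length(b) == 0L)
    stop_vamorph("both samples must be non-empty", class = "vamorph_data_error")
  d <- sort(as.vector(outer(b, a, `-`)))
  est <- median(d)
  m <- length(a); n <- length(b)
  alpha <- 1 - confidence
  k <- qwilcox(alpha / 2, m, n)
  if (stats::pwilcox(k, m, n) > alpha / 2) k <- k - 1L
  # tiny samples cannot cover at the nominal level; degrade to the extremes
  lo <- d[min(max(k + 1, 1), length(d))]
  hi <- d[min(max(length(d) - k, 1), length(d))]
  list(estimate = est, ci_lower = lo, ci_upper = hi, confidence = confidence)
}

#' Spearman rank correlation
#'
#' rho from midrank-tied ranks. For n > 9 the p-value uses the
#' t-distribution approximation on `rho * sqrt((n-2)/(1-rho^2))`; for
#' n <= 9 an exact two-sided permutation p over all n! orderings.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List: `rho`, `p_value`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_vamorph("x and y must have equal length >= 3", class = "vamorph_data_error")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop_vamorph("zero variance in ranks; correlation degenerate",
                 class = "vamorph_degenerate_error")
  rho <- cor(rx, ry)
  n <- length(x)
  if (n > 9L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  } else {
    # rho is linear in sum(rx * ry[perm]); enumerate that sum over all n!
    # orderings in one matrix product
    perms <- all_permutations(n)
    S <- matrix(ry[t(perms)], ncol = n, byrow = TRUE) %*% rx
    rhos <- (S - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from the
#' subjects-by-raters ANOVA mean squares. This is the conservative
#' standard for two fixed-instruction raters each rating every subject.
#'
#' @param ratings complete `n x k` numeric matrix (subjects x raters),
#'   n >= 2, k >= 2.
#' @return ICC value (scalar).
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings)) || nrow(ratings) < 2L || ncol(ratings) < 2L)
    stop_vamorph("ratings must be a complete n x k matrix, n >= 2, k >= 2",
                 class = "vamorph_data_error")
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  if (sum((ratings - grand)^2) < 1e-24)
    stop_vamorph("zero total variance; ICC degenerate",
                 class = "vamorph_degenerate_error")
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((sweep(sweep(ratings, 1L, row_m), 2L, col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' ROC analysis with the Youden-index cutoff
#'
#' Candidate thresholds are the unique observed scores plus -Inf; a case
#' is called positive when `score > t` (strict). The chosen cutoff
#' maximizes Youden's J = sensitivity + specificity - 1, ties broken
#' toward maximum sensitivity and then the smallest threshold.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; TRUE = positive class.
#' @return List: `curve` (data.frame threshold/sensitivity/specificity/J),
#'   `cutoff`, `sensitivity`, `specificity`, `youden_j`, `auc`.
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(scores)) || any(is.na(labels)))
    stop_vamorph("scores and labels must align with no missing values",
                 class = "vamorph_data_error")
  if (!any(labels) || all(labels))
    stop_vamorph("both classes must be present", class = "vamorph_labels_error")
  thr <- c(-Inf, sort(unique(scores)))
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[order(-sens[best], thr[best])][1L]
  # trapezoidal AUC over the (FPR, TPR) staircase
  ord <- order(1 - spec, sens)
  fpr <- (1 - spec)[ord]; tpr <- sens[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec, J = J),
       cutoff = thr[best], sensitivity = sens[best], specificity = spec[best],
       youden_j = J[best], auc = auc)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Beta-quantile form of the exact interval; the lower bound is 0 at zero
#' successes and the upper bound 1 at complete success (at `x = n` the
#' lower bound has the closed form `(alpha/2)^(1/n)`).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param confidence nominal coverage.
#' @return Named numeric: `lower`, `upper`.
#' @export
binomial_ci <- function(successes, n, confidence = 0.95) {
  if (n < 1L || successes < 0L || successes > n)
    stop_vamorph("require 0 <= successes <= n, n >= 1", class = "vamorph_data_error")
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}
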