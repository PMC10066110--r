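test_that("five-number summaries use the inclusive linear convention", {
  expect_equal(five_number_summary(c(1, 2, 3, 4, 5)),
               c(min = 1, q25 = 2, median = 3, q75 = 4, max = 5))
  expect_equal(five_number_summary(7), setNames(rep(7, 5),
               c("min", "q25", "median", "q75", "max")))
  x <- c(1, 2, 3, 4)
  expect_equal(unname(five_number_summary(x)[c("q25", "q75")]),
               unname(quantile(x, c(0.25, 0.75), type = 7)))
  expect_error(five_number_summary(numeric(0)), class = "vamorph_data_error")
})

test_that("Kruskal-Wallis H matches the hand rank formula and kruskal.test", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  ref <- kruskal.test(unlist(g), factor(rep(1:3, each = 3)))
  expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)

  set.seed(8)
  gt <- list(x = rnorm(6), y = c(rnorm(5), rnorm(1)), z = rnorm(4))
  gt$y[2] <- gt$x[1] # force a tie
  kt <- kruskal_wallis(gt)
  rt <- kruskal.test(unlist(gt), factor(rep(1:3, c(6, 6, 4))))
  expect_equal(kt$statistic, unname(rt$statistic), tolerance = 1e-12)

  expect_error(kruskal_wallis(list(a = c(2, 2), b = c(2, 2))),
               class = "vamorph_degenerate_error")
  expect_error(kruskal_wallis(list(a = 1)), class = "vamorph_data_error")
})

test_that("H is invariant under strictly increasing transforms", {
  set.seed(12)
  g <- list(a = runif(4), b = runif(3), c = runif(5))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v) - 1))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("exact Kruskal-Wallis p matches the full permutation oracle", {
  g <- list(a = c(1.2, 3.4), b = c(0.7, 5.1, 2.2), c = c(4.4, 0.1))
  res <- kruskal_wallis(g)
  expect_false(is.na(res$p_exact))

  pooled <- unlist(g)
  sizes <- lengths(g)
  gl <- rep(seq_along(g), sizes)
  H_of <- function(vals) {
    r <- rank(vals); N <- length(vals)
    mr <- tapply(r, gl, mean)
    12 / (N * (N + 1)) * sum(sizes * (mr - (N + 1) / 2)^2)
  }
  H_obs <- H_of(pooled)
  perms <- perm_list(length(pooled))
  Hs <- vapply(perms, function(ix) H_of(pooled[ix]), numeric(1))
  expect_equal(res$p_exact, mean(Hs >= H_obs - 1e-12), tolerance = 1e-9)
})

test_that("the chi-square p-value is asymptotically uniform under the null", {
  set.seed(99)
  ps <- replicate(1000, {
    kruskal_wallis(list(a = rnorm(12), b = rnorm(12)))$p_value
  })
  # rank statistics are discrete, so replicated p-values tie; the KS
  # distance still detects non-uniformity far beyond the discreteness gap
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Dunn post hoc reproduces the hand-computed worked pair", {
  g <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  d <- dunn_posthoc(g)
  row <- d[d$group1 == "g1" & d$group2 == "g3", ]
  expect_equal(row$z, -6 / sqrt(5), tolerance = 1e-9)          # -2.683
  expect_equal(row$p_raw, 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-9)
  expect_equal(row$p_adjusted, min(1, row$p_raw * 3), tolerance = 1e-12)
  expect_true(all(d$p_adjusted >= d$p_raw - 1e-15))

  same <- dunn_posthoc(list(a = c(1, 2, 3, 4), b = c(2, 3, 1, 4)))
  expect_equal(same$z, 0, tolerance = 1e-12)
  expect_equal(same$p_adjusted, 1)
})

test_that("Hodges-Lehmann difference and Moses CI come from the pairwise set", {
  hl <- hodges_lehmann(c(1, 2), c(3, 4))
  expect_equal(hl$estimate, 2)
  expect_equal(hodges_lehmann(c(5, 1, 3), c(5, 1, 3))$estimate, 0)

  set.seed(21)
  a <- rnorm(8); b <- rnorm(10, 1)
  hl2 <- hodges_lehmann(a, b)
  d <- sort(as.vector(outer(b, a, `-`)))
  expect_true(hl2$ci_lower %in% d)
  expect_true(hl2$ci_upper %in% d)
  expect_lte(hl2$ci_lower, hl2$estimate)
  expect_gte(hl2$ci_upper, hl2$estimate)
  # point estimate agrees with the rank-based reference implementation
  wt <- wilcox.test(b, a, conf.int = TRUE)
  expect_equal(hl2$estimate, unname(wt$estimate), tolerance = 1e-6)
})

test_that("Spearman rho and exact permutation p match enumeration", {
  expect_equal(spearman(1:3, 3:1)$rho, -1)
  set.seed(3)
  x <- rnorm(8)
  expect_equal(spearman(x, exp(2 * x))$rho, 1)

  x5 <- c(0.3, 1.2, -0.5, 2.2, 0.9); y5 <- c(1.1, 0.2, 0.4, 2.0, -1.3)
  res <- spearman(x5, y5)
  rx <- rank(x5); ry <- rank(y5)
  rhos <- vapply(perm_list(5), function(ix) cor(rx, ry[ix]), numeric(1))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(cor(rx, ry)) - 1e-12),
               tolerance = 1e-12)
  expect_equal(res$method, "exact permutation")

  big <- spearman(rnorm(20), rnorm(20))
  expect_equal(big$method, "t approximation")
  expect_gte(big$p_value, 0); expect_lte(big$p_value, 1)
  expect_error(spearman(rep(1, 5), rnorm(5)), class = "vamorph_degenerate_error")
})

test_that("ICC(2,1) matches the hand ANOVA and its absolute-agreement nature", {
  m <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(icc_agreement(m), 8 / 9, tolerance = 1e-12)
  ident <- cbind(c(2, 5, 9, 4), c(2, 5, 9, 4))
  expect_equal(icc_agreement(ident), 1)
  # a constant offset on one rater strictly lowers absolute agreement
  shifted <- cbind(c(2, 5, 9, 4), c(2, 5, 9, 4) + 3)
  expect_lt(icc_agreement(shifted), 1)
  expect_error(icc_agreement(matrix(1, 3, 2)), class = "vamorph_degenerate_error")
})

test_that("ROC Youden cutoff equals a brute-force scan, with documented ties", {
  r <- roc_youden(c(1, 2, 3, 5, 6), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$cutoff, 3)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)

  inter <- roc_youden(1:6, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_lte(inter$youden_j, 1 / 3 + 1e-12)

  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    scores <- round(rnorm(n), 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    res <- roc_youden(scores, labels)
    cand <- sort(unique(c(-Inf, scores, (head(sort(unique(scores)), -1) +
                                           tail(sort(unique(scores)), -1)) / 2)))
    brute <- max(vapply(cand, function(t) {
      mean(scores[labels] > t) + mean(scores[!labels] <= t) - 1
    }, numeric(1)))
    expect_equal(res$youden_j, brute, tolerance = 1e-12)
  }
  expect_error(roc_youden(1:3, c(TRUE, TRUE, TRUE)),
               class = "vamorph_labels_error")
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- c(rnorm(30), rnorm(25, 1.2))
  labels <- rep(c(FALSE, TRUE), c(30, 25))
  mine <- roc_youden(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  co <- pROC::coords(ref, "best", best.method = "youden")
  expect_equal(mine$youden_j, co$sensitivity + co$specificity - 1,
               tolerance = 1e-9)
})

test_that("Clopper-Pearson intervals match closed forms and binom.test", {
  ci <- binomial_ci(15, 15)
  expect_equal(unname(ci["lower"]), 0.025^(1 / 15), tolerance = 1e-12)
  expect_equal(unname(ci["upper"]), 1)
  expect_equal(unname(binomial_ci(0, 10)["lower"]), 0)
  ci5 <- binomial_ci(5, 10)
  expect_lt(ci5["lower"], 0.5); expect_gt(ci5["upper"], 0.5)
  ref <- binom.test(5, 10)$conf.int
  expect_equal(unname(ci5), as.vector(ref), tolerance = 1e-9)
  expect_error(binomial_ci(11, 10), class = "vamorph_data_error")
})

test_that("p-values live in [0,1] and CIs are ordered across random cases", {
  set.seed(41)
  for (i in 1:25) {
    g <- list(a = rnorm(sample(3:8, 1)), b = rnorm(sample(3:8, 1), 0.5),
              c = rnorm(sample(3:8, 1)))
    kw <- kruskal_wallis(g)
    expect_gte(kw$p_value, 0); expect_lte(kw$p_value, 1)
    d <- dunn_posthoc(g)
    expect_true(all(d$p_raw >= 0 & d$p_raw <= 1))
    expect_true(all(d$p_adjusted >= 0 & d$p_adjusted <= 1))
    hl <- hodges_lehmann(g$a, g$b)
    expect_lte(hl$ci_lower, hl$ci_upper)
  }
})
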