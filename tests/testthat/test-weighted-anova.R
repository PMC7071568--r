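random_groups <- function(n_per = 8, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    freq = runif(n_per * k),
    group = rep(c("EUR", "EAS", "AFR", "OTHER")[seq_len(k)], each = n_per),
    n = sample(5:120, n_per * k, replace = TRUE))
}

test_that("weighted group means match hand computation", {
  d <- tibble::tibble(freq = c(0.2, 0.8), group = "EUR", n = c(10, 30))
  expect_equal(weighted_group_means(d)$mean, 0.65)   # (2 + 24) / 40
  d2 <- tibble::tibble(freq = c(0.4, 0.6), group = "EUR", n = c(7, 7))
  expect_equal(weighted_group_means(d2)$mean, 0.5)
  d3 <- tibble::tibble(freq = 0.37, group = "EAS", n = 12)
  expect_equal(weighted_group_means(d3)$mean, 0.37)
})

test_that("weighted ANOVA reproduces weighted least squares exactly", {
  for (seed in 1:20) {
    d <- random_groups(seed = seed)
    fit <- weighted_anova(d)
    sm <- summary(lm(freq ~ factor(group), data = d, weights = n))
    expect_equal(fit$f, unname(sm$fstatistic[1]), tolerance = 1e-10)
    expect_equal(fit$p_value,
                 unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                           sm$fstatistic[3], lower.tail = FALSE)),
                 tolerance = 1e-10)
    expect_equal(fit$r_squared, sm$r.squared, tolerance = 1e-10)
    expect_equal(fit$adj_r_squared, sm$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("weighted ANOVA is invariant to row order and weight rescaling", {
  d <- random_groups(seed = 42)
  fit <- weighted_anova(d)
  perm <- weighted_anova(d[sample(nrow(d)), ])
  scaled <- weighted_anova(dplyr::mutate(d, n = n * 7.3))
  for (field in c("f", "p_value", "r_squared", "adj_r_squared")) {
    expect_equal(fit[[field]], perm[[field]], tolerance = 1e-12)
    expect_equal(fit[[field]], scaled[[field]], tolerance = 1e-12)
  }
})

test_that("degenerate responses give the documented F and p", {
  flat <- tibble::tibble(freq = 0.4, group = rep(c("EUR", "EAS"), each = 3),
                         n = 10)
  fit <- weighted_anova(flat)
  expect_equal(c(fit$f, fit$p_value, fit$r_squared), c(0, 1, 0))

  sep <- tibble::tibble(freq = rep(c(0.1, 0.9), each = 3),
                        group = rep(c("EUR", "EAS"), each = 3), n = 10)
  fit2 <- weighted_anova(sep)
  expect_true(fit2$perfect_separation)
  expect_equal(fit2$p_value, 0)
})

test_that("k = 2 equal weights: F equals the squared pooled t statistic", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- tibble::tibble(freq = runif(16), group = rep(c("EUR", "EAS"), each = 8),
                        n = 1)
    fit <- weighted_anova(d)
    tt <- t.test(freq ~ group, data = d, var.equal = TRUE)
    expect_equal(fit$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
    # ... and the k = 2 Tukey p is the pooled t-test p (q = t * sqrt(2))
    tk <- tukey_kramer(fit)
    expect_equal(tk$p, tt$p.value, tolerance = 1e-8)
    expect_equal(tk$q, abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-10)
  }
})

test_that("null simulation rejects at close to the nominal level", {
  set.seed(77)
  theta <- 0.05; scale <- (1 - theta) / theta
  grp <- rep(c("EUR", "EAS", "AFR"), each = 20)
  rej <- vapply(1:500, function(i) {
    y <- rbeta(60, 0.5 * scale, 0.5 * scale)
    weighted_anova(tibble::tibble(freq = y, group = grp, n = 100))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("group confidence intervals are symmetric, monotone in level and degenerate at MSW = 0", {
  d <- random_groups(seed = 5)
  fit <- weighted_anova(d)
  ci95 <- group_confidence_interval(fit, 0.95)
  expect_equal(ci95$ci_hi - ci95$mean, ci95$mean - ci95$ci_lo, tolerance = 1e-12)
  widths <- vapply(c(0.90, 0.95, 0.99), function(l) {
    ci <- group_confidence_interval(fit, l)
    mean(ci$ci_hi - ci$ci_lo)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  flat <- weighted_anova(tibble::tibble(
    freq = 0.3, group = rep(c("EUR", "EAS"), each = 3), n = 10))
  cif <- group_confidence_interval(flat)
  expect_equal(cif$ci_lo, cif$mean)
  expect_equal(cif$ci_hi, cif$mean)

  # pooled-MSW intervals may cross zero for a near-zero group mean
  d0 <- tibble::tibble(
    freq = c(0, 0, 0.01, 0.4, 0.5, 0.6, 0.2, 0.25, 0.3),
    group = rep(c("EUR", "EAS", "AFR"), each = 3), n = 20)
  ci0 <- group_confidence_interval(weighted_anova(d0))
  expect_lt(ci0$ci_lo[ci0$group == "EUR"], 0)
})

test_that("Tukey-Kramer agrees with TukeyHSD in the balanced equal-weight case", {
  set.seed(303)
  for (i in 1:50) {
    d <- tibble::tibble(freq = rnorm(18, sd = 0.2) + rep(runif(3), each = 6),
                        group = rep(c("EUR", "EAS", "AFR"), each = 6), n = 1)
    fit <- weighted_anova(d)
    tk <- tukey_kramer(fit)
    ref <- TukeyHSD(aov(freq ~ group, data = d))$group
    ref_p <- ref[, "p adj"]
    key <- vapply(rownames(ref), function(r) {
      gs <- strsplit(r, "-")[[1]]
      paste(sort(gs), collapse = "|")
    }, character(1))
    mine <- setNames(tk$p, vapply(seq_len(nrow(tk)), function(j) {
      paste(sort(c(tk$group1[j], tk$group2[j])), collapse = "|")
    }, character(1)))
    expect_equal(unname(mine[key]), unname(ref_p), tolerance = 1e-4)
  }
})

test_that("Tukey p values fall as mean separation grows, variances held fixed", {
  base <- tibble::tibble(freq = c(0.3, 0.35, 0.4, 0.5, 0.55, 0.6),
                         group = rep(c("EUR", "EAS"), each = 3), n = 10)
  shift <- function(delta) {
    d <- base
    d$freq[d$group == "EAS"] <- d$freq[d$group == "EAS"] + delta
    p <- tukey_kramer(weighted_anova(d))$p
    p
  }
  ps <- vapply(c(0, 0.1, 0.2, 0.4), shift, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("compact letters encode exactly the non-significant pairs", {
  pw <- function(p12, p13, p23) {
    tibble::tibble(group1 = c("EUR", "EUR", "EAS"),
                   group2 = c("EAS", "AFR", "AFR"),
                   p = c(p12, p13, p23))
  }
  share <- function(cld, a, b) {
    la <- strsplit(cld$letters[cld$group == a], "")[[1]]
    lb <- strsplit(cld$letters[cld$group == b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  # all significant -> three distinct letters
  cld <- compact_letter_display(pw(1e-9, 1e-9, 1e-9), alpha = 1e-4)
  expect_false(share(cld, "EUR", "EAS") || share(cld, "EUR", "AFR") ||
                 share(cld, "EAS", "AFR"))
  # none significant -> everyone shares a letter
  cld <- compact_letter_display(pw(0.5, 0.5, 0.5), alpha = 1e-4)
  expect_true(share(cld, "EUR", "EAS") && share(cld, "EUR", "AFR") &&
                share(cld, "EAS", "AFR"))
  # EAS ~ AFR only (the published shared-letter motif)
  cld <- compact_letter_display(pw(1e-9, 1e-9, 0.3), alpha = 1e-4)
  expect_true(share(cld, "EAS", "AFR"))
  expect_false(share(cld, "EUR", "EAS") || share(cld, "EUR", "AFR"))

  # property: sharing <=> non-significance on random p matrices
  set.seed(9)
  for (i in 1:300) {
    p <- runif(3, 0, 2e-4)
    cld <- compact_letter_display(pw(p[1], p[2], p[3]), alpha = 1e-4)
    expect_equal(share(cld, "EUR", "EAS"), p[1] >= 1e-4)
    expect_equal(share(cld, "EUR", "AFR"), p[2] >= 1e-4)
    expect_equal(share(cld, "EAS", "AFR"), p[3] >= 1e-4)
  }
})

test_that("Bonferroni flags use strict inequality at the printed thresholds", {
  th <- significance_thresholds()
  expect_true(apply_bonferroni(3.18e-12, th$alpha_assoc))
  expect_false(apply_bonferroni(0.001, th$alpha_assoc))
  expect_false(apply_bonferroni(3.85e-02, th$alpha_pairwise))
  expect_error(apply_bonferroni(1.5, 0.05), "\\[0, 1\\]")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- weighted_anova(random_groups(seed = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(td$ci_lo <= td$mean & td$mean <= td$ci_hi))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("statistic", "p_value", "adj_r_squared") %in% names(gl)))
  expect_lte(gl$adj_r_squared, gl$r_squared)
})
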