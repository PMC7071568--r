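#' Cohort-size-weighted group means
#'
#' @param data Data frame with one row per sample set.
#' @param y,group,w Bare column names of the response (frequency), group label
#'   and weight (cohort size). Defaults `freq`, `group`, `n`.
#' @return Tibble with `group`, `mean` (weighted), `weight_total`, `n_sets`,
#'   ordered EUR, EAS, AFR, then anything else.
#' @export
weighted_group_means <- function(data, y = freq, group = group, w = n) {
  df <- dplyr::transmute(data, y = {{ y }}, group = {{ group }}, w = {{ w }})
  df <- df[!is.na(df$y), ]
  if (any(df$w <= 0)) abort("weights must be positive")
  out <- df |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(mean = weighted.mean(.data$y, .data$w),
                     weight_total = sum(.data$w),
                     n_sets = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, match(.data$group, GROUP_LEVELS))
}

#' Weighted one-way ANOVA on group membership
#'
#' The package's statistical engine: a one-way analysis of variance of a
#' per-sample-set response (typically a variant-allele frequency) on ancestry
#' group, with every sample set weighted by its cohort size. Identical to
#' weighted least squares of the response on group indicator variables: the
#' between-group and within-group weighted sums of squares give
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`, `r^2 = SSB / (SSB + SSW)` and
#' `adjusted r^2 = 1 - (1 - r^2)(N - 1) / (N - k)`.
#'
#' Degenerate data: all responses equal gives `F = 0, p = 1`; zero
#' within-group variance with real between-group spread gives `p = 0`
#' (perfect separation, flagged).
#'
#' @inheritParams weighted_group_means
#' @return An object of class `uvb_anova`; see [tidy.uvb_anova()],
#'   [glance.uvb_anova()], [tukey_kramer()], [group_confidence_interval()].
#' @export
weighted_anova <- function(data, y = freq, group = group, w = n) {
  df <- dplyr::transmute(data, y = {{ y }}, group = {{ group }}, w = {{ w }})
  df <- df[!is.na(df$y), ]
  if (any(df$w <= 0)) abort("weights must be positive")
  grp <- weighted_group_means(df, y = y, group = group, w = w)
  k <- nrow(grp)
  N <- nrow(df)
  if (k < 2) abort("need at least 2 groups with data")
  if (N <= k) abort("need more sample sets than groups")

  ybar <- weighted.mean(df$y, df$w)
  ssb <- sum(grp$weight_total * (grp$mean - ybar)^2)
  group_mean <- grp$mean[match(df$group, grp$group)]
  ssw <- sum(df$w * (df$y - group_mean)^2)
  df_b <- k - 1
  df_w <- N - k
  msw <- ssw / df_w

  perfect <- ssw < .Machine$double.eps^0.75 && ssb > .Machine$double.eps^0.75
  if (ssb <= .Machine$double.eps^0.75 && ssw <= .Machine$double.eps^0.75) {
    f <- 0; p <- 1; r2 <- 0
  } else if (perfect) {
    f <- Inf; p <- 0; r2 <- 1
  } else {
    f <- (ssb / df_b) / msw
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
    r2 <- ssb / (ssb + ssw)
  }
  adj_r2 <- 1 - (1 - r2) * (N - 1) / df_w

  structure(list(
    groups = grp, data = tibble::as_tibble(df),
    k = k, n_sets = N, w_bar = mean(df$w),
    ssb = ssb, ssw = ssw, df_between = df_b, df_within = df_w,
    msw = msw, f = f, p_value = p, r_squared = r2, adj_r_squared = adj_r2,
    perfect_separation = perfect), class = "uvb_anova")
}

#' @export
print.uvb_anova <- function(x, ...) {
  cat(sprintf(
    "Weighted one-way ANOVA: %d groups, %d sample sets\nF(%d, %d) = %.4g, p = %.3g, r2 = %.3f (adj %.3f)\n",
    x$k, x$n_sets, x$df_between, x$df_within, x$f, x$p_value,
    x$r_squared, x$adj_r_squared))
  if (x$perfect_separation) cat("note: perfect separation (zero within-group variance)\n")
  print(x$groups)
  invisible(x)
}

#' Model-based confidence intervals for group means
#'
#' Intervals use the pooled weighted within-group mean square (MSW), placed on
#' the response scale via the mean weight: `mean_g +/- t(df_within) *
#' sqrt(MSW * w_bar / W_g)` where `W_g` is the group's weight total. Pooling
#' means a near-constant group (mean 0) can still get a positive-width,
#' possibly negative-bounded interval; bounds are deliberately not clamped to
#' \[0, 1\].
#'
#' @param fit A [weighted_anova()] fit.
#' @param level Confidence level (default 0.95).
#' @return The fit's group table with `ci_lo` and `ci_hi` columns.
#' @export
group_confidence_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "uvb_anova"))
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  se <- if (fit$df_within >= 1 && fit$msw > 0) {
    sqrt(fit$msw * fit$w_bar / fit$groups$weight_total)
  } else rep(0, nrow(fit$groups))
  tcrit <- if (fit$df_within >= 1) qt(1 - (1 - level) / 2, fit$df_within) else 0
  dplyr::mutate(fit$groups, ci_lo = .data$mean - tcrit * se,
                ci_hi = .data$mean + tcrit * se)
}

#' Tukey-Kramer pairwise comparisons
#'
#' All-pairs post hoc comparisons after [weighted_anova()], using the
#' studentized range distribution with the Tukey-Kramer unequal-size form:
#' `q_ij = |mean_i - mean_j| / sqrt((MSW / 2)(1 / W_i + 1 / W_j))` with the
#' group weight totals `W` on the same (weighted) scale as MSW.
#'
#' @param fit A [weighted_anova()] fit.
#' @return Tibble with one row per unordered group pair: `pair`, `group1`,
#'   `group2`, `diff`, `q`, `p`.
#' @export
tukey_kramer <- function(fit) {
  stopifnot(inherits(fit, "uvb_anova"))
  if (fit$df_within < 1) abort("tukey_kramer needs df_within >= 1")
  g <- fit$groups
  pairs <- utils::combn(seq_len(nrow(g)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- g$mean[i1] - g$mean[i2]
    if (fit$msw > 0) {
      se <- sqrt((fit$msw / 2) *
                   (1 / g$weight_total[i1] + 1 / g$weight_total[i2]))
      q <- abs(d) / se
      p <- ptukey(q, nmeans = fit$k, df = fit$df_within, lower.tail = FALSE)
    } else {
      q <- if (abs(d) > 0) Inf else 0
      p <- if (abs(d) > 0) 0 else 1
    }
    tibble::tibble(pair = paste0(g$group[i1], "-", g$group[i2]),
                   group1 = g$group[i1], group2 = g$group[i2],
                   diff = d, q = q, p = p)
  })
}

#' Compact letter display from pairwise p values
#'
#' Insert-and-absorb letter assignment: groups sharing at least one letter are
#' exactly the pairs whose p value is at or above `alpha` (non-significant).
#' Groups are processed in the fixed order EUR, EAS, AFR (then input order),
#' making the lettering deterministic.
#'
#' @param pairwise Tibble from [tukey_kramer()] (`group1`, `group2`, `p`).
#' @param alpha Pairwise significance threshold (strict `<`; default 1e-4).
#' @param groups Optional explicit group ordering.
#' @return Tibble `group`, `letters` (e.g. `"a"`, `"ab"`).
#' @export
compact_letter_display <- function(pairwise, alpha = 1e-4, groups = NULL) {
  groups <- groups %||% unique(c(
    intersect(GROUP_LEVELS, c(pairwise$group1, pairwise$group2)),
    pairwise$group1, pairwise$group2))
  sets <- list(groups)
  sig <- pairwise[pairwise$p < alpha, , drop = FALSE]
  for (row in seq_len(nrow(sig))) {
    g1 <- sig$group1[row]; g2 <- sig$group2[row]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets wholly contained in another
    keep <- vapply(seq_along(new_sets), function(i) {
      !any(vapply(seq_along(new_sets), function(j) {
        i != j && all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[j]]) > length(new_sets[[i]]) || j < i)
      }, logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  first_idx <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_idx)]
  letter_of <- vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = unname(letter_of))
}

#' Significance thresholds after Bonferroni adjustment
#'
#' The study-wide defaults: association p < 0.001 and pairwise p < 0.0001,
#' the Bonferroni-adjusted levels for the number of variants and pairwise
#' comparisons examined.
#'
#' @param alpha_assoc Association threshold (default 0.001).
#' @param alpha_pairwise Pairwise-comparison threshold (default 0.0001).
#' @return List with the two thresholds.
#' @export
significance_thresholds <- function(alpha_assoc = 0.001, alpha_pairwise = 0.0001) {
  if (alpha_assoc <= 0 || alpha_assoc >= 1 ||
      alpha_pairwise <= 0 || alpha_pairwise >= 1) {
    abort("thresholds must be in (0, 1)")
  }
  list(alpha_assoc = alpha_assoc, alpha_pairwise = alpha_pairwise)
}

#' Bonferroni-style significance flags
#'
#' Strict comparison: a p value exactly at the threshold is not significant.
#'
#' @param p Numeric vector of p values.
#' @param alpha Threshold.
#' @return Logical vector.
#' @export
apply_bonferroni <- function(p, alpha) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p values must be in [0, 1]")
  !is.na(p) & p < alpha
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a weighted ANOVA fit
#'
#' @param x A [weighted_anova()] fit.
#' @param conf.level Confidence level for the group-mean intervals.
#' @param ... Unused.
#' @return One row per group: `group`, `mean`, `ci_lo`, `ci_hi`,
#'   `weight_total`, `n_sets`.
#' @export
tidy.uvb_anova <- function(x, conf.level = 0.95, ...) {
  ci <- group_confidence_interval(x, level = conf.level)
  ci[c("group", "mean", "ci_lo", "ci_hi", "weight_total", "n_sets")]
}

#' One-row summary of a weighted ANOVA fit
#'
#' @param x A [weighted_anova()] fit.
#' @param ... Unused.
#' @return Tibble with `statistic` (F), `df_between`, `df_within`, `p_value`,
#'   `r_squared`, `adj_r_squared`, `msw`, `n_sets`.
#' @export
glance.uvb_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value,
                 r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 msw = x$msw, n_sets = x$n_sets)
}
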