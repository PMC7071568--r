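PATTERN_LEVELS <- c("ALL_DIFFER", "EUR_DIFFERS", "EAS_DIFFERS", "AFR_DIFFERS",
                    "PARTIAL", "NONE")

#' Distribution-pattern label from pairwise significance flags
#'
#' Maps the three pairwise comparisons (EUR-EAS, EUR-AFR, EAS-AFR) onto the
#' distribution-pattern taxonomy: all three significant means every group
#' differs; exactly two significant means the group common to both
#' significant pairs differs from the other two; exactly one significant pair
#' has no name in the three-group taxonomy and is labelled `PARTIAL`; none
#' significant is `NONE`. Total and deterministic over all 8 flag
#' combinations.
#'
#' @param sig_eur_eas,sig_eur_afr,sig_eas_afr Logical vectors of pairwise
#'   significance.
#' @return Character vector over
#'   `ALL_DIFFER, EUR_DIFFERS, EAS_DIFFERS, AFR_DIFFERS, PARTIAL, NONE`.
#' @export
classify_pattern <- function(sig_eur_eas, sig_eur_afr, sig_eas_afr) {
  n_sig <- sig_eur_eas + sig_eur_afr + sig_eas_afr
  dplyr::case_when(
    is.na(n_sig) ~ NA_character_,
    n_sig == 3 ~ "ALL_DIFFER",
    n_sig == 2 & !sig_eas_afr ~ "EUR_DIFFERS",
    n_sig == 2 & !sig_eur_afr ~ "EAS_DIFFERS",
    n_sig == 2 & !sig_eur_eas ~ "AFR_DIFFERS",
    n_sig == 1 ~ "PARTIAL",
    TRUE ~ "NONE")
}

#' Human-readable pattern labels
#'
#' Renders pattern codes the way the report prints them
#' (`EUR!=AFR!=EAS`, `EUR!=AFR and EAS`, ..., `-` for no pattern).
#'
#' @param code Character vector of pattern codes.
#' @return Character vector of display labels.
#' @export
pattern_display <- function(code) {
  map <- c(ALL_DIFFER = "EUR!=AFR!=EAS",
           EUR_DIFFERS = "EUR!=AFR and EAS",
           EAS_DIFFERS = "EAS!=AFR and EUR",
           AFR_DIFFERS = "AFR!=EUR and EAS",
           PARTIAL = "PARTIAL",
           NONE = "-")
  unname(map[code])
}

#' UVB-cline label from group means
#'
#' Orders the three group mean frequencies by ascending group mean UVB and
#' checks strict monotonicity of the point estimates (no trend test): strictly
#' increasing along the UVB gradient is `INCREASING`, strictly decreasing
#' `DECREASING`, anything else (including ties) `NONE`.
#'
#' @param means Named numeric vector of group mean frequencies (names are
#'   group labels).
#' @param uvb_order Character vector of the same groups sorted by ascending
#'   mean annual UVB (e.g. `c("EUR", "EAS", "AFR")`).
#' @return `"INCREASING"`, `"DECREASING"`, `"NONE"`, or `NA` if any mean is
#'   missing.
#' @export
classify_uvb_cline <- function(means, uvb_order) {
  if (!all(uvb_order %in% names(means))) {
    abort("means must be named with every group in uvb_order")
  }
  m <- unname(means[uvb_order])
  if (any(is.na(m))) return(NA_character_)
  d <- diff(m)
  if (all(d > 0)) "INCREASING" else if (all(d < 0)) "DECREASING" else "NONE"
}

#' Per-variant weighted group comparison
#'
#' The per-variant engine: for each rsID in the frequency table, fits the
#' cohort-size-weighted one-way ANOVA of frequency on ancestry group, derives
#' group means with 95% CIs, Tukey-Kramer pairwise p values, Bonferroni
#' significance flags, compact letters, the distribution-pattern label and
#' the UVB-cline label. Sample sets with missing frequency for a variant are
#' dropped for that variant only, and the per-variant set/subject counts
#' record what was actually used.
#'
#' @param freq Long frequency tibble (`sample_set_id`, `rsid`, `freq`).
#' @param sets Sample-set tibble (groups and cohort sizes).
#' @param annotations Optional annotation tibble supplying `locus`.
#' @param thresholds [significance_thresholds()].
#' @param uvb_order Groups by ascending mean annual UVB (default
#'   EUR < EAS < AFR, the observed ordering); used only for the cline label.
#' @param conf_level Level for the group-mean confidence intervals.
#' @return One row per variant with the full report columns (see
#'   [write_report()]) plus the significance flags `sig_*` and `f`,
#'   `r_squared`.
#' @export
compare_variants <- function(freq, sets, annotations = NULL,
                             thresholds = significance_thresholds(),
                             uvb_order = ANALYSIS_GROUPS,
                             conf_level = 0.95) {
  rsids <- unique(freq$rsid)
  joined <- dplyr::inner_join(freq, sets[c("id", "group", "n")],
                              by = c(sample_set_id = "id"))
  stats <- purrr::map_dfr(rsids, function(rs) {
    d <- joined[joined$rsid == rs & !is.na(joined$freq), ]
    fit <- weighted_anova(d, y = freq, group = group, w = n)
    ci <- group_confidence_interval(fit, level = conf_level)
    pw <- tukey_kramer(fit)
    letters_tbl <- compact_letter_display(pw, alpha = thresholds$alpha_pairwise)

    row <- tibble::tibble(rsid = rs, n_sets = fit$n_sets,
                          n_subjects = sum(d$n),
                          p_assoc = fit$p_value, adj_r2 = fit$adj_r_squared,
                          f = fit$f, r_squared = fit$r_squared)
    for (g in ANALYSIS_GROUPS) {
      i <- match(g, ci$group)
      row[[paste0("mean_", g)]] <- if (is.na(i)) NA_real_ else ci$mean[i]
      row[[paste0("ci_", g, "_lo")]] <- if (is.na(i)) NA_real_ else ci$ci_lo[i]
      row[[paste0("ci_", g, "_hi")]] <- if (is.na(i)) NA_real_ else ci$ci_hi[i]
      j <- match(g, letters_tbl$group)
      row[[paste0("letters_", g)]] <- if (is.na(j)) NA_character_ else letters_tbl$letters[j]
    }
    for (pair in PAIR_LABELS) {
      i <- match(pair, pw$pair)
      row[[paste0("p_", sub("-", "_", pair))]] <- if (is.na(i)) NA_real_ else pw$p[i]
    }
    row
  })

  stats <- stats |>
    dplyr::mutate(
      sig_assoc = apply_bonferroni(.data$p_assoc, thresholds$alpha_assoc),
      sig_EUR_EAS = apply_bonferroni(.data$p_EUR_EAS, thresholds$alpha_pairwise),
      sig_EUR_AFR = apply_bonferroni(.data$p_EUR_AFR, thresholds$alpha_pairwise),
      sig_EAS_AFR = apply_bonferroni(.data$p_EAS_AFR, thresholds$alpha_pairwise),
      pattern = classify_pattern(.data$sig_EUR_EAS, .data$sig_EUR_AFR,
                                 .data$sig_EAS_AFR))
  stats$uvb_cline <- vapply(seq_len(nrow(stats)), function(i) {
    classify_uvb_cline(
      setNames(c(stats$mean_EUR[i], stats$mean_EAS[i], stats$mean_AFR[i]),
               ANALYSIS_GROUPS), uvb_order)
  }, character(1))

  if (!is.null(annotations)) {
    stats <- dplyr::left_join(stats, annotations[c("rsid", "locus")], by = "rsid")
  } else {
    stats$locus <- NA_character_
  }
  dplyr::relocate(stats, "rsid", "locus")
}

#' Assemble per-variant components into report rows
#'
#' Joins independently computed per-variant statistics, pattern labels and
#' cline labels into the final report table, erroring if any variant is
#' present in one component and absent from another.
#'
#' @param stats Per-variant statistics tibble (must contain `rsid` and the
#'   report's numeric/letter columns).
#' @param patterns Tibble `rsid`, `pattern`.
#' @param clines Tibble `rsid`, `uvb_cline`.
#' @return Tibble with one row per variant, ready for [write_report()].
#' @export
build_results <- function(stats, patterns, clines) {
  for (nm in c("patterns", "clines")) {
    other <- get(nm)
    extra <- setdiff(other$rsid, stats$rsid)
    missing_rs <- setdiff(stats$rsid, other$rsid)
    if (length(extra) > 0 || length(missing_rs) > 0) {
      abort(paste0("component mismatch in ", nm, ": ",
                   paste(c(extra, missing_rs), collapse = ", ")))
    }
  }
  stats |>
    dplyr::select(-dplyr::any_of(c("pattern", "uvb_cline"))) |>
    dplyr::left_join(patterns[c("rsid", "pattern")], by = "rsid") |>
    dplyr::left_join(clines[c("rsid", "uvb_cline")], by = "rsid")
}
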