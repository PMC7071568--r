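#' Variant-allele frequency from diploid genotype counts
#'
#' @param hom_ref,het,hom_alt Non-negative integer vectors of genotype counts.
#' @return `(2 * hom_alt + het) / (2 * (hom_ref + het + hom_alt))`, `NA` where
#'   no samples were called.
#' @export
allele_frequency <- function(hom_ref, het, hom_alt) {
  total <- hom_ref + het + hom_alt
  if (any(c(hom_ref, het, hom_alt) < 0, na.rm = TRUE)) {
    abort("genotype counts must be non-negative")
  }
  ifelse(total == 0, NA_real_, (2 * hom_alt + het) / (2 * total))
}

#' Convert per-set genotype counts to a long frequency table
#'
#' @param genotypes Tibble as returned by [read_genotypes_vcf()].
#' @return Long frequency tibble (`sample_set_id`, `rsid`, `freq`).
#' @export
genotype_frequencies <- function(genotypes) {
  validate_frequencies(dplyr::transmute(
    genotypes, .data$sample_set_id, .data$rsid,
    freq = allele_frequency(.data$hom_ref, .data$het, .data$hom_alt)))
}

#' Wright's fixation index from population frequencies
#'
#' The frequency-variance form: the weighted variance of population allele
#' frequencies divided by `p̄ (1 - p̄)` at the weighted mean frequency `p̄`.
#' Zero when the pooled frequency is monomorphic; clamped to \[0, 1\].
#'
#' @param p Numeric vector of population allele frequencies (`NA` dropped).
#' @param w Positive weights (e.g. cohort sizes); default equal.
#' @return The fixation index in \[0, 1\].
#' @export
wright_fst <- function(p, w = rep(1, length(p))) {
  keep <- !is.na(p)
  p <- p[keep]; w <- w[keep]
  if (length(p) < 2) abort("wright_fst needs at least 2 population frequencies")
  if (any(w <= 0)) abort("weights must be positive")
  pbar <- weighted.mean(p, w)
  denom <- pbar * (1 - pbar)
  if (denom == 0) return(0)
  v <- weighted.mean((p - pbar)^2, w)
  min(1, max(0, v / denom))
}

#' Per-variant fixation indices for a frequency table
#'
#' @param freq Long frequency tibble.
#' @param sets Sample-set tibble (supplies cohort-size weights and groups).
#' @param mode `"sample_sets"`: Wright FST across all individual sample sets
#'   weighted by cohort size. `"groups"`: across the cohort-weighted group
#'   pooled frequencies, weighted by group subject totals.
#' @return Tibble `rsid`, `fst`, `n_sets` (populations used).
#' @export
fst_by_variant <- function(freq, sets, mode = c("sample_sets", "groups")) {
  mode <- match.arg(mode)
  joined <- dplyr::inner_join(freq, sets[c("id", "group", "n")],
                              by = c(sample_set_id = "id"))
  joined <- joined[!is.na(joined$freq), ]
  if (mode == "groups") {
    joined <- joined |>
      dplyr::group_by(.data$rsid, .data$group) |>
      dplyr::summarise(freq = weighted.mean(.data$freq, .data$n),
                       n = sum(.data$n), .groups = "drop")
  }
  joined |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(fst = wright_fst(.data$freq, .data$n),
                     n_sets = dplyr::n(), .groups = "drop")
}

#' Weir-Cockerham fixation index from genotype counts
#'
#' The 1984 variance-components estimator `a / (a + b + c)` for one biallelic
#' variant observed in two or more populations, using the among-population
#' (`a`), among-individual (`b`) and within-individual (`c`) components from
#' population sample sizes, allele frequencies and observed heterozygosities.
#' Negative estimates are truncated to 0 for reporting; the raw value is kept
#' in the `"raw"` attribute.
#'
#' @param counts Tibble with one row per population: columns `hom_ref`, `het`,
#'   `hom_alt`.
#' @return The estimate in \[0, 1\] (`NA` when `a + b + c` is 0), with
#'   attribute `raw`.
#' @export
weir_cockerham_fst <- function(counts) {
  n_i <- counts$hom_ref + counts$het + counts$hom_alt
  if (nrow(counts) < 2) abort("weir_cockerham_fst needs >= 2 populations")
  if (any(n_i < 1)) abort("every population needs >= 1 called sample")
  r <- nrow(counts)
  p_i <- (2 * counts$hom_alt + counts$het) / (2 * n_i)
  h_i <- counts$het / n_i
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)

  if (nbar > 1) {
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  } else {
    # single-diploid populations carry no among-individual information
    a <- (nbar / nc) * s2
    b <- 0
  }
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(structure(NA_real_, raw = NA_real_))
  raw <- a / denom
  structure(min(1, max(0, raw)), raw = raw)
}

#' Select variants by population differentiation
#'
#' Ranks variants by fixation index (descending, ties broken by rsID so the
#' result is order-invariant), keeps those in the top fraction of the ranking
#' that also meet the FST floor, then drops excluded function classes.
#' Exclusions carry a reason code: `BELOW_FLOOR`, `BELOW_RANK` or
#' `FUNCTION_CLASS`.
#'
#' @param annotations Variant-annotation tibble; every row must carry an `fst`
#'   (database-provided values take precedence; compute missing ones with
#'   [fst_by_variant()] first).
#' @param top_fraction Fraction of the ranking to keep (default 0.30); the cut
#'   is `ceiling(top_fraction * n)`.
#' @param fst_floor Minimum fixation index (default 0.13).
#' @param exclude_function_classes Function classes to drop after ranking
#'   (default `"Unknown"`).
#' @return The annotation tibble sorted by rank, with `rank`, `included`
#'   (logical) and `reason` (`NA` for retained variants) columns.
#' @export
select_variants <- function(annotations, top_fraction = 0.30, fst_floor = 0.13,
                            exclude_function_classes = "Unknown") {
  if (nrow(annotations) == 0) abort("empty annotation table")
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
  if (fst_floor < 0 || fst_floor > 1) abort("fst_floor must be in [0, 1]")
  if (any(is.na(annotations$fst))) {
    abort(paste0("missing fst for: ",
                 paste(annotations$rsid[is.na(annotations$fst)], collapse = ", ")))
  }
  ranked <- dplyr::arrange(annotations, dplyr::desc(.data$fst), .data$rsid)
  ranked$rank <- seq_len(nrow(ranked))
  cutoff <- ceiling(top_fraction * nrow(ranked))
  ranked |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$fst < fst_floor ~ "BELOW_FLOOR",
        .data$rank > cutoff ~ "BELOW_RANK",
        .data$function_class %in% exclude_function_classes ~ "FUNCTION_CLASS",
        TRUE ~ NA_character_),
      included = is.na(.data$reason))
}

#' Validate ancestry groups with pigmentation-marker frequencies
#'
#' Checks that the cohort-size-weighted group mean frequencies of the
#' validation markers fall where the groups' ancestral skin-pigmentation
#' genetics say they must (see [default_ancestry_rules()]). Sample sets
#' lacking data for any validation marker are flagged for exclusion before
#' analysis; they do not contribute to the group means.
#'
#' @param freq Long frequency tibble.
#' @param sets Sample-set tibble.
#' @param rules Rule tibble (default [default_ancestry_rules()]).
#' @return List of class `ancestry_validation`: `report` (one row per rule
#'   with the observed weighted mean and `pass`), `exclude_sets` (ids lacking
#'   any marker), `pass` (overall).
#' @export
validate_ancestry <- function(freq, sets, rules = default_ancestry_rules()) {
  missing_rsids <- setdiff(unique(rules$rsid), unique(freq$rsid))
  if (length(missing_rsids) > 0) {
    abort(paste0("validation marker(s) absent from frequency table: ",
                 paste(missing_rsids, collapse = ", ")))
  }
  marker <- freq[freq$rsid %in% rules$rsid, ]
  coverage <- marker |>
    dplyr::group_by(.data$sample_set_id) |>
    dplyr::summarise(complete = sum(!is.na(.data$freq)) ==
                       length(unique(rules$rsid)), .groups = "drop")
  exclude <- union(coverage$sample_set_id[!coverage$complete],
                   setdiff(sets$id, coverage$sample_set_id))
  usable <- dplyr::inner_join(
    marker[!marker$sample_set_id %in% exclude, ],
    sets[c("id", "group", "n")], by = c(sample_set_id = "id"))

  means <- usable |>
    dplyr::group_by(.data$rsid, .data$group) |>
    dplyr::summarise(observed = weighted.mean(.data$freq, .data$n),
                     .groups = "drop")
  report <- dplyr::left_join(rules, means, by = c("rsid", "group")) |>
    dplyr::mutate(pass = !is.na(.data$observed) &
                    .data$observed >= .data$lo & .data$observed <= .data$hi)
  if (length(exclude) > 0) {
    warn(paste0("excluding ", length(exclude),
                " sample set(s) lacking validation-marker data: ",
                paste(exclude, collapse = ", ")))
  }
  structure(list(report = report, exclude_sets = exclude,
                 pass = all(report$pass)),
            class = "ancestry_validation")
}

#' @export
print.ancestry_validation <- function(x, ...) {
  cat("Ancestry-group validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$exclude_sets) > 0) {
    cat("Sets excluded (incomplete marker data):",
        paste(x$exclude_sets, collapse = ", "), "\n")
  }
  print(x$report)
  invisible(x)
}
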