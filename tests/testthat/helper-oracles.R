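# Shared fixtures and independent oracles used across test files.

# Minimal three-group roster (two sets per group, varied cohort sizes).
tiny_sets <- function() {
  validate_sample_sets(tibble::tibble(
    id = c("E1", "E2", "A1", "A2", "F1", "F2"),
    name = paste("set", 1:6),
    group = c("EUR", "EUR", "EAS", "EAS", "AFR", "AFR"),
    n = c(10L, 30L, 20L, 20L, 15L, 25L),
    lat_min = c(50, 60, 30, 35, -5, 5),
    lat_max = c(55, 60, 30, 40, -5, 5),
    lon = c(10, 25, 110, 120, 20, 0),
    source = "SYNTHETIC"))
}

long_freq <- function(ids, rsid, freq) {
  tibble::tibble(sample_set_id = ids, rsid = rsid, freq = freq)
}

# Weir-Cockerham estimate recomputed through an allele-level nested ANOVA
# (alleles within individuals within populations) via stats::lm/anova --
# an independent computational route to the same variance components.
wc_fst_anova_oracle <- function(counts) {
  df <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    doses <- rep(c(0L, 1L, 2L),
                 times = unlist(counts[i, c("hom_ref", "het", "hom_alt")]))
    do.call(rbind, lapply(seq_along(doses), function(j) {
      al <- switch(doses[j] + 1L, c(0, 0), c(0, 1), c(1, 1))
      data.frame(pop = i, ind = paste(i, j), y = al)
    }))
  }))
  ms <- anova(lm(y ~ factor(pop) + factor(ind), data = df))
  msp <- ms["factor(pop)", "Mean Sq"]
  msi <- ms["factor(ind)", "Mean Sq"]
  msg <- ms["Residuals", "Mean Sq"]
  n_i <- counts$hom_ref + counts$het + counts$hom_alt
  r <- nrow(counts)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  s2a <- (msp - msi) / (2 * nc)
  s2b <- (msi - msg) / 2
  s2a / (s2a + s2b + msg)
}

random_genotype_counts <- function(r = NULL) {
  r <- r %||% sample(2:5, 1)
  repeat {
    counts <- tibble::tibble(hom_ref = sample(0:20, r, replace = TRUE),
                             het = sample(0:20, r, replace = TRUE),
                             hom_alt = sample(0:20, r, replace = TRUE))
    if (all(counts$hom_ref + counts$het + counts$hom_alt >= 2)) return(counts)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("1", "100", "rs_a", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1/1", "0/0", "0/0", sep = "\t"),
    paste("1", "200", "rs_b", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/0", "0/0", sep = "\t"),
    paste("1", "300", "rs_multi", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", "0/0", sep = "\t"),
    paste("1", "400", "rs_c", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/1", "1/1", "0/1", sep = "\t"))
  writeLines(lines, path)
  path
}
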