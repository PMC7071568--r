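test_that("allele_frequency matches hand-counted diploid cases", {
  expect_equal(allele_frequency(0, 0, 5), 1)
  expect_equal(allele_frequency(5, 0, 0), 0)
  expect_equal(allele_frequency(2, 4, 2), 0.5)   # 8 of 16 allele copies
  expect_true(is.na(allele_frequency(0, 0, 0)))
  expect_error(allele_frequency(-1, 0, 1), "non-negative")
})

test_that("wright_fst matches hand computation and closed form", {
  expect_equal(wright_fst(c(0.2, 0.8)), 0.36)    # var 0.09 / (0.5 * 0.5)
  expect_equal(wright_fst(c(0.3, 0.3, 0.3)), 0)
  expect_equal(wright_fst(c(0, 1)), 1)
  expect_equal(wright_fst(c(0, 0)), 0)           # monomorphic
  expect_error(wright_fst(0.4), "at least 2")
  # two equal-weight populations: ((p - q)/2)^2 / (pbar (1 - pbar))
  grid <- expand.grid(p = seq(0.05, 0.95, by = 0.15),
                      q = seq(0.05, 0.95, by = 0.15))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    pbar <- (p + q) / 2
    expect_equal(wright_fst(c(p, q)),
                 min(1, ((p - q) / 2)^2 / (pbar * (1 - pbar))),
                 tolerance = 1e-12)
  }
  # missing frequencies are dropped, weights respected
  expect_equal(wright_fst(c(0.2, NA, 0.8), c(1, 5, 1)), 0.36)
})

test_that("weir_cockerham_fst handles undifferentiated and fixed extremes", {
  same <- tibble::tibble(hom_ref = c(30, 30), het = c(40, 40), hom_alt = c(30, 30))
  expect_lte(weir_cockerham_fst(same), 0 + 1e-12)
  fixed <- tibble::tibble(hom_ref = c(50, 0), het = c(0, 0), hom_alt = c(0, 50))
  expect_gt(weir_cockerham_fst(fixed), 0.99)
  expect_error(weir_cockerham_fst(same[1, ]), ">= 2 populations")
  mono <- tibble::tibble(hom_ref = c(10, 10), het = c(0, 0), hom_alt = c(0, 0))
  expect_true(is.na(weir_cockerham_fst(mono)))
})

test_that("weir_cockerham_fst agrees with the allele-level ANOVA oracle", {
  set.seed(101)
  for (i in 1:100) {
    counts <- random_genotype_counts()
    mine <- attr(weir_cockerham_fst(counts), "raw")
    oracle <- wc_fst_anova_oracle(counts)
    if (is.finite(oracle) && is.finite(mine)) {
      expect_equal(mine, oracle, tolerance = 1e-6)
    }
  }
})

test_that("fst_by_variant computes per-variant indices in both modes", {
  sets <- tiny_sets()
  freq <- long_freq(rep(sets$id, 2), rep(c("v1", "v2"), each = 6),
                    c(0.9, 0.9, 0.1, 0.1, 0.5, 0.5, rep(0.4, 6)))
  by_set <- fst_by_variant(freq, sets, mode = "sample_sets")
  by_grp <- fst_by_variant(freq, sets, mode = "groups")
  expect_equal(by_set$fst[by_set$rsid == "v2"], 0)
  expect_equal(by_grp$fst[by_grp$rsid == "v2"], 0)
  expect_gt(by_set$fst[by_set$rsid == "v1"], 0.3)
  # group mode pools within groups first, so within-group spread vanishes
  freq2 <- long_freq(sets$id, "v3", c(0.8, 1.0, 0.1, 0.1, 0.5, 0.5))
  bs <- fst_by_variant(freq2, sets)$fst
  bg <- fst_by_variant(freq2, sets, mode = "groups")$fst
  expect_gt(bs, bg * 0.99)
})

test_that("differentiation filter ranks, floors and drops unknown classes", {
  # all 46 catalogue variants sit at or above the 0.13 floor
  kept <- select_variants(table5_variants(), top_fraction = 1, fst_floor = 0.13)
  expect_true(all(kept$included))
  expect_equal(sum(kept$included), 46)

  ann <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"), locus = "L", variant_allele = "A",
    maf = 0.2, fst = c(0.5, 0.4, 0.1), function_class = "Intron")
  out <- select_variants(ann, top_fraction = 1, fst_floor = 0.13)
  expect_equal(out$reason[out$rsid == "rs3"], "BELOW_FLOOR")
  expect_equal(sum(out$included), 2)

  # ten tied fsts, top 30% -> exactly 3, ties resolved lexicographically
  tied <- tibble::tibble(
    rsid = sprintf("rs%02d", sample(1:10)), locus = "L", variant_allele = "A",
    maf = 0.2, fst = 0.2, function_class = "Intron")
  out3 <- select_variants(tied, top_fraction = 0.3, fst_floor = 0.13)
  expect_equal(out3$rsid[out3$included], sort(tied$rsid)[1:3])
  # and the selection is invariant to input order
  out3b <- select_variants(dplyr::arrange(tied, rsid), top_fraction = 0.3,
                           fst_floor = 0.13)
  expect_equal(out3$rsid[out3$included], out3b$rsid[out3b$included])

  unk <- tied
  unk$function_class[match(sort(tied$rsid)[1], unk$rsid)] <- "Unknown"
  out4 <- select_variants(unk, top_fraction = 0.3, fst_floor = 0.13)
  expect_equal(out4$reason[out4$rsid == sort(tied$rsid)[1]], "FUNCTION_CLASS")

  expect_error(select_variants(ann[0, ]), "empty")
  ann$fst[1] <- NA
  expect_error(select_variants(ann), "missing fst")
})

test_that("ancestry validation passes on the published marker means and fails on breaches", {
  sets <- tiny_sets()
  make_freq <- function(eur, eas, afr, rsid) {
    long_freq(sets$id, rsid, c(eur, eur, eas, eas, afr, afr))
  }
  freq <- dplyr::bind_rows(
    make_freq(0.99, 0.03, 0.08, "rs1426654"),
    make_freq(0.91, 0.01, 0.00, "rs16891982"),
    make_freq(0.00, 0.59, 0.00, "rs1800414"))
  v <- validate_ancestry(freq, sets)
  expect_true(v$pass)
  expect_length(v$exclude_sets, 0)
  expect_equal(nrow(v$report), 9)

  # a 0.50 EUR mean for rs1426654 breaches the >= 0.90 rule
  bad <- freq
  bad$freq[bad$rsid == "rs1426654" & grepl("^E", bad$sample_set_id)] <- 0.50
  vb <- validate_ancestry(bad, sets)
  expect_false(vb$pass)
  failing <- vb$report[!vb$report$pass, ]
  expect_true(all(failing$rsid == "rs1426654" & failing$group == "EUR"))
  expect_equal(failing$observed, 0.50)

  # sets lacking any marker are flagged for exclusion, not averaged
  gap <- freq
  gap$freq[gap$sample_set_id == "E2" & gap$rsid == "rs1800414"] <- NA
  expect_warning(vg <- validate_ancestry(gap, sets), "E2")
  expect_equal(vg$exclude_sets, "E2")
  expect_true(vg$pass)

  expect_error(validate_ancestry(freq[freq$rsid != "rs1800414", ], sets),
               "rs1800414")
})
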