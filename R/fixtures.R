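#' Built-in 60-sample-set roster
#'
#' The study design this package was written around: 18 European (EUR), 24
#' East Asian (EAS) and 18 Sub-Saharan African (AFR) population cohorts with
#' their published cohort sizes and latitudes (972, 795 and 866 subjects per
#' group; 2633 in total). ALFRED-derived sets carry their ALFRED sample-set
#' accession as id; 1000 Genomes sets carry their panel code. Longitudes are
#' not part of the published roster; the values here are synthetic,
#' representative coordinates for each population's region and matter only for
#' raster-cell lookup. The Mongolian (China) set has no published latitude and
#' is stored without coordinates.
#'
#' @return A validated sample-set tibble (see [read_sample_sets()]).
#' @export
table6_sample_sets <- function() {
  tab <- tibble::tribble(
    ~id, ~name, ~group, ~n, ~lat_min, ~lat_max, ~lon, ~source,
    "SA000007H", "Danes",                    "EUR",  51L, 55.0, 58.0,  10.0, "ALFRED",
    "SA000018J", "Finns",                    "EUR",  36L, 60.0, 75.0,  26.0, "ALFRED",
    "SA001508O", "Orcadian",                 "EUR",  16L, 59.0, 59.0,  -3.0, "ALFRED",
    "SA000057M", "Irish",                    "EUR", 116L, 51.0, 56.0,  -8.0, "ALFRED",
    "SA001503J", "French",                   "EUR",  28L, 46.0, 46.0,   2.0, "ALFRED",
    "SA001504K", "Basque (France)",          "EUR",  24L, 43.0, 43.0,  -1.0, "ALFRED",
    "SA002023H", "Hungarians",               "EUR",  92L, 45.5, 48.5,  19.0, "ALFRED",
    "SA001507N", "Italian (Tuscan)",         "EUR",   8L, 43.0, 43.0,  11.0, "ALFRED",
    "SA002255O", "Italian (Bergamo)",        "EUR",  14L, 46.0, 46.0,   9.7, "ALFRED",
    "SA001505L", "Sardinian",                "EUR",  28L, 40.0, 40.0,   9.0, "ALFRED",
    "SA001510H", "Russians (Vologda)",       "EUR",  25L, 61.0, 61.0,  40.0, "ALFRED",
    "SA001530J", "Russians (Archangel'sk)",  "EUR",  34L, 63.0, 64.5,  40.5, "ALFRED",
    "SA000491O", "Chuvash",                  "EUR",  42L, 54.5, 56.5,  47.0, "ALFRED",
    "SA000017I", "Adygei (Krasnodar)",       "EUR",  54L, 44.0, 45.0,  40.0, "ALFRED",
    "GBR", "British from England and Scotland", "EUR",  91L, 49.8, 59.5,  -2.0, "KG1000",
    "FIN", "Finnish in Finland",             "EUR",  99L, 60.0, 75.0,  26.0, "KG1000",
    "IBS", "Iberians in Spain",              "EUR", 107L, 36.0, 43.5,  -4.0, "KG1000",
    "TSI", "Toscani in Italia",              "EUR", 107L, 38.0, 47.0,  11.0, "KG1000",
    "SA000002C", "Ami (Taiwan)",             "EAS",  40L, 22.5, 24.0, 121.0, "ALFRED",
    "SA000021D", "Atayal (Taiwan)",          "EAS",  41L, 21.8, 25.5, 121.0, "ALFRED",
    "SA001493R", "Dai (China)",              "EAS",  10L, 21.0, 21.0, 100.0, "ALFRED",
    "SA001488V", "Daur (China)",             "EAS",  10L, 48.0, 49.0, 124.0, "ALFRED",
    "SA001483Q", "Han (China)",              "EAS",  45L, 36.0, 39.0, 114.0, "ALFRED",
    "SA001490O", "Hezhen (China)",           "EAS",  10L, 47.0, 48.0, 133.0, "ALFRED",
    "SA002260K", "Japanese",                 "EAS",  29L, 38.0, 38.0, 140.0, "ALFRED",
    "SA003027M", "Koreans",                  "EAS",  53L, 34.5, 43.0, 127.0, "ALFRED",
    "SA001494S", "Lahu (China)",             "EAS",  10L, 22.0, 22.0, 100.0, "ALFRED",
    "SA001486T", "Miao (China)",             "EAS",  10L, 28.0, 28.0, 109.0, "ALFRED",
    "SA001496U", "Naxi (China)",             "EAS",  10L, 26.0, 26.0, 100.0, "ALFRED",
    "SA001487U", "Oroqen (China)",           "EAS",  10L, 48.0, 53.0, 122.0, "ALFRED",
    "SA001495T", "She (China)",              "EAS",  10L, 27.0, 27.0, 119.0, "ALFRED",
    "SA001497V", "Tu (China)",               "EAS",  10L, 36.0, 36.0, 102.0, "ALFRED",
    "SA001484R", "Tujia (China)",            "EAS",  10L, 29.0, 29.0, 109.0, "ALFRED",
    "SA001492Q", "Uygur (China)",            "EAS",  10L, 44.0, 44.0,  81.0, "ALFRED",
    "SA001491P", "Xibo (China)",             "EAS",   9L, 43.0, 44.0,  81.0, "ALFRED",
    "SA001485S", "Yizu (China)",             "EAS",  10L, 28.0, 28.0, 103.0, "ALFRED",
    "SA000003D", "Hakka (Taiwan)",           "EAS",  43L, 22.0, 35.0, 116.0, "ALFRED",
    "SA001489W", "Mongolian (China)",        "EAS",  10L,   NA,   NA, 111.0, "ALFRED",
    "CDX", "Chinese Dai in Xishuangbanna, China", "EAS",  93L, 21.0, 28.0, 100.0, "KG1000",
    "CHB", "Han Chinese in Beijing, China",  "EAS", 103L, 22.0, 40.0, 116.0, "KG1000",
    "CHS", "Han Chinese South, China",       "EAS", 105L, 22.0, 40.0, 113.0, "KG1000",
    "JPT", "Japanese in Tokyo, Japan",       "EAS", 104L, 30.0, 46.0, 140.0, "KG1000",
    "SA001818S", "Bantu (SA)",               "AFR",   8L, -29.0, -22.0,  29.0, "ALFRED",
    "SA001819T", "Bantu (Kenya)",            "AFR",  12L,  -3.0,  -3.0,  37.0, "ALFRED",
    "SA001469U", "San (Namibia)",            "AFR",   7L, -21.0, -21.0,  20.0, "ALFRED",
    "SA001465Q", "Biaka (C. African Republic)", "AFR",  35L,  4.0,  4.0,  17.0, "ALFRED",
    "SA000100B", "Hausa (Nigeria)",          "AFR",  39L,   7.0,  18.0,   8.0, "ALFRED",
    "SA000099S", "Ibo (Nigeria)",            "AFR",  48L,   5.0,   7.0,   7.0, "ALFRED",
    "SA004361O", "Mbuti (DR Congo)",         "AFR",  19L,   1.0,   1.0,  29.0, "ALFRED",
    "SA001468T", "Yoruba (Nigeria)",         "AFR",  25L,   6.0,  10.0,   4.0, "ALFRED",
    "SA000487T", "Chagga (Tanzania)",        "AFR",  45L,  -3.5,  -2.5,  37.0, "ALFRED",
    "SA000854R", "Masai (E Africa)",         "AFR",  22L,  -6.0,   1.0,  36.0, "ALFRED",
    "SA004366T", "Sandawe (Tanzania)",       "AFR",  39L,  -7.0,  -4.0,  35.0, "ALFRED",
    "SA004367U", "Zaramo (Tanzania)",        "AFR",  39L, -11.0,  -4.0,  39.0, "ALFRED",
    "SA001467S", "Mandenka (Senegal)",       "AFR",  24L,  12.0,  12.0, -16.0, "ALFRED",
    "ESN", "Esan in Nigeria",                "AFR",  99L,   4.0,  12.0,   6.0, "KG1000",
    "GWD", "Gambian in Western Division, Mandinka", "AFR", 113L, 7.0, 23.0, -16.0, "KG1000",
    "YRI", "Yoruba in Ibadan, Nigeria",      "AFR", 108L,   6.0,  10.0,   4.0, "KG1000",
    "LWK", "Luhya in Webuye, Kenya",         "AFR",  99L,  -3.0,   1.0,  35.0, "KG1000",
    "MSL", "Mende in Sierra Leone",          "AFR",  85L,   4.0,  10.0, -12.0, "KG1000"
  )
  validate_sample_sets(tab)
}

#' Built-in annotation table of the 46 study variants
#'
#' The vitamin D-pathway variants that pass the differentiation filter
#' (top 30% of fixation indices, FST >= 0.13, known function class), with
#' their database-provided fixation indices, minor-allele frequencies,
#' designated variant alleles and dbSNP function classes.
#'
#' @return A validated variant-annotation tibble (see
#'   [read_variant_annotations()]).
#' @export
table5_variants <- function() {
  ann <- tibble::tribble(
    ~rsid, ~locus, ~fst, ~maf, ~variant_allele, ~function_class,
    "rs11632698", "CYP11A1", 0.18, 0.35, "G", "Intron",
    "rs2073475",  "CYP11A1", 0.13, 0.38, "A", "nearGene-5",
    "rs3787557",  "CYP24A1", 0.13, 0.12, "C", "Intron",
    "rs927650",   "CYP24A1", 0.14, 0.34, "T", "Intron",
    "rs912505",   "CYP24A1", 0.14, 0.39, "G", "Intron",
    "rs2762929",  "CYP24A1", 0.15, 0.39, "T", "Intron",
    "rs4809956",  "CYP24A1", 0.18, 0.40, "C", "Intron",
    "rs7568196",  "CYP27A1", 0.14, 0.25, "A", "Intron",
    "rs4674338",  "CYP27A1", 0.17, 0.25, "G", "Intron",
    "rs13013510", "CYP27A1", 0.18, 0.43, "G", "Intron",
    "rs691414",   "CYP27A1", 0.30, 0.06, "C", "Intron",
    "rs692290",   "CYP27A1", 0.38, 0.11, "G", "Intron",
    "rs16930625", "CYP2R1",  0.14, 0.15, "G", "5' UTR",
    "rs11023374", "CYP2R1",  0.17, 0.17, "C", "Intron",
    "rs3750997",  "DHCR7/NADSYN1", 0.16, 0.42, "T", "Intron",
    "rs1790325",  "DHCR7/NADSYN1", 0.18, 0.26, "A", "Intron",
    "rs11603330", "DHCR7/NADSYN1", 0.18, 0.35, "A", "Intron",
    "rs7928249",  "DHCR7/NADSYN1", 0.20, 0.42, "A", "nearGene-5",
    "rs12800438", "DHCR7/NADSYN1", 0.16, 0.40, "G", "Intron",
    "rs7944926",  "DHCR7/NADSYN1", 0.22, 0.35, "A", "Intron",
    "rs3794060",  "DHCR7/NADSYN1", 0.23, 0.35, "T", "Intron",
    "rs12280295", "DHCR7/NADSYN1", 0.53, 0.05, "C", "Intron",
    "rs7041",     "GC", 0.14, 0.38, "G", "Missense",
    "rs4364228",  "GC", 0.14, 0.17, "G", "Intron",
    "rs222047",   "GC", 0.16, 0.38, "G", "Intron",
    "rs3737549",  "GC", 0.16, 0.10, "T", "Intron",
    "rs222016",   "GC", 0.17, 0.34, "A", "Intron",
    "rs222020",   "GC", 0.17, 0.34, "T", "Intron",
    "rs843006",   "GC", 0.19, 0.36, "G", "Intron",
    "rs705117",   "GC", 0.25, 0.42, "A", "Intron",
    "rs1805343",  "RXRA", 0.16, 0.48, "A", "Intron",
    "rs1805352",  "RXRA", 0.16, 0.47, "A", "Intron",
    "rs10881582", "RXRA", 0.18, 0.38, "G", "Intron",
    "rs3118571",  "RXRA", 0.19, 0.48, "A", "Intron",
    "rs3818740",  "RXRA", 0.20, 0.38, "T", "Intron",
    "rs731516",   "RXRA", 0.43, 0.11, "A", "Intron",
    "rs7040434",  "RXRA", 0.51, 0.15, "C", "Intron",
    "rs283695",   "RXRG", 0.14, 0.34, "A", "Intron",
    "rs12069160", "RXRG", 0.15, 0.14, "T", "Intron",
    "rs10800098", "RXRG", 0.16, 0.12, "A", "Intron",
    "rs10489745", "RXRG", 0.17, 0.17, "C", "Intron",
    "rs886441",   "VDR", 0.13, 0.23, "C", "Intron",
    "rs2283342",  "VDR", 0.13, 0.19, "C", "Intron",
    "rs2107301",  "VDR", 0.16, 0.34, "T", "Intron",
    "rs4334089",  "VDR", 0.17, 0.41, "G", "Intron",
    "rs4516035",  "VDR", 0.18, 0.18, "C", "2KB upstream"
  )
  validate_variant_annotations(ann[c("rsid", "locus", "variant_allele",
                                     "maf", "fst", "function_class")])
}

#' Published group means and distribution patterns for the production/transport loci
#'
#' Sixteen variants in the vitamin D production (DHCR7/NADSYN1) and transport
#' (GC) loci with their published cohort-weighted group mean frequencies and
#' distribution-pattern labels. Used as generative truth in pattern-recovery
#' simulations: seed the synthetic generator with these means and check that
#' the pipeline re-derives the labels.
#'
#' @return Tibble with `rsid`, `locus`, `mean_EUR`, `mean_EAS`, `mean_AFR`,
#'   `pattern`.
#' @export
table2_frequency_patterns <- function() {
  tibble::tribble(
    ~rsid, ~locus, ~mean_EUR, ~mean_EAS, ~mean_AFR, ~pattern,
    "rs3750997",  "DHCR7/NADSYN1", 0.30, 0.58, 0.65, "EUR_DIFFERS",
    "rs1790325",  "DHCR7/NADSYN1", 0.95, 0.73, 0.57, "EUR_DIFFERS",
    "rs11603330", "DHCR7/NADSYN1", 0.69, 0.35, 0.11, "ALL_DIFFER",
    "rs7928249",  "DHCR7/NADSYN1", 0.29, 0.66, 0.63, "EUR_DIFFERS",
    "rs12800438", "DHCR7/NADSYN1", 0.30, 0.63, 0.66, "EUR_DIFFERS",
    "rs7944926",  "DHCR7/NADSYN1", 0.30, 0.63, 0.86, "ALL_DIFFER",
    "rs3794060",  "DHCR7/NADSYN1", 0.70, 0.37, 0.11, "ALL_DIFFER",
    "rs12280295", "DHCR7/NADSYN1", 0.00, 0.00, 0.23, "AFR_DIFFERS",
    "rs7041",     "GC", 0.58, 0.28, 0.10, "ALL_DIFFER",
    "rs4364228",  "GC", 0.09, 0.12, 0.45, "AFR_DIFFERS",
    "rs222047",   "GC", 0.58, 0.23, 0.12, "ALL_DIFFER",
    "rs3737549",  "GC", 0.00, 0.14, 0.22, "EUR_DIFFERS",
    "rs222016",   "GC", 0.85, 0.62, 0.37, "ALL_DIFFER",
    "rs222020",   "GC", 0.85, 0.62, 0.36, "ALL_DIFFER",
    "rs843006",   "GC", 0.83, 0.62, 0.31, "ALL_DIFFER",
    "rs705117",   "GC", 0.84, 0.50, 0.17, "ALL_DIFFER"
  )
}

#' Default ancestry-validation rules
#'
#' Three skin-pigmentation markers with well-characterised continental
#' distributions anchor the group labels: the derived alleles of SLC24A5
#' rs1426654 and SLC45A2 rs16891982 are near-fixed in European-ancestry
#' populations and near-absent elsewhere, while OCA2 rs1800414 is restricted
#' to East Asian populations at intermediate frequency.
#'
#' @param high_min Minimum weighted group mean for a "high" rule (default 0.90).
#' @param low_max Maximum weighted group mean for a "low" rule (default 0.10).
#' @param eas_range Frequency window for rs1800414 in EAS (default
#'   `c(0.50, 0.65)`).
#' @return Tibble with columns `rsid`, `group`, `rule` (one of
#'   `"min"`, `"max"`, `"range"`), `lo`, `hi`.
#' @export
default_ancestry_rules <- function(high_min = 0.90, low_max = 0.10,
                                   eas_range = c(0.50, 0.65)) {
  tibble::tribble(
    ~rsid, ~group, ~rule, ~lo, ~hi,
    "rs1426654",  "EUR", "min",   high_min, 1,
    "rs1426654",  "EAS", "max",   0, low_max,
    "rs1426654",  "AFR", "max",   0, low_max,
    "rs16891982", "EUR", "min",   high_min, 1,
    "rs16891982", "EAS", "max",   0, low_max,
    "rs16891982", "AFR", "max",   0, low_max,
    "rs1800414",  "EAS", "range", eas_range[1], eas_range[2],
    "rs1800414",  "EUR", "max",   0, low_max,
    "rs1800414",  "AFR", "max",   0, low_max
  )
}

#' Published group means of the ancestry-validation markers
#'
#' Cohort-weighted group mean variant-allele frequencies of the three
#' pigmentation markers in the 60-set design; used to seed simulations of the
#' validation stage.
#'
#' @return Tibble with `rsid`, `mean_EUR`, `mean_EAS`, `mean_AFR`.
#' @export
pigmentation_marker_means <- function() {
  tibble::tribble(
    ~rsid, ~mean_EUR, ~mean_EAS, ~mean_AFR,
    "rs1426654",  0.99, 0.03, 0.08,
    "rs16891982", 0.91, 0.01, 0.00,
    "rs1800414",  0.00, 0.59, 0.00
  )
}
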