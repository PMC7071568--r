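#' Read sample-set metadata
#'
#' A sample set is one population cohort — the unit of analysis throughout the
#' package, weighted by its subject count `n`. Latitude is stored as a range
#' (`lat_min`, `lat_max`, equal for point locations, southern latitudes
#' negative); a set may lack coordinates entirely (both `NA`), in which case it
#' is excluded from UVB aggregation only, never from frequency statistics.
#'
#' @param path Path to a tab-delimited file with header
#'   `id, name, group, n, lat_min, lat_max, lon, source`.
#' @return A tibble with one row per sample set, validated: unique ids,
#'   `n >= 1`, `lat_min <= lat_max`, longitude in \[-180, 180\], `group` one of
#'   EUR/EAS/AFR/OTHER, `source` one of ALFRED/KG1000/SYNTHETIC.
#' @seealso [table6_sample_sets()] for the built-in 60-set roster,
#'   [read_frequency_matrix()], [uvb_by_sample_set()]
#' @export
read_sample_sets <- function(path) {
  raw <- tsv_read(path, col_types = readr::cols(
    id = readr::col_character(), name = readr::col_character(),
    group = readr::col_character(), n = readr::col_double(),
    lat_min = readr::col_double(), lat_max = readr::col_double(),
    lon = readr::col_double(), source = readr::col_character()
  ))
  validate_sample_sets(tibble::as_tibble(raw))
}

#' Validate a sample-set table
#'
#' Checks the invariants that [read_sample_sets()] enforces; useful when a
#' roster is constructed in code rather than read from disk.
#'
#' @param sets A data frame with the sample-set columns (see
#'   [read_sample_sets()]).
#' @return The validated tibble, invisibly unchanged apart from column order.
#' @export
validate_sample_sets <- function(sets) {
  required <- c("id", "name", "group", "n", "lat_min", "lat_max", "lon", "source")
  missing_cols <- setdiff(required, names(sets))
  if (length(missing_cols) > 0) {
    abort(paste0("sample-set table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sets <- tibble::as_tibble(sets)[required]
  if (nrow(sets) == 0) return(sets)

  dup <- sets$id[duplicated(sets$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample-set id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_n <- which(is.na(sets$n) | sets$n < 1 | sets$n != floor(sets$n))
  if (length(bad_n) > 0) {
    abort(paste0("cohort size n must be an integer >= 1; offending row(s): ",
                 paste(bad_n, collapse = ", ")))
  }
  bad_group <- setdiff(unique(sets$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad_group, collapse = ", ")))
  }
  bad_source <- setdiff(unique(sets$source), SOURCE_LEVELS)
  if (length(bad_source) > 0) {
    abort(paste0("unknown source label(s): ", paste(bad_source, collapse = ", ")))
  }
  has_coord <- !is.na(sets$lat_min) | !is.na(sets$lat_max)
  half <- has_coord & (is.na(sets$lat_min) | is.na(sets$lat_max))
  if (any(half)) {
    abort(paste0("lat_min/lat_max must both be present or both NA; row(s): ",
                 paste(which(half), collapse = ", ")))
  }
  with_lat <- which(has_coord)
  bad_rng <- with_lat[sets$lat_min[with_lat] > sets$lat_max[with_lat] |
                        sets$lat_min[with_lat] < -90 | sets$lat_max[with_lat] > 90]
  if (length(bad_rng) > 0) {
    abort(paste0("invalid latitude range in row(s): ", paste(bad_rng, collapse = ", ")))
  }
  bad_lon <- which(!is.na(sets$lon) & (sets$lon < -180 | sets$lon > 180))
  if (length(bad_lon) > 0) {
    abort(paste0("longitude outside [-180, 180] in row(s): ",
                 paste(bad_lon, collapse = ", ")))
  }
  sets$n <- as.integer(sets$n)
  sets
}

#' Read a variant-allele frequency matrix
#'
#' The canonical interchange format: a wide tab-delimited table whose first
#' column is the sample-set id and whose remaining columns are rsIDs, cells
#' holding the variant-allele frequency in that set (or `NA`). Frequencies are
#' expected to be oriented to the study's designated variant allele already.
#'
#' @param path Path to the wide TSV.
#' @return A long tibble with columns `sample_set_id`, `rsid`, `freq`, one row
#'   per cell of the input including missing cells (`freq = NA`).
#' @export
read_frequency_matrix <- function(path) {
  raw <- tsv_read(path)
  if (ncol(raw) < 2) abort("frequency matrix needs an id column plus >= 1 rsID column")
  names(raw)[1] <- "sample_set_id"
  long <- tidyr::pivot_longer(raw, -"sample_set_id",
                              names_to = "rsid", values_to = "freq")
  long$freq <- as.numeric(long$freq)
  validate_frequencies(long)
}

#' @noRd
validate_frequencies <- function(long) {
  bad <- which(!is.na(long$freq) & (long$freq < 0 | long$freq > 1))
  if (length(bad) > 0) {
    first <- long[bad[1], ]
    abort(sprintf(
      "frequency outside [0, 1] at (%s, %s): %g (%d offending cell%s)",
      first$sample_set_id, first$rsid, first$freq, length(bad),
      if (length(bad) > 1) "s" else ""))
  }
  tibble::as_tibble(long)
}

#' Write a frequency table back to the wide TSV layout
#'
#' @param freq Long frequency tibble (`sample_set_id`, `rsid`, `freq`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_frequency_matrix <- function(freq, path) {
  wide <- tidyr::pivot_wider(freq, id_cols = "sample_set_id",
                             names_from = "rsid", values_from = "freq")
  names(wide)[1] <- "id"
  tsv_write(wide, path)
}

#' Read a variant annotation table
#'
#' @param path TSV with columns `rsid, locus, variant_allele, maf, fst,
#'   function_class`; `fst` may be `NA` (computed downstream from frequencies).
#' @return Validated tibble; `maf` and `fst` checked to \[0, 1\],
#'   `function_class` to the known vocabulary.
#' @seealso [table5_variants()], [select_variants()]
#' @export
read_variant_annotations <- function(path) {
  ann <- tsv_read(path, col_types = readr::cols(
    rsid = readr::col_character(), locus = readr::col_character(),
    variant_allele = readr::col_character(), maf = readr::col_double(),
    fst = readr::col_double(), function_class = readr::col_character()
  ))
  validate_variant_annotations(tibble::as_tibble(ann))
}

#' @noRd
validate_variant_annotations <- function(ann) {
  required <- c("rsid", "locus", "variant_allele", "maf", "fst", "function_class")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(ann$rsid[duplicated(ann$rsid)])
  if (length(dup) > 0) abort(paste0("duplicate rsid(s): ", paste(dup, collapse = ", ")))
  if (any(!is.na(ann$maf) & (ann$maf < 0 | ann$maf > 1))) abort("maf outside [0, 1]")
  if (any(!is.na(ann$fst) & (ann$fst < 0 | ann$fst > 1))) abort("fst outside [0, 1]")
  bad_fc <- setdiff(unique(ann$function_class), FUNCTION_CLASSES)
  if (length(bad_fc) > 0) {
    abort(paste0("unknown function class(es): ", paste(bad_fc, collapse = ", ")))
  }
  tibble::as_tibble(ann)[required]
}

#' Count diploid genotypes per sample set from a VCF
#'
#' Optional genotype-mode input (frequency tables are the canonical format).
#' Only biallelic records with GT fields are consumed; multiallelic records are
#' skipped with a warning; samples with missing calls (`./.`) are dropped from
#' that variant's counts.
#'
#' @param path Path to a VCF (v4.x, plain text or gzipped).
#' @param sample_to_set Named character vector mapping VCF sample names to
#'   sample-set ids. Every VCF sample must be mapped.
#' @return Tibble with columns `sample_set_id`, `rsid`, `hom_ref`, `het`,
#'   `hom_alt` (one row per set x variant).
#' @export
read_genotypes_vcf <- function(path, sample_to_set) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  unmapped <- setdiff(samples, names(sample_to_set))
  if (length(unmapped) > 0) {
    abort(paste0("VCF sample name(s) not in sample_to_set: ",
                 paste(unmapped, collapse = ", ")))
  }
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipping %d multiallelic record(s): %s", sum(multi),
                 paste(head(fix$ID[multi], 5), collapse = ", ")))
  }
  keep <- which(!multi)
  if (length(keep) == 0) {
    return(tibble::tibble(sample_set_id = character(), rsid = character(),
                          hom_ref = integer(), het = integer(), hom_alt = integer()))
  }
  set_of <- unname(sample_to_set[samples])
  purrr::map_dfr(keep, function(i) {
    calls <- gt[i, ]
    alt_dose <- vapply(calls, function(g) {
      if (is.na(g)) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(alleles != "0")
    }, integer(1))
    ok <- !is.na(alt_dose)
    tibble::tibble(sample_set_id = set_of[ok], dose = alt_dose[ok]) |>
      dplyr::group_by(.data$sample_set_id) |>
      dplyr::summarise(hom_ref = sum(.data$dose == 0L),
                       het = sum(.data$dose == 1L),
                       hom_alt = sum(.data$dose == 2L), .groups = "drop") |>
      dplyr::mutate(rsid = fix$ID[i], .before = "hom_ref")
  })
}

#' Read a gridded daily UVB raster from long-format CSV
#'
#' Half-degree cells addressed by their centres (offsets of 0.25 from the
#' half-degree lines), one row per cell per day of noontime 305 nm surface
#' irradiance in mW/m^2/nm.
#'
#' @param path CSV with columns `lat_cell, lon_cell, date, irradiance`.
#' @return Tibble sorted by cell then date; irradiance validated `>= 0`, cell
#'   centres validated to the regular half-degree grid, duplicate (cell, date)
#'   rows rejected.
#' @export
read_uvb_raster <- function(path) {
  raster <- readr::read_csv(path, col_types = readr::cols(
    lat_cell = readr::col_double(), lon_cell = readr::col_double(),
    date = readr::col_date(), irradiance = readr::col_double()
  ), progress = FALSE)
  validate_uvb_raster(tibble::as_tibble(raster))
}

#' @noRd
on_half_degree_centres <- function(x) {
  abs((x - 0.25) %% 0.5) < 1e-9 | abs((x - 0.25) %% 0.5 - 0.5) < 1e-9
}

#' @noRd
validate_uvb_raster <- function(raster) {
  required <- c("lat_cell", "lon_cell", "date", "irradiance")
  missing_cols <- setdiff(required, names(raster))
  if (length(missing_cols) > 0) {
    abort(paste0("raster lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  off <- which(!on_half_degree_centres(raster$lat_cell) |
                 !on_half_degree_centres(raster$lon_cell))
  if (length(off) > 0) {
    abort(sprintf("off-grid cell centre at row %d: (%g, %g)",
                  off[1], raster$lat_cell[off[1]], raster$lon_cell[off[1]]))
  }
  if (any(is.na(raster$irradiance) | raster$irradiance < 0)) {
    abort("irradiance must be present and >= 0")
  }
  key <- paste(raster$lat_cell, raster$lon_cell, raster$date)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (cell, date) entry for cell (%g, %g) on %s",
                  raster$lat_cell[dup[1]], raster$lon_cell[dup[1]],
                  raster$date[dup[1]]))
  }
  dplyr::arrange(raster, .data$lat_cell, .data$lon_cell, .data$date)
}

## Column layout of the final report, fixed so written reports are stable.
REPORT_COLUMNS <- c(
  "rsid", "locus", "n_sets", "n_subjects",
  "mean_EUR", "ci_EUR_lo", "ci_EUR_hi",
  "mean_EAS", "ci_EAS_lo", "ci_EAS_hi",
  "mean_AFR", "ci_AFR_lo", "ci_AFR_hi",
  "p_assoc", "adj_r2",
  "p_EUR_EAS", "p_EUR_AFR", "p_EAS_AFR",
  "letters_EUR", "letters_EAS", "letters_AFR",
  "pattern", "uvb_cline")

#' Write the per-variant comparison report
#'
#' One row per variant with weighted group means and 95% CIs (2 decimals, the
#' precision of the source tables), association p and adjusted r^2, Tukey
#' pairwise p values (3 significant digits, scientific), compact letters,
#' distribution-pattern label and UVB-cline label.
#'
#' @param results Tibble of per-variant results as produced by
#'   [compare_variants()] / [build_results()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path) {
  if (nrow(results) == 0) abort("empty results: nothing to report")
  missing_cols <- setdiff(REPORT_COLUMNS, names(results))
  if (length(missing_cols) > 0) {
    abort(paste0("results lack report column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- results[REPORT_COLUMNS]
  fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
  fmtp <- function(x) ifelse(is.na(x), NA_character_,
                             sprintf("%.2e", signif(x, 3)))
  out <- dplyr::mutate(
    out,
    dplyr::across(dplyr::starts_with(c("mean_", "ci_")) | dplyr::all_of("adj_r2"), fmt2),
    dplyr::across(dplyr::starts_with("p_"), fmtp),
    pattern = ifelse(.data$pattern %in% PATTERN_LEVELS,
                     pattern_display(.data$pattern), .data$pattern))
  tsv_write(out, path)
}

#' Read back a written report
#'
#' Inverse of [write_report()] at the rendered precision.
#'
#' @param path Report TSV path.
#' @return Tibble with numeric means/CIs/p values and character letters/labels.
#' @export
read_report <- function(path) {
  rep <- tsv_read(path)
  num <- intersect(names(rep), REPORT_COLUMNS[grepl("^(mean_|ci_|p_|adj_r2|n_)",
                                                    REPORT_COLUMNS)])
  dplyr::mutate(rep, dplyr::across(dplyr::all_of(num), as.numeric))
}
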