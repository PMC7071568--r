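#' Simulation configuration
#'
#' Bundles everything the synthetic-data generator needs. The defaults
#' reproduce the study design the package is built around: the 60-set roster
#' ([table6_sample_sets()], 18 EUR / 24 EAS / 18 AFR cohorts with published
#' cohort sizes and latitude bands), generative group mean frequencies taken
#' from the published production/transport-locus means plus the three
#' pigmentation markers, a Balding-Nichols drift parameter `theta = 0.02`, and
#' a latitude-graded UVB raster whose parameters give group mean annual
#' irradiance near the observed 82 / 48 / 18 mW/m^2/nm (AFR / EAS / EUR).
#'
#' @param sets Sample-set roster tibble, or `NULL` to draw a roster from
#'   `design`.
#' @param design When `sets` is `NULL`: tibble with columns `group`, `n_sets`,
#'   `n_lo`, `n_hi` (cohort-size range), `lat_lo`, `lat_hi` (latitude band),
#'   `lon_lo`, `lon_hi`.
#' @param group_means Wide tibble of generative truth: `rsid`, optional
#'   `locus`, and one `mean_<group>` column per group in the roster.
#' @param theta Balding-Nichols drift parameter in \[0, 1): between-set
#'   dispersion of latent frequencies within a group. `theta -> 0` collapses
#'   every set onto its group mean.
#' @param observation `"latent"` (observed frequency is the latent
#'   Balding-Nichols draw; default, keeps analytic checks exact) or
#'   `"binomial"` (adds sampling noise: a draw of 2n alleles divided by 2n).
#' @param uvb_base Clear-day noontime 305 nm irradiance at the equator
#'   (mW/m^2/nm).
#' @param uvb_decay Linear decrease in irradiance per degree of absolute
#'   latitude.
#' @param uvb_sd Day-to-day Gaussian noise standard deviation.
#' @param uvb_days Number of simulated days (default one year).
#' @return A list of class `uvb_sim_config`.
#' @export
simulation_config <- function(sets = table6_sample_sets(),
                              design = NULL,
                              group_means = default_group_means(),
                              theta = 0.02,
                              observation = c("latent", "binomial"),
                              uvb_base = 92, uvb_decay = 1.4,
                              uvb_sd = 2, uvb_days = 365L) {
  observation <- match.arg(observation)
  if (is.null(sets) && is.null(design)) abort("supply `sets` or `design`")
  if (!is.null(sets)) sets <- validate_sample_sets(sets)
  if (theta < 0 || theta >= 1) abort("theta must be in [0, 1)")
  mean_cols <- grep("^mean_", names(group_means), value = TRUE)
  if (!"rsid" %in% names(group_means) || length(mean_cols) == 0) {
    abort("group_means needs an rsid column and mean_<group> columns")
  }
  vals <- unlist(group_means[mean_cols])
  if (any(is.na(vals) | vals < 0 | vals > 1)) abort("group means must be in [0, 1]")
  if (uvb_base < 0 || uvb_decay < 0 || uvb_sd < 0 || uvb_days < 1) {
    abort("uvb parameters must be non-negative, uvb_days >= 1")
  }
  structure(list(sets = sets, design = design, group_means = group_means,
                 theta = theta, observation = observation,
                 uvb_base = uvb_base, uvb_decay = uvb_decay,
                 uvb_sd = uvb_sd, uvb_days = as.integer(uvb_days)),
            class = "uvb_sim_config")
}

#' Default generative group means
#'
#' The published cohort-weighted group means of the sixteen
#' production/transport-locus variants plus the three ancestry-validation
#' pigmentation markers.
#'
#' @return Wide tibble `rsid`, `locus`, `mean_EUR`, `mean_EAS`, `mean_AFR`.
#' @export
default_group_means <- function() {
  pig <- pigmentation_marker_means()
  pig$locus <- c("SLC24A5", "SLC45A2", "OCA2")
  dplyr::bind_rows(
    pig[c("rsid", "locus", "mean_EUR", "mean_EAS", "mean_AFR")],
    table2_frequency_patterns()[c("rsid", "locus", "mean_EUR", "mean_EAS", "mean_AFR")]
  )
}

#' Draw a sample-set roster from a group design
#'
#' @param design See [simulation_config()].
#' @param seed Integer seed.
#' @return A validated sample-set tibble with `SYNTHETIC` source.
#' @export
simulate_roster <- function(design, seed = 1L) {
  withr_seed(seed, {
    rows <- purrr::pmap_dfr(design, function(group, n_sets, n_lo, n_hi,
                                             lat_lo, lat_hi, lon_lo, lon_hi) {
      lat <- runif(n_sets, lat_lo, lat_hi)
      tibble::tibble(
        id = sprintf("%s%02d", group, seq_len(n_sets)),
        name = sprintf("Synthetic %s cohort %d", group, seq_len(n_sets)),
        group = group,
        n = as.integer(round(runif(n_sets, n_lo, n_hi))),
        lat_min = lat, lat_max = lat,
        lon = runif(n_sets, lon_lo, lon_hi),
        source = "SYNTHETIC")
    })
    validate_sample_sets(rows)
  })
}

## Local seed scope so simulation never disturbs the caller's RNG state.
#' @noRd
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Balding-Nichols latent frequency draws
#'
#' Each subpopulation's allele frequency around ancestral mean `p` is
#' `Beta(p (1 - theta) / theta, (1 - p)(1 - theta) / theta)`, so that the
#' expected differentiation (Wright FST) across subpopulations equals `theta`.
#' Degenerate cases: `theta` below 1e-9 or `p` at 0 or 1 return `p` exactly.
#'
#' @param n Number of draws.
#' @param p Ancestral (group mean) frequency in \[0, 1\].
#' @param theta Drift parameter in \[0, 1).
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
rbalding_nichols <- function(n, p, theta) {
  if (p < 0 || p > 1) abort("p must be in [0, 1]")
  if (theta < 0 || theta >= 1) abort("theta must be in [0, 1)")
  if (theta < 1e-9 || p <= 0 || p >= 1) return(rep(p, n))
  scale <- (1 - theta) / theta
  rbeta(n, p * scale, (1 - p) * scale)
}

#' Simulate a sample-set collection with frequencies and annotations
#'
#' For every sample set and variant, draws a latent frequency from the
#' Balding-Nichols model around the set's group mean, optionally adds binomial
#' sampling noise (2n allele draws), and assembles the three tables the
#' analysis pipeline consumes.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with elements `sample_sets` (roster tibble), `frequencies`
#'   (long tibble `sample_set_id`, `rsid`, `freq`) and `annotations`
#'   (variant-annotation tibble; `fst` is the realised cohort-weighted Wright
#'   fixation index across all simulated sets).
#' @export
simulate_sample_sets <- function(config, seed = 1L) {
  stopifnot(inherits(config, "uvb_sim_config"))
  sets <- config$sets %||% simulate_roster(config$design, seed = seed)
  gm <- config$group_means
  groups <- unique(sets$group)
  needed <- paste0("mean_", groups)
  missing_cols <- setdiff(needed, names(gm))
  if (length(missing_cols) > 0) {
    abort(paste0("group_means lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }

  freqs <- withr_seed(seed + 1L, {
    purrr::map_dfr(seq_len(nrow(gm)), function(v) {
      latent <- vapply(seq_len(nrow(sets)), function(i) {
        p <- gm[[paste0("mean_", sets$group[i])]][v]
        rbalding_nichols(1L, p, config$theta)
      }, numeric(1))
      freq <- if (config$observation == "binomial") {
        rbinom(nrow(sets), 2L * sets$n, latent) / (2 * sets$n)
      } else latent
      tibble::tibble(sample_set_id = sets$id, rsid = gm$rsid[v], freq = freq)
    })
  })

  ann <- purrr::map_dfr(seq_len(nrow(gm)), function(v) {
    f <- freqs$freq[freqs$rsid == gm$rsid[v]]
    pooled <- weighted.mean(f, sets$n)
    tibble::tibble(
      rsid = gm$rsid[v],
      locus = if ("locus" %in% names(gm)) gm$locus[v] else "SYN",
      variant_allele = "A",
      maf = min(pooled, 1 - pooled),
      fst = wright_fst(f, sets$n),
      function_class = "Intron")
  })

  list(sample_sets = sets,
       frequencies = validate_frequencies(freqs),
       annotations = validate_variant_annotations(ann))
}

#' Simulate a latitude-graded daily UVB raster
#'
#' Generates daily noontime 305 nm irradiance for every half-degree cell a
#' roster's locations touch: the deterministic surface is
#' `max(0, base - decay * |latitude|)` with i.i.d. Gaussian day-to-day noise,
#' truncated at zero. The monotone decay away from the equator reproduces the
#' observed group ordering of mean annual UVB (AFR > EAS > EUR).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param sets Roster to cover (defaults to the config's roster); sets without
#'   coordinates are skipped.
#' @return A validated raster tibble (`lat_cell`, `lon_cell`, `date`,
#'   `irradiance`).
#' @export
simulate_uvb_raster <- function(config, seed = 1L, sets = NULL) {
  stopifnot(inherits(config, "uvb_sim_config"))
  sets <- sets %||% config$sets %||% simulate_roster(config$design, seed = seed)
  located <- sets[!is.na(sets$lat_min), ]
  cells <- dplyr::distinct(
    purrr::map_dfr(seq_len(nrow(located)), function(i) {
      location_cells(located$lat_min[i], located$lat_max[i], located$lon[i])
    }))
  dates <- as.Date("1980-01-01") + seq_len(config$uvb_days) - 1L
  grid <- tidyr::expand_grid(cells, date = dates)
  withr_seed(seed + 2L, {
    clear <- pmax(0, config$uvb_base - config$uvb_decay * abs(grid$lat_cell))
    noise <- if (config$uvb_sd > 0) rnorm(nrow(grid), 0, config$uvb_sd) else 0
    grid$irradiance <- pmax(0, clear + noise)
    validate_uvb_raster(grid)
  })
}

#' Write a simulated collection to disk
#'
#' Materialises the four pipeline input files (sample sets, frequency matrix,
#' annotations, raster CSV) for a configuration and seed.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(config, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_sample_sets(config, seed = seed)
  raster <- simulate_uvb_raster(config, seed = seed, sets = sim$sample_sets)
  paths <- c(
    sample_sets = file.path(out_dir, "sample_sets.tsv"),
    frequencies = file.path(out_dir, "frequencies.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    raster = file.path(out_dir, "uvb_raster.csv"))
  tsv_write(sim$sample_sets, paths[["sample_sets"]])
  write_frequency_matrix(sim$frequencies, paths[["frequencies"]])
  tsv_write(sim$annotations, paths[["annotations"]])
  readr::write_csv(raster, paths[["raster"]], progress = FALSE)
  invisible(paths)
}
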