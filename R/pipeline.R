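#' Pipeline configuration
#'
#' @param sample_sets,frequencies,annotations,uvb_raster Input file paths
#'   (TSVs and the long-format raster CSV), or in-memory tibbles of the same
#'   shapes.
#' @param out_dir Directory for the report and manifest.
#' @param selection List of [select_variants()] arguments
#'   (`top_fraction`, `fst_floor`, `exclude_function_classes`).
#' @param rules Ancestry-validation rules ([default_ancestry_rules()]).
#' @param thresholds [significance_thresholds()].
#' @param range_mode UVB cell handling for latitude-range locations.
#' @param uvb_order `"derived"` (from the raster comparison) or an explicit
#'   group vector in ascending-UVB order.
#' @param abort_on_validation_failure Abort the run when ancestry validation
#'   fails (default); set `FALSE` to continue with a warning.
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `uvb_pipeline_config`.
#' @export
pipeline_config <- function(sample_sets, frequencies, annotations = NULL,
                            uvb_raster = NULL, out_dir = tempdir(),
                            selection = list(top_fraction = 0.30,
                                             fst_floor = 0.13,
                                             exclude_function_classes = "Unknown"),
                            rules = default_ancestry_rules(),
                            thresholds = significance_thresholds(),
                            range_mode = c("all", "midpoint"),
                            uvb_order = "derived",
                            abort_on_validation_failure = TRUE,
                            seed = 1L) {
  structure(list(sample_sets = sample_sets, frequencies = frequencies,
                 annotations = annotations, uvb_raster = uvb_raster,
                 out_dir = out_dir, selection = selection, rules = rules,
                 thresholds = thresholds, range_mode = match.arg(range_mode),
                 uvb_order = uvb_order,
                 abort_on_validation_failure = abort_on_validation_failure,
                 seed = as.integer(seed)),
            class = "uvb_pipeline_config")
}

#' @noRd
load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Stage order: validate ancestry groups with the pigmentation markers,
#' exclude sets lacking marker data, apply the differentiation filter to the
#' annotations, compute the per-variant weighted comparisons, summarise UVB
#' per set and group (when a raster is supplied), classify patterns and
#' clines, and write the report plus a run manifest (input checksums, seed,
#' thresholds, stage counts).
#'
#' @param config A [pipeline_config()].
#' @return List of class `uvb_pipeline_result`: `report` (per-variant tibble),
#'   `validation`, `selection`, `uvb` (or `NULL`), `manifest`, and the output
#'   file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "uvb_pipeline_config"))
  sets <- load_input(config$sample_sets, read_sample_sets)
  freq <- load_input(config$frequencies, read_frequency_matrix)
  ann <- if (!is.null(config$annotations)) {
    load_input(config$annotations, read_variant_annotations)
  }
  raster <- if (!is.null(config$uvb_raster)) {
    load_input(config$uvb_raster, read_uvb_raster)
  }
  log_stage <- function(stage, msg) inform(sprintf("[%s] %s", stage, msg))
  rules <- config$rules
  if (is.null(rules)) rules <- default_ancestry_rules()[0, ]

  # 1. ancestry validation ---------------------------------------------------
  has_rules <- nrow(rules) > 0 && all(unique(rules$rsid) %in% freq$rsid)
  if (nrow(rules) > 0 && !has_rules) {
    warn("validation markers absent from frequency table; skipping validation")
  }
  validation <- NULL
  if (has_rules) {
    validation <- validate_ancestry(freq, sets, rules)
    log_stage("validate", sprintf("%d rules, pass = %s, %d set(s) excluded",
                                  nrow(validation$report), validation$pass,
                                  length(validation$exclude_sets)))
    if (!validation$pass) {
      if (config$abort_on_validation_failure) {
        abort("ancestry validation failed; see $report (or set abort_on_validation_failure = FALSE)")
      }
      warn("ancestry validation failed; continuing as configured")
    }
    sets <- sets[!sets$id %in% validation$exclude_sets, ]
    freq <- freq[freq$sample_set_id %in% sets$id, ]
  }

  # 2. variant selection -----------------------------------------------------
  selection <- NULL
  analysis_rsids <- setdiff(unique(freq$rsid), unique(rules$rsid))
  if (!is.null(ann)) {
    if (any(is.na(ann$fst))) {
      computed <- fst_by_variant(freq, sets)
      i <- is.na(ann$fst)
      ann$fst[i] <- computed$fst[match(ann$rsid[i], computed$rsid)]
    }
    selection <- do.call(select_variants, c(list(ann), config$selection))
    analysis_rsids <- intersect(analysis_rsids,
                                selection$rsid[selection$included])
    log_stage("select", sprintf("%d of %d variants retained",
                                sum(selection$included), nrow(selection)))
  }

  # 3. UVB -------------------------------------------------------------------
  uvb <- NULL
  uvb_order <- config$uvb_order
  if (!is.null(raster)) {
    per_set <- uvb_by_sample_set(sets, raster, range_mode = config$range_mode)
    uvb <- compare_group_uvb(per_set)
    uvb$per_set <- per_set
    if (identical(uvb_order, "derived")) uvb_order <- uvb$uvb_order
    log_stage("uvb", sprintf("groups by ascending UVB: %s",
                             paste(uvb_order, collapse = " < ")))
  } else if (identical(uvb_order, "derived")) {
    uvb_order <- ANALYSIS_GROUPS
  }

  # 4. per-variant comparison + classification --------------------------------
  report <- compare_variants(freq[freq$rsid %in% analysis_rsids, ], sets,
                             annotations = ann, thresholds = config$thresholds,
                             uvb_order = uvb_order)
  log_stage("compare", sprintf("%d variants, %d sample sets", nrow(report),
                               length(unique(freq$sample_set_id))))

  # 5. outputs ---------------------------------------------------------------
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(config$out_dir, "report.tsv")
  write_report(report, report_path)
  manifest <- list(
    seed = config$seed,
    thresholds = config$thresholds,
    selection = config$selection,
    range_mode = config$range_mode,
    uvb_order = uvb_order,
    uvb_period = "1978-1993",
    n_sample_sets = nrow(sets),
    n_groups = length(unique(sets$group)),
    n_subjects = sum(sets$n),
    n_variants_analysed = nrow(report),
    excluded_sets = if (is.null(validation)) character(0) else validation$exclude_sets,
    input_checksums = input_checksums(config))
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  tsv_write(tibble::tibble(
    key = names(unlist(manifest)),
    value = as.character(unlist(manifest))), manifest_path)
  log_stage("report", sprintf("wrote %s", report_path))

  structure(list(report = report, validation = validation,
                 selection = selection, uvb = uvb, manifest = manifest,
                 paths = c(report = report_path, manifest = manifest_path)),
            class = "uvb_pipeline_result")
}

#' @noRd
input_checksums <- function(config) {
  paths <- purrr::keep(config[c("sample_sets", "frequencies", "annotations",
                                "uvb_raster")],
                       ~ is.character(.x) && length(.x) == 1)
  if (length(paths) == 0) return(list(inputs = "in-memory"))
  lapply(paths, function(p) {
    as.character(tools::md5sum(p))
  })
}

#' @export
print.uvb_pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d variants x %d sample sets (%d subjects)\n",
              x$manifest$n_variants_analysed, x$manifest$n_sample_sets,
              x$manifest$n_subjects))
  print(dplyr::count(x$report, .data$pattern))
  invisible(x)
}
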