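# Configuration and end-to-end orchestration: a single plain-text (YAML)
# config with per-module blocks drives the design pipeline (pre-clustering
# -> probe design -> cross-hybridization screen) and the analysis pipeline
# (QC -> normalization -> differential expression -> power report).
# Stages write their outputs plus a manifest carrying the config hash and
# seed; completed stages are skipped on re-runs unless forced.

default_config <- function() {
  list(
    seed = 1,
    paths = list(input_fasta = NULL, slide_table = NULL, layout = NULL,
                 output_dir = "oligoarray_out"),
    precluster = list(min_identity = 90, min_length = 30, mask_window = 16,
                      mask_entropy = 1.2),
    design = list(tm_target = 67, tm_tol = 3, length_target = 65,
                  length_tol = 5, gc_target = 43, gc_tol = 5,
                  max_dist_3prime = 1000, max_stem = 8, max_selfdimer = 12,
                  na_mM = 50, oligo_nM = 50),
    screen = list(id_threshold = 70, lcs_threshold = 20),
    qc = list(filter_percentile = 0.90, filter_sd_multiplier = 2),
    normalize = list(span = 0.4),
    de = list(n_permutations = 200, alpha = 0.01),
    power = list(alpha = 0.10, target_power = 0.90,
                 fold = base::c(1.5, 2), model = "lognormal")
  )
}

#' Build or load a pipeline configuration
#'
#' Starts from the package defaults and merges overrides (a nested list or a
#' YAML file with the same structure). Unknown keys are rejected; a fully
#' defaulted configuration is valid. Configurations round-trip through
#' [write_config()]/`pipeline_config(path)`.
#'
#' @param overrides Nested list of settings, or a path to a YAML file.
#' @return A list of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- yaml::read_yaml(overrides)
  }
  base <- default_config()
  check_keys <- function(ov, ref, path = "") {
    unknown <- setdiff(names(ov), names(ref))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config key(s)%s: %s",
                    if (nzchar(path)) paste0(" in ", path) else "",
                    paste(unknown, collapse = ", ")))
    }
    for (k in names(ov)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        check_keys(ov[[k]], ref[[k]], paste0(path, k, "."))
      }
    }
  }
  check_keys(overrides, base)
  cfg <- modifyList(base, overrides)
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) attr(config, "hash") %||% rlang::hash(config)

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s (%s)", stage, msg,
                  format(Sys.time(), "%H:%M:%OS1")))
}

write_manifest <- function(dir, config, stages) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stages = stages
  )
  path <- file.path(dir, "manifest.json")
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

stage_header <- function(stage, config) {
  sprintf("# stage: %s\n# config_hash: %s\n# seed: %s",
          stage, config_hash(config), config$seed)
}

write_stage_tsv <- function(tbl, path, stage, config) {
  writeLines(stage_header(stage, config), path)
  suppressWarnings(
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  )
  invisible(path)
}

read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Run the probe design pipeline
#'
#' Chains sequence cleaning/pre-clustering, per-unigene probe design and the
#' cross-hybridization screen over a unigene FASTA. Each cluster is
#' represented by its longest member for design (assembly proper is outside
#' this toolkit's scope). Stage outputs are TSVs under
#' `config$paths$output_dir` with a manifest; existing stage outputs are
#' reused unless `force = TRUE`.
#'
#' An empty input FASTA yields empty reports and a warning, not an error; a
#' missing input path is an error raised before any work.
#'
#' @param config A [pipeline_config()]; `paths$input_fasta` must be set.
#' @param force Recompute stages whose outputs already exist.
#' @return Invisibly, a list with `clusters`, `design`, `crosshyb` tibbles
#'   and the output directory.
#' @export
run_design_pipeline <- function(config = pipeline_config(), force = FALSE) {
  fasta <- config$paths$input_fasta
  if (is.null(fasta) || !file.exists(fasta)) {
    abort("`paths$input_fasta` is missing or does not exist")
  }
  dir <- config$paths$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  unigenes <- read_unigene_fasta(fasta)
  if (nrow(unigenes) == 0) {
    warn("input FASTA contains no sequences; writing empty reports")
  }

  cluster_path <- file.path(dir, "clusters.tsv")
  if (file.exists(cluster_path) && !force) {
    stage_log("precluster", "reusing existing output")
    clusters <- read_stage_tsv(cluster_path)
  } else {
    stage_log("precluster", sprintf("%d sequences", nrow(unigenes)))
    masked <- tryCatch(
      mask_low_complexity(unigenes, window = config$precluster$mask_window,
                          entropy_threshold = config$precluster$mask_entropy),
      error = function(e) abort(sprintf("stage precluster failed: %s",
                                        conditionMessage(e)))
    )
    clusters <- precluster(masked,
                           min_identity = config$precluster$min_identity,
                           min_length = config$precluster$min_length)
    write_stage_tsv(clusters, cluster_path, "precluster", config)
  }

  design_path <- file.path(dir, "design_report.tsv")
  if (file.exists(design_path) && !force) {
    stage_log("design", "reusing existing output")
    design <- read_stage_tsv(design_path)
  } else {
    reps <- unigenes |>
      dplyr::left_join(clusters, by = base::c(id = "member_id")) |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::arrange(dplyr::desc(.data$length), .data$id,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    stage_log("design", sprintf("%d cluster representatives", nrow(reps)))
    constraints <- do.call(probe_constraints, config$design)
    design <- tryCatch(
      design_probes(reps[base::c("id", "sequence")], constraints),
      error = function(e) abort(sprintf("stage design failed: %s",
                                        conditionMessage(e)))
    )
    write_stage_tsv(design, design_path, "design", config)
    missing <- design[design$outcome == "missing",
                      base::c("unigene_id", "missing_reason")]
    write_stage_tsv(missing, file.path(dir, "missing_genes.tsv"),
                    "design", config)
  }

  screen_path <- file.path(dir, "crosshyb.tsv")
  if (file.exists(screen_path) && !force) {
    stage_log("screen", "reusing existing output")
    crosshyb <- read_stage_tsv(screen_path)
  } else {
    designed <- design[design$outcome == "designed", , drop = FALSE]
    if (nrow(designed) == 0) {
      crosshyb <- tibble::tibble(
        probe_id = character(), unigene_id = character(),
        target_unigene_id = character(), overall_identity = double(),
        lcs_length = integer(), flagged = logical()
      )
    } else {
      stage_log("screen", sprintf("%d probes", nrow(designed)))
      scr <- tryCatch(
        screen_crosshyb(designed, unigenes,
                        id_threshold = config$screen$id_threshold,
                        lcs_threshold = config$screen$lcs_threshold),
        error = function(e) abort(sprintf("stage screen failed: %s",
                                          conditionMessage(e)))
      )
      crosshyb <- scr$report
    }
    write_stage_tsv(crosshyb, screen_path, "screen", config)
  }

  write_manifest(dir, config,
                 list(precluster = "clusters.tsv",
                      design = "design_report.tsv",
                      screen = "crosshyb.tsv"))
  invisible(list(clusters = clusters, design = design, crosshyb = crosshyb,
                 output_dir = dir))
}

#' Run the expression analysis pipeline
#'
#' Chains spot QC and filtering, loess normalization, per-gene linear and
#' SAM permutation tests with their consensus, and the CV/power report for
#' one dye-swap contrast.
#'
#' @param config A [pipeline_config()]; `paths$slide_table` and
#'   `paths$layout` must point to a spot table TSV and a layout TSV
#'   (`slide_id`, `dye_orientation`).
#' @param force Recompute stages whose outputs already exist.
#' @return Invisibly, a list with `thresholds`, `normalized`, `linear_fit`,
#'   `sam_fit`, `consensus`, `cv`, `power` and the output directory.
#' @export
run_analysis_pipeline <- function(config = pipeline_config(), force = FALSE) {
  if (is.null(config$paths$slide_table) ||
      !file.exists(config$paths$slide_table)) {
    abort("`paths$slide_table` is missing or does not exist")
  }
  if (is.null(config$paths$layout) || !file.exists(config$paths$layout)) {
    abort("`paths$layout` is missing or does not exist")
  }
  dir <- config$paths$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spots <- read_spot_table(config$paths$slide_table)
  layout <- readr::read_tsv(config$paths$layout, show_col_types = FALSE,
                            progress = FALSE)
  bad <- setdiff(unique(spots$Slide), layout$slide_id)
  if (length(bad) > 0) {
    abort(sprintf("slide(s) missing from layout: %s",
                  paste(bad, collapse = ", ")))
  }

  stage_log("qc", sprintf("%d spots on %d slides", nrow(spots),
                          dplyr::n_distinct(spots$Slide)))
  thresholds <- expression_threshold(spots)
  write_stage_tsv(thresholds, file.path(dir, "qc_thresholds.tsv"),
                  "qc", config)
  kept <- filter_spots(spots,
                       percentile = config$qc$filter_percentile,
                       sd_multiplier = config$qc$filter_sd_multiplier)

  norm_path <- file.path(dir, "normalized.tsv")
  if (file.exists(norm_path) && !force) {
    stage_log("normalize", "reusing existing output")
    normalized <- read_stage_tsv(norm_path)
  } else {
    stage_log("normalize", sprintf("%d retained spots", nrow(kept)))
    normalized <- normalize_slides(kept, span = config$normalize$span)
    write_stage_tsv(normalized, norm_path, "normalize", config)
  }

  mat <- build_expression_matrix(normalized, layout)
  stage_log("de", sprintf("%d genes", dplyr::n_distinct(mat$feature_id)))
  fit <- per_gene_linear_fit(mat)
  sam <- sam_test(mat, n_permutations = config$de$n_permutations,
                  seed = config$seed)
  alpha <- config$de$alpha
  linear_list <- de_gene_list(
    fit$feature_id[!is.na(fit$p_adj) & fit$p_adj <= alpha],
    comparison = "contrast", method = "linear_model", threshold = alpha
  )
  sam_list <- de_gene_list(
    sam$table$feature_id[sam$table$fdr <= alpha],
    comparison = "contrast", method = "permutation", threshold = alpha
  )
  consensus <- consensus_lists(linear_list, sam_list)
  de_out <- fit |>
    tibble::as_tibble() |>
    dplyr::left_join(sam$table[base::c("feature_id", "d", "fdr")],
                     by = "feature_id")
  write_stage_tsv(de_out, file.path(dir, "de_results.tsv"), "de", config)
  write_stage_tsv(consensus, file.path(dir, "de_consensus.tsv"), "de",
                  config)

  stage_log("power", "replicate CV and power report")
  raw_intensity <- spots |>
    dplyr::filter(.data$ControlClass == "probe", .data$Flag == "ok") |>
    dplyr::mutate(intensity = (.data$F_red + .data$F_green) / 2) |>
    dplyr::select(feature_id = "ID", slide_id = "Slide", "intensity")
  cv <- cv_report(raw_intensity)
  write_stage_tsv(tibble::as_tibble(cv), file.path(dir, "cv_report.tsv"),
                  "power", config)
  pw <- power_grid(
    n_per_group = dplyr::n_distinct(spots$Slide),
    cv = base::c(20, 35, round(cv_p90(cv$cv), 1)),
    fold = config$power$fold, alpha = config$power$alpha,
    model = config$power$model
  )
  write_stage_tsv(tibble::as_tibble(pw), file.path(dir, "power_report.tsv"),
                  "power", config)

  write_manifest(dir, config,
                 list(qc = "qc_thresholds.tsv", normalize = "normalized.tsv",
                      de = "de_results.tsv", power = "power_report.tsv"))
  invisible(list(thresholds = thresholds, normalized = normalized,
                 linear_fit = fit, sam_fit = sam, consensus = consensus,
                 cv = cv, power = pw, output_dir = dir))
}
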