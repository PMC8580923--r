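#' Pipeline configuration
#'
#' Configures one end-to-end run: either a stats-only pass over an existing
#' CSV of per-region RMS records, a full synthetic run driven by a
#' [phantom_spec()], or a run on user-supplied mesh/fiducial/region files.
#' Exactly one of `records_csv`, `phantom`, or `inputs` must be given.
#'
#' @param records_csv path to an RMS-record CSV (stats-only mode).
#' @param phantom a [phantom_spec()] (synthetic mode), or `TRUE` for the
#'   default spec.
#' @param inputs list of file paths for real data: `sls`, `us_medial`,
#'   `us_lateral`, `ct` (meshes), `us_fiducials`, `ct_fiducials`,
#'   `sls_landmarks`, `ct_landmarks` (fiducial files), `regions` (JSON,
#'   defined on the SLS model).
#' @param params a [modality_params()] (synthetic mode).
#' @param icp an [icp_params()].
#' @param samples_per_mm2 region sampling density.
#' @param alpha significance level.
#' @param seed master seed; every random stage derives from it.
#' @param out_dir output directory; `NULL` skips writing files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(records_csv = NULL, phantom = NULL, inputs = NULL,
                            params = modality_params(), icp = icp_params(),
                            samples_per_mm2 = 25, alpha = 0.05, seed = 1L,
                            out_dir = NULL) {
  modes <- c(!is.null(records_csv), !is.null(phantom), !is.null(inputs))
  if (sum(modes) != 1L) {
    abort("Give exactly one of `records_csv`, `phantom` or `inputs`.")
  }
  if (isTRUE(phantom)) phantom <- phantom_spec()
  structure(list(
    records_csv = records_csv, phantom = phantom, inputs = inputs,
    params = params, icp = icp, samples_per_mm2 = samples_per_mm2,
    alpha = alpha, seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `phantom: default`
#' requests the default phantom spec, while a mapping under `phantom`
#' overrides [phantom_spec()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- NULL
  if (!is.null(y$phantom)) {
    phantom <- if (identical(y$phantom, "default")) phantom_spec() else
      do.call(phantom_spec, y$phantom)
  }
  pipeline_config(
    records_csv = y$records_csv, phantom = phantom, inputs = y$inputs,
    params = do.call(modality_params, y$params %||% list()),
    icp = do.call(icp_params, y$icp %||% list()),
    samples_per_mm2 = y$samples_per_mm2 %||% 25,
    alpha = y$alpha %||% 0.05, seed = y$seed %||% 1L, out_dir = y$out_dir
  )
}

#' Run the full analysis pipeline
#'
#' Executes the study flow end to end: (synthetic mode) phantom generation
#' and the three modality simulations; three-way registration into the CT
#' frame; per-region RMS scoring of both modality pairs against the
#' registered ground-truth model; topographic maps; summary tables and
#' Welch comparisons. In stats-only mode the geometric stages are skipped
#' and the record CSV feeds the same summary/test code path.
#'
#' When `out_dir` is set, writes `table2.csv` (registration stage RMS),
#' `table3.csv` (per-region RMS records), `table4.csv` (per-specimen-side
#' means/SDs and p values), `summary.csv`/`tests.json`, per-side topographic
#' map PLYs, and `manifest.json` recording the seed and all parameters.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `osteo_pipeline_result` with (as applicable)
#'   `registration` (stage report tibble), `records` (per-region RMS
#'   tibble), `comparison` ([compare_report()] output), `maps`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(
#'   records_csv = system.file("extdata", "osteophyte_rms.csv",
#'                             package = "osteorms")))
#' res$comparison$overall
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name, t_start) {
    message(sprintf("[osteorms] stage %-18s %7.2f s", name,
                    proc.time()[["elapsed"]] - t_start))
  }
  result <- list()
  manifest <- list(
    package = "osteorms",
    version = as.character(utils::packageVersion("osteorms")),
    seed = config$seed, alpha = config$alpha,
    samples_per_mm2 = config$samples_per_mm2,
    icp = unclass(config$icp)
  )

  if (!is.null(config$records_csv)) {
    ts <- proc.time()[["elapsed"]]
    records <- osteophyte_rms_example(config$records_csv)
    manifest$mode <- "stats_only"
    manifest$records_csv <- config$records_csv
    log_stage("load_records", ts)
  } else if (!is.null(config$phantom)) {
    manifest$mode <- "phantom"
    manifest$phantom <- lapply(
      unclass(config$phantom)[setdiff(names(unclass(config$phantom)), "osteophytes")],
      identity)
    manifest$modality_params <- unclass(config$params)

    ts <- proc.time()[["elapsed"]]
    phantom <- make_phantom(config$phantom)
    log_stage("make_phantom", ts)

    ts <- proc.time()[["elapsed"]]
    sls <- simulate_sls(phantom, config$params, pose_seed = config$seed)
    ct <- simulate_ct(phantom, config$params, pose_seed = config$seed + 1L)
    us <- simulate_us(phantom, config$params, pose_seed = config$seed + 2L)
    log_stage("simulate", ts)

    ts <- proc.time()[["elapsed"]]
    reg <- three_way_register(
      sls = sls$mesh, us_medial = us$medial_mesh, us_lateral = us$lateral_mesh,
      ct = ct$mesh, us_fiducials = us$fiducials, ct_fiducials = ct$fiducials,
      sls_landmarks = sls$landmarks, ct_landmarks = ct$landmarks,
      params = config$icp
    )
    result$registration <- reg$report
    log_stage("three_way_register", ts)

    ts <- proc.time()[["elapsed"]]
    regions <- regions_from_labels(
      reg$sls_in_ct, specimen = "phantom",
      grades = setNames(config$phantom$osteophytes$grade,
                        config$phantom$osteophytes$id),
      sides = setNames(config$phantom$osteophytes$side,
                       config$phantom$osteophytes$id)
    )
    ct_idx <- mesh_index(ct$mesh)
    us_idx <- mesh_index(reg$us_in_ct)
    records <- purrr::map_dfr(regions, function(rg) {
      dplyr::bind_rows(
        region_rms(rg, reg$sls_in_ct, ct_idx,
                   samples_per_mm2 = config$samples_per_mm2,
                   seed = config$seed, modality_pair = "CT-SLS"),
        region_rms(rg, reg$sls_in_ct, us_idx,
                   samples_per_mm2 = config$samples_per_mm2,
                   seed = config$seed, modality_pair = "3DUS-SLS")
      )
    })
    result$regions <- regions
    result$registered <- reg[c("sls_in_ct", "us_in_ct")]
    result$maps <- list(
      ct = topographic_map(reg$sls_in_ct, ct_idx),
      us = topographic_map(reg$sls_in_ct, us_idx)
    )
    log_stage("region_rms", ts)
  } else {
    manifest$mode <- "files"
    ts <- proc.time()[["elapsed"]]
    inp <- config$inputs
    sls_mesh <- load_mesh(inp$sls, frame = "sls")
    ct_mesh <- load_mesh(inp$ct, frame = "ct")
    us_m <- load_mesh(inp$us_medial, frame = "us")
    us_l <- load_mesh(inp$us_lateral, frame = "us")
    log_stage("load", ts)
    ts <- proc.time()[["elapsed"]]
    reg <- three_way_register(
      sls = sls_mesh, us_medial = us_m, us_lateral = us_l, ct = ct_mesh,
      us_fiducials = read_fiducials(inp$us_fiducials, frame = "us"),
      ct_fiducials = read_fiducials(inp$ct_fiducials, frame = "ct"),
      sls_landmarks = read_fiducials(inp$sls_landmarks, frame = "sls"),
      ct_landmarks = read_fiducials(inp$ct_landmarks, frame = "ct"),
      params = config$icp
    )
    result$registration <- reg$report
    log_stage("three_way_register", ts)
    ts <- proc.time()[["elapsed"]]
    regions <- read_regions(inp$regions, reference = reg$sls_in_ct)
    ct_idx <- mesh_index(ct_mesh)
    us_idx <- mesh_index(reg$us_in_ct)
    records <- purrr::map_dfr(regions, function(rg) {
      dplyr::bind_rows(
        region_rms(rg, reg$sls_in_ct, ct_idx,
                   samples_per_mm2 = config$samples_per_mm2,
                   seed = config$seed, modality_pair = "CT-SLS"),
        region_rms(rg, reg$sls_in_ct, us_idx,
                   samples_per_mm2 = config$samples_per_mm2,
                   seed = config$seed, modality_pair = "3DUS-SLS")
      )
    })
    result$regions <- regions
    result$registered <- reg[c("sls_in_ct", "us_in_ct")]
    log_stage("region_rms", ts)
  }

  ts <- proc.time()[["elapsed"]]
  comparison <- compare_report(records, alpha = config$alpha)
  result$records <- records
  result$comparison <- comparison
  log_stage("stats", ts)

  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  result$manifest <- manifest

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(result$registration)) {
      utils::write.csv(result$registration,
                       file.path(config$out_dir, "table2.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(records, file.path(config$out_dir, "table3.csv"),
                     row.names = FALSE)
    table4 <- comparison$summary |>
      dplyr::left_join(
        comparison$tests |>
          dplyr::filter(.data$specimen != "ALL") |>
          dplyr::select("specimen", "side", "p_value", "significant"),
        by = c("specimen", "side")
      )
    utils::write.csv(table4, file.path(config$out_dir, "table4.csv"),
                     row.names = FALSE)
    write_comparison(comparison, config$out_dir)
    if (!is.null(result$maps)) {
      write_distance_map(result$maps$ct,
                         file.path(config$out_dir, "map_ct_sls.ply"),
                         file.path(config$out_dir, "map_legend.png"))
      write_distance_map(result$maps$us,
                         file.path(config$out_dir, "map_us_sls.ply"))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(result, class = "osteo_pipeline_result")
}

#' @export
print.osteo_pipeline_result <- function(x, ...) {
  cat("<osteo_pipeline_result>\n")
  if (!is.null(x$registration)) {
    cat("\nRegistration stages:\n")
    print(as.data.frame(x$registration), digits = 3)
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
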