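#' Pipeline configuration
#'
#' Bundles a [generator_config()] with the analysis settings used by
#' [run_pipeline()]: the significance/FDR level, the number of bins of
#' the Gaussian goodness-of-fit, the leave-p-out settings, the linkage
#' cut percentile, and the output directory.
#'
#' @param generator A [generator_config()].
#' @param out_dir Output directory for the report bundle.
#' @param alpha Significance / FDR level (in (0, 1)).
#' @param n_bins Bins for the binned R-squared.
#' @param lpo_fraction,lpo_samples Leave-p-out fraction and resample count.
#' @param cut_percentile Linkage-height percentile for the flat cluster cut.
#' @param run_reliability,run_icc_between Logical switches for the two
#'   most expensive stages (both default `TRUE`).
#' @param seed Integer seed for the analysis stages (the generator carries
#'   its own seed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            out_dir = tempfile("thicknorm-run-"),
                            alpha = 0.05,
                            n_bins = 100,
                            lpo_fraction = 0.9,
                            lpo_samples = 1000,
                            cut_percentile = 50,
                            run_reliability = TRUE,
                            run_icc_between = TRUE,
                            seed = 1L) {
  stopifnot(inherits(generator, "generator_config"),
            alpha > 0, alpha < 1, n_bins >= 2)
  structure(
    list(generator = generator, out_dir = out_dir, alpha = alpha,
         n_bins = n_bins, lpo_fraction = lpo_fraction,
         lpo_samples = lpo_samples, cut_percentile = cut_percentile,
         run_reliability = run_reliability,
         run_icc_between = run_icc_between, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full normative-thickness pipeline
#'
#' Orchestrates generate -> select -> label -> sample -> model -> report
#' on synthetic data: roster generation, cohort selection, probabilistic
#' atlas and maximum probability map, per-area thickness aggregation,
#' the normative table with QQ data, the inter-areal correlation matrix
#' and cluster tree, the hemispheric ICC and bias tables, the
#' demographic ANOVA, the within-SD ANCOVA, and (optionally) leave-p-out
#' reliability. All outputs are written as CSV/JSON/Newick into
#' `config$out_dir` together with a run manifest; identical config and
#' seed give identical bundles.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every result object plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- config$generator
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  roster <- stage("roster", generate_roster(gen))
  selection <- stage("selection", select_participants(roster))
  n_areas <- nrow(gen$area_params)
  mesh <- ceiling(n_areas * gen$vertices_per_area / 0.94)
  atlas <- stage("atlas", generate_probabilistic_atlas(
    mesh, n_areas, seed = gen$seed, area_names = gen$area_params$area))
  mpm <- stage("mpm", build_mpm(atlas))
  surfaces <- stage("surfaces",
                    generate_cohort_surfaces(selection$retained, mpm, gen))
  thick <- stage("sampling", sample_area_thickness(surfaces, mpm))
  normative <- stage("normative",
                     build_normative_table(thick, n_bins = config$n_bins,
                                           alpha = config$alpha))
  corr <- stage("similarity", correlation_matrix(thick))
  clusters <- stage("clustering",
                    cluster_areas(corr, cut_percentile = config$cut_percentile))
  icc_w <- stage("icc_within", icc_within(thick))
  icc_b <- if (config$run_icc_between) stage("icc_between", icc_between(thick))
           else NULL
  bias <- stage("bias", hemispheric_bias(thick, alpha = config$alpha))
  demo <- stage("demographics", demographics_anova(thick, selection$retained))
  ancova <- stage("within_sd_ancova", within_sd_ancova(thick))
  reliability <- if (config$run_reliability) {
    stage("reliability", leave_p_out_reliability(
      surfaces, mpm, fraction = config$lpo_fraction,
      n_samples = config$lpo_samples, seed = config$seed))
  } else NULL

  od <- config$out_dir
  readr::write_csv(roster, file.path(od, "roster.csv"), na = "")
  readr::write_csv(selection$excluded, file.path(od, "selection_log.csv"))
  write_label_table(mpm, file.path(od, "label_table.tsv"))
  readr::write_csv(thick, file.path(od, "area_thickness.csv"))
  readr::write_csv(tibble::as_tibble(normative),
                   file.path(od, "normative_table.csv"))
  readr::write_csv(attr(normative, "qq"), file.path(od, "qq_data.csv"))
  readr::write_csv(tibble::as_tibble(unclass(corr), rownames = "area"),
                   file.path(od, "correlation_matrix.csv"))
  jsonlite::write_json(
    list(merges = clusters$merges, cut_height = clusters$cut_height,
         clusters = as.list(clusters$clusters)),
    file.path(od, "cluster_tree.json"), auto_unbox = TRUE, digits = NA)
  writeLines(cluster_newick(clusters), file.path(od, "cluster_tree.nwk"))
  icc_report <- list(within = tidy.icc_result(icc_w))
  if (!is.null(icc_b)) {
    icc_report$between <- list(icc = icc_b$icc,
                               left = tidy.icc_result(icc_b$icc_L),
                               right = tidy.icc_result(icc_b$icc_R))
  }
  jsonlite::write_json(icc_report, file.path(od, "icc_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_csv(bias, file.path(od, "bias_table.csv"))
  readr::write_csv(demo$effects, file.path(od, "effects_demographics.csv"))
  readr::write_csv(demo$slopes, file.path(od, "age_slopes.csv"))
  readr::write_csv(ancova, file.path(od, "effects_within_sd.csv"))
  if (!is.null(reliability)) {
    readr::write_csv(reliability, file.path(od, "reliability.csv"))
  }

  manifest <- list(
    package = "thicknorm",
    package_version = as.character(utils::packageVersion("thicknorm")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = serialize_config(config),
    n_retained = nrow(selection$retained),
    age_slope = demo$age_slope
  )
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    roster = roster, selection = selection, atlas = atlas, mpm = mpm,
    surfaces = surfaces, thickness = thick, normative = normative,
    correlation = corr, clusters = clusters, icc_within = icc_w,
    icc_between = icc_b, bias = bias, demographics = demo,
    within_sd_ancova = ancova, reliability = reliability,
    out_dir = od
  ))
}

# a plain-list view of the config for the manifest / YAML round-trip
serialize_config <- function(config) {
  gen <- config$generator
  list(
    generator = list(
      n_subjects = gen$n_subjects, n_mz_pairs = gen$n_mz_pairs,
      n_dz_pairs = gen$n_dz_pairs, age_range = gen$age_range,
      female_per_male = gen$female_per_male,
      area_params = as.list(stats::setNames(
        purrr::map2(gen$area_params$mean_mm, gen$area_params$sd_mm, c),
        gen$area_params$area)),
      within_subject_sd = as.list(gen$within_subject_sd),
      hemi_bias = as.list(gen$hemi_bias),
      age_slope = gen$age_slope,
      cluster_model = as.list(gen$cluster_model),
      vertices_per_area = gen$vertices_per_area,
      missing_frac = gen$missing_frac,
      seed = gen$seed
    ),
    alpha = config$alpha, n_bins = config$n_bins,
    lpo_fraction = config$lpo_fraction, lpo_samples = config$lpo_samples,
    cut_percentile = config$cut_percentile,
    run_reliability = config$run_reliability,
    run_icc_between = config$run_icc_between,
    seed = config$seed
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config` (the output
#'   directory must be supplied again at run time).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @param out_dir Output directory for the reconstructed config.
#' @export
read_pipeline_config <- function(path, out_dir = tempfile("thicknorm-run-")) {
  y <- yaml::read_yaml(path)
  g <- y$generator
  ap <- tibble::tibble(
    area = names(g$area_params),
    mean_mm = purrr::map_dbl(g$area_params, 1),
    sd_mm = purrr::map_dbl(g$area_params, 2)
  )
  gen <- generator_config(
    n_subjects = g$n_subjects, n_mz_pairs = g$n_mz_pairs,
    n_dz_pairs = g$n_dz_pairs, age_range = unlist(g$age_range),
    female_per_male = g$female_per_male, area_params = ap,
    within_subject_sd = unlist(g$within_subject_sd),
    hemi_bias = unlist(g$hemi_bias), age_slope = g$age_slope,
    cluster_model = unlist(g$cluster_model),
    vertices_per_area = g$vertices_per_area,
    missing_frac = g$missing_frac, seed = g$seed
  )
  pipeline_config(
    generator = gen, out_dir = out_dir, alpha = y$alpha, n_bins = y$n_bins,
    lpo_fraction = y$lpo_fraction, lpo_samples = y$lpo_samples,
    cut_percentile = y$cut_percentile,
    run_reliability = y$run_reliability,
    run_icc_between = y$run_icc_between, seed = y$seed
  )
}
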