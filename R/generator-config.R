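#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic data generator: cohort size and
#' twin structure, demographic composition, per-area Gaussian thickness
#' parameters, vertex-level noise, hemispheric offsets, the age slope, and
#' the latent-factor model that induces correlated between-subject
#' variation within the dorsal, ventral, parietal and parahippocampal
#' groups.
#'
#' The defaults describe a healthy young-adult normative cohort at full
#' study scale: 960 subjects aged 22--37, a 1:1.17
#' male:female ratio, per-area means and SDs from the packaged reference
#' table, and a mean cortical thinning of 0.002 mm per year of age.
#'
#' @param n_subjects Number of participants in the roster.
#' @param n_mz_pairs,n_dz_pairs Number of monozygotic / dizygotic twin
#'   pairs embedded in the roster (each pair contributes two records).
#' @param age_range Integer vector `c(min, max)` of ages in years; ages are
#'   drawn uniformly on this range.
#' @param female_per_male Expected ratio of female to male participants.
#' @param area_params Tibble with columns `area`, `mean_mm`, `sd_mm` giving
#'   the per-area between-subject Gaussian parameters (mm). Defaults to the
#'   packaged reference table.
#' @param within_subject_sd Named numeric vector of per-area vertex-level
#'   noise SDs (mm). Unnamed scalar recycles to all areas.
#' @param hemi_bias Named numeric vector of per-area left-minus-right
#'   offsets (mm); the generator adds half the bias to the left hemisphere
#'   and subtracts half from the right. Unnamed scalar recycles.
#' @param age_slope Linear age effect on thickness, mm per year (negative =
#'   thinning), applied uniformly to all areas about the mid-range age.
#' @param cluster_model Named numeric vector of between-subject variance
#'   fractions carried by the latent factors: one `global` factor shared by
#'   all areas plus one factor per group (`dorsal`, `ventral`, `parietal`,
#'   `parahippocampal`). For each area, `global + group` must be <= 1; the
#'   remainder is independent area-specific subject variance, so the total
#'   between-subject SD equals `sd_mm` exactly.
#' @param vertices_per_area Vertices per area per hemisphere on the
#'   synthetic mesh.
#' @param missing_frac Fraction of off-atlas vertices marked missing
#'   (medial-wall analogue), exercised by all downstream aggregation.
#' @param seed Integer seed making every draw reproducible.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 12, n_mz_pairs = 2, seed = 1)
#' cfg$n_subjects
generator_config <- function(n_subjects = 960,
                             n_mz_pairs = 143,
                             n_dz_pairs = 72,
                             age_range = c(22L, 37L),
                             female_per_male = 1.17,
                             area_params = reference_normative_table(),
                             within_subject_sd = default_within_subject_sd(),
                             hemi_bias = default_hemi_bias(),
                             age_slope = -0.002,
                             cluster_model = c(global = 0.25, dorsal = 0.36,
                                               ventral = 0.36, parietal = 0.36,
                                               parahippocampal = 0.36),
                             vertices_per_area = 400,
                             missing_frac = 0.5,
                             seed = 1L) {
  areas <- area_params$area
  within_subject_sd <- expand_area_param(within_subject_sd, areas, "within_subject_sd")
  hemi_bias <- expand_area_param(hemi_bias, areas, "hemi_bias")

  if (2 * n_mz_pairs + 2 * n_dz_pairs > n_subjects) {
    stop("inconsistent counts: 2*n_mz_pairs + 2*n_dz_pairs exceeds n_subjects",
         call. = FALSE)
  }
  if (any(area_params$sd_mm < 0) || any(within_subject_sd < 0)) {
    stop("all standard deviations must be non-negative", call. = FALSE)
  }
  if (vertices_per_area < 1) stop("vertices_per_area must be >= 1", call. = FALSE)
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    stop("age_range must be c(min, max) with min <= max", call. = FALSE)
  }
  needed <- c("global", unique(area_groups()$group))
  missing_f <- setdiff(needed, names(cluster_model))
  if (length(missing_f) > 0) {
    stop("cluster_model is missing factors: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  grp <- area_groups()
  frac <- cluster_model[["global"]] + cluster_model[grp$group[match(areas, grp$area)]]
  frac[is.na(frac)] <- cluster_model[["global"]]  # areas outside the named groups
  if (any(cluster_model < 0) || any(frac > 1 + 1e-12)) {
    stop("factor variance fractions must be >= 0 and global + group <= 1 per area",
         call. = FALSE)
  }

  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_mz_pairs = as.integer(n_mz_pairs),
      n_dz_pairs = as.integer(n_dz_pairs),
      age_range = as.integer(age_range),
      female_per_male = female_per_male,
      area_params = area_params,
      within_subject_sd = within_subject_sd,
      hemi_bias = hemi_bias,
      age_slope = age_slope,
      cluster_model = cluster_model,
      vertices_per_area = as.integer(vertices_per_area),
      missing_frac = missing_frac,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  subjects:", x$n_subjects,
      sprintf("(%d MZ + %d DZ pairs)", x$n_mz_pairs, x$n_dz_pairs), "\n")
  cat("  ages:", paste(x$age_range, collapse = "-"),
      " age slope:", x$age_slope, "mm/yr\n")
  cat("  areas:", nrow(x$area_params),
      " vertices/area/hemi:", x$vertices_per_area, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Default vertex-level noise SD (mm): smallest in early visual cortex,
# largest in the parahippocampal areas, all below 0.7 mm.
default_within_subject_sd <- function() {
  base <- c(
    V1v = 0.35, V1d = 0.35, V2v = 0.40, V2d = 0.40, V3v = 0.45, V3d = 0.45,
    hV4 = 0.45, VO1 = 0.50, VO2 = 0.50, PHC1 = 0.65, PHC2 = 0.65,
    V3A = 0.45, V3B = 0.45, LO1 = 0.45, LO2 = 0.45, TO1 = 0.50, TO2 = 0.50,
    IPS0 = 0.45, IPS1 = 0.45, IPS2 = 0.45, IPS3 = 0.45, IPS4 = 0.50,
    IPS5 = 0.55, SPL1 = 0.50, FEF = 0.55
  )
  base[visual_area_names()]
}

# Default left-minus-right offsets (mm): +0.03 on the areas with a
# left-hemisphere advantage, -0.03 on those with a right-hemisphere
# advantage, 0 elsewhere.
default_hemi_bias <- function() {
  b <- stats::setNames(rep(0, 25), visual_area_names())
  b[c("V3v", "PHC1", "IPS2", "IPS3")] <- 0.03
  b[c("PHC2", "V3d", "V3B", "IPS0")] <- -0.03
  b
}

# Recycle a scalar parameter across areas or validate names on a vector.
expand_area_param <- function(x, areas, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(areas)), areas))
  }
  if (is.null(names(x)) && length(x) == length(areas)) {
    return(stats::setNames(as.numeric(x), areas))
  }
  miss <- setdiff(areas, names(x))
  if (length(miss) > 0) {
    stop(what, " is missing areas: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(x[areas]), areas)
}
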