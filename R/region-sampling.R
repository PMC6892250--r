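#' Aggregate vertex-wise thickness into per-subject area summaries
#'
#' For every subject and every atlas area, pools the non-missing vertices
#' of both hemispheres and reports the pooled mean thickness
#' (`mean_combined`), the SD across the pooled vertices (`sd_within`,
#' n-1 denominator; the within-subject variability measure), the
#' per-hemisphere means and the per-hemisphere vertex counts. Missing
#' vertices (medial wall / non-cortex) are excluded from every statistic,
#' never imputed. "Across both hemispheres" is implemented as vertex
#' pooling, so `mean_combined` is exactly the vertex-count-weighted
#' average of `mean_L` and `mean_R`.
#'
#' Areas present in the label table but with no assigned vertices yield a
#' row of `NA` summaries and a warning.
#'
#' @param surfaces A `cohort_surfaces` (one subject or a whole cohort).
#' @param mpm The `mpm` on the same mesh.
#' @return A tibble with one row per subject x area: `subject`, `area`,
#'   `mean_combined`, `sd_within`, `mean_L`, `mean_R`, `n_vertices_L`,
#'   `n_vertices_R`.
#' @export
#' @examples
#' atlas <- generate_probabilistic_atlas(300, 4, seed = 1)
#' mpm <- build_mpm(atlas)
#' cfg <- generator_config(n_subjects = 3, n_mz_pairs = 0, n_dz_pairs = 0,
#'   area_params = tibble::tibble(area = mpm$label_table$name,
#'                                mean_mm = 2.5, sd_mm = 0.1),
#'   within_subject_sd = 0.4, hemi_bias = 0, vertices_per_area = 70, seed = 1)
#' surf <- generate_cohort_surfaces(generate_roster(cfg), mpm, cfg)
#' sample_area_thickness(surf, mpm)
sample_area_thickness <- function(surfaces, mpm) {
  stopifnot(inherits(surfaces, "cohort_surfaces"), inherits(mpm, "mpm"))
  if (ncol(surfaces$L) != length(mpm$L) || ncol(surfaces$R) != length(mpm$R)) {
    stop("mesh-size mismatch between surfaces and mpm", call. = FALSE)
  }
  n_areas <- nrow(mpm$label_table)

  hemi_stats <- function(M, labels) {
    # subjects x areas sums / sums of squares / counts over non-missing vertices
    keep <- labels > 0
    lab <- labels[keep]
    Mk <- M[, keep, drop = FALSE]
    ok <- !is.na(Mk)
    M0 <- Mk
    M0[!ok] <- 0
    G <- matrix(0, length(lab), n_areas)
    G[cbind(seq_along(lab), lab)] <- 1
    list(sum = M0 %*% G, sumsq = (M0^2) %*% G, n = (ok * 1) %*% G)
  }
  sL <- hemi_stats(surfaces$L, mpm$L)
  sR <- hemi_stats(surfaces$R, mpm$R)

  nL <- sL$n; nR <- sR$n
  n_tot <- nL + nR
  mean_L <- ifelse(nL > 0, sL$sum / nL, NA_real_)
  mean_R <- ifelse(nR > 0, sR$sum / nR, NA_real_)
  mean_c <- ifelse(n_tot > 0, (sL$sum + sR$sum) / n_tot, NA_real_)
  ss <- sL$sumsq + sR$sumsq
  sd_w <- ifelse(n_tot > 1,
                 sqrt(pmax(0, (ss - n_tot * mean_c^2) / (n_tot - 1))),
                 NA_real_)

  empty <- colSums(n_tot) == 0
  if (any(empty)) {
    warning("areas with no assigned vertices: ",
            paste(mpm$label_table$name[empty], collapse = ", "),
            call. = FALSE)
  }

  n_sub <- length(surfaces$subject_id)
  tibble::tibble(
    subject = rep(surfaces$subject_id, times = n_areas),
    area = rep(mpm$label_table$name, each = n_sub),
    mean_combined = as.vector(mean_c),
    sd_within = as.vector(sd_w),
    mean_L = as.vector(mean_L),
    mean_R = as.vector(mean_R),
    n_vertices_L = as.integer(nL),
    n_vertices_R = as.integer(nR)
  ) |>
    dplyr::arrange(match(.data$subject, surfaces$subject_id),
                   match(.data$area, mpm$label_table$name))
}
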