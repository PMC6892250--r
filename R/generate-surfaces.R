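#' Generate vertex-wise thickness surfaces for a cohort
#'
#' Simulates per-vertex cortical thickness maps (mm) for every subject in
#' a roster, on the mesh defined by a maximum probability map. The
#' generative model for subject `s`, area `a`, hemisphere `h` is
#'
#' \deqn{y = \mu_a + \beta_{age}(age_s - \bar{age})
#'        + \sigma_a(\sqrt{g}\,u_s + \sqrt{h_a}\,u_{s,grp(a)} + \sqrt{1-g-h_a}\,e_{s,a})
#'        \pm b_a/2 + \nu}
#'
#' where `u` are standard-normal latent subject factors (one global, one
#' per anatomical group), `e` is independent area-specific subject noise
#' scaled so the total between-subject SD equals `sigma_a` exactly, the
#' hemispheric offset `b_a/2` is added on the left and subtracted on the
#' right, and `nu ~ N(0, sigma_w[a])` is independent vertex noise. A fixed
#' fraction of off-atlas vertices is marked missing (`NA`), the same mask
#' for all subjects, as a medial-wall analogue; remaining off-atlas cortex
#' receives a generic thickness field so that unassigned vertices carry
#' plausible values without entering any area statistic.
#'
#' @param roster Roster tibble (needs `id` and `age`).
#' @param mpm An `mpm` whose label table covers all areas in
#'   `config$area_params`.
#' @param config A [generator_config()].
#' @return An object of class `cohort_surfaces`: `subject_id`, and
#'   per-hemisphere subjects x vertices matrices `L` and `R`. The attribute
#'   `"variance_decomposition"` records, per area, the factor and residual
#'   between-subject variance shares (they sum to `sd_mm^2` exactly).
#' @export
generate_cohort_surfaces <- function(roster, mpm, config) {
  stopifnot(inherits(mpm, "mpm"), inherits(config, "generator_config"))
  areas <- config$area_params$area
  if (!all(areas %in% mpm$label_table$name)) {
    stop("mpm does not cover all areas in area_params", call. = FALSE)
  }
  n <- nrow(roster)
  grp_tbl <- area_groups()
  grp <- grp_tbl$group[match(areas, grp_tbl$area)]
  grp[is.na(grp)] <- "global_only"
  g <- config$cluster_model[["global"]]
  h <- ifelse(grp %in% names(config$cluster_model),
              config$cluster_model[grp], 0)
  resid <- 1 - g - h
  if (any(resid < -1e-12)) {
    stop("factor loadings imply negative residual variance", call. = FALSE)
  }
  resid <- pmax(resid, 0)
  sigma <- config$area_params$sd_mm
  mu <- config$area_params$mean_mm
  decomposition <- tibble::tibble(
    area = areas,
    total_var = sigma^2,
    factor_var = (g + h) * sigma^2,
    residual_var = resid * sigma^2
  )

  withr::with_seed(config$seed + 1L, {
    # latent subject factors: one global + one per group
    groups <- unique(grp)
    u_global <- stats::rnorm(n)
    u_grp <- vapply(groups, function(gn) stats::rnorm(n), numeric(n))
    e <- matrix(stats::rnorm(n * length(areas)), n, length(areas))

    age_c <- roster$age - mean(config$age_range)
    # subjects x areas matrix of area-level true values
    A <- outer(rep(1, n), mu) + config$age_slope * outer(age_c, rep(1, length(areas)))
    for (j in seq_along(areas)) {
      A[, j] <- A[, j] + sigma[j] *
        (sqrt(g) * u_global +
           sqrt(h[j]) * u_grp[, grp[j]] +
           sqrt(resid[j]) * e[, j])
    }

    mesh <- length(mpm$L)
    ids <- mpm$label_table$id[match(areas, mpm$label_table$name)]
    b <- config$within_subject_sd  # vertex noise per area
    bias <- config$hemi_bias

    build_hemi <- function(labels, sign_bias) {
      M <- matrix(NA_real_, n, mesh)
      for (j in seq_along(areas)) {
        idx <- which(labels == ids[j])
        if (length(idx) == 0) next
        noise <- matrix(stats::rnorm(n * length(idx), 0, b[[areas[j]]]),
                        n, length(idx))
        M[, idx] <- A[, j] + sign_bias * bias[[areas[j]]] / 2 + noise
      }
      off <- which(labels == 0 | !(labels %in% ids))
      if (length(off) > 0) {
        M[, off] <- 2.5 + matrix(stats::rnorm(n * length(off), 0, 0.3),
                                 n, length(off))
      }
      M
    }
    L <- build_hemi(mpm$L, +1)
    R <- build_hemi(mpm$R, -1)

    # medial-wall analogue: a seeded fixed mask over off-atlas vertices
    mask_hemi <- function(labels) {
      off <- which(labels == 0 | !(labels %in% ids))
      n_miss <- round(config$missing_frac * length(off))
      if (n_miss > 0) sample(off, n_miss) else integer(0)
    }
    miss_L <- mask_hemi(mpm$L)
    miss_R <- mask_hemi(mpm$R)
    if (length(miss_L) > 0) L[, miss_L] <- NA_real_
    if (length(miss_R) > 0) R[, miss_R] <- NA_real_

    # thickness is strictly positive; clamp the (rare) negative noise tail
    L[!is.na(L) & L < 0.01] <- 0.01
    R[!is.na(R) & R < 0.01] <- 0.01

    structure(
      list(subject_id = roster$id, L = L, R = R),
      class = "cohort_surfaces",
      variance_decomposition = decomposition
    )
  })
}

#' @export
print.cohort_surfaces <- function(x, ...) {
  cat("<cohort_surfaces>", length(x$subject_id), "subjects x",
      ncol(x$L), "vertices per hemisphere\n")
  invisible(x)
}

#' Extract one subject's surfaces
#'
#' @param surfaces A `cohort_surfaces`.
#' @param id Subject id.
#' @return A `cohort_surfaces` restricted to that subject.
#' @export
subject_surface <- function(surfaces, id) {
  i <- match(id, surfaces$subject_id)
  if (is.na(i)) stop("unknown subject id: ", id, call. = FALSE)
  structure(
    list(subject_id = surfaces$subject_id[i],
         L = surfaces$L[i, , drop = FALSE],
         R = surfaces$R[i, , drop = FALSE]),
    class = "cohort_surfaces",
    variance_decomposition = attr(surfaces, "variance_decomposition")
  )
}
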