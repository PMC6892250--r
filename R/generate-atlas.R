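#' Generate a toy probabilistic surface atlas
#'
#' Lays `n_areas` contiguous vertex blocks along a 1-D synthetic mesh for
#' each hemisphere and assigns each block a triangular probability profile
#' that overlaps its neighbours near the block boundaries, mimicking the
#' soft boundaries of a group probabilistic atlas. Vertices outside every
#' block (the mesh margins, a medial-wall analogue) have probability zero
#' for all areas; where overlapping profiles would sum above one they are
#' renormalised, preserving the argmax. Block centres are jittered by a
#' seeded perturbation so different seeds give different (but always
#' valid) atlases.
#'
#' @param mesh_size Vertices per hemisphere.
#' @param n_areas Number of areas (25 gives the canonical area names).
#' @param seed Integer seed.
#' @param area_names Optional area names; defaults to the canonical names
#'   when `n_areas == 25` and `A01..` otherwise.
#' @return An object of class `prob_atlas`: a list with per-hemisphere
#'   probability matrices (`L`, `R`; vertices x areas) and `area_names`.
#' @export
#' @examples
#' atlas <- generate_probabilistic_atlas(200, 4, seed = 1)
#' dim(atlas$L)
generate_probabilistic_atlas <- function(mesh_size, n_areas, seed = 1L,
                                         area_names = NULL) {
  if (n_areas < 1) stop("n_areas must be >= 1", call. = FALSE)
  if (mesh_size < n_areas) stop("mesh_size must be >= n_areas", call. = FALSE)
  if (is.null(area_names)) {
    area_names <- if (n_areas == 25) visual_area_names() else
      sprintf("A%02d", seq_len(n_areas))
  }
  stopifnot(length(area_names) == n_areas, !anyDuplicated(area_names))

  withr::with_seed(seed, {
    hemis <- lapply(c(L = 1, R = 2), function(h) {
      margin <- max(1L, floor(0.02 * mesh_size))
      block <- floor((mesh_size - 2 * margin) / n_areas)
      if (block < 1) stop("mesh_size too small for n_areas", call. = FALSE)
      centres <- margin + (seq_len(n_areas) - 0.5) * block
      jitter_max <- max(0, floor(0.05 * block))
      if (jitter_max > 0) {
        centres <- centres + sample(seq(-jitter_max, jitter_max), n_areas,
                                    replace = TRUE)
      }
      v <- seq_len(mesh_size)
      width <- 0.75 * block
      p <- vapply(centres, function(cc) pmax(0, 1 - abs(v - cc) / width),
                  numeric(mesh_size))
      tot <- rowSums(p)
      over <- tot > 1
      p[over, ] <- p[over, , drop = FALSE] / tot[over]
      dimnames(p) <- list(NULL, area_names)
      p
    })
    structure(list(L = hemis$L, R = hemis$R, area_names = area_names),
              class = "prob_atlas")
  })
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat("<prob_atlas>", length(x$area_names), "areas,",
      nrow(x$L), "vertices per hemisphere\n")
  invisible(x)
}
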