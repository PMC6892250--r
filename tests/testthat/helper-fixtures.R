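# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# A moderate synthetic cohort with the default latent-factor structure.
small_cohort <- function(n_subjects = 60, vpa = 80, seed = 11) {
  key <- paste0("cohort_", n_subjects, "_", vpa, "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- generator_config(n_subjects = n_subjects, n_mz_pairs = 0,
                          n_dz_pairs = 0, vertices_per_area = vpa, seed = seed)
  mesh <- ceiling(25 * vpa / 0.94)
  atlas <- generate_probabilistic_atlas(mesh, 25, seed = seed)
  mpm <- build_mpm(atlas)
  roster <- generate_roster(cfg)
  surf <- generate_cohort_surfaces(roster, mpm, cfg)
  thick <- sample_area_thickness(surf, mpm)
  res <- list(cfg = cfg, roster = roster, atlas = atlas, mpm = mpm,
              surf = surf, thick = thick)
  .fixture_cache[[key]] <- res
  res
}

# Hand-built containers for arithmetic fixtures.
make_mpm <- function(L, R, names) {
  structure(list(L = as.integer(L), R = as.integer(R),
                 label_table = tibble::tibble(id = seq_along(names),
                                              name = names)),
            class = "mpm")
}

make_surfaces <- function(ids, L, R) {
  structure(list(subject_id = ids, L = L, R = R), class = "cohort_surfaces")
}

make_atlas <- function(pL, pR, names) {
  dimnames(pL) <- list(NULL, names); dimnames(pR) <- list(NULL, names)
  structure(list(L = pL, R = pR, area_names = names), class = "prob_atlas")
}

# A roster emulating the published cohort structure: all records eligible,
# n_mz_pairs monozygotic pairs, the rest unrelated singletons.
eligible_mz_roster <- function(n_total, n_mz_pairs) {
  generate_roster(generator_config(n_subjects = n_total,
                                   n_mz_pairs = n_mz_pairs,
                                   n_dz_pairs = 0, seed = 2024L))
}
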