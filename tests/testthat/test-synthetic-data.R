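test_that("roster generation honours size, twin structure and determinism", {
  r4 <- generate_roster(generator_config(n_subjects = 4, n_mz_pairs = 0,
                                         n_dz_pairs = 0, seed = 1))
  expect_equal(nrow(r4), 4)
  expect_equal(anyDuplicated(r4$id), 0)
  expect_true(all(is.na(r4$twin_pair_id)))

  big <- generate_roster(generator_config(n_subjects = 1103, n_mz_pairs = 143,
                                          n_dz_pairs = 0, seed = 5))
  mz <- big[big$zygosity == "MZ", ]
  expect_equal(nrow(mz), 286)
  expect_equal(sum(table(mz$twin_pair_id) == 2), 143)
  expect_true(all(big$age >= 22 & big$age <= 37))

  again <- generate_roster(generator_config(n_subjects = 1103,
                                            n_mz_pairs = 143,
                                            n_dz_pairs = 0, seed = 5))
  expect_identical(big, again)

  expect_error(generator_config(n_subjects = 5, n_mz_pairs = 2, n_dz_pairs = 1),
               "inconsistent")
})

test_that("degenerate generator (all noise off) reproduces the area means exactly", {
  ap <- tibble::tibble(area = visual_area_names(), mean_mm = seq(2, 2.96, length.out = 25),
                       sd_mm = 0)
  cfg <- generator_config(n_subjects = 3, n_mz_pairs = 0, n_dz_pairs = 0,
                          area_params = ap, within_subject_sd = 0,
                          hemi_bias = 0, age_slope = 0,
                          cluster_model = c(global = 0, dorsal = 0, ventral = 0,
                                            parietal = 0, parahippocampal = 0),
                          vertices_per_area = 20, missing_frac = 0, seed = 2)
  mesh <- ceiling(25 * 20 / 0.94)
  mpm <- build_mpm(generate_probabilistic_atlas(mesh, 25, seed = 2))
  surf <- generate_cohort_surfaces(generate_roster(cfg), mpm, cfg)
  for (a in c(1, 13, 25)) {
    idx <- which(mpm$L == a)
    expect_equal(unique(as.vector(surf$L[, idx])),
                 ap$mean_mm[a], tolerance = 1e-12)
  }
})

test_that("generator recovers configured between-subject moments at scale", {
  fx <- small_cohort(n_subjects = 960, vpa = 200, seed = 7)
  ref <- reference_normative_table()
  emp <- fx$thick |>
    dplyr::group_by(area) |>
    dplyr::summarise(m = mean(mean_combined), s = sd(mean_combined))
  emp <- emp[match(ref$area, emp$area), ]
  # empirical between-subject SD within 10% of the configured sigma_a
  expect_true(all(abs(emp$s / ref$sd_mm - 1) < 0.10))
  # empirical means within 2*sigma_a/sqrt(960) of the configured means
  expect_true(all(abs(emp$m - ref$mean_mm) < 2 * ref$sd_mm / sqrt(960)))
})

test_that("variance bookkeeping decomposes exactly and surfaces are reproducible", {
  fx <- small_cohort(n_subjects = 20, vpa = 30, seed = 9)
  dec <- attr(fx$surf, "variance_decomposition")
  expect_true(all(abs(dec$factor_var + dec$residual_var - dec$total_var) < 1e-9))

  surf2 <- generate_cohort_surfaces(fx$roster, fx$mpm, fx$cfg)
  expect_identical(fx$surf$L, surf2$L)
  expect_identical(fx$surf$R, surf2$R)
})

test_that("negating the hemispheric bias swaps the L/R mean distributions", {
  base <- generator_config(n_subjects = 150, n_mz_pairs = 0, n_dz_pairs = 0,
                           hemi_bias = 0.08, vertices_per_area = 40, seed = 3)
  flip <- generator_config(n_subjects = 150, n_mz_pairs = 0, n_dz_pairs = 0,
                           hemi_bias = -0.08, vertices_per_area = 40, seed = 3)
  mesh <- ceiling(25 * 40 / 0.94)
  mpm <- build_mpm(generate_probabilistic_atlas(mesh, 25, seed = 3))
  roster <- generate_roster(base)
  t1 <- sample_area_thickness(generate_cohort_surfaces(roster, mpm, base), mpm)
  t2 <- sample_area_thickness(generate_cohort_surfaces(roster, mpm, flip), mpm)
  expect_lt(abs(mean(t1$mean_L - t1$mean_R) - 0.08), 0.01)
  expect_lt(abs(mean(t2$mean_L - t2$mean_R) + 0.08), 0.01)
  expect_lt(abs(mean(t1$mean_L) - mean(t2$mean_R)), 0.01)
})

test_that("toy probabilistic atlas satisfies its range and coverage contracts", {
  expect_error(generate_probabilistic_atlas(100, 0), "n_areas")

  a2 <- generate_probabilistic_atlas(100, 2, seed = 1)
  expect_true(all(a2$L >= 0 & a2$L <= 1))
  expect_true(all(rowSums(a2$L) <= 1 + 1e-12))

  a25 <- generate_probabilistic_atlas(2500, 25, seed = 1)
  mpm <- build_mpm(a25)
  expect_setequal(unique(mpm$L[mpm$L > 0]), 1:25)
  expect_setequal(unique(mpm$R[mpm$R > 0]), 1:25)
  # at least one strictly maximal vertex per area
  for (a in 1:25) {
    idx <- which(mpm$L == a)
    best <- a25$L[idx, a]
    others <- a25$L[idx, -a, drop = FALSE]
    expect_true(any(best > apply(others, 1, max)))
  }
  # off-atlas vertices are zero everywhere
  off <- which(mpm$L == 0)
  expect_true(all(a25$L[off, ] == 0))
})
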