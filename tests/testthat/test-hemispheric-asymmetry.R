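# longhand two-way ANOVA mean squares, the independent ICC oracle
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_err <- ss_err + (m[i, j] - row_m[i] - col_m[j] + grand)^2
  }
  msr <- ss_rows / (n - 1); msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("ICC(A,1) equals the longhand mean-squares oracle on a 4-subject table", {
  m <- cbind(c(2.01, 2.25, 1.89, 2.40), c(2.10, 2.19, 1.95, 2.52))
  expect_equal(icc_a1(m)$icc, icc_oracle(m), tolerance = 1e-10)
  expect_equal(icc_a1(m)$icc, icc_oracle(m))
})

test_that("perfect agreement gives ICC 1; shifts and scalings behave correctly", {
  m <- cbind(c(2.0, 2.2, 2.5, 2.7), c(2.0, 2.2, 2.5, 2.7))
  expect_equal(icc_a1(m)$icc, 1)

  set.seed(5)
  base <- cbind(rnorm(50, 2.3, 0.2), rnorm(50, 2.3, 0.2))
  i0 <- icc_a1(base)$icc
  expect_equal(icc_a1(base + 0.7)$icc, i0, tolerance = 1e-12)
  expect_equal(icc_a1(base * 3)$icc, i0, tolerance = 1e-12)
})

test_that("icc_within recovers a known variance ratio in simulation", {
  rho <- 0.6
  set.seed(8)
  reps <- vapply(1:100, function(i) {
    u <- rnorm(200, 0, sqrt(rho))
    m <- cbind(u + rnorm(200, 0, sqrt(1 - rho)),
               u + rnorm(200, 0, sqrt(1 - rho)))
    icc_a1(m)$icc
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - rho), 3 * se + 0.01)
})

test_that("between-subject ICC matches brute-force pair enumeration on 3 subjects", {
  tab <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3"), 2),
    area = rep(c("A", "B"), each = 3),
    mean_L = c(2.0, 2.4, 2.1, 2.6, 2.2, 2.9),
    mean_R = c(2.1, 2.3, 2.0, 2.5, 2.4, 2.8)
  )
  got <- icc_between(tab)

  # oracle: materialise every unordered subject pair x area, per hemisphere
  brute_one <- function(vals) {  # vals: 3 subjects x 2 areas
    rows <- NULL
    for (a in 1:2) for (i in 1:2) for (j in (i + 1):3) {
      rows <- rbind(rows, c(vals[i, a], vals[j, a]))
    }
    icc_oracle(rows)
  }
  vl <- matrix(tab$mean_L, 3, 2); vr <- matrix(tab$mean_R, 3, 2)
  expect_equal(got$icc_L$icc, brute_one(vl), tolerance = 1e-10)
  expect_equal(got$icc_R$icc, brute_one(vr), tolerance = 1e-10)
  expect_equal(got$icc, mean(c(brute_one(vl), brute_one(vr))), tolerance = 1e-10)
})

test_that("exchangeable subjects give near-zero between-subject agreement", {
  set.seed(12)
  tab <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:40), each = 1),
    area = "A",
    mean_L = rnorm(40), mean_R = rnorm(40)
  )
  expect_lt(abs(icc_between(tab)$icc), 0.15)
})

test_that("within-subject agreement exceeds between-subject agreement in the cohort", {
  fx <- small_cohort(n_subjects = 60, vpa = 80, seed = 11)
  w <- icc_within(fx$thick)
  b <- icc_between(fx$thick)
  expect_gt(w$icc, b$icc)
  expect_gt(w$icc, 0.5)
})

test_that("hemispheric bias: null cohort stays unflagged, planted effect is found", {
  # symmetric generator: no area should survive FDR
  cfg0 <- generator_config(n_subjects = 100, n_mz_pairs = 0, n_dz_pairs = 0,
                           hemi_bias = 0, vertices_per_area = 60, seed = 23)
  mpm <- build_mpm(generate_probabilistic_atlas(ceiling(25 * 60 / 0.94), 25,
                                                seed = 23))
  thick0 <- sample_area_thickness(
    generate_cohort_surfaces(generate_roster(cfg0), mpm, cfg0), mpm)
  b0 <- hemispheric_bias(thick0)
  expect_equal(sum(b0$significant), 0)

  # planted +0.1 mm bias with ~0.1 mm diff SD at n = 200: d ~ 1, power ~ 1
  set.seed(14)
  n <- 200
  tabs <- purrr::map(visual_area_names(), function(a) {
    delta <- if (a == "V1d") 0.1 else 0
    tibble::tibble(subject = sprintf("s%03d", 1:n), area = a,
                   mean_L = 2.3 + rnorm(n, 0, 0.1) + delta / 2,
                   mean_R = 2.3 + rnorm(n, 0, 0.1) - delta / 2)
  })
  tab <- dplyr::bind_rows(tabs) |>
    dplyr::mutate(mean_combined = (mean_L + mean_R) / 2)
  b1 <- hemispheric_bias(tab)
  v1d <- b1[b1$area == "V1d", ]
  expect_true(v1d$significant)
  expect_equal(v1d$d, 0.1 / sqrt(2 * 0.1^2), tolerance = 0.35)
  expect_true(v1d$category %in% c("medium_to_large", "large"))
})

test_that("swapping hemispheres negates biases and preserves the tests", {
  fx <- small_cohort(n_subjects = 60, vpa = 80, seed = 11)
  b <- hemispheric_bias(fx$thick)
  swapped <- dplyr::rename(fx$thick, mean_L = "mean_R", mean_R = "mean_L")
  bs <- hemispheric_bias(swapped)
  expect_equal(bs$bias_mm, -b$bias_mm, tolerance = 1e-12)
  expect_equal(abs(bs$t), abs(b$t), tolerance = 1e-12)
  expect_equal(bs$p, b$p, tolerance = 1e-12)
  expect_equal(bs$q, b$q, tolerance = 1e-12)
  # sign(bias) = sign(t)
  expect_equal(sign(b$bias_mm), sign(b$t))
})
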