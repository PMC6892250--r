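test_that("constant vertex values give a zero reliability span", {
  mpm <- make_mpm(rep(1, 20), rep(1, 20), "A01")
  surf <- make_surfaces("s1", matrix(2.5, 1, 20), matrix(2.5, 1, 20))
  rel <- leave_p_out_reliability(surf, mpm, n_samples = 100, seed = 1)
  expect_equal(rel$ci_span, 0)
})

test_that("resampled spans match the finite-population analytic oracle", {
  V <- 300
  S <- 0.5
  mpm <- make_mpm(rep(1, V), integer(V), "A01")
  set.seed(77)
  x <- rnorm(V, 2.4, S)
  surf <- make_surfaces("s1", matrix(x, 1, V), matrix(NA_real_, 1, V))
  spans <- vapply(1:100, function(s) {
    leave_p_out_reliability(surf, mpm, n_samples = 400, seed = s)$ci_span
  }, numeric(1))
  expected <- analytic_ci_span(sd(x), V)
  expect_lt(abs(mean(spans) / expected - 1), 0.15)
})

test_that("span shrinks as the sampled fraction grows and scales with vertex SD", {
  V <- 400
  mpm <- make_mpm(rep(1, V), integer(V), "A01")
  set.seed(3)
  x <- rnorm(V, 2.2, 0.4)
  surf1 <- make_surfaces("s1", matrix(x, 1, V), matrix(NA_real_, 1, V))
  s90 <- leave_p_out_reliability(surf1, mpm, fraction = 0.9, seed = 2)$ci_span
  s99 <- leave_p_out_reliability(surf1, mpm, fraction = 0.99, seed = 2)$ci_span
  expect_lt(s99, s90 / 2)

  x2 <- 2.2 + (x - 2.2) * 3  # triple the vertex SD about the mean
  surf3 <- make_surfaces("s1", matrix(x2, 1, V), matrix(NA_real_, 1, V))
  s3 <- leave_p_out_reliability(surf3, mpm, fraction = 0.9, seed = 2)$ci_span
  expect_equal(s3 / s90, 3, tolerance = 0.15)
})

test_that("span is stable in the number of resamples", {
  V <- 350
  mpm <- make_mpm(rep(1, V), integer(V), "A01")
  set.seed(4)
  surf <- make_surfaces("s1", matrix(rnorm(V, 2.3, 0.5), 1, V),
                        matrix(NA_real_, 1, V))
  s1k <- leave_p_out_reliability(surf, mpm, n_samples = 1000, seed = 6)$ci_span
  s10k <- leave_p_out_reliability(surf, mpm, n_samples = 10000, seed = 6)$ci_span
  expect_lt(abs(s10k / s1k - 1), 0.10)
})

test_that("areas with too few vertices are skipped with a warning", {
  mpm <- make_mpm(c(rep(1, 5), rep(2, 30)), integer(35), c("A01", "A02"))
  surf <- make_surfaces("s1", matrix(rnorm(35, 2.3, 0.3), 1, 35),
                        matrix(NA_real_, 1, 35))
  expect_warning(rel <- leave_p_out_reliability(surf, mpm, n_samples = 50,
                                                seed = 1),
                 "A01")
  expect_equal(rel$area, "A02")
})

test_that("within-SD ANCOVA: constant response gives F = 0, effects match structure", {
  fx <- small_cohort(n_subjects = 30, vpa = 40, seed = 19)
  flat <- dplyr::mutate(fx$thick, sd_within = 0.4)
  eff0 <- within_sd_ancova(flat)
  expect_true(all(eff0$F == 0))

  # generator has area-dependent but subject-independent vertex noise:
  # large area effect, unremarkable subject effect
  eff <- within_sd_ancova(fx$thick)
  f_area <- eff$F[eff$effect == "area"]
  f_subj <- eff$F[eff$effect == "subject"]
  expect_gt(f_area, 50)
  expect_lt(eff$p[eff$effect == "area"], 1e-10)
  expect_lt(f_subj, 3)
})

test_that("within-SD ANCOVA sums of squares equal a longhand sequential fit", {
  tab <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3"), each = 2),
    area = rep(c("A", "B"), 3),
    mean_combined = c(2.0, 2.4, 2.1, 2.5, 1.9, 2.45),
    sd_within = c(0.30, 0.42, 0.33, 0.44, 0.29, 0.47)
  )
  eff <- within_sd_ancova(tab)

  # oracle: sequential projections built from explicit design matrices
  y <- tab$sd_within
  x0 <- matrix(1, 6, 1)
  x1 <- cbind(x0, tab$mean_combined)
  x2 <- cbind(x1, as.numeric(tab$area == "B"))
  x3 <- cbind(x2, as.numeric(tab$subject == "s2"),
              as.numeric(tab$subject == "s3"))
  rss <- function(x) sum(qr.resid(qr(x), y)^2)
  ss_cov <- rss(x0) - rss(x1)
  ss_area <- rss(x1) - rss(x2)
  ss_subj <- rss(x2) - rss(x3)
  ss_res <- rss(x3)
  df_res <- 6 - ncol(x3)
  expect_equal(eff$F[eff$effect == "mean_thickness"],
               (ss_cov / 1) / (ss_res / df_res), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "area"],
               (ss_area / 1) / (ss_res / df_res), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "subject"],
               (ss_subj / 2) / (ss_res / df_res), tolerance = 1e-8)
  expect_equal(eff$partial_eta2[eff$effect == "area"],
               ss_area / (ss_area + ss_res), tolerance = 1e-8)
})

test_that("demographic ANOVA: gender F equals the squared two-sample t", {
  set.seed(33)
  n <- 40
  tab <- tidyr::crossing(subject = sprintf("s%02d", 1:n),
                         area = c("A", "B")) |>
    dplyr::mutate(mean_combined = rnorm(dplyr::n(), 2.3, 0.1))
  roster <- tibble::tibble(id = sprintf("s%02d", 1:n), age = 25L,
                           gender = rep(c("female", "male"), each = n / 2))
  # plant a gender offset
  tab <- dplyr::mutate(tab, mean_combined = mean_combined +
                         ifelse(subject %in% roster$id[roster$gender == "male"],
                                0.05, 0))
  expect_warning(res <- demographics_anova(tab, roster), "single age level")
  subj_means <- tab |>
    dplyr::group_by(subject) |>
    dplyr::summarise(m = mean(mean_combined)) |>
    dplyr::left_join(stats::setNames(roster[, c("id", "gender")],
                                     c("subject", "gender")), by = "subject")
  tt <- t.test(m ~ gender, data = subj_means, var.equal = TRUE)
  f_gender <- res$effects$F[res$effects$effect == "gender"]
  expect_equal(f_gender, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("demographic ANOVA under the null shows no spurious effects", {
  set.seed(41)
  ps <- replicate(15, {
    n <- 30
    tab <- tidyr::crossing(subject = sprintf("s%02d", 1:n),
                           area = c("A", "B", "C")) |>
      dplyr::mutate(mean_combined = rnorm(dplyr::n(), 2.3, 0.1))
    roster <- tibble::tibble(
      id = sprintf("s%02d", 1:n),
      age = sample(22:25, n, replace = TRUE),
      gender = sample(c("female", "male"), n, replace = TRUE)
    )
    res <- demographics_anova(tab, roster)
    c(res$effects$p[res$effects$effect == "age"],
      res$effects$p[res$effects$effect == "gender"])
  })
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
})
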