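#' Leave-p-out reliability of regional mean thickness
#'
#' Estimates the reliability of each subject's per-area mean thickness by
#' resampling vertices: in each of `n_samples` draws, `round(fraction*V)`
#' of the area's pooled non-missing vertices (both hemispheres) are drawn
#' without replacement and averaged; the span between the 2.5th and
#' 97.5th empirical percentiles of the resampled means (for the default
#' `ci_level` of 0.95) is the reliability estimator. Small spans mean the
#' regional mean is insensitive to which vertices happen to be sampled.
#' Areas with fewer than 10 pooled vertices are skipped with a warning.
#'
#' Internally the complement of each draw is sampled when `fraction >
#' 0.5` (the mean over the drawn 90% is recovered from the total minus
#' the left-out 10%), which is distribution-identical and much faster.
#'
#' @param surfaces A `cohort_surfaces`.
#' @param mpm The `mpm` on the same mesh.
#' @param fraction Fraction of vertices per draw (default 0.9).
#' @param n_samples Number of resamples (default 1000).
#' @param ci_level Confidence level of the span (default 0.95).
#' @param seed Integer seed.
#' @return A tibble with one row per subject x area: `subject`, `area`,
#'   `n_vertices`, `vertex_sd`, `ci_span` (mm), `n_samples`, `fraction`,
#'   `ci_level`.
#' @export
leave_p_out_reliability <- function(surfaces, mpm, fraction = 0.9,
                                    n_samples = 1000, ci_level = 0.95,
                                    seed = 1L) {
  stopifnot(inherits(surfaces, "cohort_surfaces"), inherits(mpm, "mpm"))
  stopifnot(fraction > 0, fraction < 1, n_samples >= 2)
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  areas <- mpm$label_table$name
  idx_L <- split(seq_along(mpm$L), factor(mpm$L, levels = mpm$label_table$id))
  idx_R <- split(seq_along(mpm$R), factor(mpm$R, levels = mpm$label_table$id))

  withr::with_seed(seed, {
    skipped <- character(0)
    rows <- vector("list", length(surfaces$subject_id) * length(areas))
    r <- 0L
    for (s in seq_along(surfaces$subject_id)) {
      for (a in seq_along(areas)) {
        x <- c(surfaces$L[s, idx_L[[a]]], surfaces$R[s, idx_R[[a]]])
        x <- x[!is.na(x)]
        V <- length(x)
        r <- r + 1L
        if (V < 10) {
          skipped <- c(skipped, areas[a])
          next
        }
        m <- round(fraction * V)
        if (m > V / 2) {
          n_out <- V - m
          tot <- sum(x)
          outs <- vapply(seq_len(n_samples),
                         function(i) sum(x[sample.int(V, n_out)]),
                         numeric(1))
          means <- (tot - outs) / m
        } else {
          means <- vapply(seq_len(n_samples),
                          function(i) mean(x[sample.int(V, m)]),
                          numeric(1))
        }
        qs <- stats::quantile(means, probs, names = FALSE)
        rows[[r]] <- tibble::tibble(
          subject = surfaces$subject_id[s], area = areas[a],
          n_vertices = V, vertex_sd = stats::sd(x),
          ci_span = qs[2] - qs[1],
          n_samples = n_samples, fraction = fraction, ci_level = ci_level
        )
      }
    }
    if (length(skipped) > 0) {
      warning("areas skipped (fewer than 10 vertices): ",
              paste(unique(skipped), collapse = ", "), call. = FALSE)
    }
    dplyr::bind_rows(rows)
  })
}

#' Analytic leave-p-out span under simple random sampling
#'
#' Closed-form approximation to the expected resampled-mean CI span for a
#' region of `V` vertices with vertex SD `S`, sampled at fraction `f`
#' without replacement: `2 z S sqrt((1 - f) / (f V))` (the finite
#' population correction form). Used as an independent oracle for
#' [leave_p_out_reliability()].
#'
#' @param S Vertex SD (mm).
#' @param V Number of vertices.
#' @param fraction Sampling fraction.
#' @param ci_level Confidence level.
#' @return Expected span (mm).
#' @export
analytic_ci_span <- function(S, V, fraction = 0.9, ci_level = 0.95) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  2 * z * S * sqrt((1 - fraction) / (fraction * V))
}

#' ANCOVA on within-subject variability
#'
#' Models the within-subject SD of thickness (`sd_within`) with visual
#' area and subject identity as categorical factors while controlling for
#' mean thickness (the covariate enters first; sequential sums of
#' squares). Tests whether the vertex-level variability of the thickness
#' estimate differs across areas and across people.
#'
#' @param table An area thickness table.
#' @return An effect table (class `effect_table`): tibble with `effect`,
#'   `F`, `df_num`, `df_den`, `p`, `partial_eta2`.
#' @export
within_sd_ancova <- function(table) {
  tab <- table[stats::complete.cases(table$sd_within, table$mean_combined), ]
  if (length(unique(tab$area)) < 2 || length(unique(tab$subject)) < 3) {
    stop("need >= 2 areas and >= 3 subjects", call. = FALSE)
  }
  if (stats::var(tab$sd_within) == 0) {
    out <- tibble::tibble(
      effect = c("mean_thickness", "area", "subject"),
      F = 0, df_num = NA_integer_, df_den = NA_integer_,
      p = 1, partial_eta2 = 0
    )
    class(out) <- c("effect_table", class(out))
    return(out)
  }
  dat <- data.frame(
    sd_within = tab$sd_within,
    mean_combined = tab$mean_combined,
    area = factor(tab$area),
    subject = factor(tab$subject)
  )
  fit <- stats::lm(sd_within ~ mean_combined + area + subject, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear terms: ",
         paste(unique(gsub("[0-9]+$", "", bad)), collapse = ", "),
         call. = FALSE)
  }
  a <- stats::anova(fit)
  ss_res <- a["Residuals", "Sum Sq"]
  terms <- setdiff(rownames(a), "Residuals")
  out <- tibble::tibble(
    effect = sub("^mean_combined$", "mean_thickness", terms),
    F = a[terms, "F value"],
    df_num = as.integer(a[terms, "Df"]),
    df_den = as.integer(a["Residuals", "Df"]),
    p = a[terms, "Pr(>F)"],
    partial_eta2 = a[terms, "Sum Sq"] / (a[terms, "Sum Sq"] + ss_res)
  )
  class(out) <- c("effect_table", class(out))
  out
}

#' Mixed demographic ANOVA and the age slope
#'
#' Split-plot analysis of mean area thickness with age (categorical
#' years) and gender as between-subject factors and visual area as the
#' within-subject factor. Between-subject effects (age, gender, their
#' interaction) are tested on the per-subject mean thickness (averaged
#' over areas) with type-II sums of squares; the within stratum reports
#' the visual-area main effect on the subject-centered data with the
#' balanced split-plot degrees of freedom. Eta-squared is reported
#' relative to the total of the corresponding stratum.
#'
#' Alongside the ANOVA, the per-year age slope is estimated as the mean
#' over areas of the least-squares slope of area mean thickness on age in
#' years (mm/year; negative = thinning).
#'
#' Subjects lacking any area mean are dropped (the split-plot stratum
#' algebra assumes each subject contributes every area). A single age
#' level skips the age effect with a warning.
#'
#' @param table An area thickness table.
#' @param roster Roster tibble with `id`, `age`, `gender`.
#' @return A list with `effects` (an `effect_table`) and `age_slope`
#'   (mm/year), plus `slopes` (the per-area slopes).
#' @export
demographics_anova <- function(table, roster) {
  stopifnot(all(c("id", "age", "gender") %in% names(roster)))
  tab <- dplyr::inner_join(
    table[, c("subject", "area", "mean_combined")],
    stats::setNames(roster[, c("id", "age", "gender")],
                    c("subject", "age", "gender")),
    by = "subject"
  )
  if (anyNA(tab$age) || anyNA(tab$gender)) {
    stop("ages and genders must be present for all subjects", call. = FALSE)
  }
  # keep complete subjects only (balanced within stratum)
  k <- length(unique(tab$area))
  tab <- tab[is.finite(tab$mean_combined), ]
  complete <- names(which(table(tab$subject) == k))
  tab <- tab[tab$subject %in% complete, ]

  subj <- tab |>
    dplyr::group_by(.data$subject, .data$age, .data$gender) |>
    dplyr::summarise(m = mean(.data$mean_combined), .groups = "drop")
  n_sub <- nrow(subj)

  one_age <- length(unique(subj$age)) < 2
  one_gender <- length(unique(subj$gender)) < 2
  if (one_age) warning("single age level; age effect skipped", call. = FALSE)

  form <- if (one_age && one_gender) NULL
  else if (one_age) stats::as.formula("m ~ gender")
  else if (one_gender) stats::as.formula("m ~ age_f")
  else stats::as.formula("m ~ age_f * gender")

  effects <- NULL
  if (!is.null(form)) {
    dat <- data.frame(m = subj$m, age_f = factor(subj$age),
                      gender = factor(subj$gender))
    fit <- stats::lm(form, data = dat)
    a2 <- car::Anova(fit, type = 2)
    terms <- setdiff(rownames(a2), "Residuals")
    ss_tot <- sum((dat$m - mean(dat$m))^2)
    effects <- tibble::tibble(
      effect = sub("age_f", "age", terms),
      F = a2[terms, "F value"],
      df_num = as.integer(a2[terms, "Df"]),
      df_den = as.integer(a2["Residuals", "Df"]),
      p = a2[terms, "Pr(>F)"],
      partial_eta2 = a2[terms, "Sum Sq"] / ss_tot
    )
  }

  # within stratum: visual-area main effect on subject-centered data
  centred <- tab |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(yc = .data$mean_combined - mean(.data$mean_combined)) |>
    dplyr::ungroup()
  area_means <- centred |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(m = mean(.data$yc), .groups = "drop")
  ss_area <- n_sub * sum(area_means$m^2)
  ss_within_tot <- sum(centred$yc^2)
  ss_err <- ss_within_tot - ss_area
  df_area <- k - 1L
  df_err <- as.integer(n_sub * (k - 1) - (k - 1))
  f_area <- (ss_area / df_area) / (ss_err / df_err)
  effects <- dplyr::bind_rows(
    effects,
    tibble::tibble(
      effect = "area", F = f_area, df_num = df_area, df_den = df_err,
      p = stats::pf(f_area, df_area, df_err, lower.tail = FALSE),
      partial_eta2 = ss_area / ss_within_tot
    )
  )
  class(effects) <- c("effect_table", class(effects))

  slopes <- tab |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(
      slope = stats::cov(.data$mean_combined, .data$age) / stats::var(.data$age),
      .groups = "drop"
    )

  list(effects = effects, age_slope = mean(slopes$slope), slopes = slopes)
}

#' @export
print.effect_table <- function(x, ...) {
  cat("<effect_table>\n")
  print(tibble::as_tibble(x))
  invisible(x)
}
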