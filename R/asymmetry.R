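#' Two-way absolute-agreement single-score ICC
#'
#' Computes ICC(A,1) (two-way random effects, absolute agreement, single
#' measure) from the two-way ANOVA mean squares of an n x k table of
#' paired measurements:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with rows = measurement units and columns = raters (here hemispheres or
#' paired subjects).
#'
#' @param m Numeric matrix, rows = units, k >= 2 columns.
#' @return An object of class `icc_result`: `icc`, the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_err`), variance components, `n`, `k`.
#' @export
#' @examples
#' m <- cbind(c(2.0, 2.1, 2.3, 2.2), c(2.1, 2.0, 2.4, 2.2))
#' icc_a1(m)$icc
icc_a1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 rows and >= 2 columns", call. = FALSE)
  ss <- icc_ss_from_sums(
    col_sum = colSums(m), col_sumsq = colSums(m^2),
    row_pair_sumsq = sum(rowSums(m)^2), n = n, k = k
  )
  icc_from_ss(ss)
}

# ANOVA sums of squares from sufficient statistics, so the all-pairs
# between-subject ICC never materialises its (huge) row table.
icc_ss_from_sums <- function(col_sum, col_sumsq, row_pair_sumsq, n, k) {
  grand <- sum(col_sum) / (n * k)
  ss_total <- sum(col_sumsq) - n * k * grand^2
  ss_rows <- row_pair_sumsq / k - n * k * grand^2
  ss_cols <- n * sum((col_sum / n - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  list(ss_rows = ss_rows, ss_cols = ss_cols, ss_err = ss_err, n = n, k = k)
}

icc_from_ss <- function(ss) {
  n <- ss$n; k <- ss$k
  ms_rows <- ss$ss_rows / (n - 1)
  ms_cols <- ss$ss_cols / (k - 1)
  ms_err <- ss$ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  icc <- if (denom <= 0) NA_real_ else (ms_rows - ms_err) / denom
  structure(
    list(
      icc = icc,
      ms_rows = ms_rows, ms_cols = ms_cols, ms_err = ms_err,
      var_rows = max(0, (ms_rows - ms_err) / k),
      var_cols = max(0, (ms_cols - ms_err) / n),
      var_err = ms_err,
      n = n, k = k
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ICC(A,1) =", round(x$icc, 4),
      sprintf("(n = %d, k = %d)\n", x$n, x$k))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ms_rows = x$ms_rows, ms_cols = x$ms_cols, ms_err = x$ms_err,
    var_rows = x$var_rows, var_cols = x$var_cols, var_err = x$var_err,
    n = x$n, k = x$k
  )
}

#' Within-subject hemispheric agreement (ICC)
#'
#' Agreement between the left and right hemisphere mean thickness within
#' subjects: ICC(A,1) over the pooled subject x area rows (each row one
#' subject-area, columns = L/R). Set `per_area = TRUE` for one ICC per
#' area instead of the pooled value.
#'
#' @param table An area thickness table (needs `mean_L`, `mean_R`).
#' @param per_area Report per-area ICCs instead of the pooled one.
#' @return An `icc_result`, or a tibble of per-area results when
#'   `per_area = TRUE`.
#' @export
icc_within <- function(table, per_area = FALSE) {
  ok <- stats::complete.cases(table$mean_L, table$mean_R)
  tab <- table[ok, , drop = FALSE]
  if (per_area) {
    return(tab |>
             dplyr::group_by(.data$area) |>
             dplyr::group_modify(~ tidy.icc_result(icc_a1(cbind(.x$mean_L, .x$mean_R)))) |>
             dplyr::ungroup())
  }
  icc_a1(cbind(tab$mean_L, tab$mean_R))
}

#' Between-subject hemispheric agreement (ICC)
#'
#' Agreement of matched-hemisphere mean thickness between *different*
#' subjects: for each hemisphere, every distinct unordered subject pair
#' contributes one row per area (columns = the two subjects' values), the
#' ICC(A,1) is computed over all such rows, and the left- and right-
#' hemisphere results are averaged. Computed from accumulated sufficient
#' statistics, so no pair table is materialised.
#'
#' @param table An area thickness table (needs `subject`, `area`,
#'   `mean_L`, `mean_R`).
#' @return A list with `icc` (the L/R average), `icc_L`, `icc_R` (each an
#'   `icc_result`).
#' @export
icc_between <- function(table) {
  one_hemi <- function(values) {
    wide <- tidyr::pivot_wider(values, names_from = "area", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    ns <- nrow(m)
    if (ns < 3) stop("need >= 3 subjects", call. = FALSE)
    pairs <- utils::combn(ns, 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    col_sum <- c(0, 0); col_sumsq <- c(0, 0); rp <- 0; n <- 0
    for (a in seq_len(ncol(m))) {
      x <- m[, a]
      x1 <- x[i]; x2 <- x[j]
      keep <- !is.na(x1) & !is.na(x2)
      x1 <- x1[keep]; x2 <- x2[keep]
      col_sum <- col_sum + c(sum(x1), sum(x2))
      col_sumsq <- col_sumsq + c(sum(x1^2), sum(x2^2))
      rp <- rp + sum((x1 + x2)^2)
      n <- n + length(x1)
    }
    icc_from_ss(icc_ss_from_sums(col_sum, col_sumsq, rp, n = n, k = 2))
  }
  left <- one_hemi(stats::setNames(
    table[, c("subject", "area", "mean_L")], c("subject", "area", "value")))
  right <- one_hemi(stats::setNames(
    table[, c("subject", "area", "mean_R")], c("subject", "area", "value")))
  list(icc = mean(c(left$icc, right$icc)), icc_L = left, icc_R = right)
}

#' Per-area hemispheric bias with tests and effect sizes
#'
#' The hemispheric bias is each subject's left-minus-right mean thickness
#' in an area (positive = thicker left cortex). Per area this computes the
#' mean bias, a one-sample t-test of the bias distribution against zero,
#' Benjamini-Hochberg FDR adjustment across areas, the one-sample Cohen's
#' d (mean difference / SD of differences), and an effect-size category:
#' `large` for |d| > 0.8, `medium_to_large` for 0.3 < |d| <= 0.8,
#' `negligible` otherwise.
#'
#' @param table An area thickness table (needs `area`, `mean_L`, `mean_R`).
#' @param alpha FDR level for the `significant` flag.
#' @return A tibble (class `bias_table`) with `area`, `n`, `bias_mm`, `t`,
#'   `p`, `q`, `d`, `category`, `significant`.
#' @export
hemispheric_bias <- function(table, alpha = 0.05) {
  out <- table |>
    dplyr::filter(!is.na(.data$mean_L), !is.na(.data$mean_R)) |>
    dplyr::mutate(diff = .data$mean_L - .data$mean_R) |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias_mm = mean(.data$diff),
      sd_diff = stats::sd(.data$diff),
      .groups = "drop"
    )
  if (any(out$n < 3)) {
    stop("need >= 3 subjects with both hemisphere means per area", call. = FALSE)
  }
  zero_var <- !is.na(out$sd_diff) & out$sd_diff == 0
  if (any(zero_var)) {
    warning("zero-variance differences in: ",
            paste(out$area[zero_var], collapse = ", "), call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(
      t = ifelse(.data$sd_diff > 0,
                 .data$bias_mm / (.data$sd_diff / sqrt(.data$n)), NA_real_),
      p = 2 * stats::pt(-abs(.data$t), df = .data$n - 1),
      d = ifelse(.data$sd_diff > 0, .data$bias_mm / .data$sd_diff, NA_real_)
    ) |>
    dplyr::mutate(
      q = stats::p.adjust(.data$p, method = "BH"),
      category = dplyr::case_when(
        abs(.data$d) > 0.8 ~ "large",
        abs(.data$d) > 0.3 ~ "medium_to_large",
        TRUE ~ "negligible"
      ),
      significant = .data$q < alpha
    ) |>
    dplyr::select(-"sd_diff") |>
    dplyr::arrange(match(.data$area, visual_area_names()))
  class(out) <- c("bias_table", class(out))
  out
}
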