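#' Fit a one-dimensional Gaussian to area thickness values
#'
#' Estimates the normative Gaussian parameters by sample moments: `mu` is
#' the sample mean and `sigma` the sample SD (n-1 denominator; maximum
#' likelihood up to the n/(n-1) factor). A degenerate fit (all values
#' identical) returns `sigma = 0` with `degenerate = TRUE`.
#'
#' @param values Numeric vector of thickness values (mm), at least 3
#'   finite values.
#' @return A list with `mu`, `sigma`, `n`, `degenerate`.
#' @export
#' @examples
#' fit_gaussian(c(1, 2, 3))
fit_gaussian <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite values", call. = FALSE)
  mu <- mean(values)
  sigma <- stats::sd(values)
  list(mu = mu, sigma = sigma, n = length(values),
       degenerate = sigma == 0)
}

#' Binned coefficient of determination of a Gaussian fit
#'
#' Goodness of fit of a Gaussian model to an empirical distribution,
#' computed over `n_bins` equally spaced bins spanning the data range.
#' The empirical density in each bin is `count / (n * width)`; the model
#' density is the Gaussian probability mass of the bin divided by its
#' width (CDF differences; set `midpoint = TRUE` to instead evaluate the
#' density at bin midpoints). The statistic is `1 - SS_res / SS_tot` over
#' bins, with `SS_tot` about the mean empirical density; it can be
#' negative for pathological fits.
#'
#' @param values Numeric vector (mm).
#' @param mu,sigma Gaussian parameters; `sigma` must be > 0.
#' @param n_bins Number of bins (>= 2), default 100.
#' @param midpoint Use midpoint density evaluation instead of CDF
#'   differences (sensitivity variant).
#' @return The binned R-squared (unitless).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(960, 2.02, 0.12)
#' binned_r2(x, mean(x), sd(x))
binned_r2 <- function(values, mu, sigma, n_bins = 100, midpoint = FALSE) {
  values <- values[is.finite(values)]
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  breaks <- seq(min(values), max(values), length.out = n_bins + 1)
  width <- (max(values) - min(values)) / n_bins
  if (width == 0) stop("degenerate data range", call. = FALSE)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  emp <- counts / (length(values) * width)
  model <- if (midpoint) {
    stats::dnorm((breaks[-1] + breaks[-(n_bins + 1)]) / 2, mu, sigma)
  } else {
    diff(stats::pnorm(breaks, mu, sigma)) / width
  }
  1 - sum((emp - model)^2) / sum((emp - mean(emp))^2)
}

#' Anderson-Darling normality screen across areas with FDR control
#'
#' Applies the Anderson-Darling test for composite normality (parameters
#' estimated from the data, small-sample-adjusted p approximation) to each
#' area's values, then adjusts p-values across areas by Benjamini-Hochberg.
#' An area is called `normal` when its adjusted p is at or above `alpha`.
#' Areas with fewer than 8 values are skipped with a warning.
#'
#' @param values_by_area Named list (or tibble with `area` and `value`
#'   columns) of per-area numeric vectors.
#' @param alpha FDR level (default 0.05).
#' @return A tibble with `area`, `n`, `ad_stat`, `p`, `q`, `normal`.
#' @export
test_normality <- function(values_by_area, alpha = 0.05) {
  if (is.data.frame(values_by_area)) {
    values_by_area <- split(values_by_area$value, values_by_area$area)
  }
  areas <- names(values_by_area)
  res <- purrr::map(values_by_area, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 8) return(NULL)
    ad <- nortest::ad.test(x)
    tibble::tibble(n = length(x), ad_stat = unname(ad$statistic),
                   p = unname(ad$p.value))
  })
  skipped <- areas[purrr::map_lgl(res, is.null)]
  if (length(skipped) > 0) {
    warning("areas skipped (fewer than 8 values): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(res, .id = "area")
  if (nrow(out) == 0) {
    return(tibble::tibble(area = character(), n = integer(),
                          ad_stat = numeric(), p = numeric(),
                          q = numeric(), normal = logical()))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$normal <- out$q >= alpha
  out
}

#' Build the per-area normative table from a thickness table
#'
#' For each area: Gaussian parameters by [fit_gaussian()], goodness of fit
#' by [binned_r2()], and the Anderson-Darling/FDR normality call by
#' [test_normality()]; plus quantile-quantile data of the sample against
#' the fitted Gaussian.
#'
#' @param table An area thickness table from [sample_area_thickness()].
#' @param n_bins Bins for the binned R-squared (default 100).
#' @param alpha FDR level for the normality screen.
#' @return An object of class `normative_table`: a tibble with one row per
#'   area (`area`, `n`, `mean_mm`, `sd_mm`, `r2`, `ad_stat`, `p`, `q`,
#'   `normal`), with the QQ tibble in attribute `"qq"` (see [qq_points()]).
#' @export
build_normative_table <- function(table, n_bins = 100, alpha = 0.05) {
  vals <- split(table$mean_combined, table$area)
  vals <- vals[order(match(names(vals), visual_area_names()))]
  fits <- purrr::imap(vals, function(x, a) {
    x <- x[is.finite(x)]
    if (length(x) < 3) stop("area ", a, " has fewer than 3 subjects", call. = FALSE)
    f <- fit_gaussian(x)
    tibble::tibble(
      area = a, n = f$n, mean_mm = f$mu, sd_mm = f$sigma,
      r2 = if (f$sigma > 0) binned_r2(x, f$mu, f$sigma, n_bins) else NA_real_
    )
  })
  out <- dplyr::bind_rows(fits)
  norm <- test_normality(vals, alpha = alpha)
  out <- dplyr::left_join(out, norm[, c("area", "ad_stat", "p", "q", "normal")],
                          by = "area")
  qq <- purrr::imap(vals, function(x, a) qq_points(x, mean(x), stats::sd(x))) |>
    dplyr::bind_rows(.id = "area")
  structure(out, class = c("normative_table", class(out)), qq = qq)
}

#' Quantile-quantile data against a Gaussian
#'
#' @param values Numeric vector.
#' @param mu,sigma Gaussian parameters.
#' @return Tibble with ascending `theoretical` and `sample` quantiles (mm).
#' @export
qq_points <- function(values, mu, sigma) {
  x <- sort(values[is.finite(values)])
  tibble::tibble(
    theoretical = stats::qnorm(stats::ppoints(length(x)), mu, sigma),
    sample = x
  )
}

#' Z-score subjects against a normative reference
#'
#' Standardises each subject x area mean thickness against a normative
#' table: `z = (mean_combined - mu) / sigma`. This is the package's
#' deployment operation: comparing new individuals to the packaged healthy
#' reference range.
#'
#' @param subject_rows Area thickness rows for the subjects to score
#'   (needs `subject`, `area`, `mean_combined`).
#' @param reference A normative table: either a `normative_table` or any
#'   tibble with `area`, `mean_mm`, `sd_mm` (default: the packaged
#'   [reference_normative_table()]).
#' @return The input rows with `mu`, `sigma` and `z` columns appended.
#' @export
#' @examples
#' rows <- tibble::tibble(subject = "s1", area = "V1d", mean_combined = 2.14)
#' zscore_areas(rows)$z  # 1.0
zscore_areas <- function(subject_rows, reference = reference_normative_table()) {
  unknown <- setdiff(unique(subject_rows$area), reference$area)
  if (length(unknown) > 0) {
    stop("unknown area name(s): ", paste(unknown, collapse = ", "),
         "; valid areas are: ", paste(reference$area, collapse = ", "),
         call. = FALSE)
  }
  i <- match(subject_rows$area, reference$area)
  sigma <- reference$sd_mm[i]
  if (any(sigma <= 0, na.rm = TRUE)) {
    stop("reference sigma must be > 0 for all queried areas", call. = FALSE)
  }
  dplyr::mutate(subject_rows,
                mu = reference$mean_mm[i],
                sigma = sigma,
                z = (.data$mean_combined - .data$mu) / .data$sigma)
}
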