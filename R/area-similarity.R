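#' Inter-areal correlation matrix of mean thickness
#'
#' Correlates each pair of areas' per-subject mean thickness across
#' subjects (Pearson), giving the area x area similarity structure that
#' reflects shared thickness variation along the visual hierarchy.
#' Subjects with an undefined mean in an area are dropped pairwise.
#' Zero-variance areas yield `NA` entries with a warning.
#'
#' @param table An area thickness table from [sample_area_thickness()].
#' @return A symmetric correlation matrix (class `area_corr`) with unit
#'   diagonal, rows/columns in the canonical area order present in the
#'   table.
#' @export
correlation_matrix <- function(table) {
  wide <- tidyr::pivot_wider(table[, c("subject", "area", "mean_combined")],
                             names_from = "area", values_from = "mean_combined")
  m <- as.matrix(wide[, -1, drop = FALSE])
  ord <- order(match(colnames(m), visual_area_names()))
  m <- m[, ord, drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("zero-variance area(s): ",
            paste(colnames(m)[which(sds == 0)], collapse = ", "),
            call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  structure(r, class = c("area_corr", "matrix"))
}

#' @export
print.area_corr <- function(x, ...) {
  cat("<area_corr>", ncol(x), "areas; mean off-diagonal r =",
      round(mean(x[upper.tri(x)], na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Tidy an inter-areal correlation matrix
#'
#' @param x An `area_corr`.
#' @param ... Unused.
#' @return Long tibble with `area1`, `area2`, `r`.
#' @export
tidy.area_corr <- function(x, ...) {
  tibble::tibble(
    area1 = rep(rownames(x), times = ncol(x)),
    area2 = rep(colnames(x), each = nrow(x)),
    r = as.vector(unclass(x))
  )
}

#' Agglomerative clustering of the inter-areal correlation matrix
#'
#' Converts correlations to distances (`d = 1 - r` by default; see
#' `distance` for the alternative convention), builds a
#' complete-linkage ("fully connected")
#' agglomerative tree, and cuts it at a percentile of the merge heights
#' (default the 50th, linear-interpolation percentile over the n-1 merge
#' heights) to obtain flat clusters.
#'
#' @param corr An `area_corr` with no undefined entries.
#' @param cut_percentile Percentile of linkage heights at which to cut
#'   (0--100, default 50).
#' @param distance Either `"one_minus_r"` (default) or `"neg_r"`
#'   (clusters on `-r` shifted to be non-negative), exposed for
#'   sensitivity analysis of the distance convention.
#' @return An object of class `area_clusters`: list with `hclust` (the
#'   tree), `merges` (tibble of merge pairs and heights), `cut_height`,
#'   and `clusters` (named integer vector of flat assignments).
#' @export
cluster_areas <- function(corr, cut_percentile = 50,
                          distance = c("one_minus_r", "neg_r")) {
  distance <- match.arg(distance)
  if (anyNA(corr)) {
    stop("correlation matrix has undefined entries; drop those areas first",
         call. = FALSE)
  }
  d <- if (distance == "one_minus_r") 1 - corr else max(corr) - corr
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cut_height <- unname(stats::quantile(hc$height, cut_percentile / 100))
  clusters <- stats::cutree(hc, h = cut_height)
  structure(
    list(
      hclust = hc,
      merges = tibble::tibble(
        step = seq_len(nrow(hc$merge)),
        node1 = hc$merge[, 1],
        node2 = hc$merge[, 2],
        height = hc$height
      ),
      cut_height = cut_height,
      cut_percentile = cut_percentile,
      clusters = clusters
    ),
    class = "area_clusters"
  )
}

#' @export
print.area_clusters <- function(x, ...) {
  k <- length(unique(x$clusters))
  cat("<area_clusters>", length(x$clusters), "areas in", k,
      "flat clusters (cut height", round(x$cut_height, 3), ")\n")
  invisible(x)
}

#' @export
tidy.area_clusters <- function(x, ...) {
  tibble::tibble(area = names(x$clusters), cluster = unname(x$clusters))
}

#' @export
glance.area_clusters <- function(x, ...) {
  tibble::tibble(
    n_areas = length(x$clusters),
    n_clusters = length(unique(x$clusters)),
    cut_height = x$cut_height,
    max_height = max(x$hclust$height)
  )
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths carry the complete-linkage merge heights (via
#' [ape::as.phylo()] on the underlying tree).
#'
#' @param clusters An `area_clusters`.
#' @return A Newick string.
#' @export
cluster_newick <- function(clusters) {
  ape::write.tree(ape::as.phylo(clusters$hclust))
}
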