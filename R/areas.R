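#' Canonical visual area labels
#'
#' The 25 retinotopic visual areas used throughout the package, in the
#' canonical label order (label ids 1--25). The order is fixed so that
#' maximum probability maps, correlation matrices and report tables are
#' comparable across runs.
#'
#' @return Character vector of 25 area names.
#' @export
#' @examples
#' visual_area_names()
visual_area_names <- function() {
  c("V1v", "V1d", "V2v", "V2d", "V3v", "V3d", "hV4", "VO1", "VO2",
    "PHC1", "PHC2", "V3A", "V3B", "LO1", "LO2", "TO1", "TO2",
    "IPS0", "IPS1", "IPS2", "IPS3", "IPS4", "IPS5", "SPL1", "FEF")
}

#' Stream/group membership of the visual areas
#'
#' Assigns each canonical area to one of four anatomical groups used by the
#' latent-factor cohort generator: the ventral and dorsal visual streams,
#' the dorsal-parietal (IPS/SPL/FEF) group, and the parahippocampal group.
#' V1v and V1d are carried with their respective streams.
#'
#' @return A tibble with columns `area` and `group`.
#' @export
area_groups <- function() {
  grp <- c(
    V1v = "ventral", V1d = "dorsal",
    V2v = "ventral", V2d = "dorsal", V3v = "ventral", V3d = "dorsal",
    hV4 = "ventral", VO1 = "ventral", VO2 = "ventral",
    PHC1 = "parahippocampal", PHC2 = "parahippocampal",
    V3A = "dorsal", V3B = "dorsal", LO1 = "dorsal", LO2 = "dorsal",
    TO1 = "dorsal", TO2 = "dorsal",
    IPS0 = "parietal", IPS1 = "parietal", IPS2 = "parietal",
    IPS3 = "parietal", IPS4 = "parietal", IPS5 = "parietal",
    SPL1 = "parietal", FEF = "parietal"
  )
  tibble::tibble(area = visual_area_names(), group = unname(grp[visual_area_names()]))
}

#' Packaged reference normative table
#'
#' The packaged normative reference for curvature-corrected cortical
#' thickness in 25 visual areas: per-area Gaussian mean and standard
#' deviation (mm) across 960 healthy young adults, together with the
#' binned coefficient of determination of the Gaussian fit. New subjects
#' can be compared against this table with [zscore_areas()].
#'
#' @return A tibble with columns `area`, `mean_mm`, `sd_mm`, `r2`.
#' @export
#' @examples
#' reference_normative_table()
reference_normative_table <- function() {
  tbl <- tibble::tribble(
    ~area, ~mean_mm, ~sd_mm, ~r2,
    "V1d", 2.02, 0.12, 0.93,
    "V1v", 1.93, 0.12, 0.92,
    "V2d", 2.03, 0.12, 0.92,
    "V3d", 2.17, 0.11, 0.90,
    "V3A", 2.24, 0.12, 0.91,
    "V3B", 2.42, 0.12, 0.90,
    "LO1", 2.37, 0.11, 0.91,
    "LO2", 2.49, 0.12, 0.91,
    "TO1", 2.55, 0.12, 0.91,
    "TO2", 2.60, 0.17, 0.91,
    "V2v", 2.14, 0.13, 0.93,
    "V3v", 2.44, 0.12, 0.88,
    "hV4", 2.56, 0.12, 0.90,
    "VO1", 2.70, 0.16, 0.92,
    "VO2", 2.70, 0.14, 0.91,
    "IPS0", 2.39, 0.10, 0.93,
    "IPS1", 2.35, 0.12, 0.91,
    "IPS2", 2.31, 0.13, 0.83,
    "IPS3", 2.28, 0.13, 0.82,
    "SPL1", 2.30, 0.15, 0.88,
    "IPS4", 2.29, 0.15, 0.87,
    "IPS5", 2.29, 0.18, 0.91,
    "FEF", 2.75, 0.18, 0.87,
    "PHC1", 2.77, 0.17, 0.90,
    "PHC2", 2.68, 0.20, 0.87
  )
  # reorder to the canonical label order
  tbl[match(visual_area_names(), tbl$area), ]
}
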