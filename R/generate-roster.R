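#' Generate a synthetic participant roster
#'
#' Builds a cohort roster with the demographic and twin structure assumed
#' by the downstream selection and modeling stages: unique subject ids,
#' integer ages drawn uniformly on the configured range, genders drawn to
#' approximate the configured female:male ratio, monozygotic and dizygotic
#' twin pairs sharing a `twin_pair_id`, and the two data-completeness
#' eligibility flags (all `TRUE` by default).
#'
#' @param config A [generator_config()].
#' @return A tibble (the cohort roster) with columns `id`, `age`, `gender`,
#'   `twin_pair_id`, `zygosity`, `has_complete_structural`, `has_msmall`.
#' @export
#' @examples
#' roster <- generate_roster(generator_config(n_subjects = 8, n_mz_pairs = 1,
#'                                            n_dz_pairs = 1, seed = 42))
#' table(roster$zygosity)
generate_roster <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  withr::with_seed(config$seed, {
    id <- sprintf("sub-%04d", seq_len(n))
    age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
    p_female <- config$female_per_male / (1 + config$female_per_male)
    gender <- ifelse(stats::runif(n) < p_female, "female", "male")

    zygosity <- rep("not_twin", n)
    twin_pair_id <- rep(NA_character_, n)
    i <- 1L
    if (config$n_mz_pairs > 0) {
      for (p in seq_len(config$n_mz_pairs)) {
        zygosity[c(i, i + 1L)] <- "MZ"
        twin_pair_id[c(i, i + 1L)] <- sprintf("MZ%03d", p)
        i <- i + 2L
      }
    }
    if (config$n_dz_pairs > 0) {
      for (p in seq_len(config$n_dz_pairs)) {
        zygosity[c(i, i + 1L)] <- "DZ"
        twin_pair_id[c(i, i + 1L)] <- sprintf("DZ%03d", p)
        i <- i + 2L
      }
    }
    # twins share household -> same age, makes pairs look like real twins
    if (i > 1L) {
      pair_first <- seq(1L, i - 2L, by = 2L)
      age[pair_first + 1L] <- age[pair_first]
    }

    tibble::tibble(
      id = id,
      age = as.integer(age),
      gender = gender,
      twin_pair_id = twin_pair_id,
      zygosity = zygosity,
      has_complete_structural = TRUE,
      has_msmall = TRUE
    )
  })
}

#' Read / write a roster CSV
#'
#' @param path File path.
#' @param roster A roster tibble as returned by [generate_roster()].
#' @return `read_roster()` returns the roster tibble; `write_roster()`
#'   returns `path` invisibly.
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster, path, na = "")
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      age = readr::col_integer(),
      gender = readr::col_character(),
      twin_pair_id = readr::col_character(),
      zygosity = readr::col_character(),
      has_complete_structural = readr::col_logical(),
      has_msmall = readr::col_logical()
    ),
    na = ""
  )
}
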