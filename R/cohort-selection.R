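#' Apply cohort inclusion criteria and the one-per-MZ-pair rule
#'
#' Filters a roster down to the analysis cohort using three criteria:
#' (1) a complete structural protocol (`has_complete_structural`),
#' (2) multimodal surface registration available (`has_msmall`), and
#' (3) no monozygotic co-twin also present. When both members of an MZ
#' pair pass criteria (1) and (2), the one with the lexicographically
#' smaller id is retained and the other excluded; if one member already
#' fails (1) or (2), the survivor is retained with no extra exclusion.
#' Dizygotic pairs and unconfirmed self-reported twins are always
#' retained (subject to criteria 1--2). The result is deterministic.
#'
#' @param roster A roster tibble (see [generate_roster()]).
#' @return An object of class `selection_result`: list with `retained`
#'   (roster tibble) and `excluded` (tibble of `id`, `reason`, where
#'   reason is one of `incomplete_structural`, `no_msmall`,
#'   `mz_twin_duplicate`).
#' @export
#' @examples
#' r <- generate_roster(generator_config(n_subjects = 10, n_mz_pairs = 2,
#'                                       n_dz_pairs = 1, seed = 7))
#' sel <- select_participants(r)
#' nrow(sel$retained)
select_participants <- function(roster) {
  stopifnot(all(c("id", "twin_pair_id", "zygosity",
                  "has_complete_structural", "has_msmall") %in% names(roster)))
  if (anyDuplicated(roster$id)) stop("roster ids must be unique", call. = FALSE)
  pair_sizes <- table(roster$twin_pair_id[!is.na(roster$twin_pair_id)])
  if (any(pair_sizes > 2)) {
    stop("malformed twin structure: a twin_pair_id is shared by more than 2 records",
         call. = FALSE)
  }

  excluded <- tibble::tibble(id = character(), reason = character())

  fail1 <- !roster$has_complete_structural
  fail2 <- roster$has_complete_structural & !roster$has_msmall
  excluded <- dplyr::bind_rows(
    excluded,
    tibble::tibble(id = roster$id[fail1], reason = "incomplete_structural"),
    tibble::tibble(id = roster$id[fail2], reason = "no_msmall")
  )
  eligible <- roster[!(fail1 | fail2), , drop = FALSE]

  mz <- eligible[eligible$zygosity == "MZ" & !is.na(eligible$twin_pair_id), ]
  if (nrow(mz) > 0) {
    full_pairs <- names(which(table(mz$twin_pair_id) == 2))
    drop_ids <- vapply(full_pairs,
                       function(p) max(mz$id[mz$twin_pair_id == p]),
                       character(1), USE.NAMES = FALSE)
    excluded <- dplyr::bind_rows(
      excluded,
      tibble::tibble(id = drop_ids, reason = "mz_twin_duplicate")
    )
    eligible <- eligible[!(eligible$id %in% drop_ids), , drop = FALSE]
  }

  # keep the original roster order in both partitions
  excluded <- excluded[order(match(excluded$id, roster$id)), , drop = FALSE]
  structure(list(retained = eligible, excluded = excluded),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", nrow(x$retained), "retained,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded) > 0) print(table(x$excluded$reason))
  invisible(x)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x$retained) + nrow(x$excluded),
    n_retained = nrow(x$retained),
    n_excluded = nrow(x$excluded),
    n_mz_twin_duplicate = sum(x$excluded$reason == "mz_twin_duplicate")
  )
}
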