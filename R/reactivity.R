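#' Read an ELISpot reactivity table
#'
#' The on-disk format is a TSV with one row per T cell clone: a `clone_id`
#' column, one column of mean spot-forming-cell (SFC) counts per target
#' animal, a `background` column (mean SFC of the autologous / no-target
#' control wells) and an optional `background_sd` column (taken as 0 when
#' absent).
#'
#' @param path Path to the TSV file.
#' @return A long tibble with columns `clone_id`, `target_id`, `sfc`,
#'   `background_mean`, `background_sd`.
#' @export
read_reactivity <- function(path) {
  assert_that(file.exists(path), sprintf("reactivity table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(raw)
  assert_that(nrow(probs) == 0,
              sprintf("malformed reactivity table (row %s): ragged or non-numeric",
                      paste(unique(probs$row), collapse = ",")))
  assert_that("clone_id" %in% names(raw), "reactivity table needs a clone_id column")
  assert_that("background" %in% names(raw), "reactivity table needs a background column")
  targets <- setdiff(names(raw), c("clone_id", "background", "background_sd"))
  assert_that(nrow(raw) > 0 && length(targets) > 0, "empty table")
  num_cols <- c(targets, "background", intersect("background_sd", names(raw)))
  assert_that(all(vapply(raw[num_cols], is.numeric, logical(1))),
              "reactivity counts must be numeric")
  out <- raw |>
    dplyr::rename(background_mean = "background") |>
    tidyr::pivot_longer(dplyr::all_of(targets),
                        names_to = "target_id", values_to = "sfc")
  if (!"background_sd" %in% names(out)) out$background_sd <- 0
  out <- dplyr::select(out, "clone_id", "target_id", "sfc",
                       "background_mean", "background_sd")
  validate_reactivity(out)
}

#' Write a reactivity table to TSV (inverse of [read_reactivity()])
#'
#' @param reactivity A long reactivity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactivity <- function(reactivity, path) {
  validate_reactivity(reactivity)
  wide <- reactivity |>
    tidyr::pivot_wider(names_from = "target_id", values_from = "sfc") |>
    dplyr::rename(background = "background_mean")
  wide <- dplyr::relocate(wide, "background", "background_sd",
                          .after = dplyr::last_col())
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Validate a long reactivity tibble
#' @param reactivity Candidate tibble.
#' @return The tibble, invisibly.
#' @export
validate_reactivity <- function(reactivity) {
  need <- c("clone_id", "target_id", "sfc", "background_mean", "background_sd")
  assert_that(all(need %in% names(reactivity)),
              sprintf("reactivity table lacks columns: %s",
                      paste(setdiff(need, names(reactivity)), collapse = ", ")))
  assert_that(nrow(reactivity) > 0, "empty table")
  assert_that(!anyNA(reactivity$sfc) && !anyNA(reactivity$background_mean),
              "reactivity counts must be numeric and complete")
  assert_that(all(reactivity$sfc >= 0) && all(reactivity$background_mean >= 0) &&
                all(reactivity$background_sd >= 0),
              "spot counts must be non-negative")
  invisible(reactivity)
}

#' Positivity thresholds for ELISpot well calls
#'
#' A well is positive when its SFC count reaches *all* of three thresholds
#' (their maximum): a fold change over the background mean, the background
#' mean plus a multiple of the background SD, and an absolute floor. The
#' defaults (3x background, +3 SD, floor of 20 SFC) are deliberately
#' conservative for ELISpot-scale counts; all three are configurable.
#'
#' @param fold_over_background Minimum ratio to background mean.
#' @param sd_multiplier Number of background SDs above the background mean.
#' @param absolute_floor Minimum SFC count regardless of background.
#' @return A `positivity_params` list.
#' @export
positivity_params <- function(fold_over_background = 3,
                              sd_multiplier = 3,
                              absolute_floor = 20) {
  assert_that(fold_over_background > 0 && sd_multiplier > 0 && absolute_floor > 0,
              "positivity parameters must be strictly positive")
  structure(
    list(fold_over_background = fold_over_background,
         sd_multiplier = sd_multiplier,
         absolute_floor = absolute_floor),
    class = "positivity_params"
  )
}

#' Binary positivity call for one or more ELISpot wells
#'
#' @param sfc Spot-forming-cell count(s).
#' @param background_mean,background_sd Background well mean and SD
#'   (recycled against `sfc`).
#' @param params A [positivity_params()] object.
#' @return Logical vector: `TRUE` where the well is positive.
#' @export
#' @examples
#' call_well(150, background_mean = 5, background_sd = 2) # TRUE
call_well <- function(sfc, background_mean, background_sd = 0,
                      params = positivity_params()) {
  assert_that(all(sfc >= 0) && all(background_mean >= 0) && all(background_sd >= 0),
              "spot counts must be non-negative")
  thr <- pmax(
    background_mean * params$fold_over_background,
    background_mean + params$sd_multiplier * background_sd,
    params$absolute_floor
  )
  sfc >= thr
}

#' Add binary positivity calls to a reactivity tibble
#'
#' @param reactivity A long reactivity tibble ([read_reactivity()]).
#' @param params A [positivity_params()] object.
#' @return The input with a logical `positive` column appended.
#' @export
call_reactivity <- function(reactivity, params = positivity_params()) {
  validate_reactivity(reactivity)
  dplyr::mutate(reactivity, positive = call_well(
    .data$sfc, .data$background_mean, .data$background_sd, params
  ))
}

#' Derive mHAg-positive / mHAg-negative groupings per clone
#'
#' Binarizes each clone's wells with [call_well()] and splits its target
#' animals into the mHAg-positive group (positive wells) and the
#' mHAg-negative group (the remainder). Clones whose positive or negative
#' group is empty carry no genetic contrast and are flagged unmappable; by
#' default they are kept in the output (with a warning) so that callers can
#' report them, and dropped by downstream segregation.
#'
#' @param reactivity A long reactivity tibble.
#' @param clone_ids Clones to group; defaults to every clone in the table.
#' @param params A [positivity_params()] object.
#' @return A tibble with one row per clone: `clone_id`, list-columns
#'   `pos_animals` and `neg_animals` (sorted character vectors), and a
#'   logical `mappable` flag.
#' @export
derive_groupings <- function(reactivity, clone_ids = NULL,
                             params = positivity_params()) {
  called <- call_reactivity(reactivity, params)
  all_clones <- unique(called$clone_id)
  clone_ids <- clone_ids %||% all_clones
  unknown <- setdiff(clone_ids, all_clones)
  assert_that(length(unknown) == 0,
              sprintf("unknown clone id(s): %s", paste(unknown, collapse = ", ")))
  out <- called |>
    dplyr::filter(.data$clone_id %in% clone_ids) |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      pos_animals = list(sort(.data$target_id[.data$positive])),
      neg_animals = list(sort(.data$target_id[!.data$positive])),
      .groups = "drop"
    ) |>
    dplyr::mutate(mappable = lengths(.data$pos_animals) > 0 &
                    lengths(.data$neg_animals) > 0) |>
    dplyr::arrange(match(.data$clone_id, clone_ids))
  n_bad <- sum(!out$mappable)
  if (n_bad > 0) {
    warning(sprintf("%d clone(s) unmappable (empty positive or negative group): %s",
                    n_bad, paste(out$clone_id[!out$mappable], collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Report duplicate binary reactivity patterns across clones
#'
#' Clones are partitioned into equivalence classes by identical
#' mHAg-positive animal sets; clones sharing a pattern plausibly recognise
#' the same antigen and are reported as duplicates.
#'
#' @param groupings A groupings tibble from [derive_groupings()].
#' @return The groupings with `pattern_id` (dense class index),
#'   `pattern` (";"-joined positive set) and `n_clones_with_pattern` added.
#' @export
pattern_report <- function(groupings) {
  assert_that(nrow(groupings) >= 1, "need at least one grouping")
  out <- groupings |>
    dplyr::mutate(pattern = purrr::map_chr(.data$pos_animals,
                                           paste, collapse = ";")) |>
    dplyr::group_by(.data$pattern) |>
    dplyr::mutate(n_clones_with_pattern = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(pattern_id = dplyr::dense_rank(.data$pattern))
  out
}

#' Write / read clone groupings as TSV
#'
#' Columns: `clone_id`, `pos_animals` and `neg_animals` (";"-joined),
#' `mappable`.
#'
#' @param groupings A groupings tibble.
#' @param path File path.
#' @return `path` (write) or a groupings tibble (read).
#' @export
write_groupings <- function(groupings, path) {
  flat <- groupings |>
    dplyr::mutate(
      pos_animals = purrr::map_chr(.data$pos_animals, paste, collapse = ";"),
      neg_animals = purrr::map_chr(.data$neg_animals, paste, collapse = ";")
    )
  readr::write_tsv(flat[, c("clone_id", "pos_animals", "neg_animals", "mappable")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_groupings
#' @export
read_groupings <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  split_ids <- function(x) {
    purrr::map(x, function(s) {
      if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  flat |>
    dplyr::mutate(pos_animals = split_ids(.data$pos_animals),
                  neg_animals = split_ids(.data$neg_animals))
}
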