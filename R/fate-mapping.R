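#' BrdU/EdU fate-mapping demographics
#'
#' Fractions of the three thymidine-analog populations BrdU+EdU-,
#' BrdU+EdU+ and BrdU-EdU+ among labelled IBA1+ cells. The denominator is
#' the number of IBA1+ cells positive for BrdU or EdU (double-negative
#' cells are excluded); an all-IBA1+ denominator is available for
#' sensitivity checks. A zero denominator is flagged as undefined, never
#' reported as 0/0.
#'
#' @param cells Tibble with 0/1 columns `iba1`, `brdu`, `edu` (see
#'   [sim_fate_table()]).
#' @param denominator `"labeled"` (default) or `"all"` IBA1+ cells.
#' @return Tibble `population`, `n`, `fraction`, `defined`, with the
#'   denominator count in attribute `denominator_n`.
#' @export
#' @examples
#' fate_demographics(sim_fate_table(10, c(0.4, 0.2, 0.4), exact = TRUE))
fate_demographics <- function(cells, denominator = c("labeled", "all")) {
  denominator <- match.arg(denominator)
  cells <- dplyr::filter(tibble::as_tibble(cells), .data$iba1 == 1)
  n_pop <- c(
    "BrdU+EdU-" = sum(cells$brdu == 1 & cells$edu == 0),
    "BrdU+EdU+" = sum(cells$brdu == 1 & cells$edu == 1),
    "BrdU-EdU+" = sum(cells$brdu == 0 & cells$edu == 1)
  )
  denom <- if (denominator == "labeled") sum(n_pop) else nrow(cells)
  defined <- denom > 0
  out <- tibble::tibble(
    population = names(n_pop),
    n = as.integer(n_pop),
    fraction = if (defined) unname(n_pop) / denom else NA_real_,
    defined = defined
  )
  attr(out, "denominator_n") <- denom
  out
}

#' BrdU labelling efficiency
#'
#' Fraction of IBA1+ cells that are BrdU+ (on the study's data 40.54% and
#' 35.13% in the Saline and MIA control groups).
#'
#' @inheritParams fate_demographics
#' @return A list: `n_brdu`, `n_iba1`, `efficiency` (`NA` and
#'   `defined = FALSE` when there are no IBA1+ cells).
#' @export
labeling_efficiency <- function(cells) {
  cells <- dplyr::filter(tibble::as_tibble(cells), .data$iba1 == 1)
  n_iba1 <- nrow(cells)
  n_brdu <- sum(cells$brdu == 1)
  list(n_brdu = as.integer(n_brdu), n_iba1 = as.integer(n_iba1),
       efficiency = if (n_iba1 > 0) n_brdu / n_iba1 else NA_real_,
       defined = n_iba1 > 0)
}

#' Per-group fate-mapping demographics with section-level dispersion
#'
#' Computes demographics per tissue section, averages sections within each
#' animal, and reports per-group means of the animal means together with
#' the s.e.m. across sections (the sections/mice hierarchy avoids
#' pseudo-replication from unequal section counts).
#'
#' @inheritParams fate_demographics
#' @return Tibble `group`, `population`, `mean_fraction`, `sem_sections`,
#'   `n_sections`, `n_animals`.
#' @export
fate_group_summary <- function(cells, denominator = c("labeled", "all")) {
  denominator <- match.arg(denominator)
  cells <- tibble::as_tibble(cells)
  per_section <- cells |>
    dplyr::group_by(.data$group, .data$animal_id, .data$section_id) |>
    dplyr::group_modify(function(df, key) {
      fate_demographics(df, denominator)[, c("population", "fraction")]
    }) |>
    dplyr::ungroup()
  per_animal <- per_section |>
    dplyr::group_by(.data$group, .data$animal_id, .data$population) |>
    dplyr::summarise(fraction = mean(.data$fraction, na.rm = TRUE), .groups = "drop")
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  }
  dplyr::left_join(
    per_animal |>
      dplyr::group_by(.data$group, .data$population) |>
      dplyr::summarise(mean_fraction = mean(.data$fraction, na.rm = TRUE),
                       n_animals = dplyr::n(), .groups = "drop"),
    per_section |>
      dplyr::group_by(.data$group, .data$population) |>
      dplyr::summarise(sem_sections = sem(.data$fraction),
                       n_sections = dplyr::n(), .groups = "drop"),
    by = c("group", "population")
  )
}
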