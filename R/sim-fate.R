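#' Generate a synthetic BrdU/EdU labelled-cell table
#'
#' Draws IBA1+ cells over the three thymidine-analog label classes
#' BrdU+EdU-, BrdU+EdU+ and BrdU-EdU+ with planted class fractions, either
#' multinomially or in exact (largest-remainder) proportions for
#' deterministic fixtures.
#'
#' @param n_cells Number of cells.
#' @param fractions Length-3 numeric on the simplex (sums to 1), ordered as
#'   (BrdU+EdU-, BrdU+EdU+, BrdU-EdU+).
#' @param exact If `TRUE`, allocate `round(n * f)` cells per class with
#'   largest-remainder correction instead of a multinomial draw.
#' @param group,n_sections Group label and number of tissue sections over
#'   which cells are spread (cells are dealt round-robin to sections).
#' @param seed Integer seed (ignored when `exact = TRUE`).
#' @return A tibble with columns `cell_id`, `section_id`, `animal_id`,
#'   `group`, `iba1`, `brdu`, `edu` (0/1).
#' @export
#' @examples
#' sim_fate_table(10, c(0.4, 0.2, 0.4), exact = TRUE)
sim_fate_table <- function(n_cells, fractions, exact = FALSE,
                           group = "group1", n_sections = 1, seed = 1) {
  stopifnot(n_cells >= 0, length(fractions) == 3)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be non-negative and sum to 1")
  }
  counts <- if (exact) {
    raw <- n_cells * fractions
    base <- floor(raw)
    rem <- raw - base
    short <- n_cells - sum(base)
    if (short > 0) {
      top <- order(rem, decreasing = TRUE)[seq_len(short)]
      base[top] <- base[top] + 1
    }
    as.integer(base)
  } else {
    with_seed(seed, as.integer(rmultinom(1, n_cells, fractions)))
  }
  class_brdu <- c(1L, 1L, 0L)
  class_edu <- c(0L, 1L, 1L)
  cls <- rep(1:3, counts)
  tibble::tibble(
    cell_id = seq_along(cls),
    section_id = if (length(cls) > 0) ((seq_along(cls) - 1L) %% n_sections) + 1L else integer(),
    animal_id = 1L,
    group = group,
    iba1 = 1L,
    brdu = class_brdu[cls],
    edu = class_edu[cls]
  )
}
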