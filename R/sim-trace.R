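#' Generate a random microglia-like trace
#'
#' Grows a rooted tree from a soma at the origin: `n_primary` first-order
#' processes, each segment of length `step_um`, bifurcating with
#' probability `branch_prob` at every level up to `max_depth`. Useful as a
#' test substrate for branch-order, Sholl and hull analyses.
#'
#' @param n_primary Number of soma-adjoining processes.
#' @param max_depth Maximum number of branch levels.
#' @param branch_prob Probability that a tip bifurcates at each level.
#' @param step_um Segment length in um.
#' @param seed Integer seed.
#' @return A `mia_trace` tibble.
#' @export
#' @examples
#' tr <- sim_trace(seed = 1)
#' branch_order_counts(tr)
sim_trace <- function(n_primary = 2, max_depth = 4, branch_prob = 0.7,
                      step_um = 5, seed = 1) {
  stopifnot(n_primary >= 1, max_depth >= 1, step_um > 0)
  with_seed(seed, {
    nodes <- list(list(id = 1L, type = 1L, x = 0, y = 0, z = 0, parent = -1L))
    next_id <- 2L
    rand_dir <- function(base = NULL, spread = 0.6) {
      d <- if (is.null(base)) rnorm(3) else base + rnorm(3, sd = spread)
      d / sqrt(sum(d^2))
    }
    grow <- function(parent_id, pos, dir, depth) {
      p <- pos + dir * step_um
      id <- next_id
      next_id <<- next_id + 1L
      nodes[[length(nodes) + 1L]] <<- list(id = id, type = 3L, x = p[1],
                                           y = p[2], z = p[3],
                                           parent = parent_id)
      if (depth < max_depth && runif(1) < branch_prob) {
        grow(id, p, rand_dir(dir), depth + 1)
        grow(id, p, rand_dir(dir), depth + 1)
      }
    }
    for (b in seq_len(n_primary)) grow(1L, c(0, 0, 0), rand_dir(), 1)
    tbl <- dplyr::bind_rows(purrr::map(nodes, tibble::as_tibble))
    tbl$radius <- 0.5
    as_mia_trace(tbl)
  })
}
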