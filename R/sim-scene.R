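#' Generate a synthetic 3D dendrite/spine/microglia scene
#'
#' Builds a dendrite of given length along the x axis carrying spines of
#' controlled neck/head geometry, and one microglial process point cloud per
#' spine placed at a requested 3D offset from the spine head centre. All
#' coordinates are emitted as voxel indices on an anisotropic grid (default
#' 0.04 x 0.04 x 0.3 um per voxel), so the true minimum head-to-cloud
#' distance of each spine equals the requested offset within one voxel
#' diagonal.
#'
#' @param spines Tibble with columns `position_um`, `neck_um`, `head_um`;
#'   if `NULL`, `n_spines` random spines are drawn.
#' @param offsets Tibble with columns `dx`, `dy`, `dz` (um, all >= 0), one
#'   row per spine; if `NULL`, random non-negative offsets up to `max_offset`.
#' @param dendrite_length Dendrite length in um.
#' @param voxel Voxel size `c(sx, sy, sz)` in um, strictly positive.
#' @param n_spines,max_offset Used only when `spines`/`offsets` are `NULL`.
#' @param n_cloud_points Points per microglia cloud (the planted nearest
#'   point plus decoys strictly farther away).
#' @param seed Integer seed.
#' @return A list of class `mia_scene`: `spines` (tibble with voxel indices
#'   `i`, `j`, `k` of each head centre and the requested offset), `clouds`
#'   (tibble `spine_id`, `i`, `j`, `k`), `voxel`, `dendrite_length`.
#' @export
#' @examples
#' sc <- sim_scene(n_spines = 3, seed = 42)
#' sc$spines
sim_scene <- function(spines = NULL, offsets = NULL,
                      dendrite_length = 100,
                      voxel = c(0.04, 0.04, 0.3),
                      n_spines = 10, max_offset = 2,
                      n_cloud_points = 20, seed = 1) {
  if (any(voxel <= 0) || length(voxel) != 3) abort("voxel sizes must be three strictly positive values")
  stopifnot(dendrite_length > 0, n_cloud_points >= 1)

  with_seed(seed, {
    if (is.null(spines)) {
      spines <- tibble::tibble(
        position_um = sort(runif(n_spines, 0, dendrite_length)),
        neck_um = sample(c(0, runif(n_spines, 0.2, 4)), n_spines, replace = TRUE),
        head_um = runif(n_spines, 0.2, 1.2)
      )
    }
    spines <- tibble::as_tibble(spines)
    n <- nrow(spines)
    if (any(spines$position_um < 0 | spines$position_um > dendrite_length)) {
      abort("spine positions must lie within the dendrite length")
    }
    if (is.null(offsets)) {
      offsets <- tibble::tibble(
        dx = runif(n, 0, max_offset),
        dy = runif(n, 0, max_offset),
        dz = sample(0:4, n, replace = TRUE) * voxel[3]
      )
    }
    offsets <- tibble::as_tibble(offsets)
    if (nrow(offsets) != n) abort("one offset row per spine required")
    if (any(offsets < 0)) abort("offsets must be non-negative")

    # head centres sit one neck length above the shaft, snapped to the grid
    head_um <- cbind(spines$position_um,
                     1 + spines$neck_um + spines$head_um / 2,
                     dendrite_length / 10)
    head_idx <- sweep(head_um, 2, voxel, "/")
    head_idx <- round(head_idx)

    off <- as.matrix(offsets)
    clouds <- purrr::map_dfr(seq_len(n), function(s) {
      target_um <- head_idx[s, ] * voxel + off[s, ]
      nearest <- round(target_um / voxel)
      r0 <- sqrt(sum(off[s, ]^2))
      vdiag <- sqrt(sum(voxel^2))
      decoys <- NULL
      if (n_cloud_points > 1) {
        # decoys strictly farther than the planted nearest point
        u <- matrix(rnorm(3 * (n_cloud_points - 1)), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        rad <- r0 + 2 * vdiag + runif(n_cloud_points - 1, 0.5, 3)
        pts_um <- sweep(u * rad, 2, head_idx[s, ] * voxel, "+")
        decoys <- round(sweep(pts_um, 2, voxel, "/"))
      }
      pts <- unname(rbind(nearest, decoys))
      tibble::tibble(spine_id = s, i = pts[, 1], j = pts[, 2], k = pts[, 3])
    })

    spine_tbl <- dplyr::mutate(spines,
      spine_id = seq_len(n),
      i = head_idx[, 1], j = head_idx[, 2], k = head_idx[, 3],
      offset_dx = off[, 1], offset_dy = off[, 2], offset_dz = off[, 3],
      .before = 1
    )
    structure(list(spines = spine_tbl, clouds = clouds, voxel = voxel,
                   dendrite_length = dendrite_length),
              class = "mia_scene")
  })
}

#' @export
print.mia_scene <- function(x, ...) {
  cat("<mia_scene> ", nrow(x$spines), " spines on ", x$dendrite_length,
      " um dendrite; voxel ", paste(x$voxel, collapse = " x "), " um\n", sep = "")
  invisible(x)
}
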