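#' Classify dendritic spines from neck length and head diameter
#'
#' Assigns each spine exactly one subtype by the rules: stubby (no neck),
#' mushroom (neck present and head diameter >= 0.6 um), filopodia (neck
#' > 3 um), thin (combined head + neck extent < 3 um), applied in that
#' precedence order. "Head and neck < 3 um" is read as the combined
#' extent; spines matching no rule (combined extent exactly 3 um or more
#' with a small head and short neck) fall back to thin with a boundary
#' warning.
#'
#' @param neck_um,head_um Numeric vectors (um), non-negative, recycled to
#'   common length.
#' @return Character vector in `{"stubby", "mushroom", "filopodia",
#'   "thin"}`.
#' @export
#' @examples
#' classify_spine(c(0, 1, 3.5, 1), c(0.5, 0.8, 0.3, 0.3))
classify_spine <- function(neck_um, head_um) {
  n <- max(length(neck_um), length(head_um))
  neck_um <- rep_len(neck_um, n)
  head_um <- rep_len(head_um, n)
  if (any(neck_um < 0 | head_um < 0)) abort("neck and head measures must be non-negative")
  out <- character(n)
  stubby <- neck_um == 0
  mushroom <- !stubby & head_um >= 0.6
  filopodia <- !stubby & !mushroom & neck_um > 3
  thin <- !stubby & !mushroom & !filopodia & (neck_um + head_um < 3)
  boundary <- !stubby & !mushroom & !filopodia & !thin
  if (any(boundary)) {
    warn(paste0(sum(boundary), " spine(s) at or beyond the 3 um combined-",
                "extent boundary without a qualifying head or neck; assigned thin"))
  }
  out[stubby] <- "stubby"
  out[mushroom] <- "mushroom"
  out[filopodia] <- "filopodia"
  out[thin | boundary] <- "thin"
  out
}

#' Spine densities per 10 um of dendrite
#'
#' @param spines Tibble with at least `neck_um` and `head_um` (a `subtype`
#'   column is used if present, otherwise computed via [classify_spine()]).
#' @param length_um Dendrite segment length (> 0).
#' @return Tibble `subtype`, `n`, `density_per_10um`, including a `"total"`
#'   row; subtypes with no spines report 0.
#' @export
spine_density <- function(spines, length_um) {
  if (length_um <= 0) abort("segment length must be positive")
  spines <- tibble::as_tibble(spines)
  subtypes <- c("thin", "stubby", "mushroom", "filopodia")
  st <- if (nrow(spines) == 0) character() else if ("subtype" %in% names(spines)) {
    spines$subtype
  } else {
    classify_spine(spines$neck_um, spines$head_um)
  }
  counts <- table(factor(st, levels = subtypes))
  tibble::tibble(
    subtype = c("total", subtypes),
    n = as.integer(c(length(st), counts)),
    density_per_10um = as.numeric(c(length(st), counts)) / length_um * 10
  )
}

#' Minimum 3D distance from a spine head to a microglial point cloud
#'
#' Euclidean distance on the anisotropic voxel grid: for voxel-index
#' displacement (di, dj, dk) and voxel size (sx, sy, sz), the distance is
#' sqrt((di sx)^2 + (dj sy)^2 + (dk sz)^2); the z-plane separation is |dk|
#' of the minimizing cloud point.
#'
#' @param head Numeric voxel-index triple `(i, j, k)` of the head centre.
#' @param cloud Tibble/data frame with voxel-index columns `i`, `j`, `k`
#'   (non-empty).
#' @param voxel Voxel size `c(sx, sy, sz)` in um.
#' @return One-row tibble `distance_um`, `z_planes`.
#' @export
#' @examples
#' min_distance_3d(c(0, 0, 0), data.frame(i = 3, j = 4, k = 0))
#' # 0.2 um (3-4-5 triangle x 0.04), 0 z-planes
min_distance_3d <- function(head, cloud, voxel = c(0.04, 0.04, 0.3)) {
  cloud <- tibble::as_tibble(cloud)
  if (nrow(cloud) == 0) abort("empty microglia point cloud")
  if (any(voxel <= 0)) abort("voxel sizes must be strictly positive")
  d2 <- ((cloud$i - head[1]) * voxel[1])^2 +
        ((cloud$j - head[2]) * voxel[2])^2 +
        ((cloud$k - head[3]) * voxel[3])^2
  best <- which.min(d2)
  tibble::tibble(distance_um = unname(sqrt(d2[best])),
                 z_planes = as.integer(abs(cloud$k[best] - head[3])))
}

#' Angular coverage of a spine head by microglial processes
#'
#' Places `n_bins` evenly spaced probe points on the in-plane circle of the
#' spine head (radius = head diameter / 2, same z as the head centre) and
#' reports the fraction of probes having a cloud point within
#' `contact_radius`. A fully encircling cloud scores 1, a half-ring about
#' 0.5.
#'
#' @inheritParams min_distance_3d
#' @param head_um Head diameter in um (> 0).
#' @param contact_radius Contact distance in um (default 0.3).
#' @param n_bins Number of angular bins (default 36, i.e. 10 degrees).
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(head, head_um, cloud,
                              voxel = c(0.04, 0.04, 0.3),
                              contact_radius = 0.3, n_bins = 36) {
  if (head_um <= 0) abort("head diameter must be positive")
  cloud <- tibble::as_tibble(cloud)
  if (nrow(cloud) == 0) return(0)
  centre <- head * voxel
  pts <- cbind(cloud$i * voxel[1], cloud$j * voxel[2], cloud$k * voxel[3])
  theta <- (seq_len(n_bins) - 1) / n_bins * 2 * pi
  r <- head_um / 2
  covered <- purrr::map_lgl(theta, function(th) {
    probe <- centre + c(r * cos(th), r * sin(th), 0)
    min((pts[, 1] - probe[1])^2 + (pts[, 2] - probe[2])^2 +
        (pts[, 3] - probe[3])^2) <= contact_radius^2
  })
  mean(covered)
}

#' Classify a microglia-spine interaction
#'
#' Nested contact classes from 3D distance, z-plane separation and head
#' coverage: encapsulation (within 0.3 um, at most one z-plane, microglia
#' surrounding at least half the head), else apposition (within 0.9 um, at
#' most three z-planes), else proximity (within 1.5 um, at most five
#' z-planes), else none. Radii are inclusive at the boundary and equal the
#' plane count times the 0.3 um z-step.
#'
#' @param distance_um,z_planes,coverage Numeric vectors, recycled.
#' @return Character vector in `{"encapsulation", "apposition",
#'   "proximity", "none"}`.
#' @export
#' @examples
#' classify_interaction(c(0.2, 0.7, 1.2, 2), c(0, 2, 4, 0), c(0.6, 0.3, 0, 0.9))
classify_interaction <- function(distance_um, z_planes, coverage) {
  n <- max(length(distance_um), length(z_planes), length(coverage))
  d <- rep_len(distance_um, n)
  z <- rep_len(z_planes, n)
  cv <- rep_len(coverage, n)
  dplyr::case_when(
    d <= 0.3 & z <= 1 & cv >= 0.5 ~ "encapsulation",
    d <= 0.9 & z <= 3 ~ "apposition",
    d <= 1.5 & z <= 5 ~ "proximity",
    TRUE ~ "none"
  )
}

#' Score all microglia-spine interactions in a scene
#'
#' For each spine, finds the nearest cloud point, the z-plane separation,
#' the angular coverage, and the interaction class.
#'
#' @param scene A [sim_scene()] object, or a list with `spines`, `clouds`,
#'   `voxel` of the same shape.
#' @param contact_radius,n_bins Passed to [coverage_fraction()].
#' @return The spine tibble extended with `subtype`, `distance_um`,
#'   `z_planes`, `coverage`, `interaction`.
#' @export
score_interactions <- function(scene, contact_radius = 0.3, n_bins = 36) {
  spines <- tibble::as_tibble(scene$spines)
  clouds <- tibble::as_tibble(scene$clouds)
  voxel <- scene$voxel
  rows <- purrr::map_dfr(seq_len(nrow(spines)), function(s) {
    sp <- spines[s, ]
    cl <- clouds[clouds$spine_id == sp$spine_id, ]
    if (nrow(cl) == 0) {
      return(tibble::tibble(distance_um = Inf, z_planes = NA_integer_, coverage = 0))
    }
    md <- min_distance_3d(c(sp$i, sp$j, sp$k), cl, voxel)
    md$coverage <- coverage_fraction(c(sp$i, sp$j, sp$k), sp$head_um, cl,
                                     voxel, contact_radius, n_bins)
    md
  })
  dplyr::bind_cols(spines, rows) |>
    dplyr::mutate(
      subtype = classify_spine(.data$neck_um, .data$head_um),
      interaction = classify_interaction(.data$distance_um, .data$z_planes,
                                         .data$coverage)
    )
}

#' Microglia-spine interaction densities per 10 um
#'
#' Counts spines with an interaction class other than `"none"`, normalized
#' by dendrite length, in total and split by spine subtype and by
#' interaction class.
#'
#' @param interactions Output of [score_interactions()].
#' @param length_um Dendrite segment length (> 0).
#' @return Tibble `dimension` (`"total"`, `"subtype"`, `"class"`), `level`,
#'   `n`, `density_per_10um`.
#' @export
interaction_density <- function(interactions, length_um) {
  if (length_um <= 0) abort("segment length must be positive")
  hit <- dplyr::filter(tibble::as_tibble(interactions), .data$interaction != "none")
  subtype_levels <- c("thin", "stubby", "mushroom", "filopodia")
  class_levels <- c("encapsulation", "apposition", "proximity")
  by_subtype <- table(factor(hit$subtype, levels = subtype_levels))
  by_class <- table(factor(hit$interaction, levels = class_levels))
  tibble::tibble(
    dimension = c("total", rep("subtype", 4), rep("class", 3)),
    level = c("total", subtype_levels, class_levels),
    n = as.integer(c(nrow(hit), by_subtype, by_class))
  ) |>
    dplyr::mutate(density_per_10um = .data$n / length_um * 10)
}

#' Synaptic puncta overlapping a microglial footprint, per unit area
#'
#' Counts puncta lying within `overlap_radius` of any footprint point and
#' normalizes by the microglial surface area.
#'
#' @param puncta Tibble with 2D coordinates `x`, `y` (um).
#' @param footprint Tibble with 2D coordinates `x`, `y` (um) tracing the
#'   microglial projection.
#' @param area_um2 Microglia footprint area in um^2 (> 0).
#' @param overlap_radius Maximum puncta-to-footprint distance counted as
#'   overlap (um).
#' @return A list: `n_overlap`, `density_per_um2`.
#' @export
puncta_interaction_density <- function(puncta, footprint, area_um2,
                                       overlap_radius = 0.3) {
  if (area_um2 <= 0) abort("footprint area must be positive")
  puncta <- tibble::as_tibble(puncta)
  footprint <- tibble::as_tibble(footprint)
  n_overlap <- if (nrow(puncta) == 0 || nrow(footprint) == 0) 0L else {
    sum(purrr::map_lgl(seq_len(nrow(puncta)), function(p) {
      min((footprint$x - puncta$x[p])^2 + (footprint$y - puncta$y[p])^2) <=
        overlap_radius^2
    }))
  }
  list(n_overlap = as.integer(n_overlap), density_per_um2 = n_overlap / area_um2)
}
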