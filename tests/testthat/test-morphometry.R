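test_that("spine classification reproduces the four published rules", {
  expect_equal(classify_spine(0, 0.5), "stubby")
  expect_equal(classify_spine(1.0, 0.8), "mushroom")
  expect_equal(classify_spine(3.5, 0.3), "filopodia")
  expect_equal(classify_spine(1.0, 0.3), "thin")
  expect_error(classify_spine(-1, 0.5), "non-negative")
})

test_that("spine classes are exhaustive and mutually exclusive on a grid", {
  grid <- tidyr::expand_grid(neck = seq(0, 5, by = 0.1),
                             head = seq(0, 2, by = 0.05))
  cls <- suppressWarnings(classify_spine(grid$neck, grid$head))
  expect_true(all(cls %in% c("thin", "stubby", "mushroom", "filopodia")))
  expect_equal(length(cls), nrow(grid))
  # precedence: no neck always wins; big head beats long neck
  expect_true(all(cls[grid$neck == 0] == "stubby"))
  expect_true(all(cls[grid$neck > 0 & grid$head >= 0.6] == "mushroom"))
  expect_true(all(cls[grid$neck > 3 & grid$head < 0.6] == "filopodia"))
  # the combined-extent boundary falls back to thin with a warning
  expect_warning(cls3 <- classify_spine(2.8, 0.2), "boundary")
  expect_equal(cls3, "thin")
})

test_that("spine densities are counts per 10 um", {
  spines <- tibble::tibble(neck_um = rep(1, 10), head_um = rep(0.3, 10))
  dens <- spine_density(spines, 100)
  expect_equal(dens$density_per_10um[dens$subtype == "total"], 1)
  expect_equal(dens$density_per_10um[dens$subtype == "thin"], 1)
  empty <- spine_density(spines[0, ], 50)
  expect_true(all(empty$density_per_10um == 0))
  expect_error(spine_density(spines, 0), "positive")

  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- sample(0:30, 1)
      len <- runif(1, 10, 200)
      sp <- tibble::tibble(neck_um = runif(n, 0, 2.4), head_um = runif(n, 0, 0.5))
      expect_equal(spine_density(sp, len)$density_per_10um[1], n / len * 10)
    }
  })
})

test_that("min 3D distance uses anisotropic voxel sizes", {
  d1 <- min_distance_3d(c(0, 0, 0), data.frame(i = 3, j = 4, k = 0))
  expect_equal(d1$distance_um, 0.2)
  expect_equal(d1$z_planes, 0L)
  d2 <- min_distance_3d(c(0, 0, 0), data.frame(i = 0, j = 0, k = 1))
  expect_equal(d2$distance_um, 0.3)
  expect_equal(d2$z_planes, 1L)
  expect_error(min_distance_3d(c(0, 0, 0), data.frame(i = numeric(), j = numeric(),
                                                      k = numeric())), "empty")

  # brute-force scan over a 500-point random cloud, plus translation invariance
  withr::with_seed(21, {
    cloud <- tibble::tibble(i = sample(-50:50, 500, TRUE),
                            j = sample(-50:50, 500, TRUE),
                            k = sample(-10:10, 500, TRUE))
    head <- c(3, -7, 2)
  })
  voxel <- c(0.04, 0.04, 0.3)
  all_d <- sqrt(((cloud$i - head[1]) * voxel[1])^2 +
                  ((cloud$j - head[2]) * voxel[2])^2 +
                  ((cloud$k - head[3]) * voxel[3])^2)
  res <- min_distance_3d(head, cloud, voxel)
  expect_equal(res$distance_um, min(all_d), tolerance = 1e-12)
  shift <- c(11, -4, 6)
  res_shift <- min_distance_3d(head + shift,
                               dplyr::mutate(cloud, i = i + shift[1],
                                             j = j + shift[2], k = k + shift[3]),
                               voxel)
  expect_equal(res_shift$distance_um, res$distance_um, tolerance = 1e-12)
})

test_that("coverage fraction counts contacted angular bins", {
  voxel <- c(0.04, 0.04, 0.3)
  head <- c(100, 100, 5)
  r_um <- 0.4  # head diameter 0.8
  ring_angles <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- tibble::tibble(
    i = round((head[1] * voxel[1] + r_um * cos(ring_angles)) / voxel[1]),
    j = round((head[2] * voxel[2] + r_um * sin(ring_angles)) / voxel[2]),
    k = head[3]
  )
  expect_equal(coverage_fraction(head, 0.8, ring, voxel), 1)

  far <- tibble::tibble(i = 1000, j = 1000, k = 5)
  expect_equal(coverage_fraction(head, 0.8, far, voxel), 0)

  half_angles <- ring_angles[ring_angles <= pi]
  half <- tibble::tibble(
    i = round((head[1] * voxel[1] + r_um * cos(half_angles)) / voxel[1]),
    j = round((head[2] * voxel[2] + r_um * sin(half_angles)) / voxel[2]),
    k = head[3]
  )
  cov_half <- coverage_fraction(head, 0.8, half, voxel, contact_radius = 0.06)
  expect_lt(abs(cov_half - 0.5), 1 / 36 + 0.03)
})

test_that("interaction classes follow the nested threshold rules", {
  expect_equal(classify_interaction(0.2, 0, 0.6), "encapsulation")
  expect_equal(classify_interaction(0.7, 2, 0.3), "apposition")
  expect_equal(classify_interaction(1.2, 4, 0.0), "proximity")
  expect_equal(classify_interaction(2.0, 0, 0.9), "none")
  # within 0.3 um but low coverage is apposition, not encapsulation
  expect_equal(classify_interaction(0.25, 1, 0.2), "apposition")
  # inclusive boundaries
  expect_equal(classify_interaction(0.3, 1, 0.5), "encapsulation")
  expect_equal(classify_interaction(0.9, 3, 0), "apposition")
  expect_equal(classify_interaction(1.5, 5, 0), "proximity")

  # monotone: class never strengthens as distance grows
  strength <- c(none = 0, proximity = 1, apposition = 2, encapsulation = 3)
  d_grid <- seq(0, 2, by = 0.05)
  for (z in c(0, 2, 4)) {
    for (cv in c(0, 0.6)) {
      s <- strength[classify_interaction(d_grid, z, cv)]
      expect_true(all(diff(s) <= 0))
    }
  }
})

test_that("interaction densities normalise contacted spines by length", {
  spines <- tibble::tibble(
    spine_id = 1:10, position_um = seq(5, 95, by = 10),
    neck_um = 1, head_um = 0.3, i = 1:10 * 100, j = 100, k = 5
  )
  voxel <- c(0.04, 0.04, 0.3)
  # clouds for spines 1-3 one voxel away, none for the rest
  clouds <- purrr::map_dfr(1:3, function(s) {
    tibble::tibble(spine_id = s, i = s * 100 + 1, j = 100, k = 5)
  })
  scored <- score_interactions(list(spines = spines, clouds = clouds,
                                    voxel = voxel))
  dens <- interaction_density(scored, 100)
  expect_equal(dens$density_per_10um[dens$dimension == "total"], 0.3)
  by_class <- dens$n[dens$dimension == "class"]
  expect_equal(sum(by_class), dens$n[dens$dimension == "total"])
  by_subtype <- dens$n[dens$dimension == "subtype"]
  expect_equal(sum(by_subtype), dens$n[dens$dimension == "total"])

  # all spines beyond 1.5 um: nothing counted
  far_clouds <- dplyr::mutate(clouds, i = i + 1000)
  scored_far <- score_interactions(list(spines = spines, clouds = far_clouds,
                                        voxel = voxel))
  expect_equal(interaction_density(scored_far, 100)$n[1], 0L)
})

test_that("puncta overlap density is count within footprint over area", {
  puncta <- tibble::tibble(x = c(1, 2, 3, 4, 5, 50), y = 0)
  footprint <- tibble::tibble(x = seq(0, 6, by = 0.1), y = 0)
  res <- puncta_interaction_density(puncta, footprint, area_um2 = 50)
  expect_equal(res$n_overlap, 5L)
  expect_equal(res$density_per_um2, 0.1)
  expect_equal(puncta_interaction_density(puncta[0, ], footprint, 10)$density_per_um2, 0)
  expect_error(puncta_interaction_density(puncta, footprint, 0), "positive")

  withr::with_seed(31, {
    pts <- tibble::tibble(x = runif(40, 0, 20), y = runif(40, 0, 20))
    fp <- tibble::tibble(x = runif(60, 0, 20), y = runif(60, 0, 20))
  })
  oracle <- sum(vapply(seq_len(nrow(pts)), function(p) {
    any(sqrt((fp$x - pts$x[p])^2 + (fp$y - pts$y[p])^2) <= 0.5)
  }, logical(1)))
  expect_equal(puncta_interaction_density(pts, fp, 400, overlap_radius = 0.5)$n_overlap,
               oracle)
})

test_that("branch orders count centrifugally from the soma", {
  # soma with two primary processes, each bifurcating once
  tr <- as_mia_trace(tibble::tibble(
    id = 1:9,
    x = c(0, 1, -1, 2, 2, -2, -2, 3, 3),
    y = c(0, 0, 0, 1, -1, 1, -1, 2, 0),
    z = 0,
    parent = c(-1, 1, 1, 2, 2, 3, 3, 4, 4)
  ))
  bo <- branch_order_counts(tr)
  expect_equal(bo$n_branches[1], 2L)
  expect_equal(bo$n_branches[2], 4L)
  expect_equal(bo$n_branches[3], 2L)

  single <- as_mia_trace(tibble::tibble(id = 1:4, x = 0:3, y = 0, z = 0,
                                        parent = c(-1, 1:3)))
  bs <- branch_order_counts(single)
  expect_equal(bs$n_branches[1], 1L)
  expect_equal(sum(bs$n_branches[-1]), 0L)

  expect_error(as_mia_trace(tibble::tibble(id = 1:3, x = 0, y = 0, z = 0,
                                           parent = c(-1, 3, 2))), "cycle")

  # random trees against the recursive traversal oracle
  for (s in 1:8) {
    tr <- sim_trace(n_primary = sample(1:3, 1), max_depth = 5,
                    branch_prob = 0.8, seed = s)
    expect_equal(branch_order_counts(tr)$n_branches, branch_order_oracle(tr))
  }
})

test_that("Sholl profiles count sphere crossings", {
  straight <- as_mia_trace(tibble::tibble(id = 1:2, x = c(0, 10), y = 0, z = 0,
                                          parent = c(-1, 1)))
  pr <- sholl(straight, radii = 1:9)
  expect_equal(pr$intersections, rep(1L, 9))

  bifur <- as_mia_trace(tibble::tibble(
    id = 1:4, x = c(0, 5, 10, 10), y = c(0, 0, 3, -3), z = 0,
    parent = c(-1, 1, 2, 2)
  ))
  pb <- sholl(bifur, radii = c(2, 4, 6, 8))
  expect_equal(pb$intersections, c(1L, 1L, 2L, 2L))
  expect_error(sholl(straight, radii = c(3, 2)), "increasing")

  for (s in 1:5) {
    tr <- sim_trace(n_primary = 2, max_depth = 4, branch_prob = 0.8, seed = s + 40)
    radii <- seq(2, 30, by = 2)
    expect_equal(sholl(tr, radii)$intersections, sholl_oracle(tr, radii))
  }
})

test_that("convex hull volumes match closed forms and the brute-force oracle", {
  tetra <- rbind(c(0, 0, 0), diag(3))
  expect_equal(convex_hull_volume(tetra), 1 / 6, tolerance = 1e-12)

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)

  expect_warning(flat <- convex_hull_volume(cbind(runif(10), runif(10), 0)),
                 "degenerate")
  expect_equal(flat, 0)

  withr::with_seed(17, {
    for (rep in 1:6) {
      pts <- matrix(rnorm(3 * sample(8:20, 1)), ncol = 3)
      expect_equal(convex_hull_volume(pts), hull_volume_oracle(pts),
                   tolerance = 1e-9)
    }
  })
})

test_that("SWC files round-trip", {
  tr <- sim_trace(n_primary = 2, max_depth = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})
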