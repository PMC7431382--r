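#' Read a neuron/microglia trace from SWC
#'
#' Plain-text SWC: one node per line with columns id, type, x, y, z,
#' radius, parent (parent -1 for the root; type 1 marks soma nodes;
#' coordinates in um). Comment lines start with `#`.
#'
#' @param path File path.
#' @return A tibble of class `mia_trace`: `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @export
#' @examples
#' swc <- system.file("extdata", "synthetic_microglia_trace.swc",
#'                    package = "miaglia")
#' tr <- read_swc(swc)
#' branch_order_counts(tr)
read_swc <- function(path) {
  tbl <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  out <- tibble::as_tibble(tbl)
  class(out) <- c("mia_trace", class(out))
  validate_trace(out)
  out
}

#' Write a trace to SWC
#'
#' @param trace A `mia_trace` tibble (see [read_swc()], [as_mia_trace()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  utils::write.table(as.data.frame(trace)[, c("id", "type", "x", "y", "z",
                                              "radius", "parent")],
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a trace from a node table
#'
#' @param nodes Data frame with `id`, `x`, `y`, `z`, `parent` (and
#'   optionally `type`, `radius`; type defaults to 3 with the root set to
#'   1, radius to 0.5).
#' @return A validated `mia_trace` tibble.
#' @export
as_mia_trace <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (!"type" %in% names(nodes)) {
    nodes$type <- ifelse(nodes$parent == -1, 1L, 3L)
  }
  if (!"radius" %in% names(nodes)) nodes$radius <- 0.5
  out <- nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
  class(out) <- c("mia_trace", class(out))
  validate_trace(out)
  out
}

validate_trace <- function(trace) {
  if (anyDuplicated(trace$id)) abort("duplicate node ids in trace")
  roots <- trace$id[trace$parent == -1]
  if (length(roots) != 1) abort("trace must have exactly one root node")
  dangling <- setdiff(trace$parent, c(-1, trace$id))
  if (length(dangling) > 0) abort("parent references unknown node(s)")
  # reachability from the root proves acyclicity for parent-pointer graphs
  kids <- split(trace$id, factor(trace$parent, levels = trace$id))
  seen <- roots
  frontier <- roots
  while (length(frontier) > 0) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    frontier <- nxt
    seen <- c(seen, nxt)
  }
  if (length(seen) != nrow(trace)) abort("trace contains a cycle or disconnected nodes")
  invisible(trace)
}

trace_children <- function(trace) {
  split(trace$id, factor(trace$parent, levels = trace$id))
}

soma_centre <- function(trace) {
  soma <- trace[trace$type == 1, , drop = FALSE]
  if (nrow(soma) == 0) soma <- trace[trace$parent == -1, , drop = FALSE]
  c(mean(soma$x), mean(soma$y), mean(soma$z))
}

#' Centrifugal branch-order counts
#'
#' Labels every branch by its centrifugal order: first-order branches
#' adjoin the soma directly, and the order increases by one at each branch
#' point as processes traverse outward. Returns branch counts per order.
#'
#' @param trace A `mia_trace` tibble.
#' @param max_order Highest order reported (default 25).
#' @return Tibble `order` (1..max_order), `n_branches`.
#' @export
#' @examples
#' # soma with 2 primary processes, each bifurcating once -> orders 2, 4
branch_order_counts <- function(trace, max_order = 25) {
  validate_trace(trace)
  kids <- trace_children(trace)
  root <- trace$id[trace$parent == -1]
  soma_ids <- union(root, trace$id[trace$type == 1])
  n_children <- purrr::map_int(kids, length)

  # breadth-first: each node inherits its branch order from its parent,
  # +1 when the parent is a branch point; soma children start at order 1
  order_of <- setNames(rep(NA_integer_, nrow(trace)), trace$id)
  starts <- integer(0)
  frontier <- root
  order_of[as.character(root)] <- 0L
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (p in frontier) {
      ch <- kids[[as.character(p)]]
      if (length(ch) == 0) next
      p_ord <- order_of[[as.character(p)]]
      is_soma <- p %in% soma_ids
      branch_pt <- !is_soma && n_children[[as.character(p)]] >= 2
      ord <- if (is_soma) 1L else if (branch_pt) p_ord + 1L else p_ord
      order_of[as.character(ch)] <- ord
      if (is_soma || branch_pt) starts <- c(starts, rep(ord, length(ch)))
      nxt <- c(nxt, ch)
    }
    frontier <- nxt
  }
  counts <- table(factor(starts, levels = seq_len(max_order)))
  tibble::tibble(order = seq_len(max_order), n_branches = as.integer(counts))
}

#' Sholl intersection profile
#'
#' Counts, for each radius, the number of times trace segments cross the
#' sphere of that radius centred on the soma. Crossings are computed
#' analytically per segment: one crossing when the endpoints straddle the
#' sphere, two when both endpoints lie outside but the segment's closest
#' approach dips inside.
#'
#' @param trace A `mia_trace` tibble.
#' @param radii Strictly increasing radii in um.
#' @return Tibble `radius_um`, `intersections`.
#' @export
sholl <- function(trace, radii) {
  validate_trace(trace)
  if (is.unsorted(radii, strictly = TRUE)) abort("radii must be strictly increasing")
  ctr <- soma_centre(trace)
  seg <- dplyr::inner_join(
    tibble::as_tibble(trace),
    tibble::as_tibble(trace)[, c("id", "x", "y", "z")],
    by = c("parent" = "id"), suffix = c("", "_p")
  )
  if (nrow(seg) == 0) {
    return(tibble::tibble(radius_um = radii, intersections = 0L))
  }
  a <- cbind(seg$x_p - ctr[1], seg$y_p - ctr[2], seg$z_p - ctr[3])
  b <- cbind(seg$x - ctr[1], seg$y - ctr[2], seg$z - ctr[3])
  da <- sqrt(rowSums(a^2))
  db <- sqrt(rowSums(b^2))
  # closest approach of each segment to the soma centre
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, pmin(pmax(-rowSums(a * ab) / len2, 0), 1), 0)
  closest <- a + ab * t
  dmin <- sqrt(rowSums(closest^2))
  dmax <- pmax(da, db)
  counts <- purrr::map_int(radii, function(r) {
    straddle <- (da - r) * (db - r) < 0
    double <- da > r & db > r & dmin < r
    sum(straddle) + 2L * sum(double)
  })
  tibble::tibble(radius_um = radii, intersections = counts)
}

#' Convex hull volume of a trace
#'
#' Volume (um^3) of the 3D convex hull of all node coordinates, computed
#' with an incremental hull construction. Degenerate inputs (fewer than 4
#' points or all points coplanar) return 0 with a warning.
#'
#' @param trace A `mia_trace` tibble, or any data frame / matrix with 3D
#'   coordinates (`x`, `y`, `z` columns or 3 numeric columns).
#' @return Hull volume in um^3.
#' @export
#' @examples
#' convex_hull_volume(rbind(diag(3), c(0, 0, 0)))  # unit tetrahedron, 1/6
convex_hull_volume <- function(trace) {
  pts <- if (is.matrix(trace)) trace else {
    df <- as.data.frame(trace)
    if (all(c("x", "y", "z") %in% names(df))) {
      as.matrix(df[, c("x", "y", "z")])
    } else {
      as.matrix(df[, 1:3])
    }
  }
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  hull <- convex_hull_3d(pts)
  if (is.null(hull)) {
    warn("degenerate point set (fewer than 4 distinct non-coplanar points); volume 0")
    return(0)
  }
  interior <- colMeans(pts[unique(as.vector(hull)), , drop = FALSE])
  vol <- 0
  for (f in seq_len(nrow(hull))) {
    v1 <- pts[hull[f, 1], ] - interior
    v2 <- pts[hull[f, 2], ] - interior
    v3 <- pts[hull[f, 3], ] - interior
    vol <- vol + abs(det(rbind(v1, v2, v3))) / 6
  }
  vol
}

# incremental 3D convex hull; returns a matrix of facet vertex indices or
# NULL when the point set is degenerate
convex_hull_3d <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(NULL)
  scale <- max(abs(pts)) + 1
  eps <- 1e-10 * scale

  # seed tetrahedron: spread points, then max area, then max volume
  i1 <- which.max(rowSums(sweep(pts, 2, pts[1, ])^2))
  i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  e1 <- pts[i2, ] - pts[i1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  areas <- apply(pts, 1, function(p) sqrt(sum(cr(e1, p - pts[i1, ])^2)))
  i3 <- which.max(areas)
  if (areas[i3] <= eps^2) return(NULL)
  nrm <- cr(e1, pts[i3, ] - pts[i1, ])
  vols <- abs(as.vector(sweep(pts, 2, pts[i1, ]) %*% nrm))
  i4 <- which.max(vols)
  if (vols[i4] <= eps * sqrt(sum(nrm^2)) * scale * 1e-6 || vols[i4] == 0) return(NULL)

  seed <- c(i1, i2, i3, i4)
  centroid <- colMeans(pts[seed, ])
  orient <- function(tri) {
    nn <- cr(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
    if (sum(nn * (centroid - pts[tri[1], ])) > 0) tri[c(1, 3, 2)] else tri
  }
  faces <- rbind(orient(seed[c(1, 2, 3)]), orient(seed[c(1, 2, 4)]),
                 orient(seed[c(1, 3, 4)]), orient(seed[c(2, 3, 4)]))

  face_normal <- function(tri) cr(pts[tri[2], ] - pts[tri[1], ],
                                  pts[tri[3], ] - pts[tri[1], ])
  for (p in setdiff(seq_len(n), seed)) {
    vis <- purrr::map_lgl(seq_len(nrow(faces)), function(f) {
      tri <- faces[f, ]
      sum(face_normal(tri) * (pts[p, ] - pts[tri[1], ])) > eps
    })
    if (!any(vis)) next
    visible <- faces[vis, , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    # horizon = edges of visible faces not shared by two visible faces
    edges <- rbind(visible[, c(1, 2)], visible[, c(2, 3)], visible[, c(3, 1)])
    keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[keys %in% names(which(table(keys) == 1)), , drop = FALSE]
    # the seed-tetrahedron centroid stays interior as the hull grows
    new_faces <- t(apply(horizon, 1, function(e) {
      tri <- c(e[1], e[2], p)
      nn <- face_normal(tri)
      if (sum(nn * (centroid - pts[tri[1], ])) > 0) tri[c(1, 3, 2)] else tri
    }))
    faces <- rbind(faces, new_faces)
  }
  faces
}
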