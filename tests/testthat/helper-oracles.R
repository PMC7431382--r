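# Independent brute-force oracles used across the suite.

# recursive branch-order counter over a parent-pointer tree
branch_order_oracle <- function(trace, max_order = 25) {
  kids <- split(trace$id, factor(trace$parent, levels = trace$id))
  root <- trace$id[trace$parent == -1]
  soma_ids <- union(root, trace$id[trace$type == 1])
  counts <- integer(max_order)
  recurse <- function(node, order, from_start) {
    ch <- kids[[as.character(node)]]
    is_soma <- node %in% soma_ids
    branch_pt <- !is_soma && length(ch) >= 2
    for (c in ch) {
      new_order <- if (is_soma) 1L else if (branch_pt) order + 1L else order
      if (is_soma || branch_pt) {
        if (new_order <= max_order) counts[new_order] <<- counts[new_order] + 1L
      }
      recurse(c, new_order, FALSE)
    }
  }
  recurse(root, 0L, TRUE)
  counts
}

# Sholl intersections by dense resampling of every segment
sholl_oracle <- function(trace, radii, step = 0.01) {
  ctr <- c(mean(trace$x[trace$type == 1]), mean(trace$y[trace$type == 1]),
           mean(trace$z[trace$type == 1]))
  seg <- merge(trace, trace[, c("id", "x", "y", "z")],
               by.x = "parent", by.y = "id", suffixes = c("", "_p"))
  counts <- integer(length(radii))
  for (s in seq_len(nrow(seg))) {
    p1 <- c(seg$x_p[s], seg$y_p[s], seg$z_p[s]) - ctr
    p2 <- c(seg$x[s], seg$y[s], seg$z[s]) - ctr
    len <- sqrt(sum((p2 - p1)^2))
    t <- seq(0, 1, by = min(step / max(len, step), 0.5))
    d <- sqrt(colSums((outer(p1, rep(1, length(t))) +
                         outer(p2 - p1, rep(1, length(t))) *
                         rep(t, each = 3))^2))
    for (ri in seq_along(radii)) {
      inside <- d < radii[ri]
      counts[ri] <- counts[ri] + sum(diff(inside) != 0)
    }
  }
  counts
}

# convex hull volume by brute-force facet enumeration: a triple of points
# is a hull facet iff all points lie on one side of its plane
hull_volume_oracle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  interior <- colMeans(pts)
  vol <- 0
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    side <- (pts %*% nrm) - sum(nrm * a)
    if (all(side <= 1e-9) || all(side >= -1e-9)) {
      vol <- vol + abs(det(rbind(a - interior, b - interior, c - interior))) / 6
    }
  }
  vol
}

# Spearman rho by explicit average-ranking followed by the Pearson
# product-moment formula
spearman_oracle <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  n <- length(rx)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# small counts fixture: ng null genes, NB(mu, phi), two groups of 3
null_counts_fixture <- function(ng, mu = 100, phi = 0.1, seed = 7) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnbinom(ng * 6, mu = mu, size = 1 / phi), ng)
    dplyr::bind_cols(
      tibble::tibble(gene = sprintf("g%04d", seq_len(ng))),
      tibble::as_tibble(as.data.frame(m), .name_repair = ~ paste0("s", 1:6))
    )
  })
}
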