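#' Tidy a module fit
#'
#' @param x A `module_fit` from [kmeans_modules()].
#' @param ... Unused.
#' @return Tibble `gene`, `module`, `cluster`.
#' @exportS3Method generics::tidy
tidy.module_fit <- function(x, ...) x$assignment

#' One-row summary of a module fit
#'
#' @inheritParams tidy.module_fit
#' @return Tibble `k`, `n_genes`, `n_modules`, `wcss`, `seed`.
#' @exportS3Method generics::glance
glance.module_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$assignment),
                 n_modules = nrow(x$sizes), wcss = x$wcss, seed = x$seed)
}

#' Tidy a correlation surface
#'
#' @param x A `cor_surface` from [spearman_matrix()].
#' @param ... Unused.
#' @return Long tibble `feature1`, `feature2`, `rho`, `p_value`, `n` over
#'   all unordered feature pairs (diagonal included).
#' @exportS3Method generics::tidy
tidy.cor_surface <- function(x, ...) {
  k <- length(x$features)
  idx <- which(upper.tri(x$rho, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    feature1 = x$features[idx[, 1]],
    feature2 = x$features[idx[, 2]],
    rho = x$rho[idx],
    p_value = x$p[idx],
    n = x$n[idx]
  )
}

#' One-row summary of a correlation surface
#'
#' @inheritParams tidy.cor_surface
#' @return Tibble `n_features`, `n_pairs`, `n_significant`, `min_n`,
#'   `max_abs_rho`.
#' @exportS3Method generics::glance
glance.cor_surface <- function(x, ...) {
  off <- upper.tri(x$rho)
  tibble::tibble(
    n_features = length(x$features),
    n_pairs = sum(off),
    n_significant = sum(x$p[off] < 0.05, na.rm = TRUE),
    min_n = min(x$n[off]),
    max_abs_rho = suppressWarnings(max(abs(x$rho[off]), na.rm = TRUE))
  )
}

#' One-row summary of a differential-expression result
#'
#' @param x An `nb_de` tibble from [nb_exact_test()].
#' @param ... Unused.
#' @return Tibble `n_genes`, `n_significant`, `dispersion`.
#' @exportS3Method generics::glance
glance.nb_de <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_significant = sum(x$significant),
                 dispersion = attr(x, "dispersion"))
}

#' Heatmap of module centroid profiles
#'
#' @param object A `module_fit`.
#' @param ... Unused.
#' @return A ggplot: modules x samples tile map of centroid z-scores.
#' @exportS3Method ggplot2::autoplot
autoplot.module_fit <- function(object, ...) {
  labels <- object$sizes$module[order(object$sizes$module)]
  cent <- object$centroids
  df <- tibble::as_tibble(cent, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "sample", values_to = "z") |>
    dplyr::mutate(module = tidy(object)$module[
      match(.data$cluster, as.character(tidy(object)$cluster))])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$module, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = "module", fill = "centroid z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Colour map of a correlation surface
#'
#' @param object A `cor_surface`.
#' @param alpha Starring level for significant pairs.
#' @param ... Unused.
#' @return A ggplot tile map of rho from red (+1) to green (-1), starred
#'   at p < alpha.
#' @exportS3Method ggplot2::autoplot
autoplot.cor_surface <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(dplyr::filter(df, .data$feature1 != .data$feature2),
                                            feature1 = "feature2", feature2 = "feature1"))
  ggplot2::ggplot(df2, ggplot2::aes(.data$feature1, .data$feature2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = dplyr::filter(df2, !is.na(.data$p_value), .data$p_value < alpha,
                                            .data$feature1 != .data$feature2),
                       label = "*") +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Elbow plot of within-cluster sum of squares
#'
#' @param wcss Tibble `k`, `wcss` from [wcss_by_k()].
#' @return A ggplot with the selected elbow marked.
#' @export
plot_elbow <- function(wcss) {
  k_star <- select_k_elbow(wcss)
  ggplot2::ggplot(wcss, ggplot2::aes(.data$k, .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = k_star, linetype = "dashed") +
    ggplot2::labs(x = "k", y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
}

#' Sholl profile plot
#'
#' @param profile Tibble `radius_um`, `intersections` from [sholl()].
#' @return A ggplot step profile.
#' @export
plot_sholl <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$radius_um, .data$intersections)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "radius (um)", y = "intersections") +
    ggplot2::theme_minimal()
}
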