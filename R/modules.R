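#' K-means expression modules
#'
#' Partitions genes into `k` expression modules by k-means on per-sample
#' z-scores of log2(CPM + 1) (rows are genes, features are samples,
#' Euclidean distance, multiple restarts under a fixed seed). Each module is
#' labelled by the sample group in which its centroid is maximal; when the
#' design carries the standard age/prenatal/drug columns, the argmax group
#' is mapped to the canonical module names (IM, MIA-IM, JM, AM, REP-AM),
#' otherwise modules are named M1..Mk.
#'
#' @param expr Row-z-scored expression tibble (`gene` + sample columns),
#'   e.g. `zscore_rows(log_cpm(counts))`, or a [sim_counts()] object (the
#'   full transform is applied after CPM filtering is the caller's choice).
#' @param metadata Sample sheet with `sample` and `group` columns (and
#'   optionally `age`, `prenatal`, `drug` for canonical naming). Taken from
#'   the object when `expr` is a `mia_counts`.
#' @param k Number of modules (default 5).
#' @param seed Integer seed; fixed seed makes the partition bit-reproducible.
#' @param n_restarts Random restarts for k-means (default 25).
#' @return A list of class `module_fit`: `assignment` (tibble `gene`,
#'   `module`, `cluster`), `sizes` (tibble `module`, `n`), `centroids`
#'   (matrix cluster x sample), `wcss` (total within-cluster sum of
#'   squares), `k`, `seed`.
#' @export
#' @examples
#' sim <- sim_counts(seed = 1)
#' z <- zscore_rows(log_cpm(filter_expressed(sim)))
#' fit <- kmeans_modules(z, metadata = sim$metadata, seed = 1)
#' fit$sizes
kmeans_modules <- function(expr, metadata = NULL, k = 5, seed = 1,
                           n_restarts = 25) {
  if (inherits(expr, "mia_counts")) {
    metadata <- metadata %||% expr$metadata
    expr <- zscore_rows(log_cpm(expr$counts))
  }
  stopifnot(k >= 2)
  m <- counts_to_matrix(tibble::as_tibble(expr))
  if (k > nrow(m)) abort("k exceeds the number of genes")
  if (nrow(unique(m)) < k) {
    warn("fewer distinct gene profiles than k; collapsing to one effective cluster")
    fit <- list(cluster = rep(1L, nrow(m)),
                centers = matrix(colMeans(m), 1, dimnames = list(NULL, colnames(m))),
                tot.withinss = sum(scale(m, scale = FALSE)^2))
  } else {
    fit <- with_seed(seed, suppressWarnings(
      kmeans(m, centers = k, nstart = n_restarts, iter.max = 100)
    ))
  }
  labels <- name_modules(fit$centers, metadata)
  assignment <- tibble::tibble(
    gene = rownames(m),
    cluster = unname(fit$cluster),
    module = labels[fit$cluster]
  )
  sizes <- dplyr::count(assignment, .data$module, name = "n")
  structure(list(assignment = assignment, sizes = sizes,
                 centroids = fit$centers, wcss = fit$tot.withinss,
                 k = k, seed = seed),
            class = "module_fit")
}

# label each cluster by the group in which its centroid mean is maximal;
# canonical names when the metadata carries the standard design columns
name_modules <- function(centers, metadata) {
  k <- nrow(centers)
  if (is.null(metadata) || !all(c("sample", "group") %in% names(metadata))) {
    return(paste0("M", seq_len(k)))
  }
  meta <- metadata[match(colnames(centers), metadata$sample), ]
  group_means <- t(apply(centers, 1, function(row) {
    tapply(row, meta$group, mean)
  }))
  argmax <- colnames(group_means)[apply(group_means, 1, which.max)]
  canonical <- all(c("age", "prenatal", "drug") %in% names(meta))
  labels <- purrr::map_chr(argmax, function(g) {
    if (!canonical) return(g)
    row <- meta[match(g, meta$group), ]
    if (row$age %in% c("E17", "P7")) {
      if (row$prenatal == "MIA") "MIA-IM" else "IM"
    } else if (row$age == "P20") {
      "JM"
    } else if (row$drug == "MG-REP" && row$prenatal == "Saline") {
      "REP-AM"
    } else {
      "AM"
    }
  })
  make.unique(labels, sep = ".")
}

#' @export
print.module_fit <- function(x, ...) {
  cat("<module_fit> k = ", x$k, "; sizes: ",
      paste(x$sizes$module, x$sizes$n, sep = "=", collapse = ", "),
      "; WCSS = ", format(x$wcss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Within-cluster sum of squares over a range of k
#'
#' Runs k-means for each candidate `k` and records the total within-cluster
#' sum of squares, the input to the elbow criterion.
#'
#' @inheritParams kmeans_modules
#' @param k_range Candidate numbers of clusters (default 1:8).
#' @return Tibble `k`, `wcss`.
#' @export
wcss_by_k <- function(expr, k_range = 1:8, seed = 1, n_restarts = 25) {
  if (inherits(expr, "mia_counts")) {
    expr <- zscore_rows(log_cpm(expr$counts))
  }
  m <- counts_to_matrix(tibble::as_tibble(expr))
  tss <- sum(scale(m, scale = FALSE)^2)
  wcss <- purrr::map_dbl(k_range, function(k) {
    if (k == 1) return(tss)
    with_seed(derive_seed(seed, paste0("k", k)), suppressWarnings(
      kmeans(m, centers = k, nstart = n_restarts, iter.max = 100)$tot.withinss
    ))
  })
  tibble::tibble(k = as.integer(k_range), wcss = wcss)
}

#' Elbow-method choice of k
#'
#' Returns the `k` at which the within-cluster sum-of-squares curve bends
#' most sharply: the interior point maximising the second difference of
#' log(WCSS), i.e. the curvature of the relative WCSS drop. The relative
#' form keeps the criterion comparable across the steep early part of the
#' curve, where absolute drops shrink geometrically even before the true
#' cluster number is reached. Ties (e.g. an exactly linear curve) break to
#' the smallest k with a warning.
#'
#' @param wcss Tibble `k`, `wcss` from [wcss_by_k()] (at least 3 rows,
#'   consecutive k).
#' @return The selected integer k.
#' @export
#' @examples
#' select_k_elbow(tibble::tibble(k = 1:4, wcss = c(100, 40, 38, 37)))  # 2
select_k_elbow <- function(wcss) {
  stopifnot(all(c("k", "wcss") %in% names(wcss)))
  wcss <- dplyr::arrange(tibble::as_tibble(wcss), .data$k)
  if (nrow(wcss) < 3) abort("elbow selection needs at least 3 k values")
  d2 <- diff(log(wcss$wcss + 1e-12 * max(wcss$wcss)), differences = 2)
  tie <- sum(abs(d2 - max(d2)) < 1e-12) > 1
  if (tie || max(d2) <= 0) {
    warn("no clear elbow in the WCSS curve; returning the smallest candidate bend")
  }
  wcss$k[which.max(d2) + 1L]
}
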