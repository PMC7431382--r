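# accept a raw counts tibble (gene + samples) or a mia_counts object
as_counts_tbl <- function(x) {
  if (inherits(x, "mia_counts")) x$counts else tibble::as_tibble(x)
}

#' Counts per million
#'
#' Library-size-normalizes an integer counts table: each count is divided by
#' its sample's total and scaled to one million, so every sample column sums
#' to 1e6.
#'
#' @param counts Counts tibble (`gene` column plus one integer column per
#'   sample) or a [sim_counts()] object.
#' @return A tibble of the same shape on the CPM scale, with attribute
#'   `scale = "CPM"`.
#' @export
#' @examples
#' tb <- tibble::tibble(gene = c("a", "b"), s1 = c(2L, 999998L))
#' cpm(tb)$s1[1]  # 2
cpm <- function(counts) {
  tbl <- as_counts_tbl(counts)
  m <- counts_to_matrix(tbl)
  libs <- colSums(m)
  if (any(libs == 0)) {
    abort(paste0("zero library size in sample(s): ",
                 paste(colnames(m)[libs == 0], collapse = ", ")))
  }
  out <- matrix_to_tbl(sweep(m, 2, libs, "/") * 1e6)
  attr(out, "scale") <- "CPM"
  out
}

#' Filter genes by minimum CPM in a minimum number of samples
#'
#' Retains genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples (the criterion that yields the 14,225-gene microglial universe
#' on the full study data). Gene order is preserved.
#'
#' @inheritParams cpm
#' @param min_cpm CPM threshold (default 2).
#' @param min_samples Minimum qualifying samples (default 3).
#' @return The retained rows of the counts table; the number of retained
#'   genes is stored in attribute `n_retained`.
#' @export
filter_expressed <- function(counts, min_cpm = 2, min_samples = 3) {
  stopifnot(min_cpm > 0, min_samples > 0)
  tbl <- as_counts_tbl(counts)
  if (nrow(tbl) == 0) abort("empty counts matrix")
  cpm_m <- counts_to_matrix(cpm(tbl))
  keep <- rowSums(cpm_m >= min_cpm) >= min_samples
  out <- tbl[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Row-wise z-scores
#'
#' Centres and scales each gene row of a log-scale expression table to mean
#' 0 and unit standard deviation. Constant rows are mapped to all zeros with
#' a warning (they carry no profile information for clustering).
#'
#' @param expr Expression tibble (`gene` + sample columns), conventionally
#'   log2(CPM + 1).
#' @return A tibble of z-scores with attribute `scale = "zscore"`.
#' @export
zscore_rows <- function(expr) {
  m <- counts_to_matrix(tibble::as_tibble(expr))
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flat <- s == 0 | is.na(s)
  if (any(flat)) {
    warn(paste0(sum(flat), " constant row(s) mapped to all-zero z-scores"))
    s[flat] <- 1
  }
  z <- (m - mu) / s
  z[flat, ] <- 0
  out <- matrix_to_tbl(z)
  attr(out, "scale") <- "zscore"
  out
}

#' log2(CPM + 1) transform
#'
#' Convenience composition of [cpm()] and the log transform used throughout
#' the clustering and PCA stages.
#'
#' @inheritParams cpm
#' @return Tibble on the log2(CPM + 1) scale.
#' @export
log_cpm <- function(counts) {
  cp <- cpm(counts)
  m <- counts_to_matrix(cp)
  out <- matrix_to_tbl(log2(m + 1))
  attr(out, "scale") <- "log2(CPM+1)"
  out
}

#' Cell-type purity profile from a marker panel
#'
#' For each sample, computes the fraction of the total marker-panel
#' expression contributed by each cell type's markers:
#' fraction(type, sample) = sum(TPM of type's markers) / sum(TPM of all 25
#' panel genes). On length-free synthetic data CPM serves as the TPM
#' surrogate (the statistic is a within-panel ratio, invariant to a common
#' per-sample scale); the scale used is recorded in the output.
#'
#' @param expr Expression tibble on a TPM-like scale (e.g. [cpm()] output),
#'   or a [sim_counts()] object (CPM is computed).
#' @param panel Marker panel tibble (`cell_type`, `gene`); default
#'   [marker_panel()]. Panel genes missing from the matrix are scored as 0
#'   with a warning.
#' @return A tibble `sample`, `cell_type`, `fraction`, `defined` (FALSE
#'   where the panel total is 0 in a sample, in which case fractions are
#'   `NA`, not silently 0). Attribute `scale` records the expression scale.
#' @export
purity <- function(expr, panel = marker_panel()) {
  if (inherits(expr, "mia_counts")) expr <- cpm(expr)
  scale_used <- attr(expr, "scale") %||% "TPM"
  m <- counts_to_matrix(tibble::as_tibble(expr))
  missing <- setdiff(panel$gene, rownames(m))
  if (length(missing) > 0) {
    warn(paste0("panel gene(s) absent, scored as 0: ",
                paste(missing, collapse = ", ")))
  }
  pm <- matrix(0, nrow(panel), ncol(m),
               dimnames = list(panel$gene, colnames(m)))
  present <- intersect(panel$gene, rownames(m))
  pm[present, ] <- m[present, ]
  totals <- colSums(pm)
  out <- purrr::map_dfr(unique(panel$cell_type), function(ct) {
    rows <- panel$gene[panel$cell_type == ct]
    tibble::tibble(
      sample = colnames(m),
      cell_type = ct,
      fraction = unname(ifelse(totals > 0,
                               colSums(pm[rows, , drop = FALSE]) / totals,
                               NA_real_)),
      defined = unname(totals > 0)
    )
  })
  attr(out, "scale") <- scale_used
  out
}

#' PCA sample scores
#'
#' Principal component analysis over samples (observations) with genes as
#' variables, used to compare variability between groups. Components are
#' ordered by explained variance.
#'
#' @param expr Expression tibble (`gene` + sample columns), conventionally
#'   log2(CPM + 1).
#' @param n_components Number of components to return (default
#'   `min(n_samples, 10)`).
#' @return A tibble `sample`, `component`, `score`, `var_explained`.
#' @export
pca_scores <- function(expr, n_components = NULL) {
  m <- counts_to_matrix(tibble::as_tibble(expr))
  n_samp <- ncol(m)
  n_components <- n_components %||% min(n_samp, 10L)
  if (n_components > n_samp) abort("n_components exceeds number of samples")
  if (nrow(m) < n_components) abort("fewer genes than requested components")
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  k <- seq_len(min(n_components, ncol(fit$x)))
  tidyr::expand_grid(component = k, sample = colnames(m)) |>
    dplyr::mutate(
      score = purrr::map2_dbl(.data$sample, .data$component,
                              function(s, cc) fit$x[s, cc]),
      var_explained = ve[.data$component]
    ) |>
    dplyr::select("sample", "component", "score", "var_explained")
}
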