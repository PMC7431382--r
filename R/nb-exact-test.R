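#' Simplified gene-wise negative-binomial exact test
#'
#' Two-sided exact test for a difference in mean expression between two
#' groups of samples under a negative-binomial model with a common
#' dispersion shared across genes. Library sizes are equalised by
#' total-count normalization (counts are rescaled to the geometric-mean
#' library and rounded), the common dispersion is estimated by the method
#' of moments pooled within groups, and the p-value for each gene is the
#' total probability of all splits of the gene's count sum between the two
#' groups that are no more likely than the observed split (group sums are
#' NB-distributed with size scaled by replicate number). This is a
#' deliberately simple exact test; it does not reimplement quasi-likelihood
#' F-testing or TMM normalization, and externally computed DE tables can be
#' supplied downstream via [read_de_table()].
#'
#' @param counts Counts tibble (`gene` + sample columns) or [sim_counts()]
#'   object.
#' @param groupA,groupB Sample identifiers of the two groups, or group
#'   labels resolved against `metadata$group` when `metadata` is given.
#' @param metadata Optional sample sheet (`sample`, `group`).
#' @param dispersion Optional fixed NB dispersion phi; estimated when `NULL`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return Tibble of class `nb_de`: `gene`, `logFC` (log2 A vs B),
#'   `p_value`, `significant`; the dispersion used is in attribute
#'   `dispersion`.
#' @export
#' @examples
#' sim <- sim_counts(seed = 1)
#' de <- nb_exact_test(sim, "P60_MIA_CTRL", "P60_Saline_CTRL")
#' head(de)
nb_exact_test <- function(counts, groupA, groupB, metadata = NULL,
                          dispersion = NULL, alpha = 0.05) {
  if (inherits(counts, "mia_counts")) {
    metadata <- metadata %||% counts$metadata
    counts <- counts$counts
  }
  m <- counts_to_matrix(as_counts_tbl(counts))
  resolve <- function(g) {
    if (!is.null(metadata) && any(metadata$group %in% g)) {
      intersect(colnames(m), metadata$sample[metadata$group %in% g])
    } else {
      intersect(colnames(m), g)
    }
  }
  sa <- resolve(groupA)
  sb <- resolve(groupB)
  if (length(sa) < 2 || length(sb) < 2) abort("each group needs at least 2 samples")
  libs <- colSums(m[, c(sa, sb), drop = FALSE])
  if (any(libs == 0)) {
    abort(paste0("all-zero library in sample(s): ",
                 paste(names(libs)[libs == 0], collapse = ", ")))
  }

  # total-count normalization to the geometric-mean library
  ref <- exp(mean(log(libs)))
  norm <- sweep(m[, c(sa, sb), drop = FALSE], 2, ref / libs, "*")
  norm <- round(norm)
  a_idx <- seq_along(sa)
  b_idx <- length(sa) + seq_along(sb)
  nA <- length(sa)
  nB <- length(sb)

  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(norm, a_idx, b_idx)

  yA <- rowSums(norm[, a_idx, drop = FALSE])
  yB <- rowSums(norm[, b_idx, drop = FALSE])
  p <- purrr::map2_dbl(yA, yB, function(a, b) {
    nb_exact_p(a, b, nA, nB, dispersion)
  })
  logfc <- log2((yA / nA + 0.125) / (yB / nB + 0.125))
  out <- tibble::tibble(gene = rownames(m), logFC = unname(logfc),
                        p_value = unname(p),
                        significant = unname(p) < alpha)
  attr(out, "dispersion") <- dispersion
  class(out) <- c("nb_de", class(out))
  out
}

# method-of-moments common dispersion, pooled within groups and across
# genes (regression through the origin of excess variance on squared mean,
# with the sampling variance of the mean removed from the denominator)
estimate_common_dispersion <- function(norm, a_idx, b_idx, floor = 1e-4) {
  mm <- rowMeans(norm)
  va <- apply(norm[, a_idx, drop = FALSE], 1, var)
  vb <- apply(norm[, b_idx, drop = FALSE], 1, var)
  nA <- length(a_idx)
  nB <- length(b_idx)
  ntot <- nA + nB
  v <- ((nA - 1) * va + (nB - 1) * vb) / (nA + nB - 2)
  keep <- mm >= 1
  if (!any(keep)) return(floor)
  num <- sum(v[keep] - mm[keep])
  den <- sum(mm[keep]^2 - v[keep] / ntot)
  if (den <= 0) return(floor)
  max(num / den, floor)
}

# exact two-sided p: probability of all splits of s = a + b no more likely
# than the observed one, with group sums NB(n * mu, n / phi)
nb_exact_p <- function(a, b, nA, nB, phi) {
  s <- a + b
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  x <- 0:s
  pa <- dnbinom(x, mu = nA * mu, size = nA / phi)
  pb <- dnbinom(s - x, mu = nB * mu, size = nB / phi)
  joint <- pa * pb
  tot <- sum(joint)
  if (tot == 0) return(1)
  obs <- joint[a + 1]
  min(1, sum(joint[joint <= obs * (1 + 1e-12)]) / tot)
}

#' Read an externally computed differential-expression table
#'
#' Pluggable entry point for DE results produced by external tooling
#' (e.g. quasi-likelihood pipelines): reads a delimited table and
#' standardises it to the same shape as [nb_exact_test()] output.
#'
#' @param path TSV/CSV path with columns for gene, log fold-change and
#'   p-value.
#' @param gene,logFC,p_value Column names in the file.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble `gene`, `logFC`, `p_value`, `significant`.
#' @export
read_de_table <- function(path, gene = "gene", logFC = "logFC",
                          p_value = "p_value", alpha = 0.05) {
  tbl <- readr::read_delim(path, show_col_types = FALSE)
  missing <- setdiff(c(gene, logFC, p_value), names(tbl))
  if (length(missing) > 0) {
    abort(paste0("missing column(s) in DE table: ", paste(missing, collapse = ", ")))
  }
  p_col <- as.numeric(tbl[[p_value]])
  tibble::tibble(gene = as.character(tbl[[gene]]),
                 logFC = as.numeric(tbl[[logFC]]),
                 p_value = p_col,
                 significant = p_col < alpha)
}
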