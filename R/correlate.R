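#' Pairwise Spearman correlation surface
#'
#' Rank-based correlation (average ranks for ties) between every pair of
#' feature columns, with pairwise deletion of missing values (within-cell
#' comparisons across modalities have unequal n). Two-sided p-values use
#' the t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2
#' degrees of freedom. Constant features yield undefined correlations,
#' flagged with a warning rather than silently zeroed.
#'
#' @param features Tibble of per-cell features; non-numeric columns (e.g.
#'   `cell_id`, group labels) are dropped with a message. Missing values
#'   are allowed.
#' @param min_n Minimum complete pairs per correlation (default 3); pairs
#'   with fewer observations are undefined.
#' @return A list of class `cor_surface`: symmetric matrices `rho`, `p`,
#'   `n`, and `features` (column names).
#' @export
#' @examples
#' ft <- tibble::tibble(a = 1:8, b = (1:8)^3, c = -(1:8))
#' spearman_matrix(ft)$rho
spearman_matrix <- function(features, min_n = 3) {
  features <- tibble::as_tibble(features)
  num <- purrr::map_lgl(features, is.numeric)
  if (any(!num)) {
    message("dropping non-numeric column(s): ",
            paste(names(features)[!num], collapse = ", "))
  }
  x <- as.matrix(features[num])
  k <- ncol(x)
  if (k < 2) abort("at least two numeric features required")
  feats <- colnames(x)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(feats, feats))
  n <- matrix(0L, k, k, dimnames = list(feats, feats))
  constants <- character()
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- complete.cases(x[, i], x[, j])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
      if (nn < min_n) next
      xi <- x[ok, i]
      xj <- x[ok, j]
      if (sd(xi) == 0 || sd(xj) == 0) {
        constants <- union(constants, feats[c(i, j)[c(sd(xi) == 0, sd(xj) == 0)]])
        next
      }
      r <- cor(xi, xj, method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      pv <- if (abs(r) >= 1) 0 else {
        tt <- r * sqrt((nn - 2) / (1 - r^2))
        2 * pt(-abs(tt), nn - 2)
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  if (length(constants) > 0) {
    warn(paste0("constant feature(s), correlations undefined: ",
                paste(constants, collapse = ", ")))
  }
  structure(list(rho = rho, p = p, n = n, features = feats),
            class = "cor_surface")
}

#' @export
print.cor_surface <- function(x, ...) {
  cat("<cor_surface> ", length(x$features), " features; ",
      sum(x$p[upper.tri(x$p)] < 0.05, na.rm = TRUE),
      " significant pair(s) at alpha = 0.05\n", sep = "")
  invisible(x)
}

#' Export a correlation surface to CSV
#'
#' Writes the rho, p and n matrices as a single long-format CSV with a
#' significance star at p < alpha (or Bonferroni-corrected p when
#' requested).
#'
#' @param surface A `cor_surface`.
#' @param path Output CSV path.
#' @param alpha Starring level (default 0.05).
#' @param bonferroni Apply Bonferroni correction over the number of
#'   off-diagonal pairs before starring (default FALSE, matching per-cell
#'   starring).
#' @return The written tibble, invisibly.
#' @export
export_surface <- function(surface, path, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(surface, "cor_surface"))
  tbl <- tidy(surface)
  n_tests <- sum(upper.tri(surface$rho))
  p_eff <- if (bonferroni) pmin(1, tbl$p_value * n_tests) else tbl$p_value
  tbl$significant <- !is.na(p_eff) & p_eff < alpha
  readr::write_csv(tbl, path)
  invisible(tbl)
}

#' Read back an exported correlation surface
#'
#' @param path CSV written by [export_surface()].
#' @return A `cor_surface`.
#' @export
read_surface <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  feats <- unique(c(tbl$feature1, tbl$feature2))
  k <- length(feats)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(feats, feats))
  n <- matrix(0L, k, k, dimnames = list(feats, feats))
  idx1 <- match(tbl$feature1, feats)
  idx2 <- match(tbl$feature2, feats)
  rho[cbind(idx1, idx2)] <- rho[cbind(idx2, idx1)] <- tbl$rho
  p[cbind(idx1, idx2)] <- p[cbind(idx2, idx1)] <- tbl$p_value
  n[cbind(idx1, idx2)] <- n[cbind(idx2, idx1)] <- tbl$n
  structure(list(rho = rho, p = p, n = n, features = feats),
            class = "cor_surface")
}
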