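#' Build a cross-species overlap background from one-to-one orthologs
#'
#' Constructs the gene universe for cross-species overlap testing: the
#' ortholog map is reduced to strictly one-to-one pairs (genes appearing in
#' more than one pair on either side are dropped), human gene lists are
#' restricted to genes with mouse orthologs and mapped into mouse
#' identifier space (mouse is the measurement space), mouse module lists
#' are restricted to genes with human orthologs, and the background is the
#' union of the two filtered universes. On the study's data this recipe
#' gives the 13,757-gene background (12,487 mouse-side and 5,628
#' human-side unique genes).
#'
#' @param mouse_sets Named list of character vectors (mouse gene ids).
#' @param human_sets Named list of character vectors (human gene ids).
#' @param orthologs Data frame with columns `mouse`, `human`.
#' @return A list of class `overlap_background`: `background` (character
#'   universe, mouse ids), `mouse_sets` and `human_sets` (filtered/mapped
#'   named lists), `n` (universe size), `provenance` (tibble of per-side
#'   unique-gene counts).
#' @export
build_background <- function(mouse_sets, human_sets, orthologs) {
  stopifnot(all(c("mouse", "human") %in% names(orthologs)))
  orthologs <- dplyr::distinct(tibble::as_tibble(orthologs), .data$mouse, .data$human)
  one2one <- orthologs |>
    dplyr::group_by(.data$mouse) |> dplyr::filter(dplyr::n() == 1) |>
    dplyr::group_by(.data$human) |> dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
  h2m <- setNames(one2one$mouse, one2one$human)

  mouse_f <- purrr::imap(mouse_sets, function(s, nm) {
    out <- intersect(unique(s), one2one$mouse)
    if (length(out) == 0) warn(paste0("mouse set '", nm, "' has no orthologous members"))
    out
  })
  human_f <- purrr::imap(human_sets, function(s, nm) {
    out <- unname(h2m[intersect(unique(s), names(h2m))])
    if (length(out) == 0) warn(paste0("human set '", nm, "' has no orthologous members"))
    out
  })
  mouse_universe <- unique(unlist(mouse_f, use.names = FALSE))
  human_universe <- unique(unlist(human_f, use.names = FALSE))
  background <- union(mouse_universe, human_universe)
  structure(list(
    background = background,
    mouse_sets = mouse_f,
    human_sets = human_f,
    n = length(background),
    provenance = tibble::tibble(
      side = c("mouse", "human", "union"),
      n_unique = c(length(mouse_universe), length(human_universe), length(background))
    )
  ), class = "overlap_background")
}

#' @export
print.overlap_background <- function(x, ...) {
  cat("<overlap_background> N = ", x$n, " (mouse ",
      x$provenance$n_unique[1], ", human ", x$provenance$n_unique[2], ")\n",
      sep = "")
  invisible(x)
}

as_background <- function(bg) {
  if (inherits(bg, "overlap_background")) bg$background else unique(as.character(bg))
}

#' Hypergeometric gene-set overlap test
#'
#' One-tailed over-representation test (equivalently a one-tailed Fisher's
#' exact test) for the overlap of two gene sets drawn from a finite
#' background: p = P(X >= m) for X ~ Hypergeometric(N, n1, n2), including
#' the observed point. Percent overlap uses the first set (the module) as
#' denominator.
#'
#' @param a,b Character vectors of gene ids (both must be contained in the
#'   background).
#' @param background Character universe or [build_background()] object.
#' @return One-row tibble: `n1`, `n2`, `m`, `N`, `p_value`,
#'   `percent_overlap`.
#' @export
#' @examples
#' hypergeom_overlap(letters[1:5], letters[1:5], letters[1:20])
#' # p = 1 / choose(20, 5)
hypergeom_overlap <- function(a, b, background) {
  bg <- as_background(background)
  a <- unique(a)
  b <- unique(b)
  stray <- setdiff(c(a, b), bg)
  if (length(stray) > 0) {
    abort(paste0("gene(s) outside the background: ",
                 paste(head(stray, 10), collapse = ", "),
                 if (length(stray) > 10) " ..."))
  }
  N <- length(bg)
  n1 <- length(a)
  n2 <- length(b)
  m <- length(intersect(a, b))
  p <- phyper(m - 1, n2, N - n2, n1, lower.tail = FALSE)
  tibble::tibble(n1 = n1, n2 = n2, m = m, N = N, p_value = p,
                 percent_overlap = if (n1 > 0) 100 * m / n1 else NA_real_)
}

#' Module-by-disease-list overlap grid
#'
#' Runs [hypergeom_overlap()] for every (module, disease list) pair and
#' returns the full grid with a significance mask at `alpha`.
#'
#' @param modules,disease_lists Named lists of character vectors.
#' @param background Character universe or [build_background()] object.
#' @param alpha Significance level (default 0.05).
#' @return Tibble of class `overlap_grid`: `module`, `list`, `n1`, `n2`,
#'   `m`, `N`, `p_value`, `percent_overlap`, `significant`.
#' @export
overlap_matrix <- function(modules, disease_lists, background, alpha = 0.05) {
  grid <- tidyr::expand_grid(module = names(modules), list = names(disease_lists))
  out <- purrr::pmap_dfr(grid, function(module, list) {
    dplyr::bind_cols(tibble::tibble(module = module, list = list),
                     hypergeom_overlap(modules[[module]], disease_lists[[list]],
                                       background))
  })
  out$significant <- out$p_value < alpha
  class(out) <- c("overlap_grid", class(out))
  out
}

#' Permutation verification of a gene-set overlap
#'
#' Re-tests an observed overlap against `n_perm` uniform random draws of
#' `|b|` genes from the background (without replacement). The p-value uses
#' the add-one estimator p = (b + 1) / (n_perm + 1), which never reports
#' zero (an observed statistic beating all permutations yields
#' 1 / (n_perm + 1)); a Bonferroni-corrected value across `n_tests`
#' companion tests is also reported.
#'
#' @inheritParams hypergeom_overlap
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param n_tests Number of tests for the Bonferroni correction (default 1).
#' @return One-row tibble of class `perm_test`: `observed`, `n_perm`,
#'   `n_as_extreme`, `p_raw`, `p_bonferroni`, `seed`.
#' @export
permutation_overlap_test <- function(a, b, background, n_perm = 10000,
                                     seed = 1, n_tests = 1) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  bg <- as_background(background)
  a <- unique(a)
  b <- unique(b)
  if (length(b) > length(bg)) abort("|b| exceeds the background size")
  observed <- length(intersect(a, b))
  a_mask <- bg %in% a
  N <- length(bg)
  nb <- length(b)
  exceed <- with_seed(seed, {
    perm <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      perm[i] <- sum(a_mask[sample.int(N, nb)])
    }
    sum(perm >= observed)
  })
  p_raw <- (exceed + 1) / (n_perm + 1)
  out <- tibble::tibble(observed = observed, n_perm = as.integer(n_perm),
                        n_as_extreme = as.integer(exceed), p_raw = p_raw,
                        p_bonferroni = min(1, p_raw * n_tests),
                        seed = as.integer(seed))
  class(out) <- c("perm_test", class(out))
  out
}

#' Connectedness of a gene list in a weighted network
#'
#' Scalar summary of how strongly a gene list is interconnected: by default
#' the mean edge weight over all unordered within-list pairs (a sum-weight
#' alternative is available; the statistic's exact form is a documented
#' package choice).
#'
#' @param genes Character vector of node ids (length >= 2, all in the
#'   network).
#' @param net A `mia_network` (see [sim_network()], [as_mia_network()]).
#' @param statistic `"mean"` (default) or `"sum"` of within-list edge
#'   weights.
#' @return A single numeric value.
#' @export
connectedness <- function(genes, net, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(net, "mia_network"))
  genes <- unique(genes)
  if (length(genes) < 2) abort("gene list must contain at least 2 genes")
  stray <- setdiff(genes, net$nodes)
  if (length(stray) > 0) {
    abort(paste0("gene(s) not in network: ", paste(head(stray, 10), collapse = ", ")))
  }
  sub <- net$weights[genes, genes]
  total <- sum(sub) / 2
  if (statistic == "sum") total else total / choose(length(genes), 2)
}

#' Permutation test of network connectedness
#'
#' Compares the observed connectedness of a gene list with the
#' connectedness of `n_perm` equal-size uniform random node draws, with the
#' add-one p-value estimator (so a list beating all permutations at
#' n_perm = 100000 reports p = 1/100001, i.e. p < 0.00001).
#'
#' @inheritParams connectedness
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return One-row tibble of class `perm_test` as in
#'   [permutation_overlap_test()], with the observed statistic in
#'   `observed`.
#' @export
connectedness_permutation <- function(genes, net, n_perm = 100000, seed = 1,
                                      statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) abort("n_perm must be at least 1")
  observed <- connectedness(genes, net, statistic)
  k <- length(unique(genes))
  n_nodes <- length(net$nodes)
  w <- net$weights
  denom <- if (statistic == "mean") choose(k, 2) else 1
  exceed <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n_nodes, k)
      stat <- sum(w[idx, idx]) / 2 / denom
      if (stat >= observed) count <- count + 1L
    }
    count
  })
  p_raw <- (exceed + 1) / (n_perm + 1)
  out <- tibble::tibble(observed = observed, n_perm = as.integer(n_perm),
                        n_as_extreme = as.integer(exceed), p_raw = p_raw,
                        p_bonferroni = p_raw, seed = as.integer(seed))
  class(out) <- c("perm_test", class(out))
  out
}
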