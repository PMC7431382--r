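test_that("cpm rescales to counts per million", {
  tb <- tibble::tibble(gene = c("a", "b", "c"),
                       s1 = c(2L, 999996L, 2L), s2 = c(0L, 10L, 10L))
  out <- cpm(tb)
  expect_equal(out$s1[1], 2)
  expect_equal(out$s2[1], 0)  # all-zero gene stays zero
  withr::with_seed(1, {
    rnd <- dplyr::bind_cols(
      tibble::tibble(gene = paste0("g", 1:20)),
      tibble::as_tibble(as.data.frame(matrix(rpois(120, 50), 20)),
                        .name_repair = ~ paste0("s", 1:6))
    )
  })
  sums <- colSums(as.matrix(cpm(rnd)[, -1]))
  expect_equal(unname(sums), rep(1e6, 6), tolerance = 1e-9)
  zero <- tibble::tibble(gene = "a", s1 = 1L, s2 = 0L)
  expect_error(cpm(zero), "s2")
})

test_that("expression filter applies the CPM >= 2 in >= 3 samples rule", {
  # 30 samples with library size 1e6 so counts equal CPM
  mk <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    # pad a balance gene so libraries are exactly 1e6
    pad <- 1e6 - colSums(m)
    tbl <- as.data.frame(rbind(m, pad))
    names(tbl) <- paste0("s", seq_len(ncol(m)))
    dplyr::bind_cols(tibble::tibble(gene = c(paste0("g", seq_along(rows)), "pad")), tbl)
  }
  boundary <- c(2, 2, 2, rep(0, 27))
  two_only <- c(5, 5, rep(0, 28))
  tb <- mk(boundary, two_only)
  kept <- filter_expressed(tb, min_cpm = 2, min_samples = 3)
  expect_true("g1" %in% kept$gene)
  expect_false("g2" %in% kept$gene)

  # planted passing genes equal the brute-force per-gene scan
  withr::with_seed(5, {
    m <- matrix(rpois(50 * 30, 1), 50, 30)
    pass_rows <- sample(50, 18)
    m[pass_rows, 1:5] <- 60
    tbl <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:50)),
                            tibble::as_tibble(as.data.frame(m),
                                              .name_repair = ~ paste0("s", 1:30)))
  })
  cpm_m <- as.matrix(cpm(tbl)[, -1])
  oracle_keep <- sum(vapply(seq_len(50), function(g) {
    sum(cpm_m[g, ] >= 2) >= 3
  }, logical(1)))
  expect_equal(attr(filter_expressed(tbl), "n_retained"), oracle_keep)
  expect_error(filter_expressed(tbl[0, ]), "empty")
})

test_that("row z-scoring centres and scales, flagging constant rows", {
  tb <- tibble::tibble(gene = "a", s1 = 1, s2 = 2, s3 = 3)
  z <- as.numeric(zscore_rows(tb)[, -1])
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  const <- tibble::tibble(gene = c("a", "b"), s1 = c(5, 1), s2 = c(5, 2), s3 = c(5, 9))
  expect_warning(zc <- zscore_rows(const), "constant")
  expect_equal(as.numeric(zc[1, -1]), c(0, 0, 0))
  withr::with_seed(2, {
    rnd <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:30)),
                            tibble::as_tibble(as.data.frame(matrix(rnorm(300), 30)),
                                              .name_repair = ~ paste0("s", 1:10)))
  })
  zm <- as.matrix(zscore_rows(rnd)[, -1])
  expect_true(all(abs(rowMeans(zm)) < 1e-10))
})

test_that("purity fractions are within-panel TPM ratios", {
  panel <- marker_panel()
  base <- tibble::tibble(gene = panel$gene)
  only_mg <- dplyr::mutate(base, s1 = ifelse(panel$cell_type == "microglia", 10, 0))
  p1 <- purity(only_mg)
  expect_equal(p1$fraction[p1$cell_type == "microglia"], 1)
  expect_equal(sum(p1$fraction), 1)

  equal <- dplyr::mutate(base, s1 = 7)
  p2 <- purity(equal)
  expect_equal(p2$fraction, rep(0.2, 5))

  # 980 vs 20 split mirrors ~98% purity
  mix <- dplyr::mutate(base, s1 = ifelse(panel$cell_type == "microglia",
                                         980 / 5, 20 / 20))
  p3 <- purity(mix)
  expect_equal(p3$fraction[p3$cell_type == "microglia"], 0.98)

  # missing panel genes warn; all-zero panel flags undefined
  expect_warning(purity(only_mg[-1, ]), "absent")
  zero <- dplyr::mutate(base, s1 = 0)
  pz <- purity(zero)
  expect_true(all(!pz$defined))
  expect_true(all(is.na(pz$fraction)))
})

test_that("PCA scores match the covariance eigendecomposition and separate groups", {
  withr::with_seed(3, {
    m <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  })
  tb <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                         tibble::as_tibble(as.data.frame(m)))
  sc <- pca_scores(tb, n_components = 3)
  # oracle: eigendecomposition of the sample covariance of centred samples
  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x) / (nrow(x) - 1))
  for (comp in 1:3) {
    ours <- sc$score[sc$component == comp][match(paste0("s", 1:6),
                                                 sc$sample[sc$component == comp])]
    oracle <- as.numeric(x %*% eig$vectors[, comp])
    expect_lt(min(max(abs(ours - oracle)), max(abs(ours + oracle))), 1e-8)
  }
  expect_lte(sum(unique(sc$var_explained)), 1 + 1e-12)

  # two duplicated sample groups with distinct means split on PC1
  grp <- cbind(matrix(rnorm(40, 0, 0.01), 20, 2), matrix(rnorm(40, 5, 0.01), 20, 2))
  colnames(grp) <- paste0("s", 1:4)
  gtb <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:20)),
                          tibble::as_tibble(as.data.frame(grp)))
  g1 <- pca_scores(gtb, 2)
  pc1 <- g1$score[g1$component == 1]
  expect_true(all(sign(pc1[1:2]) != sign(pc1[3:4])))
  expect_error(pca_scores(gtb, 10), "exceeds")
})

test_that("module discovery recovers planted structure reproducibly", {
  sim <- sim_counts(seed = 1)
  z <- zscore_rows(log_cpm(filter_expressed(sim)))
  fit1 <- kmeans_modules(z, metadata = sim$metadata, seed = 7)
  fit2 <- kmeans_modules(z, metadata = sim$metadata, seed = 7)
  expect_identical(fit1$assignment, fit2$assignment)

  # partition identity: module sizes sum to the number of clustered genes
  expect_equal(sum(fit1$sizes$n), nrow(z))

  # canonical naming covers the five expected module labels
  expect_setequal(fit1$sizes$module, c("IM", "MIA-IM", "JM", "AM", "REP-AM"))

  truth <- dplyr::inner_join(tidy(fit1), sim$truth, by = "gene",
                             suffix = c("_fit", "_truth"))
  truth <- dplyr::filter(truth, .data$module_truth != "background")
  expect_gte(mclust::adjustedRandIndex(truth$module_fit, truth$module_truth), 0.9)

  expect_error(kmeans_modules(z[1:3, ], k = 10), "exceeds")
})

test_that("degenerate clustering input warns", {
  flat <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:6)),
                           tibble::as_tibble(as.data.frame(matrix(0, 6, 4)),
                                             .name_repair = ~ paste0("s", 1:4)))
  expect_warning(kmeans_modules(flat, k = 2, seed = 1), "degenerate|distinct")
})

test_that("elbow selection maximises relative-drop curvature", {
  expect_equal(select_k_elbow(tibble::tibble(k = 1:4, wcss = c(100, 40, 38, 37))), 2L)
  expect_warning(
    lin <- select_k_elbow(tibble::tibble(k = 1:5, wcss = c(50, 40, 30, 20, 10))),
    "no clear elbow"
  )
  expect_equal(lin, 2L)
  expect_error(select_k_elbow(tibble::tibble(k = 1:2, wcss = c(2, 1))), "at least 3")
})

test_that("NB exact test returns p = 1 for identical groups", {
  tb <- tibble::tibble(gene = paste0("g", 1:5),
                       a1 = c(10L, 40L, 5L, 100L, 0L), a2 = c(12L, 35L, 6L, 90L, 0L),
                       a3 = c(9L, 42L, 5L, 110L, 0L))
  tb <- dplyr::bind_cols(tb, setNames(tb[, 2:4], c("b1", "b2", "b3")))
  de <- nb_exact_test(tb, paste0("a", 1:3), paste0("b", 1:3), dispersion = 1e-4)
  expect_true(all(de$p_value == 1))
  expect_true(all(abs(de$logFC) < 1e-9))
})

test_that("NB exact test flags strong planted shifts and agrees with an external exact test", {
  skip_if_not_installed("edgeR")
  withr::with_seed(13, {
    ng <- 300
    shifted <- 1:30
    muA <- rep(100, ng); muA[shifted] <- 800
    mA <- matrix(rnbinom(ng * 3, mu = muA, size = 10), ng)
    mB <- matrix(rnbinom(ng * 3, mu = 100, size = 10), ng)
  })
  tb <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:ng)),
                         tibble::as_tibble(as.data.frame(cbind(mA, mB)),
                                           .name_repair = ~ paste0("s", 1:6)))
  de <- nb_exact_test(tb, paste0("s", 1:3), paste0("s", 4:6))
  expect_gte(mean(de$significant[shifted]), 0.9)

  # independent cross-check: edgeR's exact test at the same dispersion
  y <- edgeR::DGEList(counts = as.matrix(tb[, -1]),
                      group = rep(c("A", "B"), each = 3))
  y$common.dispersion <- attr(de, "dispersion")
  et <- edgeR::exactTest(y, pair = c("B", "A"))$table
  expect_gt(cor(rank(de$p_value), rank(et$PValue)), 0.95)
  expect_gte(mean(et$PValue[shifted] < 0.05), 0.9)
})

test_that("external DE tables are standardised on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = c("a", "b"), logFC = c(2, -1),
                                  p_value = c(0.001, 0.4)), path)
  de <- read_de_table(path)
  expect_equal(de$significant, c(TRUE, FALSE))
  expect_error(read_de_table(path, p_value = "nope"), "missing column")
})
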