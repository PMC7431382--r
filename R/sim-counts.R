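#' The ten-group MIA microglia RNA-seq design
#'
#' Enumerates the default study design: Saline and MIA offspring sampled at
#' E17, P7, P20 and P60 on control chow (CTRL), plus the two P60 microglial
#' repopulation groups (MG-REP), with a fixed number of replicates per
#' group. The default yields 10 groups and 30 samples.
#'
#' @param replicates Replicates per group (default 3).
#' @return A tibble with one row per sample: `sample`, `group`, `age`,
#'   `prenatal`, `drug`, `sex`, `litter`.
#' @export
#' @examples
#' mia_design()          # 30 samples
#' nrow(dplyr::distinct(mia_design(), group))  # 10 groups
mia_design <- function(replicates = 3) {
  stopifnot(replicates >= 1)
  groups <- dplyr::bind_rows(
    tidyr::expand_grid(
      age = c("E17", "P7", "P20", "P60"),
      prenatal = c("Saline", "MIA"),
      drug = "CTRL"
    ),
    tidyr::expand_grid(age = "P60", prenatal = c("Saline", "MIA"), drug = "MG-REP")
  )
  groups$group <- paste(groups$age, groups$prenatal, groups$drug, sep = "_")
  tidyr::expand_grid(groups, rep = seq_len(replicates)) |>
    dplyr::mutate(
      sample = paste0(.data$group, "_r", .data$rep),
      sex = c("M", "F")[(.data$rep %% 2) + 1],
      litter = paste0(.data$group, "_L", .data$rep)
    ) |>
    dplyr::select("sample", "group", "age", "prenatal", "drug", "sex", "litter")
}

#' Cell-type marker panel for microglia purity scoring
#'
#' Five marker genes for each of five brain cell types (neurons,
#' oligodendrocytes, astrocytes, endothelial cells, microglia), the panel
#' used to verify purity of sorted-microglia RNA-seq.
#'
#' @return A 25-row tibble with columns `cell_type` and `gene`.
#' @export
marker_panel <- function() {
  tibble::tribble(
    ~cell_type, ~genes,
    "neurons",           c("Dcx", "Npas4", "Npy", "Reln", "Tubb3"),
    "oligodendrocytes",  c("Mag", "Mbp", "Mog", "Ppapdc1a", "Sox10"),
    "astrocytes",        c("Aqp4", "Gfap", "Gdpd2", "Plcd4", "Slc7a2"),
    "endothelial cells", c("Emcn", "Ocln", "Pecam1", "Slc16a4", "Tek"),
    "microglia",         c("C1qa", "Csf1r", "Cx3cr1", "Fcrls", "Hexb")
  ) |>
    tidyr::unnest_longer("genes", values_to = "gene")
}

#' Specification of planted expression modules
#'
#' Defines the group-enrichment structure planted into synthetic counts.
#' The defaults mirror the five microglial expression modules (IM, MIA-IM,
#' JM, AM, REP-AM) at one tenth of their observed sizes, each enriched in
#' its characteristic age/condition groups.
#'
#' @param sizes Named integer vector: genes per module.
#' @param enriched_groups Named list: for each module, the `group` labels
#'   (as in [mia_design()]) in which its genes are upregulated.
#' @param shift Mean upregulation in enriched groups, log2 units.
#' @param dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(sizes = c("IM" = 468, "MIA-IM" = 282, "JM" = 232,
                                  "AM" = 328, "REP-AM" = 113),
                        enriched_groups = list(
                          "IM"     = c("E17_Saline_CTRL", "P7_Saline_CTRL"),
                          "MIA-IM" = c("E17_MIA_CTRL", "P7_MIA_CTRL"),
                          "JM"     = c("P20_Saline_CTRL", "P20_MIA_CTRL"),
                          "AM"     = c("P60_Saline_CTRL", "P60_MIA_CTRL",
                                       "P60_MIA_MG-REP"),
                          "REP-AM" = c("P60_Saline_MG-REP")
                        ),
                        shift = 4, dispersion = 0.1) {
  stopifnot(all(sizes > 0), dispersion > 0,
            setequal(names(sizes), names(enriched_groups)))
  structure(list(sizes = sizes, enriched_groups = enriched_groups,
                 shift = shift, dispersion = dispersion),
            class = "module_spec")
}

#' Generate a synthetic microglial counts matrix
#'
#' Draws negative-binomial gene-by-sample counts with five planted
#' expression modules, unstructured background genes, and marker-gene
#' contamination at controlled fractions. Library sizes are log-normal
#' around `lib_size` with coefficient of variation `lib_cv`. Marker-gene
#' expression is scaled so that each non-microglial cell type contributes
#' its `contamination` fraction of the total marker-panel signal in
#' expectation, the remainder being microglia.
#'
#' @param design Sample sheet from [mia_design()] (or same columns).
#' @param modules A [module_spec()].
#' @param contamination Named numeric vector of per-cell-type contamination
#'   fractions in \[0, 1\] summing to at most 1; names must be non-microglia
#'   cell types of [marker_panel()]. Default 0.5% each.
#' @param n_background Number of unstructured background genes.
#' @param lib_size,lib_cv Library-size log-normal location and CV.
#' @param seed Integer seed; fixed seed reproduces byte-identical output.
#' @return A list of class `mia_counts` with elements `counts` (tibble,
#'   `gene` + one column per sample), `metadata` (the design), `truth`
#'   (tibble `gene`, `module`; background genes labelled `"background"`),
#'   and `panel` (the marker panel used).
#' @export
#' @examples
#' sim <- sim_counts(seed = 1, n_background = 50,
#'                   modules = module_spec(sizes = c(A = 20, B = 20),
#'                     enriched_groups = list(A = "E17_Saline_CTRL",
#'                                            B = "P7_MIA_CTRL")))
#' dim(sim$counts)
sim_counts <- function(design = mia_design(),
                       modules = module_spec(),
                       contamination = c("neurons" = 0.005,
                                         "oligodendrocytes" = 0.005,
                                         "astrocytes" = 0.005,
                                         "endothelial cells" = 0.005),
                       n_background = 300,
                       lib_size = 1e7, lib_cv = 0.2,
                       seed = 1) {
  stopifnot(inherits(modules, "module_spec"), n_background >= 0)
  if (any(contamination < 0) || sum(contamination) > 1) {
    abort("contamination fractions must be in [0,1] and sum to <= 1")
  }
  panel <- marker_panel()
  bad <- setdiff(names(contamination), setdiff(unique(panel$cell_type), "microglia"))
  if (length(bad) > 0) abort(paste("unknown cell types:", paste(bad, collapse = ", ")))

  module_genes <- unlist(purrr::imap(modules$sizes, function(n, nm) {
    sprintf("%s_g%04d", gsub("[^A-Za-z0-9]", "", nm), seq_len(n))
  }), use.names = FALSE)
  bg_genes <- sprintf("bg_g%05d", seq_len(n_background))
  genes <- c(module_genes, bg_genes, panel$gene)
  if (anyDuplicated(genes)) abort("gene name collision between modules, background, and markers")

  truth <- tibble::tibble(
    gene = c(module_genes, bg_genes),
    module = c(rep(names(modules$sizes), modules$sizes),
               rep("background", n_background))
  )

  with_seed(seed, {
    n_samp <- nrow(design)
    # log-normal library sizes around lib_size with the requested CV
    sdlog <- sqrt(log(1 + lib_cv^2))
    libs <- rlnorm(n_samp, meanlog = log(lib_size) - sdlog^2 / 2, sdlog = sdlog)

    # baseline relative expression (per-million scale)
    base_cpm <- c(
      rlnorm(length(module_genes), meanlog = log(8), sdlog = 0.4),
      rlnorm(n_background, meanlog = log(20), sdlog = 1.2)
    )
    mu_cpm <- matrix(rep(base_cpm, n_samp), ncol = n_samp,
                     dimnames = list(c(module_genes, bg_genes), design$sample))
    offset <- 0L
    for (nm in names(modules$sizes)) {
      idx <- offset + seq_len(modules$sizes[[nm]])
      enriched <- design$group %in% modules$enriched_groups[[nm]]
      mu_cpm[idx, enriched] <- mu_cpm[idx, enriched] * 2^modules$shift
      offset <- offset + modules$sizes[[nm]]
    }

    # marker genes: panel totals apportioned by contamination fractions
    panel_total_cpm <- 5000
    frac <- setNames(rep(0, 5), unique(panel$cell_type))
    frac[names(contamination)] <- contamination
    frac["microglia"] <- 1 - sum(contamination)
    marker_cpm <- matrix(rep(frac[panel$cell_type] * panel_total_cpm / 5, n_samp),
                         ncol = n_samp,
                         dimnames = list(panel$gene, design$sample))

    mu_all <- rbind(mu_cpm, marker_cpm)
    counts <- matrix(0L, nrow(mu_all), n_samp, dimnames = dimnames(mu_all))
    for (s in seq_len(n_samp)) {
      mu_s <- mu_all[, s] * libs[s] / 1e6
      counts[, s] <- rnbinom(nrow(mu_all), mu = mu_s, size = 1 / modules$dispersion)
    }

    structure(list(counts = matrix_to_tbl(counts), metadata = design,
                   truth = truth, panel = panel, seed = seed),
              class = "mia_counts")
  })
}

#' @export
print.mia_counts <- function(x, ...) {
  cat("<mia_counts> ", nrow(x$counts), " genes x ", nrow(x$metadata),
      " samples; ", length(unique(x$truth$module)), " truth classes\n", sep = "")
  invisible(x)
}
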