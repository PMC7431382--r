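#' Default pipeline configuration
#'
#' Every threshold carries the study default: CPM filter 2-in-3, k = 5
#' modules, voxel 0.04 x 0.04 x 0.3 um, interaction radii 0.3/0.9/1.5 um
#' at 1/3/5 z-planes, 95 um soma-distance filter, 10,000 overlap
#' permutations and 100,000 network permutations. The demo permutation
#' counts are smaller so a full run stays interactive.
#'
#' @param seed Global seed; fans out to per-stage seeds via [derive_seed()].
#' @param out_dir Output directory.
#' @param ... Named overrides of any default field.
#' @return A named list of class `mia_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("miaglia_run_"), ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    min_cpm = 2,
    min_samples = 3,
    k = 5,
    n_restarts = 25,
    voxel = c(0.04, 0.04, 0.3),
    interaction_radii = c(0.3, 0.9, 1.5),
    interaction_planes = c(1, 3, 5),
    soma_distance_um = 95,
    n_perm_overlap = 1000,
    n_perm_network = 999,
    fate_fractions = list(
      "Saline_MG-REP" = c(0.304, 0.304, 0.392),
      "MIA_MG-REP" = c(0.165, 0.165, 0.670)
    ),
    n_fate_cells = 1000,
    stages = c("transcriptome", "enrichment", "morphometry",
               "fate_mapping", "correlate")
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  class(cfg) <- "mia_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks all constraints and reports every violation (not just the
#' first): interaction radii must equal plane counts times the z voxel
#' step, voxel sizes and thresholds must be positive, fate fractions must
#' lie on the simplex.
#'
#' @param config A config list from [default_config()].
#' @return Tibble `check`, `ok`, `message`; attribute `valid` is TRUE when
#'   all checks pass.
#' @export
#' @examples
#' validate_config(default_config())
validate_config <- function(config) {
  checks <- list(
    list("voxel sizes positive", all(config$voxel > 0),
         "all three voxel sizes must be > 0"),
    list("thresholds positive",
         config$min_cpm > 0 && config$min_samples > 0 && config$k >= 2,
         "min_cpm, min_samples must be > 0 and k >= 2"),
    list("radius/plane consistency",
         isTRUE(all.equal(config$interaction_radii,
                          config$interaction_planes * config$voxel[3])),
         paste0("interaction radii must equal planes x z-step (",
                paste(config$interaction_planes * config$voxel[3], collapse = ", "), ")")),
    list("radii nested",
         !is.unsorted(config$interaction_radii, strictly = TRUE),
         "interaction radii must be strictly increasing"),
    list("fate fractions on simplex",
         all(purrr::map_lgl(config$fate_fractions, function(f) {
           all(f >= 0) && abs(sum(f) - 1) < 1e-8
         })),
         "each fate fraction triple must be non-negative and sum to 1"),
    list("permutations positive",
         config$n_perm_overlap >= 1 && config$n_perm_network >= 1,
         "permutation counts must be >= 1"),
    list("soma distance non-negative", config$soma_distance_um >= 0,
         "soma-distance filter must be >= 0")
  )
  out <- purrr::map_dfr(checks, function(ck) {
    tibble::tibble(check = ck[[1]], ok = ck[[2]],
                   message = if (ck[[2]]) "" else ck[[3]])
  })
  attr(out, "valid") <- all(out$ok)
  out
}

write_stage <- function(tbl, out_dir, name) {
  path <- file.path(out_dir, name)
  if (grepl("\\.tsv$", name)) {
    readr::write_tsv(tbl, path)
  } else {
    readr::write_csv(tbl, path)
  }
  path
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates synthetic inputs and executes the stages in dependency order:
#' counts -> filtering -> modules/purity/PCA/DE -> overlap enrichment and
#' network connectedness; scene -> interaction scoring; fate tables ->
#' demographics; feature table -> correlation surface. Each stage writes
#' its tables under `config$out_dir` and is logged in the returned
#' manifest; re-running with an identical config and seed reproduces
#' identical checksums.
#'
#' @param config A validated config from [default_config()].
#' @return A list of class `mia_manifest`: `config`, `files` (tibble
#'   `stage`, `file`, `md5`), `elapsed` (per-stage seconds), `results`
#'   (in-memory stage outputs).
#' @export
run_mia_pipeline <- function(config = default_config()) {
  report <- validate_config(config)
  if (!attr(report, "valid")) {
    abort(paste0("invalid config: ",
                 paste(report$message[!report$ok], collapse = "; ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  elapsed <- list()
  results <- list()
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
    elapsed[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    results[[stage]] <<- out$result
    files[[stage]] <<- out$paths
    invisible(NULL)
  }

  run_stage("synthetic", function() {
    sim <- sim_counts(seed = derive_seed(config$seed, "synthetic"))
    p1 <- write_stage(sim$counts, config$out_dir, "counts.tsv")
    p2 <- write_stage(sim$metadata, config$out_dir, "metadata.csv")
    p3 <- write_stage(sim$truth, config$out_dir, "module_truth.tsv")
    list(result = sim, paths = c(p1, p2, p3))
  })
  sim <- results$synthetic

  if ("transcriptome" %in% config$stages) {
    run_stage("transcriptome", function() {
      filtered <- filter_expressed(sim, config$min_cpm, config$min_samples)
      z <- zscore_rows(log_cpm(filtered))
      fit <- kmeans_modules(z, metadata = sim$metadata, k = config$k,
                            seed = derive_seed(config$seed, "kmeans"),
                            n_restarts = config$n_restarts)
      wk <- wcss_by_k(z, k_range = 1:8,
                      seed = derive_seed(config$seed, "elbow"),
                      n_restarts = config$n_restarts)
      pur <- purity(cpm(filtered))
      pca <- pca_scores(log_cpm(filtered), n_components = 5)
      de <- nb_exact_test(filtered, "P60_MIA_CTRL", "P60_Saline_CTRL",
                          metadata = sim$metadata)
      paths <- c(
        write_stage(tidy(fit), config$out_dir, "modules.tsv"),
        write_stage(wk, config$out_dir, "wcss_by_k.csv"),
        write_stage(pur, config$out_dir, "purity.csv"),
        write_stage(pca, config$out_dir, "pca_scores.csv"),
        write_stage(de, config$out_dir, "de.tsv")
      )
      list(result = list(filtered = filtered, fit = fit, wcss = wk,
                         purity = pur, pca = pca, de = de,
                         k_elbow = select_k_elbow(wk)),
           paths = paths)
    })
  }

  if ("enrichment" %in% config$stages) {
    run_stage("enrichment", function() {
      fit <- results$transcriptome$fit
      modules <- split(fit$assignment$gene, fit$assignment$module)
      bg <- fit$assignment$gene
      seed_e <- derive_seed(config$seed, "enrichment")
      # planted disease lists: subsets of two truth modules plus noise
      lists <- with_seed(seed_e, {
        truth <- split(sim$truth$gene, sim$truth$module)
        list(
          listA = c(sample(intersect(truth[["AM"]], bg), 40),
                    sample(bg, 20)),
          listB = sample(bg, 60)
        )
      })
      lists <- purrr::map(lists, unique)
      grid <- overlap_matrix(modules, lists, bg)
      top <- dplyr::slice_min(grid, .data$p_value, n = 1, with_ties = FALSE)
      perm <- permutation_overlap_test(modules[[top$module]], lists[[top$list]],
                                       bg, n_perm = config$n_perm_overlap,
                                       seed = seed_e, n_tests = nrow(grid))
      net <- sim_network(200, 20, in_weight = 0.9, out_weight = 0.2,
                         noise_sd = 0.05,
                         seed = derive_seed(config$seed, "network"))
      connperm <- connectedness_permutation(net$planted, net,
                                            n_perm = config$n_perm_network,
                                            seed = seed_e)
      paths <- c(
        write_stage(grid, config$out_dir, "overlap_grid.csv"),
        write_stage(dplyr::bind_rows(overlap = perm, network = connperm,
                                     .id = "test"),
                    config$out_dir, "permutation_tests.csv")
      )
      list(result = list(grid = grid, perm = perm, connperm = connperm),
           paths = paths)
    })
  }

  if ("morphometry" %in% config$stages) {
    run_stage("morphometry", function() {
      scene <- sim_scene(n_spines = 20, voxel = config$voxel,
                         seed = derive_seed(config$seed, "scene"))
      scored <- score_interactions(scene)
      dens <- interaction_density(scored, scene$dendrite_length)
      sdens <- spine_density(scored, scene$dendrite_length)
      trace <- sim_trace(n_primary = 3, max_depth = 6, branch_prob = 0.8,
                         seed = derive_seed(config$seed, "trace"))
      orders <- branch_order_counts(trace)
      shl <- sholl(trace, radii = seq(2, 40, by = 2))
      hull <- convex_hull_volume(trace)
      paths <- c(
        write_stage(scored, config$out_dir, "interactions.csv"),
        write_stage(dens, config$out_dir, "interaction_density.csv"),
        write_stage(sdens, config$out_dir, "spine_density.csv"),
        write_stage(orders, config$out_dir, "branch_orders.csv"),
        write_stage(shl, config$out_dir, "sholl.csv")
      )
      list(result = list(scored = scored, interaction_density = dens,
                         spine_density = sdens, branch_orders = orders,
                         sholl = shl, hull_volume = hull),
           paths = paths)
    })
  }

  if ("fate_mapping" %in% config$stages) {
    run_stage("fate_mapping", function() {
      cells <- purrr::imap_dfr(config$fate_fractions, function(f, g) {
        sim_fate_table(config$n_fate_cells, f, group = g, n_sections = 4,
                       seed = derive_seed(config$seed, paste0("fate_", g)))
      })
      demo <- fate_group_summary(cells)
      paths <- write_stage(demo, config$out_dir, "fate_demographics.csv")
      list(result = list(cells = cells, demographics = demo), paths = paths)
    })
  }

  if ("correlate" %in% config$stages) {
    run_stage("correlate", function() {
      feats <- with_seed(derive_seed(config$seed, "correlate"), {
        n <- 40
        latent <- rnorm(n)
        tibble::tibble(
          Rn = latent + rnorm(n, sd = 0.5),
          Dur_half = latent + rnorm(n, sd = 0.5),
          AP_rise = latent + rnorm(n, sd = 0.8),
          sEPSC_amplitude = -latent + rnorm(n, sd = 0.8),
          MG_branches_o9 = latent + rnorm(n, sd = 0.6),
          total_spine_interaction_density = latent + rnorm(n, sd = 0.7),
          total_spine_density = rnorm(n)
        )
      })
      surface <- spearman_matrix(feats)
      paths <- c(
        write_stage(feats, config$out_dir, "features.csv"),
        file.path(config$out_dir, "correlation_surface.csv")
      )
      export_surface(surface, paths[2])
      list(result = list(features = feats, surface = surface), paths = paths)
    })
  }

  file_tbl <- purrr::imap_dfr(files, function(paths, stage) {
    tibble::tibble(stage = stage, file = basename(paths),
                   md5 = unname(tools::md5sum(paths)))
  })
  jsonlite::write_json(config[setdiff(names(config), "out_dir")],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(config = config, files = file_tbl,
                 elapsed = tibble::tibble(stage = names(elapsed),
                                          seconds = unlist(elapsed)),
                 results = results),
            class = "mia_manifest")
}

#' @export
print.mia_manifest <- function(x, ...) {
  cat("<mia_manifest> ", nrow(x$files), " files in ", x$config$out_dir,
      "; stages: ", paste(x$elapsed$stage, collapse = ", "), "\n", sep = "")
  invisible(x)
}
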