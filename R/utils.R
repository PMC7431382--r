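#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that each stage is
#' reproducible independently of the order in which stages run. The stage
#' name is hashed to a small integer offset; the result stays below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "transcriptome")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(seed) + h) %% .Machine$integer.max)
}

# set the RNG state locally when a seed is supplied
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# counts tibble (gene + sample columns) -> integer matrix with rownames
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene" %in% names(counts))
  if (anyDuplicated(counts$gene)) abort("duplicate gene identifiers in counts")
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers in counts")
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene
  m
}

matrix_to_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)), tibble::as_tibble(m))
}

check_metadata <- function(counts, metadata) {
  samples <- setdiff(names(counts), "gene")
  missing <- setdiff(samples, metadata$sample)
  if (length(missing) > 0) {
    abort(paste0("metadata missing for samples: ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
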