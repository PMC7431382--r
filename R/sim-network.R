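#' Generate a weighted gene network with a planted dense module
#'
#' Builds a complete weighted graph on `n_genes` nodes in which all pairs
#' inside a planted module receive `in_weight` plus noise and all other
#' pairs `out_weight` plus noise, truncated to \[0, 1\]. This is the
#' substrate for connectedness permutation tests.
#'
#' @param n_genes Number of nodes.
#' @param module_size Size of the planted dense module (`<= n_genes`).
#' @param in_weight,out_weight Mean edge weights inside/outside the module;
#'   `in_weight > out_weight >= 0` required.
#' @param noise_sd Gaussian noise standard deviation added to every edge.
#' @param seed Integer seed.
#' @return A list of class `mia_network`: `nodes` (character ids),
#'   `weights` (symmetric matrix, zero diagonal), `planted` (module node
#'   ids).
#' @export
#' @examples
#' net <- sim_network(20, 5, in_weight = 1, out_weight = 0, seed = 1)
#' connectedness(net$planted, net)
sim_network <- function(n_genes, module_size, in_weight, out_weight = 0,
                        noise_sd = 0, seed = 1) {
  if (module_size > n_genes) abort("module size exceeds number of genes")
  if (!(in_weight > out_weight && out_weight >= 0)) {
    abort("in_weight must exceed out_weight, and out_weight must be >= 0")
  }
  nodes <- sprintf("n%04d", seq_len(n_genes))
  planted <- nodes[seq_len(module_size)]
  with_seed(seed, {
    w <- matrix(out_weight, n_genes, n_genes, dimnames = list(nodes, nodes))
    w[seq_len(module_size), seq_len(module_size)] <- in_weight
    if (noise_sd > 0) {
      eps <- matrix(rnorm(n_genes^2, sd = noise_sd), n_genes)
      eps <- (eps + t(eps)) / 2
      w <- w + eps
    }
    w <- pmin(pmax(w, 0), 1)
    diag(w) <- 0
    structure(list(nodes = nodes, weights = w, planted = planted),
              class = "mia_network")
  })
}

#' Convert a network to a tidy edge list
#'
#' @param net A `mia_network`.
#' @return Tibble `from`, `to`, `weight` over unordered pairs.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "mia_network"))
  idx <- which(upper.tri(net$weights), arr.ind = TRUE)
  tibble::tibble(
    from = net$nodes[idx[, 1]],
    to = net$nodes[idx[, 2]],
    weight = net$weights[idx]
  )
}

#' Assemble a network object from an edge list
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @return A `mia_network` (missing pairs get weight 0).
#' @export
as_mia_network <- function(edges) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  nodes <- sort(unique(c(edges$from, edges$to)))
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  w[cbind(edges$from, edges$to)] <- edges$weight
  w[cbind(edges$to, edges$from)] <- edges$weight
  diag(w) <- 0
  structure(list(nodes = nodes, weights = w, planted = character()),
            class = "mia_network")
}
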