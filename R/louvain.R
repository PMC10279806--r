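#' One Louvain sweep over the supra-modularity structure
#'
#' Phase 1 of Louvain on the multilayer quality function: node-layers are
#' visited in a shuffled order; each is moved to the community with the
#' largest positive modularity gain; passes repeat until none moves. Among
#' equal maximal gains the current community is kept, otherwise the lowest
#' community id wins. The returned partition never has lower Q than the
#' input.
#'
#' @param net a [assemble_multilayer()] network.
#' @param part starting [multilayer_partition()] or assignment vector/matrix
#'   over the `n * L` node-layers; defaults to all-singletons.
#' @param order visit order (permutation of `1..n*L`); defaults to a random
#'   shuffle drawn from the current RNG state.
#' @return A [multilayer_partition()].
#' @export
louvain_sweep <- function(net, part = NULL, order = NULL) {
  stopifnot(inherits(net, "multilayer_network"))
  nL <- net$n * net$n_layers
  g <- if (is.null(part)) seq_len(nL)
       else if (inherits(part, "multilayer_partition")) as.vector(part$g)
       else as.vector(part)
  if (is.null(order)) order <- sample.int(nL)
  B <- supra_modularity_matrix(net)
  g2 <- louvain_phase_cpp(B, as.integer(g), as.integer(order))
  multilayer_partition(g2, net)
}

# Full multi-level Louvain run on a modularity matrix: phase 1 from the given
# assignment, then repeated aggregation + phase 1 on the aggregated matrix
# until aggregation yields no further merges. RNG: visit orders only.
louvain_once <- function(B, g) {
  n <- nrow(B)
  g <- match(g, unique(g))
  g <- louvain_phase_cpp(B, as.integer(g), sample.int(n))
  g <- match(g, unique(g))
  mapping <- g
  Bcur <- B
  repeat {
    k <- max(mapping)
    if (k == 1) break
    Bcur <- aggregate_matrix_cpp(Bcur, as.integer(g), max(g))
    g <- louvain_phase_cpp(Bcur, seq_len(nrow(Bcur)),
                           sample.int(nrow(Bcur)))
    g <- match(g, unique(g))
    if (max(g) == nrow(Bcur)) break  # no merges at this level
    mapping <- g[mapping]
  }
  mapping
}

#' Iterative generalized Louvain community detection
#'
#' Maximizes the multilayer modularity Q of [modularity_q()] with the
#' generalized Louvain scheme: greedy node-layer moves, aggregation of
#' communities into super-nodes, and repetition on the aggregated structure;
#' the whole multi-level run is then restarted from its own flattened
#' partition ("iterative" outer loop) until the Q gain drops below `tol`.
#' Several randomized restarts are run and the best-Q partition returned.
#' The number of communities is emergent from the optimization, never fixed
#' a priori. Deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param net a [assemble_multilayer()] network.
#' @param restarts number of randomized restarts (default 20).
#' @param seed integer seed governing all randomness (visit orders).
#' @param tol convergence tolerance on Q for the outer iteration
#'   (default 1e-10).
#' @return The best [multilayer_partition()] found.
#' @export
genlouvain <- function(net, restarts = 20, seed = 1, tol = 1e-10) {
  stopifnot(inherits(net, "multilayer_network"), restarts >= 1, tol >= 0)
  B <- supra_modularity_matrix(net)
  nL <- nrow(B)
  withr::with_seed(seed, {
    best_g <- NULL
    best_q <- -Inf
    for (r in seq_len(restarts)) {
      g <- seq_len(nL)
      q <- q_from_supra(B, g, net$two_mu)
      repeat {
        g_new <- louvain_once(B, g)
        q_new <- q_from_supra(B, g_new, net$two_mu)
        if (q_new - q < tol) break
        g <- g_new
        q <- q_new
      }
      if (q > best_q) { best_q <- q; best_g <- g }
    }
    multilayer_partition(best_g, net, q = best_q)
  })
}
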