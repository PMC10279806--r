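#' Newman-Girvan configuration-model null for one layer
#'
#' Expected edge weight between nodes i and j under random rewiring that
#' preserves node strengths: `M_ij = k_i * k_j / (2m)`, where `k_i` is the
#' strength (row sum) of node i and `2m` the total edge weight of the layer.
#' Strengths and total weight are computed from the (possibly signed) layer
#' weights as given.
#'
#' @param layer a [similarity_layer()] or a symmetric numeric matrix.
#' @return Symmetric numeric matrix `M` of the same dimension as the layer.
#' @export
newman_girvan_null <- function(layer) {
  A <- if (inherits(layer, "similarity_layer")) layer$weights else as.matrix(layer)
  k <- rowSums(A)
  two_m <- sum(A)
  if (abs(two_m) < 1e-12)
    stop("layer total weight 2m is zero; configuration-model null undefined")
  outer(k, k) / two_m
}

#' Assemble a multilayer network from per-modality similarity layers
#'
#' Layers share the subject set; each subject's node copies across layers are
#' tied by interlayer coupling edges of uniform weight `omega`. With
#' `coupling = "categorical"` (the default; modalities are unordered) every
#' pair of layers is coupled; `"ordinal"` couples consecutive layers only.
#' Per layer, the adjacency `A` is taken from the similarity weights and the
#' null model `M` is the Newman-Girvan configuration model; the interlayer
#' coupling term carries no null. The total edge weight `2mu` counts every
#' intra-layer strength plus every coupling edge from both endpoints.
#'
#' @param layers list of [similarity_layer()] objects over identical,
#'   identically ordered subject IDs.
#' @param gamma per-layer structural resolution, recycled if scalar.
#'   Larger values favor more, smaller communities. Default 1.
#' @param omega interlayer coupling strength, `>= 0`. Default 1.
#' @param coupling `"categorical"` or `"ordinal"`.
#' @return list of class `multilayer_network` with elements `layer_ids`,
#'   `subject_ids`, `A` (list of adjacency matrices), `M` (list of null
#'   matrices), `gamma`, `omega`, `coupling`, `n`, `n_layers`, `two_mu`.
#' @export
assemble_multilayer <- function(layers, gamma = 1, omega = 1,
                                coupling = c("categorical", "ordinal")) {
  coupling <- match.arg(coupling)
  stopifnot(length(layers) >= 1, omega >= 0, all(gamma > 0))
  ids <- layers[[1]]$subject_ids
  for (ly in layers)
    if (!identical(ly$subject_ids, ids))
      stop("all layers must share identical, identically ordered subject IDs")
  L <- length(layers)
  n <- length(ids)
  gamma <- rep_len(gamma, L)
  A <- lapply(layers, `[[`, "weights")
  M <- lapply(A, newman_girvan_null)
  n_couplings <- if (L < 2) 0 else if (coupling == "categorical")
    n * L * (L - 1) else n * 2 * (L - 1)
  two_mu <- sum(vapply(A, sum, 0)) + omega * n_couplings
  if (two_mu <= 0)
    stop("total edge weight 2mu must be positive, got ", two_mu)
  structure(list(layer_ids = vapply(layers, `[[`, "", "modality_id"),
                 subject_ids = ids, A = A, M = M, gamma = gamma,
                 omega = omega, coupling = coupling,
                 n = n, n_layers = L, two_mu = two_mu),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> %d subjects x %d layers (%s), gamma = %s, omega = %g, 2mu = %.4g\n",
              x$n, x$n_layers, paste(x$layer_ids, collapse = ", "),
              paste(format(x$gamma), collapse = "/"), x$omega, x$two_mu))
  invisible(x)
}

#' Supra-modularity matrix of a multilayer network
#'
#' Dense `(n * L) x (n * L)` matrix `B` whose diagonal blocks are
#' `A_l - gamma_l * M_l` and whose off-diagonal blocks carry the interlayer
#' coupling `omega` on the diagonal entries (subject i in layer l tied to
#' subject i in layer r). Node-layers are stacked layer-major: node-layer
#' `(i, l)` sits at index `(l - 1) * n + i`. Multilayer modularity is
#' `Q = sum over same-community node-layer pairs of B / 2mu`, including the
#' diagonal null terms.
#'
#' @param net a [assemble_multilayer()] network.
#' @return Numeric matrix.
#' @export
supra_modularity_matrix <- function(net) {
  stopifnot(inherits(net, "multilayer_network"))
  n <- net$n; L <- net$n_layers
  B <- matrix(0, n * L, n * L)
  for (l in seq_len(L)) {
    idx <- (l - 1) * n + seq_len(n)
    B[idx, idx] <- net$A[[l]] - net$gamma[l] * net$M[[l]]
  }
  if (net$omega > 0 && L > 1) {
    pairs <- if (net$coupling == "categorical")
      utils::combn(L, 2, simplify = FALSE)
    else lapply(seq_len(L - 1), function(l) c(l, l + 1))
    for (pr in pairs) {
      il <- (pr[1] - 1) * n + seq_len(n)
      ir <- (pr[2] - 1) * n + seq_len(n)
      B[cbind(il, ir)] <- net$omega
      B[cbind(ir, il)] <- net$omega
    }
  }
  B
}

#' Multilayer partition
#'
#' @param g integer matrix `n x L` of community assignments (subjects in
#'   rows, layers in columns), or an integer vector of length `n * L` in
#'   layer-major order. Community ids are relabeled to consecutive `1..K`
#'   by first appearance.
#' @param net the [assemble_multilayer()] network the partition belongs to.
#' @param q optional precomputed modularity value; computed via
#'   [modularity_q()] when `NULL`.
#' @return list of class `multilayer_partition` with elements `g` (n x L
#'   integer matrix), `q`, `n_communities`, `consensus` (per-subject label,
#'   see [consensus_node_labels()]) and `any_split`.
#' @export
multilayer_partition <- function(g, net, q = NULL) {
  stopifnot(inherits(net, "multilayer_network"))
  g <- matrix(as.integer(g), nrow = net$n, ncol = net$n_layers,
              dimnames = list(net$subject_ids, net$layer_ids))
  relab <- match(g, unique(as.vector(g)))
  g[] <- relab
  part <- structure(list(g = g, q = NA_real_,
                         n_communities = max(g),
                         consensus = NULL, any_split = NA),
                    class = "multilayer_partition")
  part$q <- if (is.null(q)) modularity_q(net, part) else q
  cons <- consensus_node_labels(part)
  part$consensus <- cons$labels
  part$any_split <- cons$any_split
  part
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf("<multilayer_partition> %d communities over %d subjects x %d layers, Q = %.6f%s\n",
              x$n_communities, nrow(x$g), ncol(x$g), x$q,
              if (isTRUE(x$any_split)) " (some subjects split across layers)" else ""))
  invisible(x)
}

#' Multilayer modularity of a partition
#'
#' Implements the multislice quality function
#' `Q = (1/2mu) * sum_ijlr [ (A_ijl - gamma_l M_ijl) delta_lr
#'      + delta_ij omega_jlr ] delta(g_il, g_jr)`
#' via its supra-matrix form: the sum of supra-modularity entries over all
#' ordered node-layer pairs sharing a community (diagonal included), divided
#' by the total edge weight `2mu`.
#'
#' @param net a [assemble_multilayer()] network.
#' @param part a [multilayer_partition()], or an assignment vector/matrix
#'   covering all `n * L` node-layers.
#' @return Scalar Q.
#' @export
modularity_q <- function(net, part) {
  g <- if (inherits(part, "multilayer_partition")) part$g else part
  g <- as.vector(g)
  stopifnot(length(g) == net$n * net$n_layers)
  B <- supra_modularity_matrix(net)
  q_from_supra(B, g, net$two_mu)
}

q_from_supra <- function(B, g, two_mu) {
  s <- 0
  for (c in unique(g)) {
    idx <- which(g == c)
    s <- s + sum(B[idx, idx])
  }
  s / two_mu
}

#' Collapse a multilayer partition to one label per subject
#'
#' Subject label = majority community across that subject's layers; ties are
#' broken in favor of the community the subject holds in the earliest layer
#' (layer order as assembled). A flag records whether any subject was split
#' across layers at all.
#'
#' @param part a [multilayer_partition()] or an `n x L` assignment matrix.
#' @return list with `labels` (named integer vector, one per subject) and
#'   `any_split` (logical).
#' @export
consensus_node_labels <- function(part) {
  g <- if (inherits(part, "multilayer_partition")) part$g else as.matrix(part)
  labels <- apply(g, 1, function(row) {
    tab <- table(row)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) == 1) winners else row[row %in% winners][1]
  })
  names(labels) <- rownames(g)
  list(labels = as.integer(labels) |> stats::setNames(rownames(g)),
       any_split = any(apply(g, 1, function(row) length(unique(row)) > 1)))
}
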