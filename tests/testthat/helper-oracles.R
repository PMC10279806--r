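# Independent oracles, written without the package's matrix machinery, used
# to pin down expected values for the modularity core and the evaluation
# arithmetic.

# Multilayer modularity as the literal quadruple sum over (i, j, l, r):
# intra-layer term (A_ijl - gamma_l * M_ijl) when l == r, coupling term
# omega when i == j and the two layers are coupled. The null model and the
# total weight 2mu are recomputed here from the raw layer matrices.
oracle_modularity <- function(A_list, gamma, omega, g_mat,
                              coupling = "categorical") {
  L <- length(A_list)
  n <- nrow(A_list[[1]])
  gamma <- rep_len(gamma, L)
  M_list <- lapply(A_list, function(A) {
    k <- sapply(seq_len(n), function(i) sum(A[i, ]))
    two_m <- sum(A)
    M <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) M[i, j] <- k[i] * k[j] / two_m
    M
  })
  coupled <- function(l, r) {
    if (l == r) return(FALSE)
    if (coupling == "categorical") TRUE else abs(l - r) == 1
  }
  n_coup <- 0
  for (l in seq_len(L)) for (r in seq_len(L))
    if (coupled(l, r)) n_coup <- n_coup + n
  two_mu <- sum(sapply(A_list, sum)) + omega * n_coup
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    for (l in seq_len(L)) for (r in seq_len(L)) {
      if (g_mat[i, l] != g_mat[j, r]) next
      if (l == r) total <- total + A_list[[l]][i, j] - gamma[l] * M_list[[l]][i, j]
      if (i == j && coupled(l, r)) total <- total + omega
    }
  total / two_mu
}

# All set partitions of m elements, as restricted-growth strings
# (Bell numbers: 203 for m = 6, 4140 for m = 8).
all_set_partitions <- function(m) {
  out <- list()
  recurse <- function(prefix, max_used) {
    pos <- length(prefix) + 1
    if (pos > m) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (c in seq_len(max_used + 1))
      recurse(c(prefix, c), max(max_used, c))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum of sum_{same-community pairs} B over all set
# partitions of the node-layers; returns the max quality (Q * two_mu scale
# handled by the caller) and one argmax.
exhaustive_best_partition <- function(B, two_mu) {
  m <- nrow(B)
  parts <- all_set_partitions(m)
  best_q <- -Inf
  best <- NULL
  for (g in parts) {
    s <- 0
    for (c in unique(g)) {
      idx <- which(g == c)
      s <- s + sum(B[idx, idx])
    }
    q <- s / two_mu
    if (q > best_q) { best_q <- q; best <- g }
  }
  list(q = best_q, g = best)
}

# Random signed similarity layers with guaranteed nonzero (and jointly
# positive) total weight, as inputs for the oracle-equivalence checks.
random_layers <- function(n, L, signed = TRUE) {
  lapply(seq_len(L), function(l) {
    w <- matrix(0, n, n)
    vals <- if (signed) stats::runif(n * (n - 1) / 2, -0.5, 1)
            else stats::runif(n * (n - 1) / 2, 0.05, 1)
    w[upper.tri(w)] <- vals
    w <- w + t(w)
    if (abs(sum(w)) < 0.1) return(random_layers(n, 1, signed)[[1]])
    similarity_layer(w, sprintf("s%d", seq_len(n)), "mri")
  })
}

# Two disconnected 3-cliques in one layer (classic Q = 0.5 example).
two_clique_layer <- function() {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  diag(w) <- 0
  similarity_layer(w, sprintf("s%d", 1:6), "mri")
}

# A small planted two-block multilayer toy: within-block weight 1, between 0.
planted_block_layers <- function(n_per_block = 3, L = 2) {
  n <- 2 * n_per_block
  w <- matrix(0, n, n)
  w[seq_len(n_per_block), seq_len(n_per_block)] <- 1
  w[(n_per_block + 1):n, (n_per_block + 1):n] <- 1
  diag(w) <- 0
  mods <- c("mri", "pet", "csf", "cognition", "genetics")
  lapply(seq_len(L), function(l)
    similarity_layer(w, sprintf("s%d", seq_len(n)), mods[l]))
}

# A tiny modality table, optionally flagged preprocessed, for unit tests.
toy_table <- function(values, modality_id = "mri", preprocessed = FALSE) {
  values <- as.matrix(values)
  modality_table(values,
                 sprintf("s%d", seq_len(nrow(values))),
                 sprintf("f%d", seq_len(ncol(values))),
                 modality_id = modality_id, preprocessed = preprocessed)
}

# Cohort labels whose final-diagnosis crosstab reproduces a given
# community x {CN, MCI, AD} count table.
cohort_from_counts <- function(counts) {
  rows <- list()
  id <- 0
  for (ci in seq_len(nrow(counts))) for (dx in colnames(counts)) {
    k <- counts[ci, dx]
    if (k == 0) next
    ids <- sprintf("s%04d", id + seq_len(k))
    id <- id + k
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = ids,
      baseline_dx = ifelse(dx == "MCI", "LMCI", dx),
      final_dx = dx,
      community = as.integer(rownames(counts)[ci]))
  }
  df <- do.call(rbind, rows)
  consensus <- stats::setNames(df$community, df$subject_id)
  labels <- cohort_labels(df[, c("subject_id", "baseline_dx", "final_dx")])
  list(consensus = consensus, labels = labels)
}
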