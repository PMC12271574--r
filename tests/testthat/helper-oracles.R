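# Independent oracles and tiny fixtures used across the suite. These stay
# deliberately naive (double loops, explicit path unions) so they exercise a
# different code path than the implementations they check.

# ((A:1,B:2):1,C:3)
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):1,C:3);")
}

random_counts <- function(n_samples, n_taxa, seed, lambda = 5) {
  withr::with_seed(seed, {
    m <- matrix(as.double(stats::rpois(n_samples * n_taxa, lambda)),
                n_samples, n_taxa)
    dimnames(m) <- list(paste0("S", seq_len(n_samples)),
                        paste0("t", seq_len(n_taxa)))
    m
  })
}

# Brute-force abundance-weighted MPD: explicit double loop over ordered pairs.
mpd_loop <- function(w, d) {
  idx <- which(w > 0)
  if (length(idx) < 2) return(NA_real_)
  num <- 0
  den <- 0
  for (i in idx) {
    for (j in idx) {
      if (i != j) {
        num <- num + w[i] * w[j] * d[i, j]
        den <- den + w[i] * w[j]
      }
    }
  }
  unname(num / den)
}

# Brute-force induced-subtree length: union of the branch sets of all
# tip-to-tip paths, excluding nothing (paths never cross the stem above the
# MRCA).
subtree_length_bruteforce <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) < 2) return(0)
  tipno <- match(tips, tree$tip.label)
  edges_used <- logical(nrow(tree$edge))
  # parent lookup: edge index by child node
  child_edge <- integer(max(tree$edge))
  child_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  path_edges <- function(a, b) {
    anc_a <- a
    node <- a
    while (child_edge[node] != 0) {
      node <- tree$edge[child_edge[node], 1]
      anc_a <- c(anc_a, node)
    }
    node <- b
    chain_b <- b
    while (!(node %in% anc_a)) {
      node <- tree$edge[child_edge[node], 1]
      chain_b <- c(chain_b, node)
    }
    mrca <- node
    up_a <- anc_a[seq_len(which(anc_a == mrca) - 1)]
    up_b <- chain_b[chain_b != mrca]
    child_edge[c(up_a, up_b)]
  }
  for (i in seq_along(tipno)) {
    for (j in seq_along(tipno)) {
      if (i < j) edges_used[path_edges(tipno[i], tipno[j])] <- TRUE
    }
  }
  sum(tree$edge.length[edges_used])
}

# Counts whose underlying basis abundances are log-normal with an optional
# planted correlation between taxa 1 and 2.
lognormal_basis_counts <- function(n_taxa, n_samples, seed, rho = 0,
                                   depth = 5000) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * n_taxa), n_samples, n_taxa)
    if (rho != 0) {
      z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    }
    basis <- exp(1 + 0.8 * z)
    counts <- t(vapply(seq_len(n_samples), function(s) {
      stats::rmultinom(1, depth, prob = basis[s, ])[, 1]
    }, numeric(n_taxa)))
    dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                             paste0("t", seq_len(n_taxa)))
    counts
  })
}
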