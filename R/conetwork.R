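#' SparCC compositionality-robust correlations
#'
#' Estimates linear (Pearson-type) correlations between the latent basis
#' abundances underlying compositional count data. For each of `n_inner`
#' resamples, fractions are drawn from a Dirichlet posterior with pseudocount
#' 1 on each sample's counts; the log-ratio variation matrix
#' \eqn{t_{ij} = var(\log(x_i/x_j))} is formed; basis variances
#' \eqn{\omega_i^2} solve the sparsity-approximation linear system; and
#' \eqn{r_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2 \omega_i \omega_j)},
#' clipped to \[-1, 1\]. Pairs whose correlation exceeds
#' `exclusion_threshold` are iteratively removed from the system (up to
#' `max_exclude` exclusions) so a few strong correlations do not distort the
#' basis-variance estimates. The final correlation matrix averages the
#' resamples.
#'
#' @param counts Counts matrix or wide tibble (>= 4 taxa, >= 4 samples).
#' @param n_inner Number of Dirichlet resamples averaged (default 20).
#' @param exclusion_threshold Absolute correlation above which a pair is
#'   removed from the basis-variance system (default 0.1).
#' @param max_exclude Cap on exclusion iterations per resample (default 10).
#' @param seed Integer seed.
#' @return An object of class `sparcc`: list with `r` (taxa-by-taxa
#'   correlation matrix, unit diagonal) and the call parameters.
#' @export
sparcc <- function(counts, n_inner = 20, exclusion_threshold = 0.1,
                   max_exclude = 10, seed = 1) {
  mat <- as_count_matrix(counts)
  if (ncol(mat) < 4) abort("SparCC needs at least 4 taxa.")
  if (nrow(mat) < 4) abort("SparCC needs at least 4 samples.")
  capped <- 0L
  r_sum <- withr::with_seed(seed, {
    acc <- matrix(0, ncol(mat), ncol(mat))
    for (k in seq_len(n_inner)) {
      frac <- dirichlet_fractions(mat)
      one <- sparcc_once(log(frac), exclusion_threshold, max_exclude)
      if (attr(one, "capped")) capped <- capped + 1L
      acc <- acc + one
    }
    acc
  })
  if (capped > 0) {
    warn(paste0("SparCC exclusion loop reached its iteration cap in ",
                capped, " of ", n_inner, " resamples."))
  }
  r <- r_sum / n_inner
  diag(r) <- 1
  dimnames(r) <- list(colnames(mat), colnames(mat))
  out <- list(r = r, n_inner = n_inner,
              exclusion_threshold = exclusion_threshold,
              max_exclude = max_exclude, seed = seed)
  class(out) <- "sparcc"
  out
}

# One sample of posterior fractions: row-wise Dirichlet(counts + 1).
dirichlet_fractions <- function(mat) {
  g <- matrix(stats::rgamma(length(mat), shape = t(mat) + 1),
              nrow = ncol(mat))
  frac <- t(g) / colSums(g)
  frac
}

# Single SparCC estimate from a samples-by-taxa log-fraction matrix.
sparcc_once <- function(logf, exclusion_threshold, max_exclude) {
  p <- ncol(logf)
  cv <- stats::cov(logf)
  vd <- diag(cv)
  # variation matrix t_ij = var(log(x_i/x_j)) = v_i + v_j - 2 cov_ij
  tmat <- outer(vd, vd, "+") - 2 * cv
  include <- matrix(TRUE, p, p)
  diag(include) <- FALSE
  r <- NULL
  for (iter in seq_len(max_exclude + 1)) {
    m <- rowSums(include)
    a <- include * 1
    diag(a) <- m
    tsum <- rowSums(tmat * include)
    omega2 <- tryCatch(solve(a, tsum), error = function(e) rep(NA_real_, p))
    if (anyNA(omega2)) {
      omega2 <- rep(mean(vd), p)
    }
    omega2 <- pmax(omega2, 1e-10)
    om <- sqrt(omega2)
    r <- (outer(omega2, omega2, "+") - tmat) / (2 * outer(om, om))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    if (iter > max_exclude) {
      attr(r, "capped") <- TRUE
      return(r)
    }
    cand <- abs(r) * include
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    hit <- which(cand == mx, arr.ind = TRUE)[1, ]
    include[hit[1], hit[2]] <- include[hit[2], hit[1]] <- FALSE
  }
  attr(r, "capped") <- FALSE
  r
}

#' @export
print.sparcc <- function(x, ...) {
  cat("SparCC correlations over", nrow(x$r), "taxa (",
      x$n_inner, "Dirichlet resamples )\n")
  invisible(x)
}

#' @rdname sparcc
#' @param x A `sparcc` object.
#' @param ... Unused.
#' @export
tidy.sparcc <- function(x, ...) pair_matrix_tidy(x$r, value = "r")

#' Bootstrap pseudo-p-values for SparCC correlations
#'
#' Each bootstrap permutes every taxon's counts across samples independently
#' (destroying all between-taxon association while keeping marginal
#' distributions), recomputes SparCC, and the two-sided pseudo-p-value is the
#' add-one exceedance fraction
#' \eqn{p_{ij} = (1 + \#\{|r^{boot}_{ij}| \ge |r^{obs}_{ij}|\}) / (n_{boot} + 1)},
#' so p is never 0 and p < .01 is attainable at 100 bootstraps (1/101).
#'
#' @param counts Counts matrix or wide tibble.
#' @param r_obs Observed correlation matrix (or a `sparcc` object).
#' @param n_boot Number of bootstraps (default 100).
#' @param seed Integer seed.
#' @param ... Passed on to [sparcc()] (e.g. `n_inner`).
#' @return A symmetric matrix of pseudo-p-values in (0, 1].
#' @export
bootstrap_pvalues <- function(counts, r_obs, n_boot = 100, seed = 1, ...) {
  mat <- as_count_matrix(counts)
  if (inherits(r_obs, "sparcc")) r_obs <- r_obs$r
  if (n_boot < 1) abort("n_boot must be at least 1.")
  exceed <- matrix(0, ncol(mat), ncol(mat))
  for (b in seq_len(n_boot)) {
    perm <- withr::with_seed(seed + 7919L * b, {
      apply(mat, 2, sample)
    })
    rownames(perm) <- rownames(mat)
    rb <- sparcc(perm, seed = seed + b, ...)$r
    exceed <- exceed + (abs(rb) >= abs(r_obs))
  }
  p <- (1 + exceed) / (n_boot + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(r_obs)
  p
}

#' Build the meta-community co-occurrence network
#'
#' Keeps edges with `p < p_cut` and `|r| >= r_cut` (defaults: the
#' conventional P < .01 and |r| >= 0.75), signed by the correlation.
#'
#' @param r Symmetric correlation matrix (or `sparcc` object).
#' @param p Symmetric p-value matrix.
#' @param r_cut Absolute-correlation threshold (default 0.75).
#' @param p_cut P-value threshold (default 0.01).
#' @return An object of class `metanetwork`: list with `graph` (igraph over
#'   all taxa), `edges` (tibble `taxon_i`, `taxon_j`, `r`, `p`, `sign`) and
#'   the thresholds.
#' @export
build_metanetwork <- function(r, p, r_cut = 0.75, p_cut = 0.01) {
  if (inherits(r, "sparcc")) r <- r$r
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)) ||
      !isTRUE(all.equal(p, t(p), tolerance = 1e-8))) {
    abort("`r` and `p` must be symmetric.")
  }
  keep <- (p < p_cut) & (abs(r) >= r_cut)
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  r_edge <- r[idx]
  edges <- tibble::tibble(
    taxon_i = rownames(r)[idx[, 1]],
    taxon_j = colnames(r)[idx[, 2]],
    r = r_edge,
    p = p[idx],
    sign = ifelse(r_edge > 0, "+", "-")
  )
  g <- igraph::graph_from_data_frame(
    edges[c("taxon_i", "taxon_j", "r", "p", "sign")],
    directed = FALSE,
    vertices = rownames(r)
  )
  out <- list(graph = g, edges = edges, r_cut = r_cut, p_cut = p_cut)
  class(out) <- "metanetwork"
  out
}

#' @export
print.metanetwork <- function(x, ...) {
  cat("Meta-community co-occurrence network: ",
      igraph::vcount(x$graph), " taxa, ", nrow(x$edges), " edges (|r| >= ",
      x$r_cut, ", p < ", x$p_cut, ")\n", sep = "")
  invisible(x)
}

#' @rdname build_metanetwork
#' @param x A `metanetwork` object.
#' @param ... Unused.
#' @export
tidy.metanetwork <- function(x, ...) x$edges

#' @rdname build_metanetwork
#' @export
glance.metanetwork <- function(x, ...) {
  tibble::tibble(
    n_taxa = igraph::vcount(x$graph),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "+"),
    n_negative = sum(x$edges$sign == "-"),
    r_cut = x$r_cut,
    p_cut = x$p_cut
  )
}

#' Per-sample subnetwork of the meta-network
#'
#' Induced subgraph on the taxa present (abundance > 0) in one sample.
#'
#' @param meta A `metanetwork`.
#' @param abundances Named abundance vector for one sample (names = taxa).
#' @return An igraph subgraph.
#' @export
sample_subnetwork <- function(meta, abundances) {
  nodes <- igraph::V(meta$graph)$name
  if (is.null(names(abundances))) {
    if (length(abundances) != length(nodes)) {
      abort("abundances must be named or aligned to the meta-network nodes.")
    }
    names(abundances) <- nodes
  }
  present <- names(abundances)[abundances > 0]
  igraph::induced_subgraph(meta$graph, intersect(nodes, present))
}

#' Topology metrics of a subnetwork
#'
#' Size (nodes), connectivity (edges), mean degree (2E/N), clustering
#' coefficient (average local coefficient; nodes of degree < 2 contribute 0)
#' and modularity (greedy agglomerative communities on the unsigned simple
#' graph, deterministic).
#'
#' @param g An igraph graph.
#' @return A one-row tibble.
#' @export
topology_metrics <- function(g) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    warn("empty subnetwork; all topology metrics set to 0.")
    return(tibble::tibble(size = 0L, connectivity = 0L, mean_degree = 0,
                          clustering = 0, modularity = 0))
  }
  cc <- if (e == 0) 0 else {
    mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
  }
  mod <- if (e == 0) 0 else {
    comm <- igraph::cluster_fast_greedy(
      g, weights = NULL, merges = FALSE, modularity = TRUE
    )
    igraph::modularity(comm)
  }
  tibble::tibble(
    size = n,
    connectivity = e,
    mean_degree = if (n > 0) 2 * e / n else 0,
    clustering = cc,
    modularity = mod
  )
}

#' Community cohesion from the meta-network
#'
#' Each taxon's positive (negative) connectedness is the mean correlation
#' over its positive (negative) significant edges in the meta-network, 0 if
#' it has none. Positive cohesion is the abundance-weighted sum of positive
#' connectedness over the sample; the ratio is |negative cohesion| /
#' positive cohesion.
#'
#' @param meta A `metanetwork`.
#' @param rel_abund Named relative-abundance vector for one sample
#'   (sum <= 1), names = taxa.
#' @return A one-row tibble with `pos_cohesion`, `neg_cohesion`,
#'   `neg_pos_ratio` (`NA` with a warning when positive cohesion is 0).
#' @export
cohesion <- function(meta, rel_abund) {
  nodes <- igraph::V(meta$graph)$name
  if (is.null(names(rel_abund))) {
    if (length(rel_abund) != length(nodes)) {
      abort("abundances must be named or aligned to the meta-network nodes.")
    }
    names(rel_abund) <- nodes
  }
  a <- stats::setNames(numeric(length(nodes)), nodes)
  hit <- intersect(nodes, names(rel_abund))
  a[hit] <- rel_abund[hit]
  conn_pos <- stats::setNames(numeric(length(nodes)), nodes)
  conn_neg <- conn_pos
  if (nrow(meta$edges) > 0) {
    long <- dplyr::bind_rows(
      meta$edges[c("taxon_i", "taxon_j", "r")],
      stats::setNames(meta$edges[c("taxon_j", "taxon_i", "r")],
                      c("taxon_i", "taxon_j", "r"))
    )
    pos <- long[long$r > 0, ]
    neg <- long[long$r < 0, ]
    if (nrow(pos) > 0) {
      mp <- tapply(pos$r, pos$taxon_i, mean)
      conn_pos[names(mp)] <- mp
    }
    if (nrow(neg) > 0) {
      mn <- tapply(neg$r, neg$taxon_i, mean)
      conn_neg[names(mn)] <- mn
    }
  }
  pos_coh <- sum(a * conn_pos)
  neg_coh <- sum(a * conn_neg)
  ratio <- if (pos_coh > 0) abs(neg_coh) / pos_coh else {
    warn("positive cohesion is 0; negative/positive ratio undefined.")
    NA_real_
  }
  tibble::tibble(pos_cohesion = pos_coh, neg_cohesion = neg_coh,
                 neg_pos_ratio = ratio)
}

#' Phylogenetic complementarity of co-occurring taxa
#'
#' Total branch length of the minimal subtree connecting the co-occurring
#' taxa — by default, the subgraph nodes with degree >= 1, i.e. taxa that
#' participate in at least one significant co-occurrence — excluding the stem
#' above their most recent common ancestor. Serves as a proxy for functional
#' complementarity under phylogenetic niche conservatism. Fewer than two
#' qualifying tips give 0.
#'
#' @param subgraph An igraph subnetwork (or a character vector of tip
#'   labels).
#' @param tree Rooted phylogeny containing the tips.
#' @param connected_only If TRUE (default) only nodes with degree >= 1
#'   qualify; if FALSE, all subgraph nodes.
#' @return Total branch length (tree distance units).
#' @export
complementarity <- function(subgraph, tree, connected_only = TRUE) {
  validate_phylogeny(tree)
  if (inherits(subgraph, "igraph")) {
    tips <- igraph::V(subgraph)$name
    if (connected_only) tips <- tips[igraph::degree(subgraph) >= 1]
  } else {
    tips <- as.character(subgraph)
  }
  if (!all(tips %in% tree$tip.label)) {
    abort("subnetwork contains taxa missing from the tree.")
  }
  induced_subtree_length(tree, tips)
}

# Sum of branch lengths of the minimal spanning subtree of `tips`,
# excluding the stem above their MRCA: an edge is included iff the number
# of selected tips below it is strictly between 0 and length(tips).
induced_subtree_length <- function(tree, tips) {
  k <- length(unique(tips))
  if (k < 2) return(0)
  tree <- ape::reorder.phylo(tree, "cladewise")
  sel <- tree$tip.label %in% tips
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  below <- numeric(n_node)
  below[seq_len(n_tip)] <- as.numeric(sel)
  # accumulate selected-tip counts child-to-parent in reverse edge order
  # (ape's cladewise order lists parents before children)
  ord <- rev(seq_len(nrow(tree$edge)))
  for (i in ord) {
    below[tree$edge[i, 1]] <- below[tree$edge[i, 1]] + below[tree$edge[i, 2]]
  }
  b <- below[tree$edge[, 2]]
  sum(tree$edge.length[b >= 1 & b <= k - 1])
}

#' Per-sample subnetwork metrics table
#'
#' Combines topology, cohesion and complementarity for every sample into one
#' tibble (the standard subnetwork comparison table across water masses).
#'
#' @param meta A `metanetwork`.
#' @param counts Counts matrix or wide tibble (presence defines subnetworks;
#'   relative abundances weight cohesion).
#' @param tree Rooted phylogeny of the taxa.
#' @return A tibble with one row per sample: `sample_id`, `size`,
#'   `connectivity`, `mean_degree`, `pos_cohesion`, `neg_pos_ratio`,
#'   `clustering`, `modularity`, `complementarity`.
#' @export
subnetwork_metrics <- function(meta, counts, tree) {
  mat <- as_count_matrix(counts)
  rel <- relative_abundance(mat)
  purrr::map_dfr(rownames(mat), function(s) {
    sub <- sample_subnetwork(meta, mat[s, ])
    top <- topology_metrics(sub)
    coh <- cohesion(meta, rel[s, ])
    dplyr::bind_cols(
      tibble::tibble(sample_id = s),
      top[c("size", "connectivity", "mean_degree")],
      coh[c("pos_cohesion", "neg_pos_ratio")],
      top[c("clustering", "modularity")],
      tibble::tibble(complementarity = complementarity(sub, tree))
    )
  })
}
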