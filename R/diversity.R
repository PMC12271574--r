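#' Cophenetic (tip-to-tip) distances of a phylogeny
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric taxa-by-taxa matrix of path-length distances.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2) abort("tree must have at least 2 tips.")
  ape::cophenetic.phylo(tree)
}

#' Per-sample richness and Shannon diversity
#'
#' Richness counts taxa with positive abundance; Shannon is
#' \eqn{-\sum p \log p} over positive relative abundances, in nats.
#'
#' @param counts Counts matrix or wide tibble.
#' @return A tibble with `sample_id`, `richness`, `shannon`.
#' @export
richness_shannon <- function(counts) {
  mat <- as_count_matrix(counts)
  if (any(rowSums(mat) <= 0)) abort("every sample must have a positive total.")
  tibble::tibble(
    sample_id = rownames(mat),
    richness = as.integer(rowSums(mat > 0)),
    shannon = unname(vegan::diversity(mat, index = "shannon"))
  )
}

#' Abundance-weighted mean pairwise phylogenetic distance
#'
#' \deqn{MPD = \sum_{i}\sum_{j \ne i} w_i w_j d_{ij} / \sum_{i}\sum_{j \ne i} w_i w_j}
#' over the taxa present in the sample. Invariant to rescaling the weights.
#'
#' @param w Named (or dist-aligned) abundance vector for one sample.
#' @param dists Symmetric cophenetic distance matrix.
#' @return The weighted MPD, or `NA` (with a warning) for fewer than two
#'   present taxa.
#' @export
weighted_mpd <- function(w, dists) {
  if (!is.null(names(w))) {
    if (!all(names(w) %in% rownames(dists))) {
      abort("abundance names must match distance-matrix taxa.")
    }
    v <- stats::setNames(numeric(nrow(dists)), rownames(dists))
    v[names(w)] <- w
    w <- v
  }
  if (length(w) != nrow(dists)) {
    abort("abundance vector does not align with the distance matrix.")
  }
  if (sum(w > 0) < 2) {
    warn("fewer than 2 taxa present; MPD undefined.")
    return(NA_real_)
  }
  num <- drop(t(w) %*% dists %*% w) # zero diagonal: j != i automatic
  den <- sum(w)^2 - sum(w^2)
  num / den
}

# Vectorized weighted MPD for all rows of a samples-by-taxa matrix.
# Returns NA for rows with fewer than two present taxa.
weighted_mpd_rows <- function(mat, dists) {
  dists <- dists[colnames(mat), colnames(mat), drop = FALSE]
  num <- rowSums((mat %*% dists) * mat)
  den <- rowSums(mat)^2 - rowSums(mat^2)
  out <- num / den
  out[rowSums(mat > 0) < 2] <- NA_real_
  out
}

#' Independent-swap randomization of a community matrix
#'
#' Performs `n_swaps` successful 2x2 checkerboard swaps: submatrices with
#' occupancy pattern \code{[[+,0],[0,+]]} have their nonzero entries moved to
#' the opposite diagonal, carrying their abundances. Per-sample richness and
#' per-taxon occurrence frequency are preserved exactly. If no checkerboard
#' exists the matrix is returned unchanged.
#'
#' @param counts Counts matrix or wide tibble.
#' @param n_swaps Number of successful swaps to perform (>= 0).
#' @param seed Integer seed; the result is deterministic per seed.
#' @return A randomized matrix with the same occupancy margins.
#' @export
independent_swap <- function(counts, n_swaps = 1000, seed = 1) {
  mat <- as_count_matrix(counts)
  if (n_swaps < 0) abort("n_swaps must be non-negative.")
  out <- withr::with_seed(seed, independent_swap_cpp(mat, as.integer(n_swaps)))
  dimnames(out) <- dimnames(mat)
  out
}

#' Standardized effect size of MPD under the independent-swap null
#'
#' For each sample, \deqn{SES_{MPD} = (MPD_{obs} - \bar{MPD}_{null}) / sd(MPD_{null})}
#' where the null distribution comes from `n_null` independent-swap
#' randomizations of the whole community matrix, each followed by the
#' abundance-weighted MPD. Positive values indicate co-occurring taxa that
#' are more phylogenetically distant than expected by chance. Each replicate
#' starts from the observed matrix with its own seed derived from `seed`,
#' so replicates are mutually independent.
#'
#' @param counts Counts matrix or wide tibble.
#' @param dists Cophenetic distance matrix covering all taxa.
#' @param n_null Number of null replicates (>= 2; default 999).
#' @param n_swaps Successful swaps per replicate (default 1000).
#' @param seed Master integer seed.
#' @return An object of class `ses_mpd`: a list with `table` (tibble of
#'   `sample_id`, `richness`, `shannon`, `mpd`, `ses_mpd`, `null_mean`,
#'   `null_sd`) and `null` (samples-by-replicates matrix of null MPDs).
#' @export
ses_mpd <- function(counts, dists, n_null = 999, n_swaps = 1000, seed = 1) {
  mat <- as_count_matrix(counts)
  if (n_null < 2) abort("n_null must be at least 2.")
  if (!all(colnames(mat) %in% rownames(dists))) {
    abort("all taxa must appear in the distance matrix.")
  }
  obs <- weighted_mpd_rows(mat, dists)
  null_seeds <- seed + seq_len(n_null)
  null <- vapply(null_seeds, function(s) {
    weighted_mpd_rows(independent_swap(mat, n_swaps = n_swaps, seed = s), dists)
  }, numeric(nrow(mat)))
  null <- matrix(null, nrow = nrow(mat),
                 dimnames = list(rownames(mat), NULL))
  null_mean <- rowMeans(null)
  null_sd <- apply(null, 1, stats::sd)
  ses <- (obs - null_mean) / null_sd
  degenerate <- !is.na(null_sd) & null_sd < 1e-12
  if (any(degenerate)) {
    warn("degenerate null distribution for some samples; SES set to NA.")
    ses[degenerate] <- NA_real_
  }
  rs <- richness_shannon(mat)
  out <- list(
    table = tibble::tibble(
      sample_id = rownames(mat),
      richness = rs$richness,
      shannon = rs$shannon,
      mpd = unname(obs),
      ses_mpd = unname(ses),
      null_mean = unname(null_mean),
      null_sd = unname(null_sd)
    ),
    null = null,
    n_null = n_null,
    n_swaps = n_swaps,
    seed = seed
  )
  class(out) <- "ses_mpd"
  out
}

#' @export
print.ses_mpd <- function(x, ...) {
  cat("Abundance-weighted MPD with independent-swap null (",
      x$n_null, " replicates, ", x$n_swaps, " swaps each)\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' @rdname ses_mpd
#' @param x A `ses_mpd` object.
#' @param ... Unused.
#' @export
tidy.ses_mpd <- function(x, ...) x$table

#' @rdname ses_mpd
#' @export
glance.ses_mpd <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$table),
    n_null = x$n_null,
    n_swaps = x$n_swaps,
    mean_mpd = mean(x$table$mpd, na.rm = TRUE),
    mean_ses_mpd = mean(x$table$ses_mpd, na.rm = TRUE)
  )
}

#' Full per-sample diversity table
#'
#' Convenience wrapper joining richness, Shannon, MPD and SES_MPD into one
#' tibble keyed by sample.
#'
#' @inheritParams ses_mpd
#' @param tree Rooted phylogeny covering the taxa (used when `dists` is NULL).
#' @param dists Optional precomputed cophenetic matrix.
#' @return A tibble with one row per sample.
#' @export
diversity_table <- function(counts, tree = NULL, dists = NULL,
                            n_null = 999, n_swaps = 1000, seed = 1) {
  if (is.null(dists)) {
    if (is.null(tree)) abort("supply either `tree` or `dists`.")
    dists <- cophenetic_distances(tree)
  }
  tidy(ses_mpd(counts, dists, n_null = n_null, n_swaps = n_swaps, seed = seed))
}
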