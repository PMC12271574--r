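#' Bin a phylogeny at a fixed pairwise-distance threshold
#'
#' Bins are the maximal clades whose within-clade maximum pairwise
#' cophenetic distance does not exceed `threshold` (default 0.1 tree
#' distance units), found by a root-to-tip traversal; tips in no qualifying
#' multi-tip clade become singleton bins. Bin ids follow traversal order,
#' so the assignment is deterministic.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param threshold Maximum within-bin pairwise cophenetic distance (>= 0).
#' @return An object of class `bin_assignment`: list with `assignment`
#'   (tibble `taxon_id`, `bin_id`), `bins` (tibble `bin_id`, `n_taxa`,
#'   `mean_pd` — mean pairwise cophenetic distance, `NA` for singletons) and
#'   `threshold`.
#' @export
bin_phylogeny <- function(tree, threshold = 0.1) {
  validate_phylogeny(tree)
  if (threshold < 0) abort("threshold must be non-negative.")
  tree <- ape::reorder.phylo(tree, "cladewise")
  dmat <- cophenetic_distances(tree)
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_below), use.names = FALSE)
  }
  bins <- list()
  visit <- function(node) {
    tips <- tips_below(node)
    labs <- tree$tip.label[tips]
    if (length(tips) == 1 || max(dmat[labs, labs]) <= threshold) {
      bins[[length(bins) + 1]] <<- labs
    } else {
      for (ch in children[[as.character(node)]]) visit(ch)
    }
  }
  root <- n_tip + 1L
  visit(root)
  assignment <- tibble::tibble(
    taxon_id = unlist(bins, use.names = FALSE),
    bin_id = rep(paste0("bin", seq_along(bins)), lengths(bins))
  )
  summary <- tibble::tibble(
    bin_id = paste0("bin", seq_along(bins)),
    n_taxa = lengths(bins),
    mean_pd = vapply(bins, function(labs) {
      if (length(labs) < 2) return(NA_real_)
      d <- dmat[labs, labs]
      mean(d[upper.tri(d)])
    }, numeric(1))
  )
  out <- list(assignment = assignment, bins = summary, threshold = threshold)
  class(out) <- "bin_assignment"
  out
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat("Phylogenetic binning at threshold", x$threshold, ":",
      nrow(x$assignment), "tips in", nrow(x$bins), "bins\n")
  invisible(x)
}

#' @rdname bin_phylogeny
#' @param x A `bin_assignment` object.
#' @param ... Unused.
#' @export
tidy.bin_assignment <- function(x, ...) x$assignment

#' @rdname bin_phylogeny
#' @export
glance.bin_assignment <- function(x, ...) {
  tibble::tibble(
    n_tips = nrow(x$assignment),
    n_bins = nrow(x$bins),
    threshold = x$threshold,
    max_bin_size = max(x$bins$n_taxa)
  )
}

#' Per-bin niche and productivity statistics
#'
#' For every phylogenetic bin: the member count and mean pairwise distance;
#' Pearson correlations of the bin's per-sample mean relative abundance with
#' bacterial production, abundance and cell-specific production across
#' samples; and the mean pairwise niche overlap and niche difference over
#' member pairs (singleton bins give missing pairwise statistics).
#'
#' @param bins A `bin_assignment` from [bin_phylogeny()].
#' @param rel_abund Relative-abundance matrix (samples x taxa) or wide
#'   tibble.
#' @param samples Sample metadata with `sample_id` and any of `bp`, `ba`,
#'   `sbp`.
#' @param overlap Pairwise niche-overlap matrix from [niche_overlap()].
#' @param differences Pairwise niche-difference matrix from
#'   [niche_difference()].
#' @return A tibble with one row per bin: `bin_id`, `n_taxa`, `mean_pd`,
#'   `r_bp`, `r_ba`, `r_sbp`, `mean_overlap`, `mean_niche_difference`.
#' @export
bin_statistics <- function(bins, rel_abund, samples, overlap = NULL,
                           differences = NULL) {
  mat <- as_count_matrix(rel_abund)
  samples <- tibble::as_tibble(samples)
  if (!all(rownames(mat) %in% samples$sample_id)) {
    abort("every sample in `rel_abund` must appear in `samples`.")
  }
  samples <- samples[match(rownames(mat), samples$sample_id), ]
  n_complete <- sum(stats::complete.cases(
    samples[intersect(c("bp", "ba", "sbp"), names(samples))]
  ))
  if (n_complete < 3) {
    warn("fewer than 3 complete samples; productivity correlations undefined.")
  }
  cor_with <- function(x, col) {
    if (!col %in% names(samples)) return(NA_real_)
    y <- samples[[col]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])
  }
  mean_pairs <- function(m, labs) {
    labs <- intersect(labs, rownames(m))
    if (length(labs) < 2) return(NA_real_)
    mm <- m[labs, labs]
    mean(mm[upper.tri(mm)])
  }
  members <- split(bins$assignment$taxon_id, bins$assignment$bin_id)
  purrr::map_dfr(seq_len(nrow(bins$bins)), function(i) {
    b <- bins$bins$bin_id[i]
    labs <- intersect(members[[b]], colnames(mat))
    mean_ab <- if (length(labs) == 0) rep(NA_real_, nrow(mat)) else {
      rowMeans(mat[, labs, drop = FALSE])
    }
    tibble::tibble(
      bin_id = b,
      n_taxa = bins$bins$n_taxa[i],
      mean_pd = bins$bins$mean_pd[i],
      r_bp = cor_with(mean_ab, "bp"),
      r_ba = cor_with(mean_ab, "ba"),
      r_sbp = cor_with(mean_ab, "sbp"),
      mean_overlap = if (is.null(overlap)) NA_real_ else {
        mean_pairs(overlap, members[[b]])
      },
      mean_niche_difference = if (is.null(differences)) NA_real_ else {
        mean_pairs(differences, members[[b]])
      }
    )
  })
}
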