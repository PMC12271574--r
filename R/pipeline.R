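#' Pipeline run configuration
#'
#' Bundles input locations (file paths or in-memory objects) and every
#' tunable parameter of the analysis. Thresholds default to the
#' conventional values: network edges at P < .01 and |r| >= 0.75,
#' phylogenetic bins at 0.1 tree distance units.
#'
#' @param counts Count table: path (TSV/BIOM) or samples-by-taxa matrix /
#'   wide tibble.
#' @param tree Rooted phylogeny: newick path or `phylo`.
#' @param metadata Per-sample metadata: CSV path or data frame.
#' @param copy_numbers Optional copy-number table: TSV path or named vector.
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param seed Master seed for every stochastic stage.
#' @param n_null,n_swaps Null-model replicates and swaps per replicate.
#' @param n_inner,n_boot,exclusion_threshold SparCC parameters.
#' @param p_cut,r_cut Meta-network thresholds.
#' @param bin_threshold Phylogenetic bin width (tree distance units).
#' @param overlap_method Niche-overlap index (default `"levins"`).
#' @param cache Reuse cached SparCC results when inputs and parameters are
#'   unchanged (content-hash keyed; default TRUE when `out_dir` is set).
#' @return A `run_config` list.
#' @export
run_config <- function(counts, tree, metadata, copy_numbers = NULL,
                       out_dir = NULL, seed = 1,
                       n_null = 999, n_swaps = 1000,
                       n_inner = 20, n_boot = 100, exclusion_threshold = 0.1,
                       p_cut = 0.01, r_cut = 0.75,
                       bin_threshold = 0.1,
                       overlap_method = "levins",
                       cache = !is.null(out_dir)) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

load_inputs <- function(config) {
  counts <- if (is.character(config$counts)) {
    read_count_table(config$counts)
  } else {
    as_count_matrix(config$counts)
  }
  tree <- if (is.character(config$tree)) {
    read_phylogeny(config$tree)
  } else {
    validate_phylogeny(config$tree)
  }
  samples <- if (is.character(config$metadata)) {
    read_sample_table(config$metadata)
  } else {
    validate_sample_table(config$metadata)
  }
  copies <- config$copy_numbers
  if (is.character(copies)) copies <- read_copy_numbers(copies)
  missing_tip <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing_tip) > 0) {
    abort(paste0("taxa absent from the tree: ",
                 paste(utils::head(missing_tip, 5), collapse = ", "),
                 if (length(missing_tip) > 5) ", ..." else ""))
  }
  missing_meta <- setdiff(rownames(counts), samples$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("samples absent from the metadata: ",
                 paste(utils::head(missing_meta, 5), collapse = ", "),
                 if (length(missing_meta) > 5) ", ..." else ""))
  }
  samples <- samples[match(rownames(counts), samples$sample_id), ]
  list(counts = counts, tree = tree, samples = samples, copies = copies)
}

#' Run the full gradient analysis pipeline
#'
#' Preprocessing (copy-number correction, rarefaction, relative abundance)
#' -> diversity (richness, Shannon, MPD, SES_MPD) -> niches (salinity
#' optima, indicators, overlap, differences) -> co-occurrence network
#' (SparCC, bootstrap p-values, thresholded meta-network, per-sample
#' subnetwork topology, cohesion, complementarity) -> phylogenetic bins ->
#' group statistics (Kruskal-Wallis + BH across water masses, hierarchical
#' partitioning of diversity on indicator groups). All stages derive their
#' seeds from the master seed; a second run with the same configuration is
#' bit-identical.
#'
#' @param config A [run_config()].
#' @return A list (class `dpr_bundle`) of result tibbles: `diversity`,
#'   `niche`, `network_edges`, `subnetworks`, `bin_assignment`, `bin_stats`,
#'   `tests`, `hier_part`, plus `meta` (the `metanetwork` object) and
#'   `manifest`. Written as TSVs + `manifest.yaml` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  inputs <- load_inputs(config)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    counts <- inputs$counts
    if (!is.null(inputs$copies)) {
      counts <- correct_copy_number(counts, inputs$copies)
    }
    rare <- rarefy_counts(counts, seed = config$seed + 11L)
    rel <- relative_abundance(rare)
    dists <- cophenetic_distances(inputs$tree)

    div <- ses_mpd(rare, dists, n_null = config$n_null,
                   n_swaps = config$n_swaps, seed = config$seed + 23L)
    diversity <- dplyr::left_join(
      tidy(div),
      inputs$samples[c("sample_id", "salinity", "water_mass",
                       intersect(c("bp", "ba", "sbp"), names(inputs$samples)))],
      by = "sample_id"
    )

    niche <- niche_table(rare, inputs$samples)
    overlap <- niche_overlap(rare, method = config$overlap_method)
    differences <- niche_difference(niche)

    net <- sparcc_cached(rare, config)
    pvals <- net$p
    meta <- build_metanetwork(net$r, pvals,
                              r_cut = config$r_cut, p_cut = config$p_cut)
    subnets <- dplyr::left_join(
      subnetwork_metrics(meta, rare, inputs$tree),
      inputs$samples[c("sample_id", "water_mass")],
      by = "sample_id"
    )

    bins <- bin_phylogeny(inputs$tree, threshold = config$bin_threshold)
    bstats <- bin_statistics(bins, rel, inputs$samples,
                             overlap = overlap, differences = differences)

    test_vars <- intersect(
      c("bp", "ba", "sbp", "richness", "shannon", "mpd", "ses_mpd"),
      names(diversity)
    )
    tests <- compare_water_masses(diversity, test_vars)
    topo_tests <- compare_water_masses(
      subnets, c("size", "connectivity", "mean_degree", "pos_cohesion",
                 "neg_pos_ratio", "clustering", "modularity",
                 "complementarity")
    )
    hp <- indicator_partitioning(rel, niche, diversity)

    bundle <- list(
      diversity = diversity,
      niche = niche,
      network_edges = tidy(meta),
      subnetworks = subnets,
      bin_assignment = tidy(bins),
      bin_stats = bstats,
      tests = dplyr::bind_rows(tests, topo_tests),
      hier_part = hp,
      meta = meta,
      rarefied = rare
    )
    bundle$manifest <- build_manifest(config, inputs, warnings_log)
    class(bundle) <- "dpr_bundle"
    if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
    bundle
  }, warning = note)
}

# Hierarchical partitioning of each diversity metric on the summed relative
# abundance of plume / mixed / SCS indicator taxa.
indicator_partitioning <- function(rel, niche, diversity) {
  groups <- split(niche$taxon_id, niche$indicator)
  preds <- tibble::as_tibble(purrr::map(groups, function(taxa) {
    taxa <- intersect(taxa, colnames(rel))
    if (length(taxa) == 0) return(rep(0, nrow(rel)))
    rowSums(rel[, taxa, drop = FALSE])
  }))
  names(preds) <- paste0(names(groups), "_indicators")
  keep <- vapply(preds, function(x) stats::sd(x) > 0, logical(1))
  preds <- preds[keep]
  purrr::map_dfr(c("richness", "shannon", "mpd", "ses_mpd"), function(resp) {
    y <- diversity[[resp]]
    ok <- is.finite(y)
    if (sum(ok) <= ncol(preds) + 1 || ncol(preds) == 0) {
      return(tibble::tibble(response = character(0)))
    }
    hp <- hierarchical_partitioning(y[ok], preds[ok, , drop = FALSE])
    dplyr::mutate(tidy(hp), response = resp, total_r2 = hp$total_r2,
                  .before = 1)
  })
}

sparcc_cached <- function(rare, config) {
  compute <- function() {
    fit <- sparcc(rare, n_inner = config$n_inner,
                  exclusion_threshold = config$exclusion_threshold,
                  seed = config$seed + 31L)
    p <- bootstrap_pvalues(rare, fit, n_boot = config$n_boot,
                           seed = config$seed + 47L,
                           n_inner = config$n_inner,
                           exclusion_threshold = config$exclusion_threshold)
    list(r = fit$r, p = p)
  }
  if (!isTRUE(config$cache) || is.null(config$out_dir)) return(compute())
  key <- rlang::hash(list(rare, config$n_inner, config$exclusion_threshold,
                          config$n_boot, config$seed))
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  cache_file <- file.path(cache_dir, paste0("sparcc-", key, ".rds"))
  if (file.exists(cache_file)) return(readRDS(cache_file))
  out <- compute()
  saveRDS(out, cache_file)
  out
}

build_manifest <- function(config, inputs, warnings_log) {
  params <- config[setdiff(names(config),
                           c("counts", "tree", "metadata", "copy_numbers"))]
  params$out_dir <- if (is.null(params$out_dir)) NA else params$out_dir
  list(
    inputs = list(
      counts = if (is.character(config$counts)) config$counts else "<in-memory>",
      tree = if (is.character(config$tree)) config$tree else "<in-memory>",
      metadata = if (is.character(config$metadata)) config$metadata else "<in-memory>",
      copy_numbers = if (is.null(config$copy_numbers)) {
        NA
      } else if (is.character(config$copy_numbers)) {
        config$copy_numbers
      } else "<in-memory>",
      n_samples = nrow(inputs$counts),
      n_taxa = ncol(inputs$counts)
    ),
    parameters = lapply(params, function(x) if (is.null(x)) NA else x),
    versions = list(
      plumedpr = as.character(utils::packageVersion("plumedpr")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    ),
    warnings = as.list(warnings_log)
  )
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("diversity", "niche", "network_edges", "subnetworks",
              "bin_assignment", "bin_stats", "tests", "hier_part")
  for (nm in tables) {
    readr::write_tsv(bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  igraph::write_graph(bundle$meta$graph,
                      file.path(out_dir, "metanetwork.graphml"),
                      format = "graphml")
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.dpr_bundle <- function(x, ...) {
  cat("Gradient DPR analysis bundle\n")
  cat("  samples:", nrow(x$diversity), " taxa:", nrow(x$niche), "\n")
  cat("  network:", nrow(x$network_edges), "edges;",
      nrow(x$bin_stats), "phylogenetic bins\n")
  invisible(x)
}
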