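#' Configuration for the synthetic gradient community generator
#'
#' Defaults emulate a rarefied coastal 16S survey spanning an estuarine
#' plume-to-open-sea salinity gradient: ~70 samples over salinity 28-34.5
#' PSU (all three water-mass classes represented), a few hundred taxa on an
#' ultrametric tree, a copiotroph guild concentrated in several deep,
#' mutually distant clades with low-salinity optima and high per-cell
#' productivity, an oligotroph guild with high-salinity optima dominated by
#' one abundant streamlined clade, log-normal sequencing depths, and
#' productivity (BA, sBP, BP) coupled to community composition.
#'
#' @param n_taxa Number of tips/taxa (>= 4; default 300).
#' @param n_samples Number of samples (default 72).
#' @param salinity_range Gradient range in PSU (default c(28, 34.5); must
#'   span all three water-mass classes).
#' @param class_fractions Fractions of samples drawn in the plume, mixed and
#'   SCS salinity bands (default c(0.40, 0.25, 0.35)).
#' @param copiotroph_fraction Fraction of taxa assigned to the copiotroph
#'   guild (default 0.35).
#' @param n_copiotroph_clades Minimum number of deep clades carrying the
#'   copiotroph guild (default 4).
#' @param copiotroph_optimum,oligotroph_optimum Guild-mean salinity optima
#'   (PSU; defaults 30.5 and 34.1).
#' @param optimum_sd Within-guild sd of optima (PSU), named for both guilds.
#' @param niche_breadth Gaussian niche breadths (PSU), named for both
#'   guilds.
#' @param phylo_signal Weight (PSU per unit trait) of the Brownian trait
#'   diffusion added to the salinity optima (default 0.5).
#' @param productivity_mean Guild-mean per-cell productivity traits
#'   (fg C cell^-1 d^-1); copiotroph default 3x the oligotroph mean.
#' @param productivity_sdlog Log-scale sd of the productivity traits.
#' @param dominant_share Target share of the dominant oligotroph clade in
#'   the oligotroph guild's summed base abundance (default 0.65): the
#'   streamlined-ecotype dominance of open-sea communities.
#' @param copiotroph_abundance_boost Base-abundance multiplier of copiotroph
#'   taxa (default 3), reflecting bloom-type growth in the plume.
#' @param base_abundance_sdlog Log-scale sd of per-taxon base abundances.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters
#'   (defaults log(8000) and 0.3).
#' @param ba_scale Mean bacterial abundance (cells ml^-1) mapped to the mean
#'   expected community size (default 5e5).
#' @param coupling Multiplier linking community-weighted productivity traits
#'   to realized cell-specific production (default 1).
#' @param noise_sd Log-scale sd of the multiplicative abundance and
#'   productivity noise (default 0.3).
#' @param copiotroph_pendant Additive elongation of copiotroph pendant
#'   branches (tree distance units; default 0.035) applied when a dataset is
#'   assembled: metabolically versatile copiotroph taxa are internally
#'   divergent even within clades, linking within-bin phylogenetic distance
#'   to the productive guild.
#' @param dominant_divergence Branch-length scaling inside the dominant
#'   oligotroph clade (default 0.3): the streamlined ecotype is internally
#'   near-uniform.
#' @param tree_depth Root-to-tip depth of the rescaled tree (default 0.5,
#'   so pairwise distances span (0, 1]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 300,
                       n_samples = 72,
                       salinity_range = c(28, 34.5),
                       class_fractions = c(plume = 0.40, mixed = 0.25, scs = 0.35),
                       copiotroph_fraction = 0.35,
                       n_copiotroph_clades = 4,
                       copiotroph_optimum = 30.5,
                       oligotroph_optimum = 34.1,
                       optimum_sd = c(copiotroph = 0.6, oligotroph = 0.35),
                       niche_breadth = c(copiotroph = 1.2, oligotroph = 1.0),
                       phylo_signal = 0.5,
                       productivity_mean = c(copiotroph = 6, oligotroph = 2),
                       productivity_sdlog = 0.3,
                       dominant_share = 0.65,
                       copiotroph_abundance_boost = 3,
                       base_abundance_sdlog = 0.6,
                       depth_meanlog = log(8000),
                       depth_sdlog = 0.3,
                       ba_scale = 5e5,
                       coupling = 1,
                       noise_sd = 0.3,
                       copiotroph_pendant = 0.035,
                       dominant_divergence = 0.3,
                       tree_depth = 0.5) {
  cfg <- as.list(environment())
  if (cfg$n_taxa < 4) abort("n_taxa must be at least 4.")
  if (cfg$n_samples < 3) abort("n_samples must be at least 3.")
  if (cfg$salinity_range[1] >= 33 || cfg$salinity_range[2] <= 33.75) {
    abort("salinity_range must span the plume, mixed and SCS classes.")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Branch lengths are rescaled so the root-to-tip depth equals `depth`.
#' Deterministic per seed.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Integer seed.
#' @param depth Root-to-tip depth after rescaling (default 0.5).
#' @return An ultrametric `phylo` with tips `ASV0001`, `ASV0002`, ...
#' @export
simulate_tree <- function(n_taxa, seed = 1, depth = 0.5) {
  if (n_taxa < 4) abort("n_taxa must be at least 4.")
  tree <- withr::with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / h
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_taxa))
  tree
}

# Internal: pick mutually disjoint clades by a seeded greedy pass.
# size_range is in tips; returns a list of tip-index vectors.
pick_clades <- function(tree, n_target_tips, size_range,
                        exclude_tips = integer(0), prefer_shallow = FALSE) {
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  children <- split(tree$edge[, 2], tree$edge[, 1])
  clade_tips <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(children[[as.character(node)]], clade_tips), use.names = FALSE)
  }
  internal <- (n_tip + 1L):max(tree$edge)
  tips_of <- lapply(internal, clade_tips)
  sizes <- lengths(tips_of)
  cand <- which(sizes >= size_range[1] & sizes <= size_range[2])
  if (prefer_shallow) {
    # shallow MRCA = phylogenetically tight clade (small within distances)
    node_depth <- ape::node.depth.edgelength(tree)
    cand <- cand[order(node_depth[internal[cand]], decreasing = TRUE)]
  } else {
    cand <- cand[sample.int(length(cand))]
  }
  chosen <- list()
  used <- exclude_tips
  total <- 0
  for (ci in cand) {
    tp <- tips_of[[ci]]
    if (length(intersect(tp, used)) > 0) next
    chosen[[length(chosen) + 1]] <- tp
    used <- c(used, tp)
    total <- total + length(tp)
    if (total >= n_target_tips) break
  }
  chosen
}

#' Simulate per-taxon ground-truth traits
#'
#' A latent trait diffuses along the tree (Brownian increments with variance
#' proportional to branch length). The copiotroph guild is assigned to
#' several deep, mutually disjoint clades so plume communities are
#' phylogenetically dispersed; one additional oligotroph clade is marked
#' dominant (a streamlined, SAR11-like ecotype) and receives a base-abundance
#' boost. Salinity optima are drawn around guild means plus the scaled
#' Brownian trait; per-cell productivity traits are log-normal with the
#' copiotroph mean a configurable multiple of the oligotroph mean; 16S
#' operon copy numbers are higher for copiotrophs.
#'
#' @param tree Phylogeny from [simulate_tree()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble (class `sim_truth`) with one row per taxon: `taxon_id`,
#'   `guild`, `clade`, `salinity_optimum`, `niche_breadth`,
#'   `productivity_trait`, `base_abundance`, `copy_number`.
#' @export
simulate_traits <- function(tree, config = sim_config(), seed = 1) {
  n_tip <- length(tree$tip.label)
  withr::with_seed(seed, {
    # Brownian diffusion root-to-tip
    tr <- ape::reorder.phylo(tree, "cladewise")
    node_val <- numeric(max(tr$edge))
    for (i in seq_len(nrow(tr$edge))) {
      par <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      node_val[ch] <- node_val[par] +
        stats::rnorm(1, sd = sqrt(tr$edge.length[i]))
    }
    bm <- node_val[seq_len(n_tip)]
    bm <- (bm - mean(bm)) / max(stats::sd(bm), 1e-12)

    target <- ceiling(config$copiotroph_fraction * n_tip)
    max_size <- max(3, ceiling(target / config$n_copiotroph_clades))
    copio_clades <- pick_clades(tree, target,
                                c(max(3, floor(0.02 * n_tip)), max_size))
    guild <- rep("oligotroph", n_tip)
    clade <- rep("oligo", n_tip)
    for (ci in seq_along(copio_clades)) {
      guild[copio_clades[[ci]]] <- "copiotroph"
      clade[copio_clades[[ci]]] <- paste0("copio_clade", ci)
    }
    copio_tips <- which(guild == "copiotroph")
    dom <- pick_clades(tree, 1,
                       c(max(3, floor(0.05 * n_tip)), ceiling(0.15 * n_tip)),
                       exclude_tips = copio_tips, prefer_shallow = TRUE)
    if (length(dom) > 0) clade[dom[[1]]] <- "dominant_oligo"

    is_cop <- guild == "copiotroph"
    optimum <- ifelse(is_cop, config$copiotroph_optimum,
                      config$oligotroph_optimum) +
      config$phylo_signal * bm +
      stats::rnorm(n_tip, sd = ifelse(is_cop, config$optimum_sd["copiotroph"],
                                      config$optimum_sd["oligotroph"]))
    # the dominant streamlined clade is an open-sea specialist by
    # construction: its optima sit at the guild mean, free of the clade-level
    # Brownian offset
    dom_now <- clade == "dominant_oligo"
    optimum[dom_now] <- config$oligotroph_optimum +
      stats::rnorm(sum(dom_now), sd = 0.2)
    breadth <- ifelse(is_cop, config$niche_breadth["copiotroph"],
                      config$niche_breadth["oligotroph"])
    trait <- stats::rlnorm(
      n_tip,
      meanlog = log(ifelse(is_cop, config$productivity_mean["copiotroph"],
                           config$productivity_mean["oligotroph"])),
      sdlog = config$productivity_sdlog
    )
    base <- stats::rlnorm(n_tip, 0, config$base_abundance_sdlog) *
      ifelse(is_cop, config$copiotroph_abundance_boost, 1)
    dom_idx <- clade == "dominant_oligo"
    other_oligo <- !is_cop & !dom_idx
    if (any(dom_idx) && any(other_oligo)) {
      # scale the dominant clade to a fixed share of the oligotroph guild,
      # conserving the guild total so open-sea community size is unchanged
      oligo_total <- sum(base[!is_cop])
      tgt <- config$dominant_share
      base[dom_idx] <- base[dom_idx] * tgt / (1 - tgt) *
        sum(base[other_oligo]) / sum(base[dom_idx])
      base[!is_cop] <- base[!is_cop] * oligo_total / sum(base[!is_cop])
    }
    copy_number <- ifelse(is_cop, sample(3:8, n_tip, replace = TRUE),
                          sample(1:2, n_tip, replace = TRUE))
    truth <- tibble::tibble(
      taxon_id = tree$tip.label,
      guild = guild,
      clade = clade,
      salinity_optimum = unname(optimum),
      niche_breadth = unname(breadth),
      productivity_trait = unname(trait),
      base_abundance = unname(base),
      copy_number = as.numeric(copy_number)
    )
    class(truth) <- c("sim_truth", class(truth))
    truth
  })
}

#' Simulate a gradient community and its metadata
#'
#' Sample salinities are drawn stratified over the plume, mixed and SCS
#' bands. The expected abundance of each taxon is a Gaussian response to
#' salinity around its true optimum, times its base abundance and
#' multiplicative log-normal noise; observed counts are multinomial draws at
#' a log-normal per-sample sequencing depth (the raw reads, before copy
#' correction and rarefaction). Bacterial abundance (BA) is proportional to
#' the expected community size; cell-specific production (sBP) is the
#' abundance-weighted mean productivity trait times noise; BP = sBP x BA.
#'
#' @param tree Phylogeny from [simulate_tree()].
#' @param truth Trait table from [simulate_traits()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `counts` (samples-by-taxa matrix of reads, scaled by
#'   copy number so copy-number correction is a real preprocessing step) and
#'   `samples` (metadata tibble with salinity, temperature, chla,
#'   depth_layer, leu_rate, bp, ba, sbp, hna, lna, water_mass).
#' @export
simulate_community <- function(tree, truth, config = sim_config(), seed = 1) {
  if (config$salinity_range[1] >= 33 || config$salinity_range[2] <= 33.75) {
    abort("configuration must span all three water-mass classes.")
  }
  n <- config$n_samples
  withr::with_seed(seed, {
    n_plume <- round(config$class_fractions[[1]] * n)
    n_mixed <- round(config$class_fractions[[2]] * n)
    n_scs <- n - n_plume - n_mixed
    sal <- c(
      stats::runif(n_plume, config$salinity_range[1], 33 - 1e-6),
      stats::runif(n_mixed, 33, 33.75),
      stats::runif(n_scs, 33.75 + 1e-6, config$salinity_range[2])
    )
    sal <- sal[sample.int(n)]
    wm <- classify_water_mass(sal)

    # Gaussian niche response x base abundance x log-normal noise
    resp <- exp(-outer(sal, truth$salinity_optimum, "-")^2 /
                  matrix(2 * truth$niche_breadth^2, n, nrow(truth), byrow = TRUE))
    expected <- sweep(resp, 2, truth$base_abundance, "*") *
      matrix(stats::rlnorm(n * nrow(truth), 0, config$noise_sd), n)
    depth <- round(stats::rlnorm(n, config$depth_meanlog, config$depth_sdlog))
    cells <- t(vapply(seq_len(n), function(s) {
      stats::rmultinom(1, size = depth[s], prob = expected[s, ])[, 1]
    }, numeric(nrow(truth))))
    # reads scale with 16S operon copy number
    counts <- sweep(cells, 2, truth$copy_number, "*")
    dimnames(counts) <- list(sprintf("S%03d", seq_len(n)), truth$taxon_id)

    tot <- rowSums(expected)
    ba <- config$ba_scale * tot / mean(tot)
    rel <- expected / tot
    sbp <- config$coupling * drop(rel %*% truth$productivity_trait) *
      stats::rlnorm(n, 0, config$noise_sd)
    bp <- sbp * ba / 1e6
    cop_frac <- drop(rel %*% (truth$guild == "copiotroph"))
    s_scaled <- (sal - config$salinity_range[1]) / diff(config$salinity_range)
    layer_probs <- rbind(plume = c(0.7, 0.2, 0.1),
                         mixed = c(0.3, 0.4, 0.3),
                         scs = c(0.2, 0.4, 0.4))
    layer <- vapply(as.character(wm), function(w) {
      sample(c("surface", "middle", "bottom"), 1, prob = layer_probs[w, ])
    }, character(1))
    samples <- tibble::tibble(
      sample_id = rownames(counts),
      salinity = sal,
      temperature = 30 - 4.5 * s_scaled + stats::rnorm(n, 0, 0.3),
      chla = 3 * exp(-3 * s_scaled) + 0.05 +
        stats::rlnorm(n, 0, config$noise_sd) * 0.1,
      depth_layer = layer,
      leu_rate = bp / 0.0084,
      bp = bp,
      ba = ba,
      sbp = sbp,
      hna = ba * cop_frac,
      lna = ba * (1 - cop_frac),
      water_mass = wm,
      true_expected_bp = config$coupling *
        drop(rel %*% truth$productivity_trait) * ba / 1e6,
      true_expected_ba = ba
    )
    list(counts = counts, samples = samples)
  })
}

#' Simulate a complete synthetic dataset
#'
#' One master seed deterministically produces the tree, the per-taxon ground
#' truth, the raw counts, the copy-number table and the sample metadata.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return A list (class `sim_dataset`) with `tree`, `truth`, `counts`,
#'   `samples`, `copy_numbers`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  tree <- simulate_tree(config$n_taxa, seed = seed + 101L,
                        depth = config$tree_depth)
  truth <- simulate_traits(tree, config, seed = seed + 202L)
  tree <- scale_guild_divergence(tree, truth, config)
  comm <- simulate_community(tree, truth, config, seed = seed + 303L)
  out <- list(
    tree = tree,
    truth = truth,
    counts = comm$counts,
    samples = comm$samples,
    copy_numbers = stats::setNames(truth$copy_number, truth$taxon_id),
    config = config,
    seed = seed
  )
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic gradient dataset:", nrow(x$counts), "samples x",
      ncol(x$counts), "taxa (seed", x$seed, ")\n")
  print(table(x$samples$water_mass))
  invisible(x)
}

#' Write a synthetic dataset to disk in the package's input formats
#'
#' Emits `counts.tsv` (samples x taxa), `tree.nwk`, `metadata.csv`,
#' `copy_numbers.tsv` and `truth.tsv` under `dir`.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    tree = file.path(dir, "tree.nwk"),
    metadata = file.path(dir, "metadata.csv"),
    copy_numbers = file.path(dir, "copy_numbers.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_count_table(dataset$counts, paths["counts"])
  ape::write.tree(dataset$tree, paths["tree"], digits = 15)
  meta <- dataset$samples[setdiff(names(dataset$samples),
                                  c("true_expected_bp", "true_expected_ba"))]
  readr::write_csv(meta, paths["metadata"])
  readr::write_tsv(
    tibble::tibble(taxon_id = names(dataset$copy_numbers),
                   copies = unname(dataset$copy_numbers)),
    paths["copy_numbers"]
  )
  readr::write_tsv(dataset$truth, paths["truth"])
  invisible(paths)
}

# Guild-linked divergence: copiotroph pendant branches are elongated by a
# constant, and edges fully inside the dominant oligotroph clade are shrunk
# multiplicatively.
scale_guild_divergence <- function(tree, truth, config) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  scale_set <- function(tree_obj, tips, factor) {
    sel <- tree_obj$tip.label %in% tips
    inside <- numeric(n_node)   # selected tips below each node
    below <- numeric(n_node)    # all tips below each node
    inside[seq_len(n_tip)] <- as.numeric(sel)
    below[seq_len(n_tip)] <- 1
    for (i in rev(seq_len(nrow(tree_obj$edge)))) {
      par <- tree_obj$edge[i, 1]; ch <- tree_obj$edge[i, 2]
      inside[par] <- inside[par] + inside[ch]
      below[par] <- below[par] + below[ch]
    }
    pure <- inside[tree_obj$edge[, 2]] == below[tree_obj$edge[, 2]] &
      inside[tree_obj$edge[, 2]] > 0
    tree_obj$edge.length[pure] <- tree_obj$edge.length[pure] * factor
    tree_obj
  }
  cop <- truth$taxon_id[truth$guild == "copiotroph"]
  if (length(cop) > 0) {
    pend <- match(match(cop, tr$tip.label), tr$edge[, 2])
    tr$edge.length[pend] <- tr$edge.length[pend] + config$copiotroph_pendant
  }
  dom <- truth$taxon_id[truth$clade == "dominant_oligo"]
  if (length(dom) > 0) tr <- scale_set(tr, dom, config$dominant_divergence)
  tr
}

#' Small fixture dataset for examples and tests
#'
#' A 30-sample x 60-taxon dataset from the default generator, scaled down.
#'
#' @param seed Master seed.
#' @return A `sim_dataset`.
#' @export
fixture_dataset <- function(seed = 1) {
  simulate_dataset(
    sim_config(n_taxa = 60, n_samples = 30, depth_meanlog = log(2000)),
    seed = seed
  )
}
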