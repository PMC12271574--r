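#' Coerce a counts object to a samples-by-taxa matrix
#'
#' Community data move through the package as plain numeric matrices with
#' samples as rows and taxa as columns (the convention of vegan and picante).
#' User-facing functions also accept a wide data frame or tibble whose first
#' column (or the column named by `id_col`) holds sample identifiers.
#'
#' @param x A numeric matrix (rownames = sample ids, colnames = taxon ids) or
#'   a wide data frame / tibble with one sample-id column and one numeric
#'   column per taxon.
#' @param id_col Name of the sample-id column used when `x` is a data frame.
#' @return A numeric matrix with unique row (sample) and column (taxon) names.
#' @export
as_count_matrix <- function(x, id_col = "sample_id") {
  if (is.matrix(x)) {
    mat <- x
  } else if (is.data.frame(x)) {
    if (!id_col %in% names(x)) {
      # fall back to the first column as the identifier
      id_col <- names(x)[1]
    }
    ids <- as.character(x[[id_col]])
    mat <- as.matrix(x[setdiff(names(x), id_col)])
    rownames(mat) <- ids
  } else {
    abort("`x` must be a matrix or data frame of counts.")
  }
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("count matrix must have sample rownames and taxon colnames.")
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    abort("sample and taxon identifiers must be unique.")
  }
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort("counts must be finite and non-negative.")
  }
  mat
}

#' Convert a counts matrix to a wide tibble
#'
#' @param mat Samples-by-taxa numeric matrix.
#' @param id_col Name for the sample-id column.
#' @return A tibble with one row per sample.
#' @export
counts_to_tibble <- function(mat, id_col = "sample_id") {
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(mat)), out)
  out
}

#' Read a count table from TSV or BIOM
#'
#' The TSV layout is samples as rows and taxa as columns, with a header row
#' and the sample identifier in the first column. BIOM 2.x files are read via
#' the biomformat package (taxa-by-samples, transposed on read).
#'
#' @param path Path to a `.tsv`/`.txt` or `.biom` file.
#' @return A samples-by-taxa numeric matrix.
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the biomformat package.")
    }
    b <- biomformat::read_biom(path)
    mat <- t(as.matrix(biomformat::biom_data(b)))
    return(as_count_matrix(mat))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_count_matrix(df, id_col = names(df)[1])
}

#' Write a count table as TSV
#'
#' @param mat Samples-by-taxa matrix.
#' @param path Output path.
#' @export
write_count_table <- function(mat, path) {
  readr::write_tsv(counts_to_tibble(mat), path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a CSV with at least `sample_id` and `salinity`; recognised columns
#' (`temperature`, `chla`, `depth_layer`, `leu_rate`, `bp`, `ba`, `sbp`,
#' `hna`, `lna`, `water_mass`) are validated and unknown columns pass through
#' untouched. When `water_mass` is absent it is derived from salinity; when
#' `bp`/`sbp` are absent but `leu_rate` (and `ba`) are present they are
#' derived with [derive_productivity()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per sample and a `water_mass` factor.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_sample_table(df)
}

#' Validate and complete a sample metadata table
#'
#' @param df Data frame of per-sample metadata.
#' @return A tibble with derived `water_mass` (and productivity columns when
#'   derivable) added.
#' @export
validate_sample_table <- function(df) {
  df <- tibble::as_tibble(df)
  for (col in c("sample_id", "salinity")) {
    if (!col %in% names(df)) {
      abort(paste0("metadata is missing required column `", col, "`."))
    }
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in metadata.")
  if (any(!is.finite(df$salinity)) || any(df$salinity < 0)) {
    abort("salinity must be finite and non-negative.")
  }
  if (!"bp" %in% names(df) && "leu_rate" %in% names(df)) {
    ba <- if ("ba" %in% names(df)) df$ba else NULL
    prod <- derive_productivity(df$leu_rate, ba)
    df$bp <- prod$bp
    if (!is.null(ba)) df$sbp <- prod$sbp
  }
  if (!"sbp" %in% names(df) && all(c("bp", "ba") %in% names(df))) {
    df$sbp <- derive_productivity(df$bp / 0.0084, df$ba)$sbp
  }
  for (col in c("bp", "ba", "sbp")) {
    if (col %in% names(df) && any(df[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("`", col, "` must be non-negative."))
    }
  }
  if (all(c("bp", "ba", "sbp") %in% names(df))) {
    expect <- 1e6 * df$bp / df$ba
    ok <- is.na(expect) | is.na(df$sbp) |
      abs(df$sbp - expect) <= 1e-6 * pmax(abs(expect), 1)
    if (!all(ok)) abort("sbp is inconsistent with bp / ba.")
  }
  df$water_mass <- classify_water_mass(df$salinity)
  df
}

#' Read a two-column taxon copy-number table
#'
#' @param path TSV with columns `taxon_id` and `copies`.
#' @return A named numeric vector of 16S rRNA operon copy numbers.
#' @export
read_copy_numbers <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  cn <- df[[2]]
  names(cn) <- as.character(df[[1]])
  if (any(!is.finite(cn)) || any(cn <= 0)) {
    abort("copy numbers must be positive.")
  }
  cn
}

#' Read a rooted phylogeny with branch lengths
#'
#' @param path Newick file.
#' @return An `ape::phylo` object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  validate_phylogeny(tree)
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be a `phylo` object.")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree must have branch lengths on every edge.")
  }
  if (any(tree$edge.length < 0)) abort("branch lengths must be non-negative.")
  invisible(tree)
}

#' Correct counts for 16S rRNA operon copy number
#'
#' Each taxon's reads are divided by its operon copy number, then rounded
#' half-up so the table stays integral for rarefaction. Taxa without a copy
#' number fall back to `default_copies` (a no-op at the default of 1) with a
#' warning.
#'
#' @param counts Counts matrix or wide tibble (see [as_count_matrix()]).
#' @param copies Named numeric vector, taxon id -> copy number (> 0).
#' @param default_copies Copy number assumed for taxa missing from `copies`.
#' @return A corrected counts matrix (same dimnames, integer-valued).
#' @export
correct_copy_number <- function(counts, copies, default_copies = 1) {
  mat <- as_count_matrix(counts)
  if (any(!is.finite(copies)) || any(copies <= 0)) {
    abort("copy numbers must be positive.")
  }
  cn <- rep(default_copies, ncol(mat))
  names(cn) <- colnames(mat)
  hit <- intersect(colnames(mat), names(copies))
  cn[hit] <- copies[hit]
  missing <- setdiff(colnames(mat), names(copies))
  if (length(missing) > 0) {
    warn(paste0(length(missing), " taxa without a copy number; assuming ",
                default_copies, "."))
  }
  # round half-up, not banker's rounding
  out <- floor(sweep(mat, 2, cn, "/") + 0.5)
  dimnames(out) <- dimnames(mat)
  out
}

#' Rarefy samples to a common sequencing depth
#'
#' Each sample is subsampled without replacement to `depth` (default: the
#' minimum row sum). A single seed governs all samples; the draw is a
#' deterministic function of the seed.
#'
#' @param counts Counts matrix or wide tibble.
#' @param seed Integer seed.
#' @param depth Target depth; defaults to the minimum sample sum.
#' @return A rarefied counts matrix in which every row sums to `depth`.
#' @export
rarefy_counts <- function(counts, seed, depth = NULL) {
  mat <- as_count_matrix(counts)
  if (nrow(mat) < 1) abort("count table has no samples.")
  sums <- rowSums(mat)
  if (any(sums < 1)) abort("every sample must have at least one read.")
  if (is.null(depth)) depth <- min(sums)
  if (depth < 1) abort("rarefaction depth must be >= 1.")
  if (any(sums < depth)) abort("rarefaction depth exceeds a sample's total.")
  out <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(round(mat), sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  out <- matrix(as.double(out), nrow = nrow(mat), dimnames = dimnames(mat))
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param counts Counts matrix or wide tibble.
#' @return A matrix whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  mat <- as_count_matrix(counts)
  sums <- rowSums(mat)
  if (any(sums <= 0)) abort("every sample must have a positive total.")
  sweep(mat, 1, sums, "/")
}

#' Classify salinities into water masses
#'
#' Plume water is salinity < 33, oceanic (SCS) water is salinity > 33.75 and
#' mixed water lies between; both boundary values fall in the mixed class,
#' matching the strict inequalities that define the outer classes.
#'
#' @param salinity Numeric vector of practical salinities (PSU), >= 0.
#' @return A factor with levels `plume`, `mixed`, `scs`.
#' @export
classify_water_mass <- function(salinity) {
  if (any(!is.finite(salinity))) abort("salinity contains missing values.")
  if (any(salinity < 0)) abort("salinity must be non-negative.")
  out <- ifelse(salinity < 33, "plume", ifelse(salinity > 33.75, "scs", "mixed"))
  factor(out, levels = c("plume", "mixed", "scs"))
}

#' Derive bacterial production from leucine incorporation
#'
#' Leucine incorporation (pmol leucine l^-1 h^-1) is converted to carbon
#' units with the empirical factor 0.35 kg C (mol leucine)^-1 and a linear
#' 24 h day: 1 pmol l^-1 h^-1 equals 0.0084 mg C m^-3 d^-1. Cell-specific
#' production is the ratio of production to abundance, expressed in
#' fg C cell^-1 d^-1.
#'
#' @param leu_rate Leucine incorporation rate, pmol l^-1 h^-1 (>= 0).
#' @param ba Optional bacterial abundance, cells ml^-1 (> 0), required for
#'   cell-specific production.
#' @return A tibble with columns `bp` (mg C m^-3 d^-1) and, when `ba` is
#'   given, `sbp` (fg C cell^-1 d^-1).
#' @export
derive_productivity <- function(leu_rate, ba = NULL) {
  if (any(leu_rate < 0, na.rm = TRUE)) abort("leu_rate must be non-negative.")
  # 1 pmol l-1 h-1 * 24 h * 0.35e-12 kg C/pmol-mol algebra -> 0.0084 mg C m-3 d-1
  bp <- leu_rate * 24 * 0.35e-3
  out <- tibble::tibble(bp = bp)
  if (!is.null(ba)) {
    if (any(ba <= 0, na.rm = TRUE)) {
      abort("bacterial abundance must be positive to derive sbp.")
    }
    # mg C m-3 d-1 -> fg C ml-1 d-1 is a factor 1e6
    out$sbp <- bp * 1e6 / ba
  }
  out
}
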