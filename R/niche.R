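#' Abundance-weighted mean strategy value
#'
#' For each taxon, the mean of a per-sample variable weighted by that taxon's
#' abundance across samples: \eqn{\sum_i w_i v_i / \sum_i w_i}. With salinity
#' as the variable this is the taxon's salinity niche (its optimum along the
#' plume-to-sea gradient); with cell-specific production it is a relative
#' productivity score.
#'
#' @param counts Counts (or abundance) matrix or wide tibble, samples x taxa.
#' @param v Per-sample variable aligned to the rows of `counts`.
#' @return A named numeric vector, one weighted mean per taxon (`NA` for taxa
#'   with zero total abundance).
#' @export
awm_strategy <- function(counts, v) {
  mat <- as_count_matrix(counts)
  if (length(v) != nrow(mat)) abort("`v` must have one value per sample.")
  v <- as.numeric(v)
  bad <- (mat > 0) & (is.na(v) | !is.finite(v))
  if (any(bad)) abort("`v` must be finite wherever abundance is positive.")
  w_tot <- colSums(mat)
  vv <- ifelse(is.finite(v), v, 0)
  out <- colSums(mat * vv) / w_tot
  out[w_tot == 0] <- NA_real_
  out
}

#' Classify taxa as plume, mixed or SCS indicators
#'
#' Applies the water-mass salinity thresholds to each taxon's
#' abundance-weighted mean salinity (niche < 33 is a plume indicator,
#' > 33.75 an SCS indicator, in between mixed). Taxa with an undefined niche
#' are returned as `NA` with a warning.
#'
#' @param awm_salinity Numeric vector of salinity niches (PSU).
#' @return A factor with levels `plume`, `mixed`, `scs`.
#' @export
classify_indicators <- function(awm_salinity) {
  out <- factor(rep(NA_character_, length(awm_salinity)),
                levels = c("plume", "mixed", "scs"))
  ok <- is.finite(awm_salinity)
  if (any(!ok)) warn("taxa with undefined salinity niche left unclassified.")
  out[ok] <- classify_water_mass(awm_salinity[ok])
  names(out) <- names(awm_salinity)
  out
}

#' Per-taxon niche table
#'
#' Computes the abundance-weighted mean salinity (salinity niche) and mean
#' cell-specific production of every taxon, its indicator class, and its mean
#' relative abundance.
#'
#' @param counts Counts matrix or wide tibble (rarefied counts recommended).
#' @param samples Sample metadata with `sample_id`, `salinity` and
#'   (optionally) `sbp`, ordered or keyed to match the rows of `counts`.
#' @return A tibble with `taxon_id`, `awm_salinity`, `awm_sbp`, `indicator`,
#'   `mean_rel_abundance`.
#' @export
niche_table <- function(counts, samples) {
  mat <- as_count_matrix(counts)
  samples <- tibble::as_tibble(samples)
  if (!all(rownames(mat) %in% samples$sample_id)) {
    abort("every sample in `counts` must appear in `samples`.")
  }
  samples <- samples[match(rownames(mat), samples$sample_id), ]
  awm_sal <- awm_strategy(mat, samples$salinity)
  awm_sbp <- if ("sbp" %in% names(samples)) {
    awm_strategy(mat, samples$sbp)
  } else {
    rep(NA_real_, ncol(mat))
  }
  rel <- relative_abundance(mat)
  tibble::tibble(
    taxon_id = colnames(mat),
    awm_salinity = unname(awm_sal),
    awm_sbp = unname(awm_sbp),
    indicator = classify_indicators(unname(awm_sal)),
    mean_rel_abundance = unname(colMeans(rel))
  )
}

#' Pairwise niche overlap between taxa
#'
#' Each taxon's abundance profile across samples is normalized to proportions
#' \eqn{p_{ih}} (\eqn{\sum_h p_{ih} = 1}). The default Levins index,
#' \eqn{O_{ij} = \sum_h p_{ih} p_{jh} / \sum_h p_{ih}^2}, is asymmetric; the
#' returned matrix symmetrizes each pair by averaging the two directions.
#' Pianka and Schoener indices (both symmetric) are available as
#' alternatives.
#'
#' @param counts Counts or abundance matrix, samples x taxa.
#' @param method One of `"levins"`, `"pianka"`, `"schoener"`.
#' @param symmetrize For Levins: return the mean of the two directions
#'   (default) instead of the asymmetric matrix.
#' @return A taxa-by-taxa overlap matrix (diagonal 1 for taxa with positive
#'   total abundance).
#' @export
niche_overlap <- function(counts, method = c("levins", "pianka", "schoener"),
                          symmetrize = TRUE) {
  method <- match.arg(method)
  mat <- as_count_matrix(counts)
  tot <- colSums(mat)
  if (any(tot <= 0)) abort("taxa with zero total abundance have no niche.")
  p <- sweep(mat, 2, tot, "/") # samples x taxa, columns sum to 1
  cross <- crossprod(p) # sum_h p_ih p_jh
  self <- diag(cross) # sum_h p_ih^2
  out <- switch(method,
    levins = {
      o <- cross / self # O_ij = cross_ij / self_i, rows = i
      if (symmetrize) (o + t(o)) / 2 else o
    },
    pianka = cross / sqrt(outer(self, self)),
    schoener = {
      n <- ncol(p)
      o <- matrix(1, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          o[i, j] <- o[j, i] <- 1 - 0.5 * sum(abs(p[, i] - p[, j]))
        }
      }
      o
    }
  )
  dimnames(out) <- list(colnames(mat), colnames(mat))
  out
}

#' Pairwise niche differences between taxa
#'
#' Absolute difference in abundance-weighted mean salinity between every pair
#' of taxa: a pseudometric on the salinity gradient (PSU).
#'
#' @param awm_salinity Named numeric vector of salinity niches, or a niche
#'   table from [niche_table()].
#' @return A symmetric taxa-by-taxa matrix with zero diagonal; taxa with an
#'   undefined niche are dropped.
#' @export
niche_difference <- function(awm_salinity) {
  if (is.data.frame(awm_salinity)) {
    awm_salinity <- stats::setNames(awm_salinity$awm_salinity,
                                    awm_salinity$taxon_id)
  }
  x <- awm_salinity[is.finite(awm_salinity)]
  out <- abs(outer(x, x, "-"))
  dimnames(out) <- list(names(x), names(x))
  out
}

#' Long-format view of a pairwise taxon matrix
#'
#' @param mat Square taxa-by-taxa matrix (overlap or difference).
#' @param value Name of the value column.
#' @return A tibble with `taxon_i`, `taxon_j` (unordered pairs, i < j) and
#'   the value.
#' @export
pair_matrix_tidy <- function(mat, value = "value") {
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  tibble::tibble(
    taxon_i = rownames(mat)[idx[, 1]],
    taxon_j = colnames(mat)[idx[, 2]],
    !!value := mat[idx]
  )
}
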