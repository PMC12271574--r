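#' Kruskal-Wallis test with BH-corrected pairwise follow-up
#'
#' Omnibus Kruskal-Wallis H (tie-corrected) across groups, pairwise
#' rank-sum (Wilcoxon) follow-up tests with Benjamini-Hochberg correction
#' across the pairs, and a compact letter display in which groups sharing a
#' letter are not significantly different at adjusted p >= `alpha`.
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Factor (or coercible) of group labels, e.g. water masses.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `kw_test`: list with `statistic` (H), `df`,
#'   `p_value`, `pairwise` (tibble: `group_1`, `group_2`, `p`, `p_adj`),
#'   `letters` (named character), and `group_summary` (tibble with n, mean,
#'   sd, letter per group).
#' @export
kruskal_wallis_bh <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("excluding groups with < 2 observations: ",
                paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) abort("need at least 2 groups with >= 2 values.")
  if (stats::sd(values) == 0) {
    # all observations tied: no evidence of any difference
    kw <- list(statistic = 0, parameter = nlevels(groups) - 1, p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
  }
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (stats::sd(c(x, y)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  pairwise <- tibble::tibble(
    group_1 = pairs[1, ], group_2 = pairs[2, ],
    p = p_raw, p_adj = p_adj
  )
  letters <- compact_letters(lev, pairwise, alpha = alpha)
  group_summary <- tibble::tibble(
    group = lev,
    n = as.integer(table(groups)[lev]),
    mean = as.numeric(tapply(values, groups, mean)[lev]),
    sd = as.numeric(tapply(values, groups, stats::sd)[lev]),
    letter = unname(letters[lev])
  )
  out <- list(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    pairwise = pairwise,
    letters = letters,
    group_summary = group_summary,
    alpha = alpha
  )
  class(out) <- "kw_test"
  out
}

# Compact letter display via greedy clique cover of the
# "not significantly different" graph. Groups are processed in order of
# decreasing mean rank is not needed here; level order keeps it
# deterministic.
compact_letters <- function(lev, pairwise, alpha = 0.05) {
  k <- length(lev)
  same <- matrix(TRUE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(pairwise))) {
    if (!is.na(pairwise$p_adj[i]) && pairwise$p_adj[i] < alpha) {
      same[pairwise$group_1[i], pairwise$group_2[i]] <- FALSE
      same[pairwise$group_2[i], pairwise$group_1[i]] <- FALSE
    }
  }
  cliques <- list()
  for (g in lev) {
    placed <- FALSE
    for (ci in seq_along(cliques)) {
      if (all(same[g, cliques[[ci]]])) {
        cliques[[ci]] <- c(cliques[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1]] <- g
  }
  out <- stats::setNames(character(k), lev)
  for (ci in seq_along(cliques)) {
    for (g in cliques[[ci]]) {
      out[g] <- paste0(out[g], letters[ci])
    }
  }
  out
}

#' @export
print.kw_test <- function(x, ...) {
  cat("Kruskal-Wallis: H =", signif(x$statistic, 4), ", df =", x$df,
      ", p =", signif(x$p_value, 3), "\n")
  print(x$group_summary, ...)
  invisible(x)
}

#' @rdname kruskal_wallis_bh
#' @param x A `kw_test` object.
#' @param ... Unused.
#' @export
tidy.kw_test <- function(x, ...) x$pairwise

#' @rdname kruskal_wallis_bh
#' @export
glance.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Compare variables across water masses
#'
#' Runs [kruskal_wallis_bh()] for each named variable of a per-sample table
#' against its `water_mass` column and returns a compact summary table
#' (group mean, sd and letter per variable).
#'
#' @param data Per-sample tibble with a `water_mass` column.
#' @param vars Character vector of numeric columns to test.
#' @param group Name of the grouping column (default `water_mass`).
#' @return A tibble with one row per variable and group.
#' @export
compare_water_masses <- function(data, vars, group = "water_mass") {
  data <- tibble::as_tibble(data)
  if (!group %in% names(data)) {
    abort(paste0("metadata is missing required column `", group, "`."))
  }
  purrr::map_dfr(vars, function(v) {
    kw <- tryCatch(kruskal_wallis_bh(data[[v]], data[[group]]),
                   error = function(e) NULL)
    if (is.null(kw)) {
      warn(paste0("`", v, "`: too few complete observations to test."))
      return(tibble::tibble(variable = v, H = NA_real_, p_value = NA_real_,
                            group = NA_character_, n = NA_integer_,
                            mean = NA_real_, sd = NA_real_,
                            letter = NA_character_))
    }
    dplyr::mutate(kw$group_summary, variable = v,
                  H = kw$statistic, p_value = kw$p_value,
                  .before = 1)
  })
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("need at least 3 paired finite observations.")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warn("zero variance; correlation undefined.")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Hierarchical partitioning of explained variance
#'
#' Decomposes the full-model least-squares R-squared of a response on
#' groups of predictors into one independent effect per group: the average,
#' over all orderings of the groups, of the group's incremental R-squared.
#' The independent effects sum exactly to the full-model R-squared.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame / tibble of predictor columns.
#' @param groups Optional named list mapping group names to character
#'   vectors of predictor columns; defaults to one group per predictor.
#' @return An object of class `hier_part`: list with `effects` (tibble
#'   `group`, `independent_effect`), `total_r2` and `n_groups`.
#' @export
hierarchical_partitioning <- function(response, predictors, groups = NULL) {
  predictors <- as.data.frame(predictors)
  if (is.null(groups)) {
    groups <- as.list(stats::setNames(names(predictors), names(predictors)))
  }
  k <- length(groups)
  if (k > 10) abort("at most 10 predictor groups (2^k subset enumeration).")
  if (nrow(predictors) <= length(unlist(groups))) {
    abort("need more observations than predictors.")
  }
  x_full <- as.matrix(predictors[unique(unlist(groups))])
  qr_full <- qr(cbind(1, x_full))
  if (qr_full$rank < ncol(x_full) + 1) {
    warn("rank-deficient full model; collinear columns dropped by lm.")
  }
  r2 <- function(vars) {
    if (length(vars) == 0) return(0)
    fit <- stats::lm.fit(cbind(1, as.matrix(predictors[vars])), response)
    res <- fit$residuals
    1 - sum(res^2) / sum((response - mean(response))^2)
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  subset_r2 <- apply(subsets, 1, function(inc) {
    r2(unique(unlist(groups[inc])))
  })
  key <- apply(subsets, 1, function(inc) {
    paste0("k", paste(which(inc), collapse = ","))
  })
  names(subset_r2) <- key
  effects <- vapply(seq_len(k), function(g) {
    others <- setdiff(seq_len(k), g)
    total <- 0
    for (m in 0:length(others)) {
      combos <- if (m == 0) {
        list(integer(0))
      } else if (length(others) == 1) {
        list(others) # combn(n, m) would expand a scalar to 1:n
      } else {
        utils::combn(others, m, simplify = FALSE)
      }
      w <- factorial(m) * factorial(k - m - 1) / factorial(k)
      for (s in combos) {
        with_g <- subset_r2[[paste0("k", paste(sort(c(s, g)), collapse = ","))]]
        without <- subset_r2[[paste0("k", paste(sort(s), collapse = ","))]]
        total <- total + w * (with_g - without)
      }
    }
    total
  }, numeric(1))
  out <- list(
    effects = tibble::tibble(
      group = names(groups),
      independent_effect = unname(effects)
    ),
    total_r2 = r2(unique(unlist(groups))),
    n_groups = k
  )
  class(out) <- "hier_part"
  out
}

#' @export
print.hier_part <- function(x, ...) {
  cat("Hierarchical partitioning over", x$n_groups,
      "groups; total R2 =", signif(x$total_r2, 4), "\n")
  print(x$effects, ...)
  invisible(x)
}

#' @rdname hierarchical_partitioning
#' @param x A `hier_part` object.
#' @param ... Unused.
#' @export
tidy.hier_part <- function(x, ...) x$effects

#' @rdname hierarchical_partitioning
#' @export
glance.hier_part <- function(x, ...) {
  tibble::tibble(total_r2 = x$total_r2, n_groups = x$n_groups)
}
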