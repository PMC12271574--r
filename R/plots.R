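#' Boxplots of diversity and productivity across water masses
#'
#' @param diversity Per-sample tibble with a `water_mass` column (e.g. the
#'   `diversity` table of a pipeline bundle).
#' @param vars Variables to facet (defaults to the available diversity and
#'   productivity columns).
#' @return A ggplot.
#' @export
plot_water_mass_boxes <- function(diversity,
                                  vars = intersect(
                                    c("bp", "ba", "sbp", "richness", "shannon",
                                      "mpd", "ses_mpd"),
                                    names(diversity))) {
  long <- tidyr::pivot_longer(diversity[c("water_mass", vars)],
                              dplyr::all_of(vars))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$water_mass, y = .data$value,
                                     fill = .data$water_mass)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "water mass", y = NULL) +
    ggplot2::theme_minimal()
}

#' Diversity-productivity scatter
#'
#' Scatter of bacterial production against a diversity metric with a linear
#' trend, colored by water mass.
#'
#' @param diversity Per-sample tibble with `bp`, `water_mass` and the metric.
#' @param metric Diversity column (default `"mpd"`).
#' @return A ggplot.
#' @export
plot_dpr <- function(diversity, metric = "mpd") {
  ggplot2::ggplot(diversity, ggplot2::aes(x = .data[[metric]], y = .data$bp)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$water_mass)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "grey30") +
    ggplot2::labs(x = metric, y = "bacterial production (mg C m⁻³ d⁻¹)") +
    ggplot2::theme_minimal()
}

#' @rdname ses_mpd
#' @param object A `ses_mpd` object.
#' @export
autoplot.ses_mpd <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$mpd, y = .data$ses_mpd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "abundance-weighted MPD",
                  y = expression(SES[MPD])) +
    ggplot2::theme_minimal()
}

#' @rdname build_metanetwork
#' @param object A `metanetwork` object.
#' @export
autoplot.metanetwork <- function(object, ...) {
  g <- object$graph
  keep <- igraph::V(g)[igraph::degree(g) > 0]
  g <- igraph::induced_subgraph(g, keep)
  lay <- igraph::layout_with_fr(g, niter = 200)
  edges <- igraph::as_data_frame(g, what = "edges")
  verts <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  edges <- dplyr::left_join(edges, verts, by = c("from" = "name"))
  edges <- dplyr::left_join(edges, verts, by = c("to" = "name"),
                            suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$sign),
      linewidth = 0.3, alpha = 0.7
    ) +
    ggplot2::geom_point(data = verts,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 1) +
    ggplot2::scale_color_manual(values = c("+" = "#2166ac", "-" = "#b2182b")) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "edge sign")
}

#' Per-bin niche structure against phylogenetic distance
#'
#' Scatter of mean niche overlap and mean niche difference against the mean
#' pairwise phylogenetic distance of each bin.
#'
#' @param bin_stats Tibble from [bin_statistics()].
#' @return A ggplot.
#' @export
plot_bin_niche <- function(bin_stats) {
  long <- tidyr::pivot_longer(
    bin_stats[c("mean_pd", "mean_overlap", "mean_niche_difference")],
    c("mean_overlap", "mean_niche_difference")
  )
  long <- long[is.finite(long$value) & is.finite(long$mean_pd), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_pd, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "mean within-bin phylogenetic distance", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname hierarchical_partitioning
#' @param object A `hier_part` object.
#' @export
autoplot.hier_part <- function(object, ...) {
  ggplot2::ggplot(object$effects,
                  ggplot2::aes(x = .data$group,
                               y = .data$independent_effect)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = NULL, y = expression("independent effect (" * R^2 * ")")) +
    ggplot2::theme_minimal()
}
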