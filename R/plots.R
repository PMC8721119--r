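#' Plot a contact map as a dot matrix
#'
#' Renders persistent contacts as dots over residue indices, the conventional
#' way contact maps are displayed.
#'
#' @param object A [contact_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  keys <- rownames(object$probability)
  df <- tidy(object)
  df$i <- match(df$res_i, keys)
  df$j <- match(df$res_j, keys)
  pts <- dplyr::filter(df, .data$contact)
  pts <- dplyr::bind_rows(pts, dplyr::rename(pts, i = "j", j = "i"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "residue index", y = "residue index",
      title = sprintf("Persistent contacts (< %.1f Å in ≥ %.0f%% of frames)",
                      object$cutoff, 100 * object$occupancy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a single-subunit consensus contact map
#'
#' @param object A [subunit_consensus()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_map <- function(object, ...) {
  df <- tidy(object)
  pts <- dplyr::filter(df, .data$consensus)
  pts <- dplyr::bind_rows(
    pts, dplyr::rename(pts, resno_i = "resno_j", resno_j = "resno_i")
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$resno_i, y = .data$resno_j)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "residue", y = "residue",
      title = sprintf("Consensus contacts (≥ %d of %d subunits)",
                      object$min_subunits, object$n_subunits)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-subunit path lengths of an analysis
#'
#' @param object An `analysis_bundle`.
#' @param ... Unused.
#' @return A ggplot object showing each subunit's path length by family, with
#'   the family mean marked.
#' @export
autoplot.analysis_bundle <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$family, y = .data$length)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$subunit), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(
      x = "pathway family", y = "path length (-ln |Corr| sum)",
      title = sprintf("Per-subunit shortest path lengths: %s", object$label)
    ) +
    ggplot2::theme_minimal()
}

#' Plot residue centrality with betweenness bands
#'
#' @param bundle An `analysis_bundle`.
#' @return A ggplot lollipop chart of the per-residue centrality index,
#'   coloured by betweenness band, restricted to residues on at least one
#'   near-optimal path.
#' @export
plot_centrality <- function(bundle) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  tab <- dplyr::filter(bundle$centrality, .data$ci > 0)
  tab$band <- factor(tab$band, levels = c("low", "medium", "high"))
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$residue), y = .data$ci)) +
    ggplot2::geom_segment(ggplot2::aes(xend = factor(.data$residue), yend = 0),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 2) +
    ggplot2::labs(x = "residue", y = "centrality index",
                  colour = "betweenness",
                  title = sprintf("Pathway residue centrality: %s", bundle$label)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
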