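#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a correlation matrix into residue pairs
#'
#' @param x A [correlation_matrix()].
#' @param ... Unused.
#' @return A tibble with `res_i`, `res_j` (upper triangle), `corr` and the
#'   corresponding [edge_weight()].
#' @export
tidy.correlation_matrix <- function(x, ...) {
  keys <- rownames(x)
  sel <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    res_i = keys[sel[, 1L]],
    res_j = keys[sel[, 2L]],
    corr = x[sel],
    weight = edge_weight(x[sel])
  )
}

#' Tidy a contact map into residue pairs
#'
#' @param x A [contact_map()].
#' @param ... Unused.
#' @return A tibble with `res_i`, `res_j`, `probability` and `contact`.
#' @export
tidy.contact_map <- function(x, ...) {
  keys <- rownames(x$probability)
  sel <- which(upper.tri(x$probability), arr.ind = TRUE)
  tibble::tibble(
    res_i = keys[sel[, 1L]],
    res_j = keys[sel[, 2L]],
    probability = x$probability[sel],
    contact = x$contact[sel]
  )
}

#' Tidy a consensus map into position pairs
#'
#' @param x A [subunit_consensus()] result.
#' @param ... Unused.
#' @return A tibble with `resno_i`, `resno_j`, the number of subunits forming
#'   the contact, and the consensus flag.
#' @export
tidy.consensus_map <- function(x, ...) {
  sel <- which(upper.tri(x$counts), arr.ind = TRUE)
  tibble::tibble(
    resno_i = x$resno[sel[, 1L]],
    resno_j = x$resno[sel[, 2L]],
    n_subunits = as.integer(x$counts[sel]),
    consensus = x$consensus[sel]
  )
}

#' Tidy a dynamical network into its edge list
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return The edge tibble (`res_i`, `res_j`, `corr`, `weight`).
#' @export
tidy.dynamic_network <- function(x, ...) x$edges

#' One-row network summary
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return A tibble with node/edge counts and weight range.
#' @export
glance.dynamic_network <- function(x, ...) {
  tibble::tibble(
    n_residues = length(x$residues),
    n_edges = nrow(x$edges),
    min_weight = if (nrow(x$edges)) min(x$edges$weight) else NA_real_,
    max_weight = if (nrow(x$edges)) max(x$edges$weight) else NA_real_,
    contact_cutoff = x$settings$cutoff,
    contact_occupancy = x$settings$occupancy
  )
}

#' Tidy a path result
#'
#' @param x A [shortest_path()] result.
#' @param ... Unused.
#' @return A tibble with one row per path step (`residue`, `step_weight`,
#'   `cumulative_length`).
#' @export
tidy.path_result <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    subunit = x$subunit,
    step = seq_along(x$residues),
    residue = x$residues,
    step_weight = c(NA_real_, x$weights),
    cumulative_length = cumsum(c(0, x$weights))
  )
}

#' Tidy an analysis bundle into its per-subunit path table
#'
#' @param x An `analysis_bundle` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with one row per family and subunit: anchors, total
#'   `length`, residue count and the ordered residue keys (list-column).
#' @export
tidy.analysis_bundle <- function(x, ...) x$path_table

#' One-row summary of an analysis bundle
#'
#' @param x An `analysis_bundle`.
#' @param ... Unused.
#' @return A tibble with the run label, sizes, and the mean path length per
#'   family (`vsd_sf_length`, `pd_sf_length`).
#' @export
glance.analysis_bundle <- function(x, ...) {
  fl <- stats::setNames(x$family_lengths$mean_length, x$family_lengths$family)
  tibble::tibble(
    label = x$label,
    analytic = x$analytic,
    n_residues = length(x$network$residues),
    n_edges = nrow(x$network$edges),
    n_paths = nrow(x$path_table),
    vsd_sf_length = unname(fl["VSD-SF"]),
    pd_sf_length = unname(fl["PD-SF"])
  )
}
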