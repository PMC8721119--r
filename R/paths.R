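#' Minimum-weight path between a source and a sink region
#'
#' Runs Dijkstra's algorithm over all source-member x sink-member pairs and
#' returns the overall minimum-total-weight path.  Ties are broken
#' deterministically in favour of the lexicographically smallest residue-key
#' sequence.  If the two regions share a residue the result is a zero-length
#' single-node path.
#'
#' @param net A [build_network()] result.
#' @param source,sink [define_region()] objects or character vectors of
#'   residue keys.
#' @param family Optional label, conventionally `"VSD-SF"` or `"PD-SF"`.
#' @param subunit Optional subunit label for bookkeeping.
#' @return An object of class `path_result`: ordered `residues`, per-edge
#'   `weights`, total `length`, `family`, `subunit`.
#' @export
shortest_path <- function(net, source, sink, family = NA_character_,
                          subunit = NA_character_) {
  stopifnot(inherits(net, "dynamic_network"))
  src <- check_members(net, region_members(source), "source")
  snk <- check_members(net, region_members(sink), "sink")
  common <- intersect(src, snk)
  if (length(common) > 0L) {
    node <- sort(common)[1L]
    return(new_path_result(node, numeric(0L), family, subunit,
                           region_anchor(source), region_anchor(sink)))
  }
  g <- net$graph
  d <- igraph::distances(g, v = src, to = snk, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  if (all(is.infinite(d))) {
    comp <- igraph::components(g)$membership
    abort_allopath(
      paste0(
        "No path connects the source and sink regions. ",
        "Source components: {", paste(unique(comp[src]), collapse = ","), "}; ",
        "sink components: {", paste(unique(comp[snk]), collapse = ","), "}."
      ),
      "disconnection_error"
    )
  }
  best <- which(d == min(d), arr.ind = TRUE)
  candidates <- list()
  for (r in seq_len(nrow(best))) {
    asp <- igraph::all_shortest_paths(
      g, from = src[best[r, 1L]], to = snk[best[r, 2L]],
      weights = igraph::E(g)$weight
    )
    candidates <- c(candidates, lapply(asp$vpaths, names))
  }
  residues <- lex_min_path(candidates)
  w <- path_edge_weights(g, residues)
  new_path_result(residues, w, family, subunit,
                  region_anchor(source), region_anchor(sink))
}

check_members <- function(net, members, what) {
  missing <- setdiff(members, net$residues)
  if (length(missing) > 0L) {
    abort_allopath(
      paste0("Unknown ", what, " residue(s): ", paste(missing, collapse = ", ")),
      "lookup_error"
    )
  }
  if (length(members) == 0L) {
    abort_allopath(paste0("The ", what, " region has no members."), "argument_error")
  }
  members
}

region_anchor <- function(x) if (inherits(x, "region")) x$anchor else NA_character_

path_edge_weights <- function(g, residues) {
  if (length(residues) < 2L) return(numeric(0L))
  igraph::E(g, path = residues)$weight
}

new_path_result <- function(residues, weights, family, subunit,
                            source_anchor = NA_character_, sink_anchor = NA_character_) {
  structure(
    list(
      residues = residues,
      weights = weights,
      length = sum(weights),
      family = family,
      subunit = subunit,
      source_anchor = source_anchor,
      sink_anchor = sink_anchor
    ),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf(
    "<path_result> %s%slength %.4f: %s\n",
    if (is.na(x$family)) "" else paste0(x$family, ", "),
    if (is.na(x$subunit)) "" else paste0("subunit ", x$subunit, ", "),
    x$length, paste(x$residues, collapse = " - ")
  ))
  invisible(x)
}

#' Average path length over subunits
#'
#' Arithmetic mean of total path lengths, typically one path per subunit of
#' the same family.
#'
#' @param paths A list of [shortest_path()] results sharing a family tag.
#' @return The mean total length.
#' @export
average_path_length <- function(paths) {
  if (!is.list(paths) || length(paths) == 0L ||
      !all(vapply(paths, inherits, logical(1L), "path_result"))) {
    abort_allopath("`paths` must be a non-empty list of path results.", "argument_error")
  }
  fams <- unique(vapply(paths, function(p) p$family, character(1L)))
  if (length(fams) > 1L) {
    abort_allopath(
      paste0("Paths mix families: ", paste(fams, collapse = ", ")),
      "argument_error"
    )
  }
  mean(vapply(paths, function(p) p$length, numeric(1L)))
}

#' Source/sink-restricted betweenness
#'
#' For every node v, sums over all source-member s and sink-member t pairs the
#' fraction \eqn{\sigma_{st}(v)/\sigma_{st}} of minimum-weight s-t paths
#' passing through v (endpoints excluded), accumulated over all supplied
#' region pairs (typically one source/sink pair per subunit and family).
#' Disconnected pairs contribute zero.  Unlike all-pairs betweenness, this
#' restriction keeps values on the small scale on which the low/medium/high
#' bands are defined.
#'
#' @param net A [build_network()] result.
#' @param sources,sinks Regions (or key vectors), or lists of them paired by
#'   index.
#' @return A tibble with `residue` and `betweenness` for every network node.
#' @export
path_betweenness <- function(net, sources, sinks) {
  stopifnot(inherits(net, "dynamic_network"))
  pairs <- pair_regions(sources, sinks)
  g <- net$graph
  wts <- igraph::E(g)$weight
  b <- stats::setNames(rep(0, length(net$residues)), net$residues)
  for (pr in pairs) {
    src <- check_members(net, region_members(pr$source), "source")
    snk <- check_members(net, region_members(pr$sink), "sink")
    for (s in src) {
      for (t in setdiff(snk, s)) {
        asp <- tryCatch(
          igraph::all_shortest_paths(g, from = s, to = t, weights = wts),
          error = function(e) NULL
        )
        if (is.null(asp) || length(asp$vpaths) == 0L) next
        sigma <- length(asp$vpaths)
        interior <- unlist(lapply(asp$vpaths, function(p) names(p)[-c(1L, length(p))]))
        if (length(interior) > 0L) {
          tab <- table(interior)
          b[names(tab)] <- b[names(tab)] + as.numeric(tab) / sigma
        }
      }
    }
  }
  tibble::tibble(residue = names(b), betweenness = unname(b))
}

pair_regions <- function(sources, sinks) {
  to_list <- function(x) {
    if (inherits(x, "region") || is.character(x)) list(x) else x
  }
  sources <- to_list(sources)
  sinks <- to_list(sinks)
  if (length(sources) != length(sinks)) {
    abort_allopath("`sources` and `sinks` must pair up one-to-one.", "argument_error")
  }
  purrr::map2(sources, sinks, function(s, t) list(source = s, sink = t))
}

#' Enumerate near-optimal source-sink paths
#'
#' Uses Yen's k-shortest-paths algorithm (through an auxiliary zero-weight
#' super-source and super-sink joined to the region members) to list all
#' simple paths whose total weight is within `epsilon` of the region-to-region
#' optimum, capped at `k_max` enumerated paths.
#'
#' @param net A [build_network()] result.
#' @param source,sink Regions or residue-key vectors.
#' @param epsilon Length slack above the optimum (default 1.0).
#' @param k_max Enumeration cap (default 200); if the cap is hit before the
#'   length bound, a warning is raised and the computed set is used.
#' @return A tibble with `path_id`, `length` and a `residues` list-column.
#' @export
suboptimal_paths <- function(net, source, sink, epsilon = 1.0, k_max = 200L) {
  stopifnot(inherits(net, "dynamic_network"))
  assert_scalar_number(epsilon, "epsilon", min = 0)
  k_max <- as.integer(assert_scalar_number(k_max, "k_max", min = 1))
  src <- check_members(net, region_members(source), "source")
  snk <- check_members(net, region_members(sink), "sink")
  g <- net$graph
  g2 <- igraph::add_vertices(g, 2L, name = c("..source..", "..sink.."))
  aux <- c(rbind("..source..", src), rbind(snk, "..sink.."))
  g2 <- igraph::add_edges(g2, aux, weight = 0)
  ksp <- tryCatch(
    igraph::k_shortest_paths(g2, from = "..source..", to = "..sink..",
                             k = k_max, weights = igraph::E(g2)$weight),
    error = function(e) NULL
  )
  if (is.null(ksp) || length(ksp$epaths) == 0L) {
    abort_allopath("No path connects the source and sink regions.", "disconnection_error")
  }
  lens <- vapply(ksp$epaths, function(e) sum(e$weight), numeric(1L))
  keep <- lens <= lens[1L] + epsilon + 1e-9
  if (all(keep) && length(lens) == k_max) {
    rlang::warn(sprintf(
      "k_max = %d exhausted before the length bound; centrality computed on the enumerated set.",
      k_max
    ))
  }
  paths <- lapply(ksp$vpaths[keep], function(p) setdiff(names(p), c("..source..", "..sink..")))
  tibble::tibble(
    path_id = seq_along(paths),
    length = lens[keep],
    residues = paths
  )
}

#' Centrality index from near-optimal paths
#'
#' The centrality index of a residue is the fraction of near-optimal
#' source-sink paths (total length within `epsilon` of the optimum, see
#' [suboptimal_paths()]) that contain it, pooled over the supplied region
#' pairs.  Values lie in \[0, 1\]; residues on every near-optimal route score
#' 1.
#'
#' @inheritParams path_betweenness
#' @inheritParams suboptimal_paths
#' @return A tibble with `residue`, `ci` and the pooled path count `n_paths`.
#' @export
centrality_index <- function(net, sources, sinks, epsilon = 1.0, k_max = 200L) {
  stopifnot(inherits(net, "dynamic_network"))
  pairs <- pair_regions(sources, sinks)
  pooled <- purrr::map(pairs, function(pr) {
    suboptimal_paths(net, pr$source, pr$sink, epsilon = epsilon, k_max = k_max)$residues
  })
  pooled <- purrr::flatten(pooled)
  n <- length(pooled)
  counts <- table(factor(unlist(pooled), levels = net$residues))
  tibble::tibble(
    residue = net$residues,
    ci = as.numeric(counts) / n,
    n_paths = n
  )
}

#' Band a betweenness value
#'
#' Classifies betweenness into the reporting bands low (0 <= B <= 1), medium
#' (1 < B <= 4) and high (4 < B <= B_max).  Zero betweenness is reported as
#' low; the logical attribute `"zero"` flags such residues.
#'
#' @param b Betweenness value(s), non-negative.
#' @param b_max Maximum observed betweenness; values above it are an error.
#' @return Character vector in `c("low", "medium", "high")` with attribute
#'   `"zero"`.
#' @export
band_betweenness <- function(b, b_max) {
  assert_scalar_number(b_max, "b_max", min = 0)
  if (!is.numeric(b) || any(b < 0) || any(b > b_max + 1e-9)) {
    abort_allopath("Betweenness values must lie in [0, b_max].", "argument_error")
  }
  band <- ifelse(b <= 1, "low", ifelse(b <= 4, "medium", "high"))
  attr(band, "zero") <- b == 0
  band
}
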