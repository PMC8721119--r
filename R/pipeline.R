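#' Analysis configuration
#'
#' Collects and validates every tunable of the pathway analysis.  Defaults
#' follow the standard protocol: 5.0 A side-chain contact cutoff with 75%
#' occupancy, 6.0 A region spheres with 75% occupancy, superposition on.  The
#' three region anchors have no defaults - they are system-specific choices
#' (for Kv1.2, the S4 and S6 anchors are typically taken among the
#' high-centrality residues, e.g. I304 and I402, with Y377 anchoring the
#' selectivity-filter sink) - and must be supplied as residue numbers shared
#' by all chains.
#'
#' @param anchors Named list with integer residue numbers `s4` (sensor source),
#'   `s6` (pore source) and `sf` (filter sink).
#' @param chains Named character vector, chain id -> subunit label.
#' @param neighbor Named character vector, subunit -> neighboring subunit whose
#'   pore the sensor contacts.
#' @param superpose Superpose frames before correlation (default TRUE).
#' @param stride Frame stride on input (default 1).
#' @param contact_cutoff,contact_occupancy Persistent-contact rule (5.0 A,
#'   0.75).
#' @param region_radius,region_occupancy Region sphere rule (6.0 A, 0.75).
#' @param ci_epsilon,ci_k_max Near-optimal path slack and enumeration cap for
#'   the centrality index.
#' @param label Run label used in reports (default "run").
#' @param out_dir Optional output directory for [write_bundle()].
#' @param seed Optional seed recorded in the resolved config.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(anchors, chains, neighbor,
                            superpose = TRUE, stride = 1L,
                            contact_cutoff = 5.0, contact_occupancy = 0.75,
                            region_radius = 6.0, region_occupancy = 0.75,
                            ci_epsilon = 1.0, ci_k_max = 200L,
                            label = "run", out_dir = NULL, seed = NULL) {
  known <- names(formals(analysis_config))
  if (!is.list(anchors) || !all(c("s4", "s6", "sf") %in% names(anchors))) {
    abort_allopath(
      "`anchors` must name the s4, s6 and sf anchor residue numbers (no defaults exist).",
      "config_error"
    )
  }
  unknown <- setdiff(names(anchors), c("s4", "s6", "sf"))
  if (length(unknown) > 0L) {
    abort_allopath(
      paste0("Unknown anchor field(s): ", paste(unknown, collapse = ", ")),
      "config_error"
    )
  }
  for (a in c("s4", "s6", "sf")) assert_scalar_number(anchors[[a]], paste0("anchors$", a))
  smap <- subunit_map(chains, neighbor)
  assert_scalar_number(stride, "stride", min = 1)
  assert_scalar_number(contact_cutoff, "contact_cutoff", min = 1e-8)
  assert_scalar_number(contact_occupancy, "contact_occupancy", min = 0, max = 1)
  assert_scalar_number(region_radius, "region_radius", min = 1e-8)
  assert_scalar_number(region_occupancy, "region_occupancy", min = 0, max = 1)
  assert_scalar_number(ci_epsilon, "ci_epsilon", min = 0)
  assert_scalar_number(ci_k_max, "ci_k_max", min = 1)
  structure(
    list(
      anchors = lapply(anchors, as.integer),
      chains = chains, neighbor = neighbor,
      superpose = isTRUE(superpose), stride = as.integer(stride),
      contact_cutoff = contact_cutoff, contact_occupancy = contact_occupancy,
      region_radius = region_radius, region_occupancy = region_occupancy,
      ci_epsilon = ci_epsilon, ci_k_max = as.integer(ci_k_max),
      label = as.character(label), out_dir = out_dir,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Strict: unknown keys are errors, not warnings.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    abort_allopath(sprintf("Config file not found: %s", path), "config_error")
  }
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(analysis_config)), "")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort_allopath(
      paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
      "config_error"
    )
  }
  if (!is.null(vals$chains)) vals$chains <- unlist(vals$chains)
  if (!is.null(vals$neighbor)) vals$neighbor <- unlist(vals$neighbor)
  do.call(analysis_config, vals)
}

#' Default configuration for the toy tetramer
#'
#' Convenience wrapper building an [analysis_config()] from the anchors and
#' subunit maps stored on a [build_toy_tetramer()] topology.
#'
#' @param topo A bead topology.
#' @param ... Overrides passed to [analysis_config()].
#' @return An `analysis_config`.
#' @export
toy_analysis_config <- function(topo, ...) {
  stopifnot(inherits(topo, "bead_topology"))
  args <- list(
    anchors = topo$anchors,
    chains = topo$chains,
    neighbor = topo$neighbor
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(analysis_config, args)
}

#' Run the full pathway analysis
#'
#' Executes the whole workflow: superposition, persistent-contact map,
#' fluctuation correlations, network construction, source/sink regions,
#' per-subunit shortest paths for both pathway families (sensor-to-filter
#' across the swap interface, and pore-to-filter within a subunit), family
#' average path lengths, restricted betweenness, centrality index and
#' banding.  On a trajectory the correlations are estimated from frames; on a
#' bead topology the analytic correlations and the reference-geometry contact
#' map are used instead, giving the noise-free limit of the same analysis.
#'
#' @param x A trajectory or a `bead_topology`.
#' @param config An [analysis_config()].
#' @param quiet Suppress stage messages.
#' @return An `analysis_bundle`; see [tidy.analysis_bundle()],
#'   [glance.analysis_bundle()], [centrality_table()] and [write_bundle()].
#' @export
run_pipeline <- function(x, config, quiet = FALSE) {
  UseMethod("run_pipeline")
}

#' @export
run_pipeline.traj <- function(x, config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- stage_logger(quiet)
  smap <- subunit_map(config$chains, config$neighbor)
  x <- assign_subunits(x, smap)
  if (config$stride > 1L) {
    x$xyz <- x$xyz[seq(1L, x$n_frames, by = config$stride), , drop = FALSE]
    x$n_frames <- nrow(x$xyz)
  }
  stage("input", sprintf("%d frames, %d residues", x$n_frames, nrow(x$residues)))
  if (config$superpose) {
    x <- superpose(x)
    stage("superpose", "iterative C-alpha mean fit")
  }
  cmap <- contact_map(x, cutoff = config$contact_cutoff,
                      occupancy = config$contact_occupancy)
  stage("contacts", sprintf("%d persistent contacts",
                            sum(cmap$contact[upper.tri(cmap$contact)])))
  corr <- correlation_matrix(x, check_superposed = config$superpose)
  stage("correlation", sprintf("%d x %d matrix", nrow(corr), ncol(corr)))
  net <- build_network(corr, cmap)
  stage("network", sprintf("%d edges", nrow(net$edges)))
  region_fn <- function(anchor) {
    define_region(x, anchor, radius = config$region_radius,
                  occupancy = config$region_occupancy)
  }
  bundle <- pipeline_core(net, corr, cmap, x$residues, smap, region_fn,
                          config, analytic = FALSE, stage = stage)
  bundle$n_frames <- x$n_frames
  finish_bundle(bundle, config)
}

#' @export
run_pipeline.bead_topology <- function(x, config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- stage_logger(quiet)
  smap <- subunit_map(config$chains, config$neighbor)
  cmap <- reference_contact_map(x, cutoff = config$contact_cutoff,
                                occupancy = config$contact_occupancy)
  stage("contacts", sprintf("%d reference contacts",
                            sum(cmap$contact[upper.tri(cmap$contact)])))
  corr <- analytic_correlations(x)
  stage("correlation", "analytic Kirchhoff pseudo-inverse")
  net <- build_network(corr, cmap)
  stage("network", sprintf("%d edges", nrow(net$edges)))
  ref_dist <- as.matrix(stats::dist(x$xyz))
  dimnames(ref_dist) <- list(x$residues$key, x$residues$key)
  residues <- cmap$residues
  region_fn <- function(anchor) {
    members <- residues$key[ref_dist[anchor, ] < config$region_radius]
    new_region(anchor, union(anchor, members), config$region_radius,
               config$region_occupancy,
               residues$subunit[match(anchor, residues$key)])
  }
  bundle <- pipeline_core(net, corr, cmap, residues, smap, region_fn,
                          config, analytic = TRUE, stage = stage)
  finish_bundle(bundle, config)
}

stage_logger <- function(quiet) {
  if (quiet) return(function(...) invisible(NULL))
  function(stage, detail) rlang::inform(sprintf("[%s] %s", stage, detail))
}

pipeline_core <- function(net, corr, cmap, residues, smap, region_fn, config,
                          analytic, stage) {
  anchors <- config$anchors
  fam_pairs <- list()
  paths <- list()
  for (lab in smap$order) {
    ch <- subunit_chain(smap, lab)
    nbr_ch <- subunit_chain(smap, smap$neighbor[[lab]])
    vsd <- list(
      family = "VSD-SF", subunit = lab,
      source = region_fn(residue_key(ch, anchors$s4)),
      sink = region_fn(residue_key(nbr_ch, anchors$sf))
    )
    pd <- list(
      family = "PD-SF", subunit = lab,
      source = region_fn(residue_key(ch, anchors$s6)),
      sink = region_fn(residue_key(ch, anchors$sf))
    )
    fam_pairs <- c(fam_pairs, list(vsd), list(pd))
  }
  stage("regions", sprintf("%d source/sink region pairs", length(fam_pairs)))
  for (pr in fam_pairs) {
    key <- paste(pr$family, pr$subunit, sep = "/")
    paths[[key]] <- shortest_path(net, pr$source, pr$sink,
                                  family = pr$family, subunit = pr$subunit)
  }
  path_table <- purrr::map_dfr(paths, function(p) {
    tibble::tibble(
      family = p$family, subunit = p$subunit,
      source = p$source_anchor, sink = p$sink_anchor,
      length = p$length, n_residues = length(p$residues),
      residues = list(p$residues)
    )
  })
  family_lengths <- path_table |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(mean_length = mean(.data$length), .groups = "drop")
  stage("paths", paste(
    sprintf("%s mean length %.3f", family_lengths$family, family_lengths$mean_length),
    collapse = "; "
  ))
  btw <- path_betweenness(
    net,
    purrr::map(fam_pairs, "source"),
    purrr::map(fam_pairs, "sink")
  )
  ci_by_family <- lapply(split(fam_pairs, purrr::map_chr(fam_pairs, "family")), function(prs) {
    centrality_index(
      net,
      purrr::map(prs, "source"), purrr::map(prs, "sink"),
      epsilon = config$ci_epsilon, k_max = config$ci_k_max
    )
  })
  stage("centrality", sprintf("betweenness over %d region pairs; CI per family",
                              length(fam_pairs)))
  list(
    label = config$label,
    settings = config,
    analytic = analytic,
    residues = residues,
    subunits = smap,
    contact_map = cmap,
    correlation = corr,
    network = net,
    region_pairs = fam_pairs,
    paths = paths,
    path_table = path_table,
    family_lengths = family_lengths,
    betweenness = btw,
    ci_by_family = ci_by_family
  )
}

finish_bundle <- function(bundle, config) {
  bundle <- structure(bundle, class = "analysis_bundle")
  bundle$centrality <- centrality_table(bundle)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Residue centrality table of an analysis
#'
#' Aggregates betweenness and centrality index per residue number across the
#' four chains (a pathway and its three symmetry mates traverse the same
#' residue numbers), bands the betweenness, and keeps the per-family maximum
#' centrality index, mirroring a per-residue hub table.
#'
#' @param bundle An `analysis_bundle`.
#' @param by `"site"` (default) for per-residue-number aggregation across
#'   chains, or `"key"` for per chain:resno records.
#' @return A tibble with `betweenness`, `band`, `zero` and `ci` columns.
#' @export
centrality_table <- function(bundle, by = c("site", "key")) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  by <- match.arg(by)
  btw <- bundle$betweenness
  if (by == "key") {
    ci <- purrr::imap(bundle$ci_by_family, function(tab, fam) {
      stats::setNames(tab[, c("residue", "ci")], c("residue", paste0("ci_", fam)))
    })
    out <- Reduce(function(a, b) dplyr::left_join(a, b, by = "residue"), ci, btw)
    ci_cols <- grep("^ci_", names(out))
    out$ci <- do.call(pmax, out[ci_cols])
    out <- out[, c("residue", "betweenness", "ci")]
  } else {
    info <- split_key(btw$residue)
    btw$resno <- info$resno
    agg_b <- btw |>
      dplyr::group_by(.data$resno) |>
      dplyr::summarise(betweenness = sum(.data$betweenness), .groups = "drop")
    # Per-site CI: fraction of pooled near-optimal paths (per family) that
    # visit the residue number in any chain; families combined by maximum.
    ci_site <- purrr::map(bundle$ci_by_family, function(tab) {
      tab$resno <- split_key(tab$residue)$resno
      tab |>
        dplyr::group_by(.data$resno) |>
        dplyr::summarise(ci = min(1, sum(.data$ci)), .groups = "drop")
    })
    agg_ci <- dplyr::bind_rows(ci_site) |>
      dplyr::group_by(.data$resno) |>
      dplyr::summarise(ci = max(.data$ci), .groups = "drop")
    out <- dplyr::left_join(agg_b, agg_ci, by = "resno")
    out <- dplyr::rename(out, residue = "resno")
  }
  band <- band_betweenness(out$betweenness, max(out$betweenness))
  out$band <- as.character(band)
  out$zero <- attr(band, "zero")
  dplyr::arrange(out, .data$residue)
}

#' Compare analysis runs by average path length
#'
#' Mirrors the wild-type-versus-mutant comparison: for every variant and
#' pathway family it reports the path-length difference
#' `delta = variant - reference`, the implied correlation-product ratio
#' `exp(delta)` (a delta of two units is roughly one order of magnitude of
#' correlation), and a qualitative flag: `"hindered"` when `delta >= 2`,
#' `"enhanced"` when `delta <= -0.3`, otherwise `"comparable"`.  All runs
#' must share contact, region and centrality settings and anchors.
#'
#' @param reference An `analysis_bundle` (typically the wild type).
#' @param ... Variant bundles (typically mutants).
#' @return A tibble with one row per variant and family.
#' @export
compare_runs <- function(reference, ...) {
  variants <- list(...)
  stopifnot(inherits(reference, "analysis_bundle"))
  if (length(variants) == 0L) {
    abort_allopath("Supply at least one variant bundle.", "argument_error")
  }
  purrr::map_dfr(variants, function(v) {
    stopifnot(inherits(v, "analysis_bundle"))
    check_settings_match(reference$settings, v$settings)
    ref <- reference$family_lengths
    var <- v$family_lengths
    tab <- dplyr::inner_join(ref, var, by = "family", suffix = c("_ref", "_var"))
    tibble::tibble(
      label = v$label,
      family = tab$family,
      reference_length = tab$mean_length_ref,
      variant_length = tab$mean_length_var,
      delta = tab$mean_length_var - tab$mean_length_ref,
      ratio = exp(tab$mean_length_var - tab$mean_length_ref),
      flag = dplyr::case_when(
        tab$mean_length_var - tab$mean_length_ref >= 2 ~ "hindered",
        tab$mean_length_var - tab$mean_length_ref <= -0.3 ~ "enhanced",
        TRUE ~ "comparable"
      )
    )
  })
}

check_settings_match <- function(a, b) {
  fields <- c("anchors", "contact_cutoff", "contact_occupancy",
              "region_radius", "region_occupancy", "ci_epsilon", "ci_k_max",
              "superpose")
  for (f in fields) {
    if (!identical(a[[f]], b[[f]])) {
      abort_allopath(
        sprintf("Runs were produced with different settings (field `%s`).", f),
        "comparison_error"
      )
    }
  }
  invisible(TRUE)
}

#' Write an analysis bundle to disk
#'
#' Writes the resolved configuration (YAML), residue table, correlation
#' matrix, edge list and GraphML network, contact probabilities (TSV) and the
#' thresholded contact map (MatrixMarket), the per-subunit paths (TSV and
#' JSON) and the centrality table.  Outputs are plain text and reproducible
#' bit-for-bit from the same inputs, config and seed.
#'
#' @param bundle An `analysis_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(bundle$settings)
  cfg$out_dir <- NULL
  cfg$chains <- as.list(cfg$chains)
  cfg$neighbor <- as.list(cfg$neighbor)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  res <- bundle$residues[, c("chain", "resno", "resname", "subunit")]
  readr::write_tsv(res, file.path(dir, "residues.tsv"))
  readr::write_tsv(
    tibble::as_tibble(as.data.frame(unclass(bundle$correlation)), rownames = "residue"),
    file.path(dir, "correlation.tsv")
  )
  write_network(bundle$network,
                graphml = file.path(dir, "network.graphml"),
                edges = file.path(dir, "edges.tsv"))
  readr::write_tsv(tidy(bundle$contact_map), file.path(dir, "contacts.tsv"))
  Matrix::writeMM(
    methods::as(Matrix::Matrix(bundle$contact_map$contact, sparse = TRUE), "nMatrix"),
    file.path(dir, "contacts.mtx")
  )
  paths_tbl <- tidy(bundle)
  readr::write_tsv(
    dplyr::mutate(paths_tbl, residues = purrr::map_chr(.data$residues, paste, collapse = "-")),
    file.path(dir, "paths.tsv")
  )
  jsonlite::write_json(
    purrr::map(bundle$paths, function(p) {
      list(family = p$family, subunit = p$subunit, residues = p$residues,
           weights = p$weights, length = p$length)
    }),
    file.path(dir, "paths.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_tsv(bundle$centrality, file.path(dir, "centrality.tsv"))
  readr::write_tsv(bundle$family_lengths, file.path(dir, "family_lengths.tsv"))
  invisible(dir)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("<analysis_bundle> '%s'%s\n", x$label,
              if (x$analytic) " (analytic, noise-free)" else ""))
  cat(sprintf("  %d residues, %d edges\n",
              length(x$network$residues), nrow(x$network$edges)))
  for (r in seq_len(nrow(x$family_lengths))) {
    cat(sprintf("  %s mean path length: %.4f\n",
                x$family_lengths$family[r], x$family_lengths$mean_length[r]))
  }
  invisible(x)
}
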