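# Fixtures are built in code: tiny trajectories, ad-hoc networks, and the
# text of small multi-model PDB files.

# A trajectory of single-bead glycine residues from a list of per-frame
# n_res x 3 coordinate matrices.
bead_traj <- function(frames, chain = "A", superposed = TRUE) {
  n_res <- nrow(frames[[1]])
  if (length(chain) == 1L) chain <- rep(chain, n_res)
  atoms <- tibble::tibble(
    elety = "CA", chain = chain, resno = seq_len(n_res), resname = "GLY"
  )
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  new_trajectory(xyz, atoms, superposed = superposed)
}

# A dynamic_network built directly from an edge table (res_i, res_j, weight).
test_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!("corr" %in% names(edges))) edges$corr <- exp(-edges$weight)
  nodes <- if (is.null(nodes)) sort(unique(c(edges$res_i, edges$res_j))) else nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$res_i, to = edges$res_j,
               weight = edges$weight, corr = edges$corr),
    directed = FALSE, vertices = data.frame(name = nodes)
  )
  structure(
    list(graph = g, edges = edges, residues = nodes,
         settings = list(cutoff = 5, occupancy = 0.75)),
    class = "dynamic_network"
  )
}

# Random connected-ish weighted graph on n named nodes.
random_graph_edges <- function(n, p = 0.45, wmin = 0.1, wmax = 2) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  # always keep a spanning path so most graphs are connected
  chain <- cbind(seq_len(n - 1L), seq(2L, n))
  sel <- unique(rbind(t(pairs[, keep, drop = FALSE]), chain))
  tibble::tibble(
    res_i = nodes[sel[, 1L]],
    res_j = nodes[sel[, 2L]],
    weight = stats::runif(nrow(sel), wmin, wmax)
  )
}

# --- Independent brute-force oracles -------------------------------------

# All simple paths between two nodes, as lists of node names, with lengths.
enumerate_simple_paths <- function(edges, from, to) {
  adj <- list()
  add <- function(a, b, w) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(to = b, w = w))
  }
  for (r in seq_len(nrow(edges))) {
    add(edges$res_i[r], edges$res_j[r], edges$weight[r])
    add(edges$res_j[r], edges$res_i[r], edges$weight[r])
  }
  paths <- list()
  lens <- numeric(0)
  walk <- function(node, visited, len) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- visited
      lens <<- c(lens, len)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb$to[r]
      if (!(nxt %in% visited)) walk(nxt, c(visited, nxt), len + nb$w[r])
    }
  }
  walk(from, from, 0)
  list(paths = paths, lengths = lens)
}

# Minimum path length between two member sets by exhaustive enumeration.
brute_shortest <- function(edges, sources, sinks) {
  common <- intersect(sources, sinks)
  if (length(common) > 0L) return(list(length = 0, paths = as.list(sort(common)[1L])))
  best <- Inf
  best_paths <- list()
  for (s in sources) {
    for (t in sinks) {
      enum <- enumerate_simple_paths(edges, s, t)
      if (length(enum$lengths) == 0L) next
      m <- min(enum$lengths)
      if (m < best - 1e-9) {
        best <- m
        best_paths <- enum$paths[abs(enum$lengths - m) < 1e-9]
      } else if (abs(m - best) < 1e-9) {
        best_paths <- c(best_paths, enum$paths[abs(enum$lengths - m) < 1e-9])
      }
    }
  }
  list(length = best, paths = best_paths)
}

# Source/sink-restricted betweenness by exhaustive shortest-path enumeration.
brute_betweenness <- function(edges, sources, sinks, nodes) {
  b <- stats::setNames(rep(0, length(nodes)), nodes)
  for (s in sources) {
    for (t in setdiff(sinks, s)) {
      enum <- enumerate_simple_paths(edges, s, t)
      if (length(enum$lengths) == 0L) next
      m <- min(enum$lengths)
      geo <- enum$paths[enum$lengths < m + 1e-9]
      sigma <- length(geo)
      for (p in geo) {
        inner <- p[-c(1L, length(p))]
        b[inner] <- b[inner] + 1 / sigma
      }
    }
  }
  b
}

# Four chains, two residues each, side by side; the pair is in contact in a
# controllable subset of chains.
consensus_fixture <- function(contact_chains) {
  chains <- c("A", "B", "C", "D")
  coords <- do.call(rbind, lapply(seq_along(chains), function(s) {
    gap <- if (chains[s] %in% contact_chains) 3 else 8
    rbind(c(0, 40 * s, 0), c(gap, 40 * s, 0))
  }))
  frames <- lapply(1:4, function(f) coords)
  traj <- bead_traj(frames, chain = rep(chains, each = 2))
  traj$atoms$resno <- rep(1:2, 4)
  new_trajectory(traj$xyz, traj$atoms, superposed = TRUE)
}

# Text of a small multi-model PDB, built line by line.
write_mini_pdb <- function(file, models, resnames, chain = "A") {
  lines <- character(0)
  for (m in seq_along(models)) {
    coords <- models[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(coords))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, resnames[i], chain, i, coords[i, 1], coords[i, 2], coords[i, 3]
      ))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), file)
  file
}
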