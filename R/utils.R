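# Internal helpers shared across modules.

# Residue keys are "chain:resno", e.g. "A:293"; unique within a system.
residue_key <- function(chain, resno) paste0(chain, ":", resno)

split_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  tibble::tibble(
    chain = purrr::map_chr(parts, 1),
    resno = as.integer(purrr::map_chr(parts, 2))
  )
}

abort_allopath <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("allopath_", class), "allopath_error"), ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort_allopath(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, min, max),
      "argument_error"
    )
  }
  invisible(x)
}

# xyz matrices follow the bio3d layout: one frame per row, columns
# x1,y1,z1,x2,... ; these helpers move between that and [frame, atom, axis].
xyz_to_array <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  aperm(array(t(xyz), dim = c(3L, na, nf)), c(3L, 2L, 1L))
}

array_to_xyz <- function(arr) {
  nf <- dim(arr)[1L]
  na <- dim(arr)[2L]
  matrix(aperm(arr, c(3L, 2L, 1L)), nrow = nf, ncol = 3L * na, byrow = TRUE)
}

atom_cols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

# Per-frame distance between two atoms, vectorised over frames.
atom_pair_distance <- function(xyz, i, j) {
  di <- xyz[, atom_cols(i), drop = FALSE] - xyz[, atom_cols(j), drop = FALSE]
  sqrt(di[, 1L]^2 + di[, 2L]^2 + di[, 3L]^2)
}

# Lexicographic comparison of two character vectors (shorter prefix wins).
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

lex_min_path <- function(paths) {
  best <- paths[[1L]]
  for (p in paths[-1L]) if (lex_less(p, best)) best <- p
  best
}
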