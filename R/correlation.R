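#' Fluctuation correlation matrix of C-alpha positions
#'
#' For residues i, j with per-frame displacement vectors
#' \eqn{\delta r_i = r_i - \langle r_i \rangle} (time mean over frames), the
#' correlation coefficient is the normalized covariance
#' \deqn{Corr_{ij} = \frac{\langle \delta r_i \cdot \delta r_j \rangle}
#'   {\sqrt{\langle |\delta r_i|^2\rangle \langle |\delta r_j|^2\rangle}},}
#' which lies in \[-1, 1\] and equals 1 on the diagonal.  Frames must be
#' superposed first so that only internal fluctuations contribute.
#'
#' @param traj A superposed trajectory (override with `check_superposed =
#'   FALSE` at your own risk).
#' @param check_superposed Refuse non-superposed input (default).
#' @return An n_res x n_res matrix of class `correlation_matrix` with residue
#'   keys as dimnames.
#' @export
correlation_matrix <- function(traj, check_superposed = TRUE) {
  stopifnot(inherits(traj, "traj"))
  if (check_superposed && !isTRUE(traj$superposed)) {
    abort_allopath(
      "Trajectory is not superposed; run superpose() first (or set check_superposed = FALSE).",
      "argument_error"
    )
  }
  keys <- traj$residues$key
  ca <- traj$residues$calpha
  nf <- traj$n_frames
  dots <- matrix(0, length(ca), length(ca))
  for (a in 0:2) {
    xa <- traj$xyz[, 3L * ca - 2L + a, drop = FALSE]
    xa <- sweep(xa, 2L, colMeans(xa))
    dots <- dots + crossprod(xa)
  }
  dots <- dots / nf
  v <- diag(dots)
  if (any(v < 1e-12)) {
    bad <- keys[v < 1e-12]
    abort_allopath(
      paste0(
        "Residue(s) with zero positional variance (correlation undefined): ",
        paste(utils::head(bad, 5L), collapse = ", ")
      ),
      "degenerate_error"
    )
  }
  corr <- dots / sqrt(outer(v, v))
  corr <- (corr + t(corr)) / 2
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  dimnames(corr) <- list(keys, keys)
  class(corr) <- c("correlation_matrix", class(corr))
  corr
}

#' Edge weight from a correlation coefficient
#'
#' Converts correlations to graph distances via \eqn{d = -\ln |Corr|} (natural
#' log): perfectly correlated (or anti-correlated) residue pairs are at
#' distance 0, uncorrelated pairs at infinite distance.  With the natural log,
#' a path-length difference of two units corresponds to roughly one order of
#' magnitude in the correlation product along the path.
#'
#' @param corr Numeric vector of correlation values in \[-1, 1\] (values up to
#'   1e-8 beyond are clamped; larger excursions are an error).
#' @return Non-negative weights; `Inf` where `corr == 0` (meaning "no edge").
#' @examples
#' edge_weight(c(1, -1, 0.5, 0))
#' @export
edge_weight <- function(corr) {
  if (!is.numeric(corr)) {
    abort_allopath("`corr` must be numeric.", "domain_error")
  }
  a <- abs(corr)
  if (any(a > 1 + 1e-8, na.rm = TRUE)) {
    abort_allopath("Correlation values outside [-1, 1] beyond tolerance.", "domain_error")
  }
  a[a > 1] <- 1
  -log(a)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d residues\n", nrow(x), ncol(x)))
  invisible(x)
}
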