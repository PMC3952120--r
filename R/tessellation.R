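#' Delaunay tessellation of atomic coordinates
#'
#' Computes the 3D Delaunay tessellation of a point set: the partition of
#' its convex hull into tetrahedra such that no input point falls strictly
#' inside any tetrahedron's circumsphere.  Each simplex identifies a
#' quadruplet of nearest-neighbour atoms.
#'
#' Uses an incremental insertion algorithm with double-precision insphere
#' tests.  Near-degenerate inputs (e.g. exactly coplanar subsets arising
#' from coordinates printed at 3 decimal places) are handled by retrying on
#' deterministically jittered coordinates (amplitude at most 1e-6 Å, seeded
#' from the coordinates themselves) with a warning.
#'
#' @param coords Numeric matrix (n x 3) of coordinates in Å, n >= 4, not all
#'   coplanar and without duplicate points.
#' @return Integer matrix (m x 4) of 1-based vertex indices, one row per
#'   tetrahedron, each row sorted increasingly; row order is deterministic.
#' @export
#' @examples
#' pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
#' tessellate(pts)
tessellate <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3) {
    abort("coords must be an n x 3 numeric matrix")
  }
  if (any(!is.finite(coords))) abort("coords must be finite")
  if (nrow(coords) < 4) {
    abort("tessellation requires at least 4 points")
  }
  if (anyDuplicated(round(coords, 9))) {
    abort("degenerate input: duplicate points")
  }
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    abort("degenerate input: points are (nearly) coplanar")
  }

  res <- try(delaunay3d_cpp(coords), silent = TRUE)
  attempt <- 0
  while (inherits(res, "try-error") &&
         grepl("delaunay_retry", attr(res, "condition")$message) &&
         attempt < 5) {
    attempt <- attempt + 1
    amp <- 1e-8 * 10^(attempt - 1)  # 1e-8 .. 1e-4? capped below
    amp <- min(amp, 1e-6)
    jit <- matrix(jitter_stream(length(coords), attempt), ncol = 3)
    warning(sprintf(
      "tessellation degenerate; retrying with %.0e Å deterministic jitter",
      amp), call. = FALSE)
    res <- try(delaunay3d_cpp(coords + amp * jit), silent = TRUE)
  }
  if (inherits(res, "try-error")) {
    abort(paste("tessellation failed:", attr(res, "condition")$message))
  }
  res
}

# deterministic uniform(-1,1) stream (splitmix-style), independent of the
# global RNG state
jitter_stream <- function(n, salt) {
  state <- 0x9E3779B9 + salt * 2654435761
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 69069 + 1234567) %% 2^31
    out[i] <- 2 * (state / 2^31) - 1
  }
  out
}

#' Pairwise maximum edge length of a tetrahedron
#'
#' @param vidx Integer vector of 4 vertex indices (1-based).
#' @param coords Coordinate matrix the indices refer to.
#' @return The maximum over the 6 pairwise Euclidean distances, in Å.
#' @export
max_edge_length <- function(vidx, coords) {
  stopifnot(length(vidx) == 4)
  p <- coords[vidx, , drop = FALSE]
  d <- stats::dist(p)
  max(d)
}

# max edge per simplex, vectorized over rows of an m x 4 index matrix
simplex_max_edges <- function(simplices, coords) {
  if (nrow(simplices) == 0) return(numeric(0))
  pairs <- utils::combn(4, 2)
  m2 <- matrix(0, nrow(simplices), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- coords[simplices[, pairs[1, k]], , drop = FALSE]
    b <- coords[simplices[, pairs[2, k]], , drop = FALSE]
    m2[, k] <- rowSums((a - b)^2)
  }
  sqrt(apply(m2, 1, max))
}

#' Apply the edge-length cutoff to raw Delaunay simplices
#'
#' Tetrahedra near the hull of a structure can have arbitrarily long edges
#' that do not represent physical atomic contacts.  A tetrahedron is
#' retained only when all 6 of its edges are at most `cutoff` (strictly
#' longer edges disqualify it; a tetrahedron at exactly the cutoff is
#' kept).  The retained count `n_retained` is the normalization `N` of the
#' topological score.
#'
#' @param raw Integer matrix of simplices from [tessellate()].
#' @param coords The coordinate matrix the simplices refer to.
#' @param cutoff Edge-length threshold in Å; default 8.0.
#' @return An `fb_tessellation` object: list with `simplices` (retained
#'   m x 4 index matrix), `max_edge` (per retained simplex), `n_raw`,
#'   `n_retained` and `cutoff`.
#' @export
filter_tetrahedra <- function(raw, coords, cutoff = 8.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    abort("cutoff must be a single non-negative length in Å")
  }
  raw <- as.matrix(raw)
  me <- simplex_max_edges(raw, coords)
  keep <- me <= cutoff
  # canonical (lexicographic) row order: identical retained sets score
  # bit-identically regardless of construction order
  ord <- order(raw[keep, 1], raw[keep, 2], raw[keep, 3], raw[keep, 4])
  structure(
    list(simplices = raw[keep, , drop = FALSE][ord, , drop = FALSE],
         max_edge = me[keep][ord],
         n_raw = nrow(raw), n_retained = sum(keep), cutoff = cutoff),
    class = "fb_tessellation")
}

#' Tessellate a structure and apply the edge cutoff
#'
#' Convenience wrapper: [tessellate()] on the atom coordinates followed by
#' [filter_tetrahedra()].
#'
#' @param s A filtered `fb_structure`.
#' @param cutoff Edge-length threshold in Å; default 8.0.
#' @return An `fb_tessellation`.
#' @export
tessellate_structure <- function(s, cutoff = 8.0) {
  filter_tetrahedra(tessellate(atom_coords(s)), atom_coords(s),
                    cutoff = cutoff)
}

#' @export
print.fb_tessellation <- function(x, ...) {
  cat(sprintf(
    "Delaunay tessellation: %d simplices (%d raw, cutoff %.1f Å)\n",
    x$n_retained, x$n_raw, x$cutoff))
  invisible(x)
}

#' @rdname tidy.fb_potential
#' @method tidy fb_tessellation
#' @export
tidy.fb_tessellation <- function(x, ...) {
  tibble(v1 = x$simplices[, 1], v2 = x$simplices[, 2],
         v3 = x$simplices[, 3], v4 = x$simplices[, 4],
         max_edge = x$max_edge)
}
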