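#' Specify a synthetic structure fixture
#'
#' The generators produce seeded, labelled 3D point clouds written as valid
#' fixed-column PDB text, so every pipeline stage can be exercised without
#' external structure files.  They make no claim of chemical realism (no
#' bonds, no sterics beyond a minimum separation): they exercise geometry
#' and bookkeeping.
#'
#' @param n_atoms Number of protein-block atoms.
#' @param composition Named numeric vector of target class proportions over
#'   `C`, `N`, `O`, `S`, `M`, `X`; must sum to 1.  Classes are drawn from
#'   this distribution.
#' @param box Edge length of the cubic placement box, Å.
#' @param min_sep Minimum pairwise atom separation, Å (> 0).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @param ligand Optional list with `n_atoms` and `offset` (xyz
#'   displacement of the ligand block's box, Å) describing a ligand block
#'   with residue name `LIG`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_atoms, composition = c(C = 1), box = 25,
                         min_sep = 1.5, seed = 1, ligand = NULL) {
  composition <- composition[composition > 0]
  if (abs(sum(composition) - 1) > 1e-9) {
    abort("fixture composition must sum to 1")
  }
  if (!all(names(composition) %in% atom_classes())) {
    abort("fixture composition names must be atom classes")
  }
  if (min_sep <= 0) abort("min_sep must be positive")
  structure(list(n_atoms = n_atoms, composition = composition, box = box,
                 min_sep = min_sep, seed = as.integer(seed),
                 ligand = ligand),
            class = "fixture_spec")
}

# representative element per class for generated atoms
class_element <- c(C = "C", N = "N", O = "O", S = "S", M = "ZN", X = "P")

place_points <- function(n, box, min_sep, origin = c(0, 0, 0)) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0
  rejections <- 0
  while (placed < n) {
    cand <- runif(3) * box + origin
    ok <- placed == 0 ||
      min(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2,
                        cand)^2)) >= min_sep^2
    if (ok) {
      placed <- placed + 1
      pts[placed, ] <- cand
      rejections <- 0
    } else {
      rejections <- rejections + 1
      if (rejections > 1e4) {
        abort("fixture packing infeasible: too many placement rejections")
      }
    }
  }
  round(pts, 3)  # PDB coordinate precision
}

#' Generate a seeded random structure
#'
#' @param spec A [fixture_spec()].
#' @return An `fb_structure` tibble; its PDB text is available via
#'   [write_pdb()] and round-trips through [parse_structure()].
#' @export
#' @examples
#' s <- random_structure(fixture_spec(20, seed = 7))
#' nrow(s)
random_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    pts <- place_points(spec$n_atoms, spec$box, spec$min_sep)
    cls <- sample(names(spec$composition), spec$n_atoms, replace = TRUE,
                  prob = spec$composition)
  })
  fixture_atoms(pts, cls, start_serial = 1, resname = "UNK", het = FALSE,
                source_id = sprintf("fixture-seed%d", spec$seed))
}

fixture_atoms <- function(pts, cls, start_serial, resname, het, source_id) {
  n <- nrow(pts)
  el <- unname(class_element[cls])
  serial <- seq_len(n) + start_serial - 1
  new_structure(tibble(
    serial = as.integer(serial),
    name = paste0(el, seq_len(n) %% 100),
    altloc = "", resname = resname, chain = "A",
    resseq = as.integer(serial), icode = "",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    occupancy = 1, element = el, is_het = het
  ), source_id = source_id)
}

#' Generate a toy protein-ligand complex
#'
#' Builds a protein block plus a ligand block (residue name `LIG`,
#' `HETATM` records) displaced by `spec$ligand$offset`, with exact atom
#' counts recorded so ligand removal can be verified.
#'
#' @param spec A [fixture_spec()] whose `ligand` field is set.
#' @return A list with `structure` (`fb_structure` of the complex),
#'   `pdb_text`, `selector` (a [ligand_selector()] for `LIG`) and
#'   `bookkeeping` (`n_protein`, `n_ligand`).
#' @export
toy_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(spec$ligand)) abort("spec$ligand must be set for toy_complex")
  nl <- spec$ligand$n_atoms
  off <- spec$ligand$offset %||% c(0, 0, 0)
  lig_box <- spec$ligand$box %||% spec$box
  lig_sep <- spec$ligand$min_sep %||% spec$min_sep
  withr::with_seed(spec$seed, {
    pts <- place_points(spec$n_atoms, spec$box, spec$min_sep)
    cls <- sample(names(spec$composition), spec$n_atoms, replace = TRUE,
                  prob = spec$composition)
    lpts <- place_points(nl, lig_box, lig_sep, origin = off)
    lcls <- sample(names(spec$composition), nl, replace = TRUE,
                   prob = spec$composition)
  })
  prot <- fixture_atoms(pts, cls, 1, "UNK", FALSE,
                        sprintf("toy-complex-seed%d", spec$seed))
  lig <- fixture_atoms(lpts, lcls, spec$n_atoms + 1, "LIG", TRUE,
                       "ligand")
  cmplx <- new_structure(bind_rows(prot, lig),
                         source_id = sprintf("toy-complex-seed%d",
                                             spec$seed))
  list(structure = cmplx, pdb_text = write_pdb(cmplx),
       selector = ligand_selector("LIG"),
       bookkeeping = list(n_protein = nrow(prot), n_ligand = nl))
}

#' Exhaustive empty-circumsphere check
#'
#' Brute-force Delaunay-property oracle: for every simplex, computes the
#' circumsphere and verifies that no other input point lies strictly
#' inside it (relative tolerance `tol`).  Intended for small point sets
#' (exhaustive, O(m * n)).
#'
#' @param coords n x 3 coordinate matrix.
#' @param simplices m x 4 matrix of 1-based vertex indices.
#' @param tol Relative tolerance on the squared radius.
#' @return A list with `pass` (logical) and `violations`, a tibble of
#'   (simplex row, offending point) pairs; degenerate (zero-volume)
#'   simplices are reported with point 0.
#' @export
empty_circumsphere_check <- function(coords, simplices, tol = 1e-7) {
  coords <- as.matrix(coords)
  simplices <- as.matrix(simplices)
  viol <- list()
  for (i in seq_len(nrow(simplices))) {
    v <- simplices[i, ]
    cs <- circumsphere_r(coords[v, , drop = FALSE])
    if (is.null(cs)) {
      viol[[length(viol) + 1]] <- tibble(simplex = i, point = 0L)
      next
    }
    d2 <- rowSums(sweep(coords, 2, cs$center)^2)
    inside <- which(d2 < cs$r2 * (1 - tol))
    inside <- setdiff(inside, v)
    if (length(inside) > 0) {
      viol[[length(viol) + 1]] <- tibble(simplex = i,
                                         point = as.integer(inside))
    }
  }
  violations <- if (length(viol) > 0) bind_rows(viol) else
    tibble(simplex = integer(), point = integer())
  list(pass = nrow(violations) == 0, violations = violations)
}

# circumcenter + squared radius of 4 points; NULL when degenerate
circumsphere_r <- function(p) {
  a <- p[1, ]
  m <- sweep(p[2:4, , drop = FALSE], 2, a)
  b <- 0.5 * rowSums(m^2)
  det <- det(m)
  scale <- max(rowSums(m^2))
  if (abs(det) < 1e-10 * scale^1.5) return(NULL)
  ctr <- drop(solve(m, b))
  list(center = a + ctr, r2 = sum(ctr^2))
}
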