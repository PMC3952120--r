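#' Normalized topological score of a tessellation
#'
#' Every retained tetrahedron is scored by the potential entry of its
#' canonical quadruplet, and the topological score is the mean:
#' `Q = (1/N) * sum(s)`, with `N` the number of retained tetrahedra.
#'
#' A structure may contain a quadruplet whose potential score is undefined
#' (never observed in the derivation corpus).  The `missing_policy` decides
#' how such tetrahedra enter `Q`:
#' * `"zero"` (default): contribute 0 to the sum but still count in `N`;
#' * `"skip"`: excluded from both the sum and the denominator;
#' * `"error"`: abort, naming the offending key.
#'
#' @param tess An `fb_tessellation` from [filter_tetrahedra()] /
#'   [tessellate_structure()].
#' @param classes Atom-class vector aligned with the tessellated coordinates.
#' @param pot An `fb_potential`.
#' @param missing_policy One of `"zero"`, `"skip"`, `"error"`.
#' @param structure_id Label carried in the result.
#' @return An `fb_topo_score`: list with `Q`, `N` (retained tetrahedra),
#'   `n_undefined`, `structure_id` and the potential signature.
#' @export
topological_score <- function(tess, classes, pot,
                              missing_policy = c("zero", "skip", "error"),
                              structure_id = "structure") {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(tess, "fb_tessellation"), inherits(pot, "fb_potential"))
  if (tess$n_retained == 0) {
    abort("tessellation has no retained tetrahedra (N = 0)")
  }
  keys <- canonical_quadruplet(matrix(classes[tess$simplices], ncol = 4))
  s <- pot$s[match(keys, pot$quad)]
  undef <- is.na(s)
  if (any(undef) && missing_policy == "error") {
    abort(sprintf("quadruplet '%s' has an undefined potential score",
                  keys[which(undef)[1]]))
  }
  if (any(undef) && missing_policy == "zero") {
    warning(sprintf(
      "%d tetrahedra carry undefined potential scores; counted as 0",
      sum(undef)), call. = FALSE)
  }
  n <- if (missing_policy == "skip") sum(!undef) else tess$n_retained
  if (n == 0) abort("all tetrahedra have undefined scores (skip policy)")
  q <- sum(s[!undef]) / n
  structure(list(Q = q, N = n, n_undefined = sum(undef),
                 structure_id = structure_id,
                 potential = potential_signature(pot)),
            class = "fb_topo_score")
}

#' @export
print.fb_topo_score <- function(x, ...) {
  cat(sprintf("Q(%s) = %.6f  [N = %d, undefined = %d]\n",
              x$structure_id, x$Q, x$N, x$n_undefined))
  invisible(x)
}

#' Topological score difference between complex and isolated protein
#'
#' @param q_complex,q_protein `fb_topo_score` objects computed with the same
#'   potential and cutoff.
#' @return The scalar difference `Q_complex - Q_protein`.
#' @export
delta_q <- function(q_complex, q_protein) {
  stopifnot(inherits(q_complex, "fb_topo_score"),
            inherits(q_protein, "fb_topo_score"))
  if (!identical(q_complex$potential, q_protein$potential)) {
    abort("the two scores were computed with different potentials")
  }
  q_complex$Q - q_protein$Q
}

#' Binding free energy from the topological score difference
#'
#' The empirical linear model mapping the (small, sign-mixed) score
#' difference onto the binding free-energy scale:
#' `dG_calc = dq / 0.0003 - 10.49` kcal/mol.  The coefficients are fixed
#' constants of the published model; refitting on new data is available in
#' [fit_regression()] and never applied silently.
#'
#' @param dq Topological score difference(s).
#' @return Predicted binding free energy, kcal/mol.
#' @export
#' @examples
#' predict_binding_energy(0)       # intercept: -10.49
#' predict_binding_energy(-0.003)  # -20.49
predict_binding_energy <- function(dq) {
  if (any(!is.finite(dq))) abort("dq must be finite")
  dq / 0.0003 - 10.49
}

#' Experimental binding free energy from a dissociation or inhibition
#' constant
#'
#' `dG_exp = RT * ln(k) = 0.592 * ln(k)` kcal/mol, with the lumped
#' coefficient 0.592 kcal/mol (R = 1.986e-3 kcal/K/mol at T = 298 K) used
#' verbatim.
#'
#' @param k Dissociation (`k_d`) or inhibition (`k_i`) constant, molar;
#'   must be positive.
#' @param pk `-log10(k)`; e.g. `pk = 6.52` for `k_d = 10^-6.52`.
#' @return Binding free energy, kcal/mol (negative for sub-molar
#'   constants).
#' @export
#' @examples
#' free_energy_from_constant(1e-6)
#' pk_to_free_energy(6.52)
free_energy_from_constant <- function(k) {
  if (any(!is.finite(k) | k <= 0)) {
    abort("dissociation/inhibition constants must be positive")
  }
  0.592 * log(k)
}

#' @rdname free_energy_from_constant
#' @export
pk_to_free_energy <- function(pk) {
  if (any(!is.finite(pk))) abort("pk must be finite")
  -0.592 * log(10) * pk
}

#' Score a protein-ligand complex and predict its binding energy
#'
#' Runs the full pipeline on one complex: parse (if needed) and filter the
#' coordinates, tessellate the entire complex and score it, remove the
#' ligand atoms and tessellate/score the isolated protein, then map the
#' score difference to a binding free energy.  The complex tessellation
#' keeps all its tetrahedra, including any internal to the ligand (the
#' model assumes ligands small enough that interface tetrahedra dominate).
#'
#' @param complex A PDB path/text or an `fb_structure` of the complex.
#' @param ligand A [ligand_selector()] identifying the ligand atoms.
#' @param pot An `fb_potential`; defaults to the bundled reference
#'   potential.
#' @param cutoff Edge-length threshold in Å; default 8.0.
#' @param missing_policy Passed to [topological_score()].
#' @return An `fb_affinity`: list with `q_complex` and `q_protein`
#'   (`fb_topo_score`s), `delta_q`, `dg_calc` (kcal/mol) and
#'   `ligand_atom_count`.  Use [tidy()] for a one-row tibble.
#' @export
score_complex <- function(complex, ligand, pot = load_reference_potential(),
                          cutoff = 8.0, missing_policy = "zero") {
  s <- if (is.data.frame(complex)) complex else parse_structure(complex)
  s <- filter_structure(s)
  m <- selector_matches(s, ligand)
  if (!any(m)) abort("ligand selector matches no atoms in the complex")
  cls <- classify_atom(s$element)
  tess_c <- tessellate_structure(s, cutoff = cutoff)
  qc <- topological_score(tess_c, cls, pot, missing_policy,
                          structure_id = "complex")
  strip <- strip_ligand(s, ligand)
  prot <- strip$protein
  tess_p <- tessellate_structure(prot, cutoff = cutoff)
  if (tess_p$n_retained == 0) {
    abort("protein tessellation retains no tetrahedra at this cutoff")
  }
  qp <- topological_score(tess_p, classify_atom(prot$element), pot,
                          missing_policy, structure_id = "protein")
  dq <- delta_q(qc, qp)
  structure(list(q_complex = qc, q_protein = qp, delta_q = dq,
                 dg_calc = predict_binding_energy(dq),
                 ligand_atom_count = strip$ligand_atom_count,
                 cutoff = cutoff),
            class = "fb_affinity")
}

#' @export
print.fb_affinity <- function(x, ...) {
  cat(sprintf("Q_complex = %.6f (N = %d)\nQ_protein = %.6f (N = %d)\n",
              x$q_complex$Q, x$q_complex$N, x$q_protein$Q, x$q_protein$N))
  cat(sprintf("delta_Q = %.6g\ndG_calc = %.4f kcal/mol\n",
              x$delta_q, x$dg_calc))
  invisible(x)
}

#' @rdname tidy.fb_potential
#' @method tidy fb_affinity
#' @export
tidy.fb_affinity <- function(x, ...) {
  tibble(q_complex = x$q_complex$Q, n_complex = x$q_complex$N,
         undefined_complex = x$q_complex$n_undefined,
         q_protein = x$q_protein$Q, n_protein = x$q_protein$N,
         undefined_protein = x$q_protein$n_undefined,
         delta_q = x$delta_q, dg_calc = x$dg_calc,
         ligand_atoms = x$ligand_atom_count, cutoff = x$cutoff)
}

#' @rdname tidy.fb_potential
#' @method tidy fb_topo_score
#' @export
tidy.fb_topo_score <- function(x, ...) {
  tibble(structure_id = x$structure_id, Q = x$Q, N = x$N,
         n_undefined = x$n_undefined)
}
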