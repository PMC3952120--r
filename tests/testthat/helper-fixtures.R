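# shared helpers: tiny hand-built PDB records and brute-force oracles

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1, element = "C", het = FALSE,
                          altloc = " ") {
  nm <- if (nchar(name) < 4 && nchar(element) == 1) {
    sprintf(" %-3s", name)
  } else {
    sprintf("%-4s", name)
  }
  sprintf("%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM  ", serial, nm, altloc, resname,
          chain, resseq, x, y, z, occ, 0, element)
}

# tetrahedron with unit edges, one vertex at origin
regular_tetrahedron <- function(edge = 1) {
  edge * rbind(c(0, 0, 0),
               c(1, 0, 0),
               c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
}

# brute-force per-simplex quadruplet tally, independent of count_quadruplets
brute_quad_tally <- function(simplices, classes) {
  keys <- apply(simplices, 1, function(v) {
    paste(sort(classes[v]), collapse = "")
  })
  table(keys)
}

# all permutations of a length-4 vector
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# simplex matrices as comparable sets of sorted rows
simplex_set <- function(m) {
  sort(apply(m, 1, function(v) paste(sort(v), collapse = "-")))
}

protein_spec <- function(n = 60, seed = 1, box = 18) {
  fixture_spec(n, composition = c(C = 0.6, N = 0.2, O = 0.2), box = box,
               seed = seed)
}
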