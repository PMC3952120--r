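#' Parse a PDB-format coordinate file
#'
#' Reads fixed-column `ATOM`/`HETATM` records into a tibble with one row per
#' atom.  For multi-model files (NMR-style `MODEL`/`ENDMDL` blocks) only the
#' first model is read, so a single conformer is tessellated downstream.  No
#' filtering is applied at this stage; see [filter_structure()].
#'
#' @param pdb Either a path to a PDB file or a character vector of PDB lines
#'   (anything containing a newline or of length > 1 is treated as text).
#' @param source_id Label stored with the structure; defaults to the file
#'   name or `"<text>"`.
#'
#' @return A tibble of class `fb_structure` with columns `serial`, `name`,
#'   `altloc`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `element` and `is_het`.  Row order is file order.
#' @export
#' @examples
#' pdb <- "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C"
#' parse_structure(pdb)
parse_structure <- function(pdb, source_id = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(source_id)) source_id <- basename(pdb)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "<text>"
  }
  lines <- sub("[ \t\r]+$", "", lines)
  lineno <- seq_along(lines)
  rec <- substr(formatC(lines, width = 6, flag = "-"), 1, 6)

  # first MODEL only
  model_start <- which(rec == "MODEL ")
  if (length(model_start) > 1) {
    lines <- lines[seq_len(model_start[2] - 1)]
    lineno <- lineno[seq_len(model_start[2] - 1)]
    rec <- rec[seq_len(model_start[2] - 1)]
  }
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) {
    abort("no ATOM/HETATM records found in PDB input")
  }
  ln <- format(lines[keep], width = 80)
  lineno <- lineno[keep]

  num_field <- function(chars, what) {
    raw <- trimws(chars)
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & nzchar(raw)
    if (any(bad)) {
      abort(sprintf("malformed %s field at line %d: '%s'",
                    what, lineno[which(bad)[1]], raw[which(bad)[1]]))
    }
    val
  }

  serial <- num_field(substr(ln, 7, 11), "serial")
  name <- trimws(substr(ln, 13, 16))
  altloc <- trimws(substr(ln, 17, 17))
  resname <- trimws(substr(ln, 18, 20))
  chain <- trimws(substr(ln, 22, 22))
  resseq <- num_field(substr(ln, 23, 26), "residue number")
  icode <- trimws(substr(ln, 27, 27))
  x <- num_field(substr(ln, 31, 38), "x coordinate")
  y <- num_field(substr(ln, 39, 46), "y coordinate")
  z <- num_field(substr(ln, 47, 54), "z coordinate")
  occ <- num_field(substr(ln, 55, 60), "occupancy")
  occ[is.na(occ)] <- 1
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z))) {
    i <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))[1]
    abort(sprintf("missing coordinates at line %d", lineno[i]))
  }
  element <- resolve_element(trimws(substr(ln, 77, 78)), substr(ln, 13, 16),
                             lineno)
  atoms <- tibble(
    serial = as.integer(serial), name = name, altloc = altloc,
    resname = resname, chain = chain, resseq = as.integer(resseq),
    icode = icode, x = x, y = y, z = z, occupancy = occ,
    element = element, is_het = substr(ln, 1, 6) == "HETATM"
  )
  new_structure(atoms, source_id = source_id)
}

new_structure <- function(atoms, source_id = "structure", filter_log = NULL) {
  out <- as_tibble(atoms)
  class(out) <- c("fb_structure", class(tibble()))
  attr(out, "source_id") <- source_id
  attr(out, "filter_log") <- filter_log
  out
}

# recognized element symbols (uppercase), hydrogen isotopes included
pdb_elements <- function() {
  c("H", "D", "T", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
    "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA", "SC",
    "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN", "GA", "GE",
    "AS", "SE", "BR", "KR", "RB", "SR", "Y", "ZR", "NB", "MO", "TC",
    "RU", "RH", "PD", "AG", "CD", "IN", "SN", "SB", "TE", "I", "XE",
    "CS", "BA", "LA", "CE", "PR", "ND", "PM", "SM", "EU", "GD", "TB",
    "DY", "HO", "ER", "TM", "YB", "LU", "HF", "TA", "W", "RE", "OS",
    "IR", "PT", "AU", "HG", "TL", "PB", "BI", "PO", "AT", "RN", "FR",
    "RA", "AC", "TH", "PA", "U", "NP", "PU", "AM", "CM")
}

# Element from columns 77-78 when present, else from the atom-name field:
# a symbol occupying column 13 (e.g. "FE  ", "CA  " for calcium) is read as a
# two-letter element; names starting at column 14 (" CA " = C-alpha) use the
# first letter.
resolve_element <- function(elem_col, name_field, lineno) {
  known <- pdb_elements()
  el <- toupper(elem_col)
  need <- !nzchar(el) | !(el %in% known)
  if (any(need)) {
    nf <- toupper(name_field[need])
    two <- gsub("[^A-Z]", "", substr(nf, 1, 2))
    first <- substr(gsub("[^A-Z]", "", nf), 1, 1)
    guess <- ifelse(substr(nf, 1, 1) != " " & two %in% known, two, first)
    el[need] <- guess
  }
  bad <- !(el %in% known)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("cannot resolve element for atom '%s' at line %d",
                  trimws(name_field[i]), lineno[i]))
  }
  el
}

#' Remove hydrogens, waters and alternate locations
#'
#' Applies the standard pre-tessellation filter: all hydrogen (and deuterium)
#' atoms are removed, as are atoms belonging to water residues (`HOH`, `WAT`,
#' `DOD`).  Alternate locations are collapsed to a single copy per atom,
#' keeping the highest-occupancy conformer (ties broken by alphabetically
#' first altloc identifier).  Idempotent.
#'
#' @param s An `fb_structure` tibble from [parse_structure()].
#' @return The filtered structure; `attr(, "filter_log")` records the number
#'   of atoms removed by each rule (`hydrogens`, `waters`, `altlocs`).
#' @export
filter_structure <- function(s) {
  stopifnot(is.data.frame(s))
  n0 <- nrow(s)
  is_h <- s$element %in% c("H", "D", "T")
  s1 <- s[!is_h, , drop = FALSE]
  is_wat <- toupper(s1$resname) %in% c("HOH", "WAT", "DOD")
  s2 <- s1[!is_wat, , drop = FALSE]
  # altloc resolution: within each atom site keep max occupancy, tie -> first id
  s3 <- s2 %>%
    mutate(.ord = row_number()) %>%
    group_by(.data$chain, .data$resseq, .data$icode, .data$resname,
             .data$name) %>%
    arrange(desc(.data$occupancy), .data$altloc, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-".ord")
  log <- c(hydrogens = sum(is_h), waters = sum(is_wat),
           altlocs = nrow(s2) - nrow(s3))
  if (nrow(s3) == 0) {
    abort("structure is empty after hydrogen/water filtering")
  }
  new_structure(s3, source_id = attr(s, "source_id") %||% "structure",
                filter_log = log)
}

#' Describe the ligand to remove from a complex
#'
#' @param resname Residue name(s) identifying the ligand (e.g. `"NAG"`).
#' @param chain Optional chain identifier restricting the match.
#' @param resseq Optional residue-number vector (or range) restricting the
#'   match.
#' @return A `ligand_selector` object for use with [strip_ligand()] and
#'   [score_complex()].
#' @export
ligand_selector <- function(resname, chain = NULL, resseq = NULL) {
  stopifnot(is.character(resname), length(resname) >= 1)
  structure(list(resname = toupper(resname), chain = chain, resseq = resseq),
            class = "ligand_selector")
}

selector_matches <- function(s, sel) {
  m <- toupper(s$resname) %in% sel$resname
  if (!is.null(sel$chain)) m <- m & s$chain %in% sel$chain
  if (!is.null(sel$resseq)) {
    m <- m & s$resseq >= min(sel$resseq) & s$resseq <= max(sel$resseq)
  }
  m
}

#' Remove the ligand atoms from a filtered complex
#'
#' The binding-energy model scores a complex twice: once whole and once with
#' the ligand's atomic coordinates removed.  This performs the removal.
#'
#' @param s A filtered complex (`fb_structure`).
#' @param sel A [ligand_selector()].
#' @return A list with `protein` (the structure minus the ligand atoms) and
#'   `ligand_atom_count`.
#' @export
strip_ligand <- function(s, sel) {
  stopifnot(inherits(sel, "ligand_selector"))
  m <- selector_matches(s, sel)
  if (!any(m)) {
    abort(sprintf("ligand selector (resname %s) matches no atoms",
                  paste(sel$resname, collapse = "/")))
  }
  if (all(m)) {
    abort("ligand selector matches every atom; no protein would remain")
  }
  protein <- new_structure(s[!m, , drop = FALSE],
                           source_id = paste0(attr(s, "source_id") %||%
                                                "structure", ":protein"),
                           filter_log = attr(s, "filter_log"))
  list(protein = protein, ligand_atom_count = sum(m))
}

#' Write a structure back out as fixed-column PDB text
#'
#' Serials, residue numbering and coordinates are preserved as parsed, so a
#' parse/write round trip is byte-stable in the coordinate fields.
#'
#' @param s An `fb_structure` tibble.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the PDB lines.
#' @export
write_pdb <- function(s, path = NULL) {
  rec <- ifelse(s$is_het, "HETATM", "ATOM  ")
  # one-letter elements with short names start in column 14
  nm <- ifelse(nchar(s$name) < 4 & nchar(s$element) == 1,
               sprintf(" %-3s", s$name), sprintf("%-4s", s$name))
  lines <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, s$serial, nm, s$altloc, s$resname, s$chain, s$resseq, s$icode,
    s$x, s$y, s$z, s$occupancy, 0, s$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.fb_structure <- function(x, ...) {
  cat(sprintf("# %s: %d atoms\n", attr(x, "source_id") %||% "structure",
              nrow(x)))
  fl <- attr(x, "filter_log")
  if (!is.null(fl)) {
    cat(sprintf("# filtered: %s\n",
                paste(names(fl), fl, sep = "=", collapse = ", ")))
  }
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate matrix of a structure
#'
#' @param s An `fb_structure` tibble (or any data frame with `x`, `y`, `z`).
#' @return A numeric matrix with one row per atom.
#' @export
atom_coords <- function(s) {
  cbind(x = s$x, y = s$y, z = s$z)
}
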