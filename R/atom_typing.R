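#' The six-letter atomic alphabet
#'
#' Atoms are classified as carbon (`C`), nitrogen (`N`), oxygen (`O`),
#' sulfur (`S`), any metal (`M`), or any other non-metal (`X`).  The class
#' order used for canonical quadruplet keys is alphabetical:
#' `C < M < N < O < S < X`.
#'
#' @return Character vector of the six class letters in canonical order.
#' @export
atom_classes <- function() c("C", "M", "N", "O", "S", "X")

#' Metal elements mapped to class M
#'
#' An explicit, auditable list of the element symbols treated as metals:
#' alkali, alkaline-earth, transition and post-transition metals plus
#' lanthanides and actinides.  Metalloids (B, Si, Ge, As, Sb, Se, Te) are
#' classed as other non-metals (`X`).
#'
#' @return Character vector of uppercase element symbols.
#' @export
metal_elements <- function() {
  c("LI", "BE", "NA", "MG", "AL", "K", "CA", "SC", "TI", "V", "CR",
    "MN", "FE", "CO", "NI", "CU", "ZN", "GA", "RB", "SR", "Y", "ZR",
    "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN", "SN", "CS",
    "BA", "LA", "CE", "PR", "ND", "PM", "SM", "EU", "GD", "TB", "DY",
    "HO", "ER", "TM", "YB", "LU", "HF", "TA", "W", "RE", "OS", "IR",
    "PT", "AU", "HG", "TL", "PB", "BI", "PO", "FR", "RA", "AC", "TH",
    "PA", "U", "NP", "PU", "AM", "CM")
}

#' Classify elements into the six-letter alphabet
#'
#' @param element Character vector of element symbols (case-insensitive).
#'   Hydrogen and deuterium are rejected: they must be removed by
#'   [filter_structure()] before typing.
#' @param metals Character vector of element symbols treated as metals;
#'   override to move the metal/non-metal boundary.
#' @return Character vector of class letters (`C`, `N`, `O`, `S`, `M`, `X`).
#' @export
#' @examples
#' classify_atom(c("C", "ZN", "P", "SE"))
classify_atom <- function(element, metals = metal_elements()) {
  el <- toupper(element)
  if (any(el %in% c("H", "D", "T"))) {
    abort("hydrogen/deuterium atoms must be filtered out before classification")
  }
  unknown <- !(el %in% pdb_elements())
  if (any(unknown)) {
    abort(sprintf("unknown element symbol: '%s'", el[which(unknown)[1]]))
  }
  out <- rep("X", length(el))
  out[el %in% c("C", "N", "O", "S")] <- el[el %in% c("C", "N", "O", "S")]
  out[el %in% toupper(metals)] <- "M"
  out
}

#' Atomic composition vector
#'
#' Computes the relative frequency `a_n` of each atom class from raw counts.
#' These frequencies parameterize the multinomial background distribution of
#' [expected_probability()]; they are kept at full precision internally
#' (displayed values are conventionally rounded to 6 decimal places).
#'
#' @param counts Named numeric vector of per-class counts (names among the
#'   six class letters; missing classes count 0), or a data frame with
#'   columns `class` and `count`.
#' @return A tibble with columns `class`, `count`, `a` (relative frequency),
#'   carrying the total count as attribute `total`.
#' @export
#' @examples
#' composition(c(C = 3, N = 1))
composition <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$class)
  }
  cls <- atom_classes()
  bad <- setdiff(names(counts), cls)
  if (length(bad) > 0) {
    abort(sprintf("unknown atom class in counts: %s",
                  paste(bad, collapse = ", ")))
  }
  full <- setNames(numeric(6), cls)
  full[names(counts)] <- full[names(counts)] + as.numeric(counts)
  if (any(full < 0)) abort("negative class counts")
  total <- sum(full)
  if (total <= 0) abort("composition requires a positive total atom count")
  out <- tibble(class = cls, count = unname(full), a = unname(full) / total)
  attr(out, "total") <- total
  out
}

#' Composition of a structure's atoms
#'
#' @param s A filtered `fb_structure`.
#' @inheritParams classify_atom
#' @return A composition tibble as from [composition()].
#' @export
structure_composition <- function(s, metals = metal_elements()) {
  cls <- classify_atom(s$element, metals = metals)
  composition(table(factor(cls, levels = atom_classes())))
}
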