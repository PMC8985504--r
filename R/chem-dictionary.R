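#' Chemical dictionary of charged residues and metals
#'
#' The dictionary names the ligand residue codes treated as anions (with the
#' atom names carrying the formal charge), the element symbols treated as
#' metal cations, and the subsets of anion codes whose charged group is planar
#' (trigonal carboxylate/nitrate-like) or linear.  Amino-acid carboxylates
#' (Asp, Glu, C-terminal), and nucleotide phosphates are recognised by
#' [detect_anion_sites()] independently of this dictionary.
#'
#' The shipped defaults cover the common crystallisation and biological anions:
#' sulfate (SO4), phosphate (PO4), acetate (ACT/ACY), formate (FMT), nitrate
#' (NO3), citrate (CIT), malonate (MLI) and the halides Cl-, Br-, I-, F-.
#'
#' @param anion_residues named list, residue code -> character vector of
#'   anionic atom names. Monoatomic entries list exactly one atom.
#' @param metal_elements character vector of element symbols counted as
#'   cationic metals.
#' @param planar_anion_codes codes whose site atoms plus the central atom form
#'   a trigonal planar group; a plane is fitted for these.
#' @param linear_anion_codes codes with a linear charged group (none shipped).
#' @param planar_centers named list, code -> central atom name used when
#'   fitting the anion plane.
#' @return An object of class `chem_dictionary`.
#' @examples
#' d <- default_chem_dictionary()
#' d$anion_residues$SO4
#' @export
default_chem_dictionary <- function(anion_residues = NULL,
                                    metal_elements = NULL,
                                    planar_anion_codes = NULL,
                                    linear_anion_codes = character(),
                                    planar_centers = NULL) {
  if (is.null(anion_residues)) {
    anion_residues <- list(
      SO4 = c("O1", "O2", "O3", "O4"),
      PO4 = c("O1", "O2", "O3", "O4"),
      ACT = c("O", "OXT"),
      ACY = c("O", "OXT"),
      FMT = c("O1", "O2"),
      NO3 = c("O1", "O2", "O3"),
      CIT = c("O1", "O2", "O3", "O4", "O5", "O6"),
      MLI = c("O1", "O2", "O3", "O4"),
      CL  = "CL",
      BR  = "BR",
      IOD = "I",
      F   = "F"
    )
  }
  if (is.null(metal_elements)) {
    metal_elements <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                        "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL",
                        "V", "CR", "MO", "W", "PT", "PD", "AU", "AG", "PB",
                        "GA", "TL", "Y", "LA", "CE", "GD", "YB", "LU")
  }
  if (is.null(planar_anion_codes)) {
    planar_anion_codes <- c("ACT", "ACY", "FMT", "NO3")
  }
  if (is.null(planar_centers)) {
    planar_centers <- list(ACT = "C", ACY = "C", FMT = "C", NO3 = "N")
  }
  stopifnot(all(lengths(anion_residues) >= 1))
  mono <- names(anion_residues)[lengths(anion_residues) == 1]
  d <- list(
    anion_residues = anion_residues,
    metal_elements = toupper(metal_elements),
    planar_anion_codes = planar_anion_codes,
    linear_anion_codes = linear_anion_codes,
    monoatomic_codes = mono,
    planar_centers = planar_centers
  )
  class(d) <- "chem_dictionary"
  d
}

#' Read or write a chemical dictionary as a YAML config file
#'
#' @param path file path.
#' @return `read_chem_dictionary()` returns a `chem_dictionary`;
#'   `write_chem_dictionary()` returns `path` invisibly.
#' @export
read_chem_dictionary <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read dictionary config files")
  }
  cfg <- yaml::read_yaml(path)
  default_chem_dictionary(
    anion_residues = lapply(cfg$anion_residues, as.character),
    metal_elements = cfg$metal_elements,
    planar_anion_codes = cfg$planar_anion_codes,
    linear_anion_codes = as.character(cfg$linear_anion_codes),
    planar_centers = cfg$planar_centers
  )
}

#' @rdname read_chem_dictionary
#' @param dict a `chem_dictionary`.
#' @export
write_chem_dictionary <- function(dict, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write dictionary config files")
  }
  yaml::write_yaml(unclass(dict)[c("anion_residues", "metal_elements",
                                   "planar_anion_codes", "linear_anion_codes",
                                   "planar_centers")], path)
  invisible(path)
}

# ---- residue classification tables ------------------------------------------

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.RNA3 <- c("A", "G", "C", "U", "I")
.DNA3 <- c("DA", "DG", "DC", "DT", "DU", "DI")
.WATER3 <- c("HOH", "WAT", "DOD", "H2O")

#' Classify a residue code into a polymer class
#'
#' @param resid character vector of 3-letter (or ligand) residue codes.
#' @param n_atoms optional integer vector of heavy-atom counts, used to tell
#'   monoatomic ions from ligands.
#' @param elements optional element symbol of the single atom (for ions).
#' @param metals element symbols counted as metals.
#' @return character vector in `{amino-acid, ribonucleotide,
#'   deoxyribonucleotide, water, ion, ligand}`.
#' @export
polymer_class <- function(resid, n_atoms = NULL, elements = NULL,
                          metals = default_chem_dictionary()$metal_elements) {
  out <- rep("ligand", length(resid))
  out[resid %in% .AA3] <- "amino-acid"
  out[resid %in% .RNA3] <- "ribonucleotide"
  out[resid %in% .DNA3] <- "deoxyribonucleotide"
  out[resid %in% .WATER3] <- "water"
  if (!is.null(n_atoms) && !is.null(elements)) {
    ion <- out == "ligand" & n_atoms == 1L &
      (toupper(elements) %in% metals |
         resid %in% c("CL", "BR", "IOD", "F"))
    out[ion] <- "ion"
  }
  out
}
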