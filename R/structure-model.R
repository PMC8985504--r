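#' Construct a structure model from an atom table
#'
#' The in-memory representation of one macromolecular model: a flat atom table
#' (bio3d-style column names) plus entry-level metadata.  Exactly one
#' coordinate model is retained and, after construction, no residue carries
#' two atoms with the same name (the alternate-location policy has been
#' applied).
#'
#' @param atom data.frame with columns `eleno`, `elety` (atom name), `elesy`
#'   (element), `alt`, `resid` (residue code), `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `o` (occupancy), `type` (`"ATOM"`/`"HETATM"`).
#' @param pdb_id 4-character entry code (or any identifier).
#' @param resolution resolution in Angstrom, or `NA` when the experiment does
#'   not define one (e.g. solution NMR).
#' @param experiment_method free-text method string.
#' @param model_number which model of the deposition these coordinates are.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atom, pdb_id = "XXXX", resolution = NA_real_,
                            experiment_method = NA_character_,
                            model_number = 1L) {
  need <- c("eleno", "elety", "elesy", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "type")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atom) == 0L) stop("empty model: no atoms")
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atom$o < 0 | atom$o > 1, na.rm = TRUE)) stop("occupancy outside [0,1]")
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be > 0")
  m <- list(pdb_id = pdb_id, atom = atom, resolution = resolution,
            experiment_method = experiment_method,
            model_number = as.integer(model_number))
  class(m) <- "structure_model"
  m
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("structure_model %s: %d atoms, %d residues, %d chain(s)",
              x$pdb_id, nrow(x$atom), nrow(rt), length(unique(x$atom$chain))))
  cat(sprintf(", resolution %s\n",
              if (is.na(x$resolution)) "n/a" else sprintf("%.2f A", x$resolution)))
  invisible(x)
}

# unique residue key used throughout: chain|resno|insert|resid
.res_key <- function(chain, resno, insert, resid) {
  ins <- ifelse(is.na(insert) | insert == "", "", as.character(insert))
  paste(chain, resno, ins, resid, sep = "|")
}

#' Residue-level summary of a structure model
#'
#' @param m a `structure_model`.
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `resid`, `class` (polymer class) and `natoms`.
#' @export
residue_table <- function(m) {
  a <- m$atom
  key <- .res_key(a$chain, a$resno, a$insert, a$resid)
  first <- !duplicated(key)
  natoms <- as.vector(table(key)[key[first]])
  rt <- data.frame(key = key[first], chain = a$chain[first],
                   resno = a$resno[first], insert = a$insert[first],
                   resid = a$resid[first], natoms = natoms,
                   stringsAsFactors = FALSE)
  el1 <- a$elesy[first]
  rt$class <- polymer_class(rt$resid, rt$natoms, el1)
  rt
}

# ---- reading ----------------------------------------------------------------

# keep, per (residue, atom name), the highest-occupancy altloc;
# ties broken by the lexicographically smallest altloc code
.apply_altloc_policy <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  akey <- paste(.res_key(atom$chain, atom$resno, atom$insert, atom$resid),
                atom$elety, sep = "|")
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  ord <- order(akey, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(akey[ord]), , drop = FALSE]
  atom[order(atom$eleno), , drop = FALSE]
}

.scan_cif_meta <- function(lines) {
  res <- NA_real_
  hit <- grep("^_refine\\.ls_d_res_high", lines, value = TRUE)
  if (length(hit)) {
    v <- suppressWarnings(as.numeric(sub("^\\S+\\s+", "", hit[1])))
    if (length(v) && is.finite(v)) res <- v
  }
  id <- NA_character_
  hit <- grep("^_entry\\.id", lines, value = TRUE)
  if (length(hit)) id <- sub("^\\S+\\s+", "", hit[1])
  meth <- NA_character_
  hit <- grep("^_exptl\\.method", lines, value = TRUE)
  if (length(hit)) meth <- gsub("'", "", sub("^\\S+\\s+", "", hit[1]))
  list(resolution = res, pdb_id = id, method = meth)
}

.scan_pdb_meta <- function(lines) {
  res <- NA_real_
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(hit)) {
    v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1",
                                         hit[1])))
    if (length(v) && is.finite(v)) res <- v
  }
  id <- NA_character_
  hit <- grep("^HEADER", lines, value = TRUE)
  if (length(hit) && nchar(hit[1]) >= 66) id <- trimws(substr(hit[1], 63, 66))
  meth <- NA_character_
  hit <- grep("^EXPDTA", lines, value = TRUE)
  if (length(hit)) meth <- trimws(substr(hit[1], 11, nchar(hit[1])))
  list(resolution = res, pdb_id = id, method = meth)
}

#' Read a macromolecular structure from mmCIF or legacy PDB
#'
#' Parsing is delegated to \pkg{bio3d}.  The first coordinate model is
#' selected; for atoms with alternate locations only the highest-occupancy
#' altloc is retained (ties broken by the lexicographically smallest code);
#' the resolution is taken from the refinement record when present.
#'
#' @param path file path.
#' @param format `"mmCIF"`, `"PDB"`, or `"auto"` (by file extension:
#'   `.cif` is mmCIF, `.pdb`/`.ent` is legacy PDB).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "mmCIF", "PDB")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "mmCIF", pdb = , ent = "PDB",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  lines <- readLines(path, warn = FALSE)
  p <- tryCatch(
    if (format == "mmCIF") {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) stop("unreadable ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- p$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in '", path, "'")
  atom <- data.frame(
    eleno = as.integer(a$eleno), elety = a$elety, elesy = toupper(a$elesy),
    alt = a$alt, resid = a$resid, chain = a$chain,
    resno = as.integer(a$resno), insert = a$insert,
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), type = a$type,
    stringsAsFactors = FALSE
  )
  atom <- .apply_altloc_policy(atom)
  meta <- if (format == "mmCIF") .scan_cif_meta(lines) else .scan_pdb_meta(lines)
  id <- meta$pdb_id
  if (is.na(id) || !nzchar(id)) {
    id <- toupper(tools::file_path_sans_ext(basename(path)))
  }
  structure_model(atom, pdb_id = id, resolution = meta$resolution,
                  experiment_method = meta$method, model_number = 1L)
}

#' Resolution filter
#'
#' `TRUE` iff the model has a recorded resolution better than or equal to the
#' cutoff.  Models without a resolution record (e.g. pure solution NMR) fail
#' the filter under the default policy; set `keep_unresolved = TRUE` to keep
#' them.
#'
#' @param m a `structure_model`.
#' @param cutoff resolution cutoff in Angstrom (default 2.5).
#' @param keep_unresolved keep models with no resolution record?
#' @return logical scalar.
#' @export
filter_by_resolution <- function(m, cutoff = 2.5, keep_unresolved = FALSE) {
  stopifnot(cutoff > 0)
  if (is.na(m$resolution)) return(isTRUE(keep_unresolved))
  m$resolution <= cutoff
}

#' Classify the polymer content of a structure
#'
#' The label is the set of polymer types present: a single docked nucleotide
#' suffices to flag the nucleic component of a complex, and vice versa.
#'
#' @param m a `structure_model`.
#' @return one of `"protein"`, `"RNA"`, `"DNA"`, `"protein-RNA"`,
#'   `"protein-DNA"`, `"RNA-DNA"`, `"protein-RNA-DNA"`, `"other"`.
#' @export
classify_structure_type <- function(m) {
  rt <- residue_table(m)
  types <- character()
  if (any(rt$class == "amino-acid")) types <- c(types, "protein")
  if (any(rt$class == "ribonucleotide")) types <- c(types, "RNA")
  if (any(rt$class == "deoxyribonucleotide")) types <- c(types, "DNA")
  if (!length(types)) return("other")
  paste(types, collapse = "-")
}
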