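#' @name chem_perception
#' @title Perception of rings, charged sites, donors and methyls
#' @description
#' Aromatic rings of the standard residues are found by atom-name templates;
#' rings of arbitrary ligands by cycle perception on the intra-residue
#' covalent graph.  Anion and cation sites combine built-in rules for the
#' biopolymer groups (Asp/Glu and C-terminal carboxylates, nucleotide
#' phosphates, Arg/Lys side chains) with a user-editable
#' [default_chem_dictionary()] for ligand ions.
NULL

# single-bond covalent radii (Angstrom); generous default for other elements
.COV_RAD <- c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
              P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
              B = 0.84, SI = 1.11)
.cov_rad <- function(el) {
  r <- .COV_RAD[toupper(el)]
  r[is.na(r)] <- 1.4
  unname(r)
}

.is_hydrogen <- function(elesy) toupper(elesy) %in% c("H", "D")

# ring atom-name templates; each entry: list(id, atoms (cyclic order))
.RING_TEMPLATES <- list(
  PHE = list(list(id = "6", atoms = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))),
  TYR = list(list(id = "6", atoms = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))),
  HIS = list(list(id = "5", atoms = c("CG", "ND1", "CE1", "NE2", "CD2"))),
  TRP = list(list(id = "5", atoms = c("CG", "CD1", "NE1", "CE2", "CD2")),
             list(id = "6", atoms = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))
)
.PURINE_RINGS <- list(
  list(id = "6", atoms = c("N1", "C2", "N3", "C4", "C5", "C6")),
  list(id = "5", atoms = c("C4", "C5", "N7", "C8", "N9"))
)
.PYRIMIDINE_RINGS <- list(
  list(id = "6", atoms = c("N1", "C2", "N3", "C4", "C5", "C6"))
)
.PURINES <- c("A", "G", "I", "DA", "DG", "DI")
.PYRIMIDINES <- c("C", "U", "DC", "DT", "DU")

.max_plane_dev <- function(coords) {
  fr <- ring_frame(coords)
  max(abs(as.vector(sweep(coords, 2, fr$centroid) %*% fr$normal)))
}

.mk_ring <- function(atom, idx, res_row, id, ring_class, res_rows = idx) {
  heavy <- res_rows[!.is_hydrogen(atom$elesy[res_rows])]
  r <- list(atom_idx = idx,
            coords = as.matrix(atom[idx, c("x", "y", "z")]),
            parent_coords = as.matrix(atom[heavy, c("x", "y", "z")]),
            names = atom$elety[idx],
            resid = res_row$resid, chain = res_row$chain,
            resno = res_row$resno, insert = res_row$insert,
            res_key = res_row$key,
            ring_class = ring_class,
            ring_code = paste0(res_row$resid, ".", id),
            size = length(idx))
  class(r) <- "aromatic_ring"
  r
}

#' Detect aromatic rings
#'
#' Template hits for Phe, Tyr, Trp (two rings), His, and the purine (6- and
#' 5-membered, reported separately) and pyrimidine nucleobases; ligand rings
#' are found by 5/6-cycle perception on the intra-residue covalent graph
#' (bond when the interatomic distance is below the covalent-radius sum plus
#' `bond_slack`).  Candidate rings must be planar (maximum member deviation
#' from the least-squares plane at most `planarity_tol`), contain only
#' C/N/O/S, and every member must have at most 3 heavy-atom neighbours.
#'
#' @param m a `structure_model`.
#' @param planarity_tol maximum out-of-plane deviation in Angstrom.
#' @param bond_slack covalent bond inference slack in Angstrom.
#' @return list of `aromatic_ring` objects.
#' @export
detect_aromatic_rings <- function(m, planarity_tol = 0.10, bond_slack = 0.45) {
  atom <- m$atom
  rkey <- .res_key(atom$chain, atom$resno, atom$insert, atom$resid)
  rt <- residue_table(m)
  rings <- list()
  for (i in seq_len(nrow(rt))) {
    rr <- rt[i, ]
    if (rr$class %in% c("water", "ion")) next
    rows <- which(rkey == rr$key)
    templ <- NULL
    cls <- NULL
    if (rr$class == "amino-acid" && rr$resid %in% names(.RING_TEMPLATES)) {
      templ <- .RING_TEMPLATES[[rr$resid]]; cls <- "amino-acid"
    } else if (rr$class %in% c("ribonucleotide", "deoxyribonucleotide")) {
      templ <- if (rr$resid %in% .PURINES) .PURINE_RINGS else
        if (rr$resid %in% .PYRIMIDINES) .PYRIMIDINE_RINGS else NULL
      cls <- rr$class
    }
    if (!is.null(templ)) {
      for (tp in templ) {
        idx <- rows[match(tp$atoms, atom$elety[rows])]
        if (anyNA(idx)) {
          message("ring skipped (missing atoms): ", rr$key, " [", tp$id, "]")
          next
        }
        co <- as.matrix(atom[idx, c("x", "y", "z")])
        if (.max_plane_dev(co) > planarity_tol) next
        rings[[length(rings) + 1L]] <- .mk_ring(atom, idx, rr, tp$id, cls,
                                                res_rows = rows)
      }
    } else if (rr$class %in% c("ligand", "amino-acid")) {
      # generic perception (ligands, and non-aromatic AAs carry no rings)
      if (rr$class == "amino-acid") next
      rings <- c(rings, .perceive_ligand_rings(atom, rows, rr, planarity_tol,
                                               bond_slack))
    }
  }
  rings
}

.perceive_ligand_rings <- function(atom, rows, res_row, planarity_tol,
                                   bond_slack) {
  heavy <- rows[!.is_hydrogen(atom$elesy[rows])]
  n <- length(heavy)
  if (n < 5) return(list())
  co <- as.matrix(atom[heavy, c("x", "y", "z")])
  el <- atom$elesy[heavy]
  d <- as.matrix(stats::dist(co))
  thr <- outer(.cov_rad(el), .cov_rad(el), "+") + bond_slack
  adj <- d < thr & d > 0.1
  nbr_count <- rowSums(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  out <- list()
  seen <- character()
  for (k in c(5L, 6L)) {
    iso <- igraph::subgraph_isomorphisms(igraph::make_ring(k), g,
                                         method = "vf2")
    for (mp in iso) {
      v <- as.integer(mp)
      key <- paste(sort(v), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (!all(el[v] %in% c("C", "N", "O", "S"))) next
      if (any(nbr_count[v] > 3)) next
      if (.max_plane_dev(co[v, , drop = FALSE]) > planarity_tol) next
      out[[length(out) + 1L]] <- .mk_ring(atom, heavy[v], res_row,
                                          paste0("L", length(out) + 1L),
                                          "ligand", res_rows = heavy)
    }
  }
  out
}

# ---- anion sites ------------------------------------------------------------

.fit_site_plane <- function(coords) {
  fr <- ring_frame(coords)  # least-squares plane; works for any >=3 points
  list(point = fr$centroid, normal = fr$normal)
}

.mk_anion <- function(atom, idx, res_row, planarity, plane = NULL,
                      site_class) {
  s <- list(site_idx = idx,
            site_names = atom$elety[idx],
            coords = matrix(as.matrix(atom[idx, c("x", "y", "z")]), ncol = 3),
            resid = res_row$resid, chain = res_row$chain,
            resno = res_row$resno, insert = res_row$insert,
            res_key = res_row$key,
            planarity = planarity, plane = plane,
            metal_bound = FALSE, site_class = site_class)
  class(s) <- "anion_site"
  s
}

#' Detect anionic sites
#'
#' Emits one site per charged group: Asp/Glu side-chain carboxylates,
#' C-terminal carboxylates (residues bearing `OXT`), the charged phosphate
#' oxygens of nucleotides (`OP1`/`OP2` and aliases, plus a free `OP3`;
#' ester oxygens excluded), and dictionary ligand anions.  Trigonal
#' carboxylate/nitrate-like groups carry a fitted plane; a site is flagged
#' `metal_bound` when any of its atoms lies within `metal_cut` of a metal.
#'
#' @param m a `structure_model`.
#' @param dict a [default_chem_dictionary()].
#' @param metal_cut metal contact distance in Angstrom (default 3.0).
#' @return list of `anion_site` objects.
#' @export
detect_anion_sites <- function(m, dict = default_chem_dictionary(),
                               metal_cut = 3.0) {
  atom <- m$atom
  rkey <- .res_key(atom$chain, atom$resno, atom$insert, atom$resid)
  rt <- residue_table(m)
  sites <- list()
  pick <- function(rows, nms) rows[stats::na.omit(match(nms, atom$elety[rows]))]
  for (i in seq_len(nrow(rt))) {
    rr <- rt[i, ]
    rows <- which(rkey == rr$key)
    if (rr$class == "amino-acid") {
      if (rr$resid == "ASP") {
        idx <- pick(rows, c("OD1", "OD2")); cidx <- pick(rows, "CG")
        if (length(idx) == 2 && length(cidx) == 1) {
          pl <- .fit_site_plane(as.matrix(atom[c(cidx, idx), c("x", "y", "z")]))
          sites[[length(sites) + 1L]] <-
            .mk_anion(atom, idx, rr, "planar", pl, "carboxylate")
        } else message("anion site skipped (missing atoms): ", rr$key)
      }
      if (rr$resid == "GLU") {
        idx <- pick(rows, c("OE1", "OE2")); cidx <- pick(rows, "CD")
        if (length(idx) == 2 && length(cidx) == 1) {
          pl <- .fit_site_plane(as.matrix(atom[c(cidx, idx), c("x", "y", "z")]))
          sites[[length(sites) + 1L]] <-
            .mk_anion(atom, idx, rr, "planar", pl, "carboxylate")
        } else message("anion site skipped (missing atoms): ", rr$key)
      }
      oxt <- pick(rows, "OXT")
      if (length(oxt) == 1) {
        idx <- pick(rows, c("O", "OXT")); cidx <- pick(rows, "C")
        if (length(idx) == 2 && length(cidx) == 1) {
          pl <- .fit_site_plane(as.matrix(atom[c(cidx, idx), c("x", "y", "z")]))
          sites[[length(sites) + 1L]] <-
            .mk_anion(atom, idx, rr, "planar", pl, "c-terminus")
        }
      }
    } else if (rr$class %in% c("ribonucleotide", "deoxyribonucleotide")) {
      idx <- pick(rows, c("OP1", "OP2", "O1P", "O2P", "OP3", "O3P"))
      if (length(idx)) {
        sites[[length(sites) + 1L]] <- .mk_anion(atom, idx, rr, "other",
                                                 NULL, "phosphate")
      }
    } else if (rr$resid %in% names(dict$anion_residues)) {
      nms <- dict$anion_residues[[rr$resid]]
      idx <- pick(rows, nms)
      if (!length(idx)) {
        message("anion site skipped (dictionary atoms missing): ", rr$key)
        next
      }
      planarity <- if (rr$resid %in% dict$monoatomic_codes) "monoatomic"
        else if (rr$resid %in% dict$linear_anion_codes) "linear"
        else if (rr$resid %in% dict$planar_anion_codes) "planar"
        else "other"
      pl <- NULL
      if (planarity == "planar") {
        ctr <- dict$planar_centers[[rr$resid]]
        cidx <- if (!is.null(ctr)) pick(rows, ctr) else integer()
        pts <- as.matrix(atom[c(cidx, idx), c("x", "y", "z")])
        if (nrow(pts) >= 3) pl <- .fit_site_plane(pts) else planarity <- "other"
      }
      sites[[length(sites) + 1L]] <- .mk_anion(atom, idx, rr, planarity, pl,
                                               "ligand")
    }
  }
  # metal proximity flag
  metal_rows <- which(toupper(atom$elesy) %in% dict$metal_elements)
  if (length(metal_rows) && length(sites)) {
    mco <- as.matrix(atom[metal_rows, c("x", "y", "z")])
    for (j in seq_along(sites)) {
      dmin <- min(apply(sites[[j]]$coords, 1, function(p) {
        min(sqrt(colSums((t(mco) - p)^2)))
      }))
      sites[[j]]$metal_bound <- dmin <= metal_cut
    }
  }
  sites
}

# ---- cation sites -----------------------------------------------------------

#' Detect cationic sites
#'
#' One site per metal atom (iron-sulphur cluster irons are emitted as
#' individual metal sites), plus one per Arg guanidinium (position `CZ`) and
#' Lys ammonium (position `NZ`).
#'
#' @inheritParams detect_anion_sites
#' @return list of `cation_site` objects with fields `kind`
#'   (`metal`/`Arg-guanidinium`/`Lys-ammonium`), `position`, `element`,
#'   `res_key`, `atom_idx`.
#' @export
detect_cation_sites <- function(m, dict = default_chem_dictionary()) {
  atom <- m$atom
  rkey <- .res_key(atom$chain, atom$resno, atom$insert, atom$resid)
  out <- list()
  metal_rows <- which(toupper(atom$elesy) %in% dict$metal_elements)
  for (i in metal_rows) {
    out[[length(out) + 1L]] <- structure(
      list(kind = "metal", element = toupper(atom$elesy[i]),
           position = c(atom$x[i], atom$y[i], atom$z[i]),
           res_key = rkey[i], atom_idx = i),
      class = "cation_site")
  }
  side <- which(atom$resid %in% c("ARG", "LYS") &
                  atom$elety %in% c("CZ", "NZ"))
  for (i in side) {
    if (atom$resid[i] == "ARG" && atom$elety[i] != "CZ") next
    if (atom$resid[i] == "LYS" && atom$elety[i] != "NZ") next
    out[[length(out) + 1L]] <- structure(
      list(kind = if (atom$resid[i] == "ARG") "Arg-guanidinium"
             else "Lys-ammonium",
           element = NA_character_,
           position = c(atom$x[i], atom$y[i], atom$z[i]),
           res_key = rkey[i], atom_idx = i),
      class = "cation_site")
  }
  out
}

# ---- hydrogen-bond donors ---------------------------------------------------

#' Detect hydrogen-bond donor sites
#'
#' Every N/O/S heavy atom with at least one covalently attached hydrogen
#' (within `h_bond_max` Angstrom) becomes a donor.  Ligand donors are found
#' only when the file carries their hydrogens; [add_amino_acid_hydrogens()]
#' supplies the standard amino-acid polar hydrogens otherwise.
#'
#' @param m a `structure_model`.
#' @param h_bond_max covalent H attachment cutoff in Angstrom.
#' @return list of donor sites: `atom_idx`, `position`, `h_pos` (matrix of
#'   attached hydrogen coordinates), `res_key`, `resid`, `name`.
#' @export
detect_h_donors <- function(m, h_bond_max = 1.3) {
  atom <- m$atom
  rkey <- .res_key(atom$chain, atom$resno, atom$insert, atom$resid)
  hrow <- which(.is_hydrogen(atom$elesy))
  if (!length(hrow)) return(list())
  heavy <- which(atom$elesy %in% c("N", "O", "S"))
  if (!length(heavy)) return(list())
  hco <- as.matrix(atom[hrow, c("x", "y", "z")])
  out <- list()
  for (i in heavy) {
    p <- c(atom$x[i], atom$y[i], atom$z[i])
    dd <- sqrt(colSums((t(hco) - p)^2))
    att <- which(dd <= h_bond_max)
    if (!length(att)) next
    out[[length(out) + 1L]] <- list(
      atom_idx = i, position = p,
      h_pos = hco[att, , drop = FALSE],
      res_key = rkey[i], resid = atom$resid[i], name = atom$elety[i])
  }
  out
}

# ---- methyl groups ----------------------------------------------------------

.METHYLS <- list(VAL = c("CG1", "CG2"), THR = "CG2", ALA = "CB",
                 LEU = c("CD1", "CD2"), ILE = c("CG2", "CD1"))

#' Detect methyl groups of the aliphatic amino acids
#'
#' Methyl carbons of valine, threonine, alanine, leucine and isoleucine,
#' identified by atom name (hydrogens implicit).
#'
#' @param m a `structure_model`.
#' @return list of sites: `atom_idx`, `position`, `res_key`, `resid`, `name`.
#' @export
detect_methyl_sites <- function(m) {
  atom <- m$atom
  rkey <- .res_key(atom$chain, atom$resno, atom$insert, atom$resid)
  out <- list()
  idx <- which(atom$resid %in% names(.METHYLS))
  for (i in idx) {
    if (!(atom$elety[i] %in% .METHYLS[[atom$resid[i]]])) next
    out[[length(out) + 1L]] <- list(
      atom_idx = i, position = c(atom$x[i], atom$y[i], atom$z[i]),
      res_key = rkey[i], resid = atom$resid[i], name = atom$elety[i])
  }
  out
}
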