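#' @name synthetic_fixtures
#' @title Synthetic structures with exactly known geometry
#' @description
#' Builders for small synthetic structures in which rings, anions, cations,
#' donors, methyls and secondary rings sit at prescribed `(x, h, azimuth,
#' side)` positions around a primary aromatic ring, so that every stage of
#' the mining pipeline can be verified against planted ground truth without
#' downloading real structures.  Idealised residue template geometries are
#' embedded; fixtures are deliberately minimal scaffolds, not physically
#' refined models.
NULL

# ---- local RNG scope --------------------------------------------------------

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# ---- idealised templates (ring plane = z = 0, centroid at origin) -----------

.polygon <- function(n, side, start_deg = 180) {
  r <- side / (2 * sin(pi / n))
  th <- (start_deg - 360 / n * (seq_len(n) - 1)) * pi / 180
  cbind(r * cos(th), r * sin(th), 0)
}

# fuse a regular pentagon onto edge A-B of an existing ring; returns the three
# new vertices in order (bonded to A first)
.fuse_pentagon <- function(A, B) {
  M <- (A + B) / 2
  s <- sqrt(sum((A - B)^2))
  u <- .unit(M)                      # outward from the parent ring centre
  P <- M + (s / (2 * tan(pi / 5))) * u
  rot2 <- function(v, ang) {
    c(cos(ang) * v[1] - sin(ang) * v[2],
      sin(ang) * v[1] + cos(ang) * v[2], 0)
  }
  step <- 2 * pi / 5
  cand1 <- P + rot2(A - P, step)
  sgn <- if (sqrt(sum((cand1 - B)^2)) < 0.2) -step else step
  v1 <- P + rot2(A - P, sgn)
  v2 <- P + rot2(A - P, 2 * sgn)
  v3 <- P + rot2(A - P, 3 * sgn)
  rbind(v1, v2, v3)
}

.tdf <- function(names, coords, elesy = substr(names, 1, 1)) {
  data.frame(elety = names, elesy = elesy,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

# backbone + CB stub attached outward along -x, shared by the AA templates
.aa_stub <- function(xoff) {
  .tdf(c("CB", "CA", "N", "C", "O"),
       rbind(c(xoff, 0, 0),
             c(xoff - 0.9, 1.25, 0),
             c(xoff - 2.1, 1.05, 0.8),
             c(xoff - 1.4, 2.0, -1.1),
             c(xoff - 2.3, 2.8, -1.3)),
       elesy = c("C", "C", "N", "C", "O"))
}

.ring_template <- function(kind) {
  switch(kind,
    BNZ = list(atoms = .tdf(paste0("C", 1:6), .polygon(6, 1.39)),
               ring = paste0("C", 1:6), het = TRUE),
    PHE = ,
    TYR = {
      hex <- .polygon(6, 1.39)  # CG at 180 deg, so CB extends along -x
      at <- rbind(.tdf(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       hex[c(1, 2, 3, 4, 5, 6), , drop = FALSE]),
                  .aa_stub(-2.89))
      if (kind == "TYR") {
        at <- rbind(at, .tdf("OH", matrix(c(2.76, 0, 0), 1), "O"))
      }
      list(atoms = at, ring = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
           het = FALSE)
    },
    HIS = {
      pen <- .polygon(5, 1.37)
      at <- rbind(.tdf(c("CG", "ND1", "CE1", "NE2", "CD2"), pen,
                       c("C", "N", "C", "N", "C")),
                  .aa_stub(-2.67))
      list(atoms = at, ring = c("CG", "ND1", "CE1", "NE2", "CD2"),
           het = FALSE)
    },
    TRP = {
      hex <- .polygon(6, 1.39, start_deg = 180)
      nm6 <- c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")
      new <- .fuse_pentagon(hex[2, ], hex[1, ])  # edge CD2-CE2, CG next to CD2
      at <- rbind(.tdf(nm6, hex),
                  .tdf(c("CG", "CD1", "NE1"), new, c("C", "C", "N")),
                  .aa_stub(min(new[, 1]) - 1.3))
      list(atoms = at, ring = nm6, het = FALSE)
    },
    G = ,
    A = {
      hex <- .polygon(6, 1.39)
      nm6 <- c("C4", "C5", "C6", "N1", "C2", "N3")
      # imidazole ring C4-C5-N7-C8-N9 fused on the C4-C5 edge; N9 bonds C4
      at <- rbind(.tdf(nm6, hex, c("C", "C", "C", "N", "C", "N")),
                  .tdf(c("N9", "C8", "N7"),
                       .fuse_pentagon(hex[1, ], hex[2, ]),
                       c("N", "C", "N")))
      list(atoms = at, ring = nm6, het = FALSE)
    },
    U = ,
    C = {
      hex <- .polygon(6, 1.39)
      nm6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
      at <- .tdf(nm6, hex, c("N", "C", "N", "C", "C", "C"))
      list(atoms = at, ring = nm6, het = FALSE)
    },
    stop("unknown ring kind: ", kind)
  )
}

# anion group templates: anchor (nearest site atom) at the origin, the rest
# of the group extending towards +x, group plane = xy
.ANION_TEMPLATES <- list(
  CL = list(atoms = data.frame(elety = "CL", elesy = "CL",
                               x = 0, y = 0, z = 0), anchor = "CL"),
  ACT = list(atoms = .tdf(c("O", "C", "OXT", "CH3"),
                          rbind(c(0, 0, 0), c(1.25, 0, 0),
                                c(1.87, 1.08, 0), c(1.95, -1.25, 0))),
             anchor = "O"),
  FMT = list(atoms = .tdf(c("O1", "C", "O2"),
                          rbind(c(0, 0, 0), c(1.25, 0, 0), c(1.87, 1.08, 0))),
             anchor = "O1"),
  NO3 = list(atoms = .tdf(c("O1", "N", "O2", "O3"),
                          rbind(c(0, 0, 0), c(1.25, 0, 0),
                                c(1.875, 1.0825, 0), c(1.875, -1.0825, 0))),
             anchor = "O1"),
  SO4 = list(atoms = {
    s <- c(1.49, 0, 0)
    d <- rbind(c(1 / 3, 2 * sqrt(2) / 3, 0),
               c(1 / 3, -sqrt(2) / 3, sqrt(6) / 3),
               c(1 / 3, -sqrt(2) / 3, -sqrt(6) / 3))
    .tdf(c("O1", "S", "O2", "O3", "O4"),
         rbind(c(0, 0, 0), s, sweep(1.49 * d, 2, s, "+")))
  }, anchor = "O1")
)

.rot_axis <- function(coords, axis, angle_deg) {
  t(apply(coords, 1, .rodrigues, axis = axis, angle_deg = angle_deg))
}

# orient a template: map its +x to `xdir`, its z to the global z, then tilt
# the group plane by `plane_angle` degrees about xdir; translate to p
.place_template <- function(tmpl_xyz, p, xdir, plane_angle = 0) {
  xd <- .unit(c(xdir[1], xdir[2], 0))
  yd <- .cross(c(0, 0, 1), xd)
  R <- cbind(xd, yd, c(0, 0, 1))
  out <- t(R %*% t(as.matrix(tmpl_xyz)))
  if (plane_angle != 0) out <- .rot_axis(out, xd, plane_angle)
  sweep(out, 2, p, "+")
}

.atom_row <- function(eleno, elety, elesy, resid, chain, resno, xyz,
                      het = TRUE) {
  data.frame(eleno = eleno, elety = elety, elesy = elesy, alt = NA_character_,
             resid = resid, chain = chain, resno = resno,
             insert = NA_character_, x = xyz[1], y = xyz[2], z = xyz[3],
             o = 1, type = if (het) "HETATM" else "ATOM",
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic fixture
#'
#' @param ring_kind primary ring residue: `"BNZ"` (benzene-like ligand),
#'   `"PHE"`, `"TYR"`, `"HIS"`, `"TRP"`, `"G"`, `"A"`, `"U"`, `"C"`.
#' @param placements data.frame with columns `entity` (an anion code known
#'   to the dictionary, a cation element such as `"ZN"`, `"ring"`, `"donor"`
#'   or `"methyl"`), `x`, `h` (Angstrom), `azimuth` (degrees, `NA` =
#'   uniform-random under the seed), `side` (+1/-1) and `plane_angle`
#'   (degrees, for planar anions and secondary rings).
#' @param chain_context `NULL`, or `list(type = "helix", n_res, contacts)`
#'   (see [make_helix_fixture()]) or `list(type = "gnra", sequence,
#'   anion_pos, x, h)` (see [make_gnra_fixture()]).
#' @param seed integer; fixes all randomness.
#' @param resolution recorded resolution of the fixture in Angstrom.
#' @param pdb_id identifier written into the fixture.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(ring_kind = "BNZ", placements = NULL,
                         chain_context = NULL, seed = 1L, resolution = 2.0,
                         pdb_id = "FIX1") {
  if (is.null(placements)) {
    placements <- data.frame(entity = character(), x = numeric(),
                             h = numeric(), azimuth = numeric(),
                             side = integer(), plane_angle = numeric())
  }
  placements$azimuth <- if (is.null(placements$azimuth)) {
    rep(NA_real_, nrow(placements))
  } else placements$azimuth
  if (is.null(placements$side)) placements$side <- rep(1L, nrow(placements))
  if (is.null(placements$plane_angle)) {
    placements$plane_angle <- rep(0, nrow(placements))
  }
  if (nrow(placements) &&
      any(sqrt(placements$x^2 + placements$h^2) > 6)) {
    stop("placements must lie within 6 A of the ring centroid")
  }
  s <- list(ring_kind = ring_kind, placements = placements,
            chain_context = chain_context, seed = as.integer(seed),
            resolution = resolution, pdb_id = pdb_id)
  class(s) <- "fixture_spec"
  s
}

#' Build a synthetic structure from a fixture specification
#'
#' Returns a well-formed [structure_model()] (writable as mmCIF) together
#' with the ground-truth table of intended positions: for every placed
#' entity its `(x, h, side, azimuth, plane_angle)` and the region label its
#' coordinates imply.  Placements that bring two atoms of different entities
#' closer than 1 Angstrom are rejected.
#'
#' @param spec a [fixture_spec()].
#' @return list with `model` (a `structure_model`) and `truth` (data.frame).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    if (!is.null(spec$chain_context)) {
      cc <- spec$chain_context
      return(switch(cc$type,
        helix = make_helix_fixture(n_res = cc$n_res, contacts = cc$contacts,
                                   seed = spec$seed,
                                   resolution = spec$resolution,
                                   pdb_id = spec$pdb_id),
        gnra = make_gnra_fixture(sequence = cc$sequence,
                                 anion_pos = cc$anion_pos,
                                 x = cc$x, h = cc$h, seed = spec$seed,
                                 resolution = spec$resolution,
                                 pdb_id = spec$pdb_id),
        stop("unknown chain context: ", cc$type)))
    }
    tm <- .ring_template(spec$ring_kind)
    rows <- list()
    ent_of <- integer()
    add_entity <- function(df, resid, chain, resno, het) {
      n <- length(rows) + 1L
      rows[[n]] <<- data.frame(
        eleno = 0L, elety = df$elety, elesy = df$elesy, alt = NA_character_,
        resid = resid, chain = chain, resno = resno, insert = NA_character_,
        x = df$x, y = df$y, z = df$z, o = 1,
        type = if (het) "HETATM" else "ATOM", stringsAsFactors = FALSE)
      ent_of <<- c(ent_of, rep(n, nrow(df)))
    }
    add_entity(tm$atoms, spec$ring_kind, "A", 1L, tm$het)
    truth <- list()
    pl <- spec$placements
    anchor_pos <- NULL
    for (i in seq_len(nrow(pl))) {
      az <- pl$azimuth[i]
      if (is.na(az)) az <- stats::runif(1, 0, 360)
      th <- az * pi / 180
      p <- c(pl$x[i] * cos(th), pl$x[i] * sin(th), pl$side[i] * pl$h[i])
      xdir <- if (pl$x[i] > 1e-9) c(cos(th), sin(th), 0) else c(1, 0, 0)
      ent <- pl$entity[i]
      resno <- 100L + i
      if (ent %in% names(.ANION_TEMPLATES)) {
        at <- .ANION_TEMPLATES[[ent]]
        co <- .place_template(as.matrix(at$atoms[, c("x", "y", "z")]), p,
                              xdir, pl$plane_angle[i])
        df <- at$atoms; df$x <- co[, 1]; df$y <- co[, 2]; df$z <- co[, 3]
        add_entity(df, ent, "X", resno, het = TRUE)
        if (is.null(anchor_pos)) anchor_pos <- p
        # the anchor must remain the nearest site atom to the centroid
        site <- df[df$elesy %in% c("O", "CL", "BR", "I", "F"), , drop = FALSE]
        dall <- sqrt(site$x^2 + site$y^2 + site$z^2)
        if (any(dall < dall[site$elety == at$anchor] - 1e-9)) {
          stop("impossible placement: anchor atom of ", ent,
               " is not the nearest site atom")
        }
      } else if (ent == "ring") {
        co <- .place_template(as.matrix(.ring_template("BNZ")$atoms[, c("x", "y", "z")]),
                              p, xdir, pl$plane_angle[i])
        df <- .ring_template("BNZ")$atoms
        df$x <- co[, 1]; df$y <- co[, 2]; df$z <- co[, 3]
        add_entity(df, "BNZ", "X", resno, het = TRUE)
      } else if (ent == "donor") {
        aim <- if (!is.null(anchor_pos)) anchor_pos else c(0, 0, 0)
        u <- .unit(aim - p)
        df <- .tdf(c("C1", "O1", "HO1"),
                   rbind(p - 1.4 * u, p, p + 0.96 * u),
                   c("C", "O", "H"))
        add_entity(df, "MOH", "X", resno, het = TRUE)
      } else if (ent == "methyl") {
        stub <- .aa_stub(-1.54)
        co <- sweep(as.matrix(stub[, c("x", "y", "z")]),
                    2, c(-1.54, 0, 0), "-")     # CB at the origin
        co <- .place_template(co, p, -xdir)     # backbone points outward
        stub$x <- co[, 1]; stub$y <- co[, 2]; stub$z <- co[, 3]
        add_entity(stub, "ALA", "M", resno, het = FALSE)
      } else if (grepl("^[A-Z]{1,2}$", ent)) {
        df <- data.frame(elety = ent, elesy = ent, x = p[1], y = p[2],
                         z = p[3], stringsAsFactors = FALSE)
        add_entity(df, ent, "X", resno, het = TRUE)
      } else {
        stop("unknown placement entity: ", ent)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        entity = ent, chain = if (ent == "methyl") "M" else "X",
        resno = resno, x = pl$x[i], h = pl$h[i], side = pl$side[i],
        azimuth = az, plane_angle = pl$plane_angle[i],
        region = tryCatch(assign_region(pl$x[i], pl$h[i]),
                          error = function(e) "outside"),
        stringsAsFactors = FALSE)
    }
    atom <- do.call(rbind, rows)
    atom$eleno <- seq_len(nrow(atom))
    # clash check across entities
    if (length(rows) > 1L) {
      d <- as.matrix(stats::dist(atom[, c("x", "y", "z")]))
      same <- outer(ent_of, ent_of, "==")
      if (any(d[!same] < 1.0)) {
        stop("impossible placement: atoms of different entities closer than 1 A")
      }
    }
    list(model = structure_model(atom, pdb_id = spec$pdb_id,
                                 resolution = spec$resolution,
                                 experiment_method = "SYNTHETIC"),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame())
  })
}

# ---- chain-context fixtures -------------------------------------------------

#' Ideal-helix fixture with planted ring-anion contacts
#'
#' Builds an alpha-helix-like chain of alanines (backbone on an ideal helix:
#' 100 degrees twist and 1.5 Angstrom rise per residue).  Each contact turns
#' residue `ring_pos` into a Phe whose ring sits outside the helix body and
#' residue `anion_pos` into a Glu whose carboxylate is planted at the
#' prescribed `(x, h)` in that ring's frame, so the mined pair has
#' `delta = ring_pos - anion_pos` (the classic helix contact is
#' `anion_pos = ring_pos + 4`, one helical turn, giving delta = -4).
#'
#' @param n_res chain length.
#' @param contacts data.frame with columns `ring_pos`, `anion_pos` and
#'   optionally `x`, `h` (defaults 0.8 and 3.4: region A).
#' @param seed RNG seed (azimuths of the planted rings).
#' @param resolution,pdb_id fixture metadata.
#' @return list with `model` and `truth` (one row per contact, with the
#'   intended `x`, `h`, `region` and `delta`).
#' @export
make_helix_fixture <- function(n_res = 12L,
                               contacts = data.frame(ring_pos = 3L,
                                                     anion_pos = 7L),
                               seed = 1L, resolution = 2.0,
                               pdb_id = "HLX1") {
  if (is.null(contacts$x)) contacts$x <- rep(0.8, nrow(contacts))
  if (is.null(contacts$h)) contacts$h <- rep(3.4, nrow(contacts))
  .with_seed(seed, {
    helix_pt <- function(t) {
      c(2.3 * cos(100 * t * pi / 180), 2.3 * sin(100 * t * pi / 180), 1.5 * t)
    }
    rows <- list()
    eleno <- 0L
    add <- function(elety, elesy, resid, resno, p, chain = "A") {
      eleno <<- eleno + 1L
      rows[[length(rows) + 1L]] <<- .atom_row(eleno, elety, elesy, resid,
                                              chain, resno, p, het = FALSE)
    }
    resnames <- rep("ALA", n_res)
    resnames[contacts$ring_pos] <- "PHE"
    resnames[contacts$anion_pos] <- "GLU"
    ca <- lapply(seq_len(n_res), function(i) helix_pt(i))
    for (i in seq_len(n_res)) {
      add("N", "N", resnames[i], i, helix_pt(i - 0.35))
      add("CA", "C", resnames[i], i, ca[[i]])
      add("C", "C", resnames[i], i, helix_pt(i + 0.34))
      co <- helix_pt(i + 0.34)
      add("O", "O", resnames[i], i, co + 1.23 * .unit(c(co[1], co[2], 0)))
      if (resnames[i] == "ALA") {
        add("CB", "C", resnames[i], i,
            ca[[i]] + 1.54 * .unit(c(ca[[i]][1], ca[[i]][2], 0)))
      }
    }
    truth <- list()
    for (k in seq_len(nrow(contacts))) {
      ip <- contacts$ring_pos[k]; ia <- contacts$anion_pos[k]
      u <- .unit(c(ca[[ip]][1], ca[[ip]][2], 0))   # radially out of the helix
      centroid <- ca[[ip]] + 4.0 * u
      # ring plane normal along the helix axis; ring atoms in the xy-plane
      hex <- .polygon(6, 1.39)
      co <- sweep(hex, 2, centroid, "+")
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      add("CB", "C", "PHE", ip, ca[[ip]] + 1.54 * u)
      for (j in 1:6) add(nm[j], "C", "PHE", ip, co[j, ])
      az <- stats::runif(1, 0, 360) * pi / 180
      x0 <- contacts$x[k]; h0 <- contacts$h[k]
      p <- centroid + c(x0 * cos(az), x0 * sin(az), h0)
      xdir <- if (x0 > 1e-9) c(cos(az), sin(az), 0) else c(1, 0, 0)
      # carboxylate parallel to the ring plane, OE1 is the anchor
      tmpl <- rbind(OE1 = c(0, 0, 0), CD = c(1.25, 0, 0),
                    OE2 = c(1.87, 1.08, 0), CG = c(1.95, -1.25, 0))
      cog <- .place_template(tmpl, p, xdir, 0)
      add("CB", "C", "GLU", ia, ca[[ia]] + 1.54 *
            .unit(c(ca[[ia]][1], ca[[ia]][2], 0)))
      add("CG", "C", "GLU", ia, cog[4, ])
      add("CD", "C", "GLU", ia, cog[2, ])
      add("OE1", "O", "GLU", ia, cog[1, ])
      add("OE2", "O", "GLU", ia, cog[3, ])
      truth[[k]] <- data.frame(
        entity = "GLU", chain = "A", resno = ia, x = x0, h = h0,
        side = 1L, azimuth = az * 180 / pi, plane_angle = 0,
        region = assign_region(x0, h0), delta = ip - ia,
        stringsAsFactors = FALSE)
    }
    atom <- do.call(rbind, rows)
    list(model = structure_model(atom, pdb_id = pdb_id,
                                 resolution = resolution,
                                 experiment_method = "SYNTHETIC"),
         truth = do.call(rbind, truth))
  })
}

#' GNRA-like RNA tetraloop fixture
#'
#' Builds a short RNA chain (default sequence `GAGA`) whose first residue's
#' guanine ring sits at the origin and whose `anion_pos`-th residue carries
#' a phosphate with its `OP1` planted at the prescribed `(x, h)` in the
#' G ring frame; the remaining bases and phosphates are parked well outside
#' the search sphere.  With `anion_pos = 3` the mined pair has
#' `delta = -2` (the G-quadrupole/R-anion tetraloop motif); with
#' `anion_pos = 4`, `delta = -3` (the G/A variant).
#'
#' @param sequence character scalar over `A`, `C`, `G`, `U` (first residue
#'   should be `G` for the tetraloop motif).
#' @param anion_pos 1-based position of the phosphate-bearing residue.
#' @param x,h planted cylindrical position of `OP1` (defaults in region A).
#' @param seed RNG seed (azimuth).
#' @param resolution,pdb_id fixture metadata.
#' @return list with `model` and `truth`.
#' @export
make_gnra_fixture <- function(sequence = "GAGA", anion_pos = 3L,
                              x = 0.8, h = 3.3, seed = 1L,
                              resolution = 2.0, pdb_id = "GNR1") {
  bases <- strsplit(sequence, "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "U")), anion_pos <= length(bases))
  .with_seed(seed, {
    rows <- list()
    eleno <- 0L
    add <- function(elety, elesy, resid, resno, p) {
      eleno <<- eleno + 1L
      rows[[length(rows) + 1L]] <<- .atom_row(eleno, elety, elesy, resid,
                                              "R", resno, p, het = FALSE)
    }
    for (i in seq_along(bases)) {
      tm <- .ring_template(bases[i])
      off <- if (i == 1L) c(0, 0, 0) else c(10 + 7 * (i - 1), 8, 0)
      for (j in seq_len(nrow(tm$atoms))) {
        add(tm$atoms$elety[j], tm$atoms$elesy[j], bases[i], i,
            c(tm$atoms$x[j], tm$atoms$y[j], tm$atoms$z[j]) + off)
      }
      if (i > 1L) {
        # each later residue carries a phosphate; the anion residue's OP1 is
        # planted near the G1 ring, the others sit by their own base
        if (i == anion_pos) {
          az <- stats::runif(1, 0, 360) * pi / 180
          p <- c(x * cos(az), x * sin(az), h)
          xd <- if (x > 1e-9) c(cos(az), sin(az), 0) else c(1, 0, 0)
          tmpl <- rbind(OP1 = c(0, 0, 0), P = c(1.5, 0, 0),
                        OP2 = c(2.1, 1.3, 0))
          co <- .place_template(tmpl, p, xd, 0)
          add("P", "P", bases[i], i, co[2, ])
          add("OP1", "O", bases[i], i, co[1, ])
          add("OP2", "O", bases[i], i, co[3, ])
        } else {
          add("P", "P", bases[i], i, off + c(0, 4, 0))
          add("OP1", "O", bases[i], i, off + c(0.9, 5.1, 0))
          add("OP2", "O", bases[i], i, off + c(-0.9, 5.1, 0))
        }
      }
    }
    atom <- do.call(rbind, rows)
    truth <- data.frame(entity = bases[anion_pos], chain = "R",
                        resno = anion_pos, x = x, h = h, side = 1L,
                        plane_angle = 0,
                        region = assign_region(x, h),
                        delta = 1L - anion_pos, stringsAsFactors = FALSE)
    list(model = structure_model(atom, pdb_id = pdb_id,
                                 resolution = resolution,
                                 experiment_method = "SYNTHETIC"),
         truth = truth)
  })
}

# ---- writers ----------------------------------------------------------------

#' Write a structure model as minimal valid mmCIF
#'
#' Coordinates are written with six decimals, so fixture round-trips through
#' [read_structure()] preserve planted geometry to 1e-6 Angstrom.
#'
#' @param m a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(m, path) {
  a <- m$atom
  id <- gsub("[^A-Za-z0-9]", "", m$pdb_id)
  hdr <- c(paste0("data_", id),
           paste0("_entry.id ", id))
  if (!is.na(m$experiment_method)) {
    hdr <- c(hdr, sprintf("_exptl.method '%s'", m$experiment_method))
  }
  if (!is.na(m$resolution)) {
    hdr <- c(hdr, sprintf("_refine.ls_d_res_high %.2f", m$resolution))
  }
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
              "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
  alt <- ifelse(is.na(a$alt) | a$alt == "", ".", a$alt)
  ins <- ifelse(is.na(a$insert) | a$insert == "", "?", a$insert)
  body <- sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.6f %.6f %.6f %.2f 10.00 %d %s %s %s 1",
    a$type, a$eleno, a$elesy, a$elety, alt, a$resid, a$chain, a$resno, ins,
    a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(hdr, "loop_", paste0("_atom_site.", fields), body, "#"), path)
  invisible(path)
}

#' Write a structure model in legacy PDB format
#'
#' Delegates the coordinate records to [bio3d::write.pdb()] and prepends the
#' `HEADER`/`REMARK 2` lines that carry the entry id and resolution.  The
#' fixed-column format limits coordinates to three decimals.
#'
#' @param m a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(m, path) {
  a <- m$atom
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   insert = a$insert, alt = a$alt, o = a$o,
                   b = rep(10, nrow(a)), elesy = a$elesy)
  body <- readLines(path, warn = FALSE)
  hdr <- sprintf("HEADER    SYNTHETIC FIXTURE                       01-JAN-26   %-4s",
                 substr(m$pdb_id, 1, 4))
  rem <- if (!is.na(m$resolution)) {
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", m$resolution)
  }
  writeLines(c(hdr, rem, body), path)
  invisible(path)
}

#' Write a classic-format DSSP-like annotation file for a fixture
#'
#' Emits the fixed-column per-residue block that [read_dssp()] (and real
#' DSSP output) uses, for attaching secondary-structure codes to synthetic
#' chains in tests and examples.
#'
#' @param chain,resno,ss equal-length vectors of chain ids, residue numbers
#'   and one-letter structure codes (`H`, `E`, `-`, ...).
#' @param path output file.
#' @param aa one-letter amino-acid codes (cosmetic).
#' @return `path`, invisibly.
#' @export
write_dssp_fixture <- function(chain, resno, ss, path, aa = "A") {
  aa <- rep_len(aa, length(resno))
  head <- c("==== Secondary Structure Definition (synthetic fixture) ====",
            "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- sprintf("%5d%5d %s %s  %s", seq_along(resno), resno,
                  substr(chain, 1, 1), aa, substr(ss, 1, 1))
  writeLines(c(head, body), path)
  invisible(path)
}
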