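# Ideal-geometry placement of amino-acid polar hydrogens.
# Bond lengths: N-H 1.01, O-H 0.96, S-H 1.34 Angstrom; sp2 hydrogens lie in
# the plane of the heavy-atom frame, sp3 hydrogens are staggered.

.rodrigues <- function(v, axis, angle_deg) {
  k <- .unit(axis)
  th <- angle_deg * pi / 180
  v * cos(th) + .cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# H on sp2 X bonded to heavy A and B: along the external bisector
.h_sp2_bisector <- function(X, A, B, len) {
  X + len * .unit(-(.unit(A - X) + .unit(B - X)))
}

# two H on terminal sp2 N (X) bonded to single heavy A; P defines the plane
.h_sp2_terminal <- function(X, A, P, len) {
  u <- .unit(X - A)
  n <- .unit(.cross(X - A, P - A))
  v <- .unit(.cross(n, u))
  list(X + len * (0.5 * u + sqrt(3) / 2 * v),
       X + len * (0.5 * u - sqrt(3) / 2 * v))
}

# n_h sp3 hydrogens on X bonded to A, staggered anti to reference B (on A)
.h_sp3 <- function(X, A, B, len, n_h = 1L) {
  v_xa <- .unit(A - X)
  w <- (B - A) - sum((B - A) * v_xa) * v_xa
  t0 <- if (sqrt(sum(w * w)) < 1e-6) {
    ref <- if (abs(v_xa[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    .unit(.cross(v_xa, ref))
  } else -.unit(w)
  th <- 109.47 * pi / 180
  lapply(seq_len(n_h), function(k) {
    t_k <- .rodrigues(t0, v_xa, (k - 1) * 120)
    X + len * (cos(th) * v_xa + sin(th) * t_k)
  })
}

.DONOR_TEMPLATES <- list(
  ARG = list(list(X = "NE", kind = "sp2b", A = "CD", B = "CZ",
                  h = "HE", len = 1.01),
             list(X = "NH1", kind = "sp2t", A = "CZ", P = "NE",
                  h = c("HH11", "HH12"), len = 1.01),
             list(X = "NH2", kind = "sp2t", A = "CZ", P = "NE",
                  h = c("HH21", "HH22"), len = 1.01)),
  LYS = list(list(X = "NZ", kind = "sp3", A = "CE", B = "CD",
                  h = c("HZ1", "HZ2", "HZ3"), len = 1.01)),
  HIS = list(list(X = "ND1", kind = "sp2b", A = "CG", B = "CE1",
                  h = "HD1", len = 1.01),
             list(X = "NE2", kind = "sp2b", A = "CD2", B = "CE1",
                  h = "HE2", len = 1.01)),
  TRP = list(list(X = "NE1", kind = "sp2b", A = "CD1", B = "CE2",
                  h = "HE1", len = 1.01)),
  ASN = list(list(X = "ND2", kind = "sp2t", A = "CG", P = "OD1",
                  h = c("HD21", "HD22"), len = 1.01)),
  GLN = list(list(X = "NE2", kind = "sp2t", A = "CD", P = "OE1",
                  h = c("HE21", "HE22"), len = 1.01)),
  SER = list(list(X = "OG", kind = "sp3", A = "CB", B = "CA",
                  h = "HG", len = 0.96)),
  THR = list(list(X = "OG1", kind = "sp3", A = "CB", B = "CA",
                  h = "HG1", len = 0.96)),
  TYR = list(list(X = "OH", kind = "sp3", A = "CZ", B = "CE1",
                  h = "HH", len = 0.96)),
  CYS = list(list(X = "SG", kind = "sp3", A = "CB", B = "CA",
                  h = "HG", len = 1.34))
)

#' Add standard polar hydrogens to amino-acid residues
#'
#' Places missing polar hydrogens at ideal geometry on the backbone amide
#' nitrogen and on the side-chain donor groups of Arg, Lys, His, Trp, Asn,
#' Gln, Ser, Thr, Tyr and Cys.  Residues that already bear any hydrogen are
#' left untouched (the deposited protonation state is trusted), ligand
#' residues never receive hydrogens, and the operation is idempotent.
#' Donors whose heavy-atom frame is incomplete are skipped with a warning.
#'
#' @param m a `structure_model`.
#' @return the model with hydrogens appended to its atom table.
#' @export
add_amino_acid_hydrogens <- function(m) {
  atom <- m$atom
  rkey <- .res_key(atom$chain, atom$resno, atom$insert, atom$resid)
  rt <- residue_table(m)
  aa <- rt[rt$class == "amino-acid", , drop = FALSE]
  if (!nrow(aa)) return(m)
  has_h <- tapply(.is_hydrogen(atom$elesy), rkey, any)
  new <- list()
  next_no <- max(atom$eleno) + 1L
  pos_of <- function(rows, name) {
    i <- rows[match(name, atom$elety[rows])]
    if (is.na(i)) return(NULL)
    c(atom$x[i], atom$y[i], atom$z[i])
  }
  add_h <- function(rr, name, p) {
    new[[length(new) + 1L]] <<- data.frame(
      eleno = next_no, elety = name, elesy = "H", alt = NA_character_,
      resid = rr$resid, chain = rr$chain, resno = rr$resno,
      insert = rr$insert, x = p[1], y = p[2], z = p[3], o = 1,
      type = "ATOM", stringsAsFactors = FALSE)
    next_no <<- next_no + 1L
  }
  for (i in seq_len(nrow(aa))) {
    rr <- aa[i, ]
    if (isTRUE(has_h[[rr$key]])) next
    rows <- which(rkey == rr$key)
    # backbone amide H (not for proline; N-terminal residues are skipped)
    if (rr$resid != "PRO") {
      N <- pos_of(rows, "N"); CA <- pos_of(rows, "CA")
      prev <- which(atom$chain == rr$chain & atom$resno == rr$resno - 1L &
                      atom$elety == "C")
      if (!is.null(N) && !is.null(CA) && length(prev) == 1L) {
        Cp <- c(atom$x[prev], atom$y[prev], atom$z[prev])
        if (sqrt(sum((N - Cp)^2)) < 1.8) {
          add_h(rr, "H", .h_sp2_bisector(N, CA, Cp, 1.01))
        }
      }
    }
    tmpl <- .DONOR_TEMPLATES[[rr$resid]]
    if (is.null(tmpl)) next
    for (tp in tmpl) {
      X <- pos_of(rows, tp$X)
      if (is.null(X)) next
      ok <- TRUE
      hp <- switch(tp$kind,
        sp2b = {
          A <- pos_of(rows, tp$A); B <- pos_of(rows, tp$B)
          if (is.null(A) || is.null(B)) { ok <- FALSE; NULL }
          else list(.h_sp2_bisector(X, A, B, tp$len))
        },
        sp2t = {
          A <- pos_of(rows, tp$A); P <- pos_of(rows, tp$P)
          if (is.null(A) || is.null(P)) { ok <- FALSE; NULL }
          else .h_sp2_terminal(X, A, P, tp$len)
        },
        sp3 = {
          A <- pos_of(rows, tp$A); B <- pos_of(rows, tp$B)
          if (is.null(A) || is.null(B)) { ok <- FALSE; NULL }
          else .h_sp3(X, A, B, tp$len, n_h = length(tp$h))
        })
      if (!ok) {
        warning("donor ", tp$X, " of ", rr$key,
                " skipped: frame atoms missing", call. = FALSE)
        next
      }
      for (k in seq_along(hp)) add_h(rr, tp$h[k], hp[[k]])
    }
  }
  if (length(new)) m$atom <- rbind(atom, do.call(rbind, new))
  m
}
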