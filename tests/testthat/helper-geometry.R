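# shared geometric helpers for the test suite

vdist <- function(a, b) sqrt(sum((a - b)^2))

# uniformly random proper rotation matrix
rand_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  R %*% diag(sign(diag(qr.R(qr_d))))
}

# regular hexagon (benzene-like ring), side = circumradius = 1.39 A
hexagon <- function(r = 1.39) {
  th <- seq(0, 300, by = 60) * pi / 180
  cbind(r * cos(th), r * sin(th), 0)
}

# hexagon with an arbitrary frame: tilt about the x-axis, then translate
placed_hexagon <- function(center, tilt_deg = 0, axis = c(1, 0, 0)) {
  co <- hexagon()
  if (tilt_deg != 0) {
    th <- tilt_deg * pi / 180
    K <- rbind(c(0, -axis[3], axis[2]),
               c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    co <- co %*% t(R)
  }
  sweep(co, 2, center, "+")
}

# build a structure_model straight from an atom-description data.frame with
# columns elety, elesy, resid, chain, resno, x, y, z (+ optional o, alt, type)
mk_model <- function(df, pdb_id = "TST1", resolution = 2.0) {
  n <- nrow(df)
  atom <- data.frame(
    eleno = seq_len(n), elety = df$elety, elesy = df$elesy,
    alt = if (is.null(df$alt)) NA_character_ else df$alt,
    resid = df$resid, chain = df$chain, resno = df$resno,
    insert = if (is.null(df$insert)) NA_character_ else df$insert,
    x = df$x, y = df$y, z = df$z,
    o = if (is.null(df$o)) 1 else df$o,
    type = if (is.null(df$type)) "HETATM" else df$type,
    stringsAsFactors = FALSE)
  structure_model(atom, pdb_id = pdb_id, resolution = resolution)
}

# atoms of a benzene ligand as an atom-description block
benzene_block <- function(center = c(0, 0, 0), chain = "A", resno = 1L,
                          resid = "BNZ", tilt_deg = 0) {
  co <- placed_hexagon(center, tilt_deg)
  data.frame(elety = paste0("C", 1:6), elesy = "C", resid = resid,
             chain = chain, resno = resno,
             x = co[, 1], y = co[, 2], z = co[, 3],
             stringsAsFactors = FALSE)
}

chloride_block <- function(p, chain = "X", resno = 100L) {
  data.frame(elety = "CL", elesy = "CL", resid = "CL", chain = chain,
             resno = resno, x = p[1], y = p[2], z = p[3],
             stringsAsFactors = FALSE)
}
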