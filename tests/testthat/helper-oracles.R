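# Independent brute-force oracles.  These deliberately re-derive every
# quantity from raw coordinates with plain R geometry, bypassing the package
# helpers they are used to check.

# all (ring, anion-site) pairs by exhaustive double loop
bf_pairs <- function(rings, anions, radius = 5.0) {
  out <- list()
  for (ri in seq_along(rings)) {
    cen <- colMeans(rings[[ri]]$coords)
    for (ai in seq_along(anions)) {
      a <- anions[[ai]]
      if (a$res_key == rings[[ri]]$res_key) next
      d <- apply(a$coords, 1, function(p) sqrt(sum((p - cen)^2)))
      if (min(d) <= radius) {
        out[[length(out) + 1L]] <- c(ring = ri, anion = ai,
                                     rep = which.min(d))
      }
    }
  }
  if (!length(out)) return(matrix(numeric(), 0, 3,
                                  dimnames = list(NULL, c("ring", "anion", "rep"))))
  do.call(rbind, out)
}

# brute-force synthon decisions on one raw geometry description:
#   frame: list(centroid, normal); ring_xyz / parent_xyz: matrices
#   rep: anion representative position; site_xyz: matrix of site atoms
#   side: +1/-1; region: "A"/"B"/"C"
#   metals: matrix of metal positions; cat_all: matrix of all cation
#   positions (metals + Arg/Lys); donors: list of list(D, H) positions;
#   rings2: list of list(centroid, normal) for candidate second rings
bf_synthons <- function(geo, t) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  sideof <- function(p) {
    if (sum((p - geo$frame$centroid) * geo$frame$normal) >= 0) 1L else -1L
  }
  ang_deg <- function(u, v) {
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  fold <- function(a) if (a > 90) 180 - a else a
  nmet <- if (is.null(geo$metals)) 0L else nrow(geo$metals)
  ring_bonded <- FALSE
  if (nmet) {
    for (k in seq_len(nmet)) {
      if (min(apply(geo$ring_xyz, 1, d, b = geo$metals[k, ])) <
          t$d_cation_ring_coord) ring_bonded <- TRUE
    }
  }
  flags <- character()
  # (i)
  if (!ring_bonded && nmet) {
    for (k in seq_len(nmet)) {
      mp <- geo$metals[k, ]
      if (d(mp, geo$rep) < t$d_anion_cation_close &&
          (!(geo$region %in% c("A", "B")) || sideof(mp) == geo$side)) {
        flags <- c(flags, "i"); break
      }
    }
  }
  # (ii)
  if (nmet) {
    for (k in seq_len(nmet)) {
      mp <- geo$metals[k, ]
      if (min(apply(geo$ring_xyz, 1, d, b = mp)) < t$d_cation_ring_coord &&
          d(mp, geo$rep) < t$d_anion_cation_close) {
        flags <- c(flags, "ii"); break
      }
    }
  }
  # (iii)
  ncat <- if (is.null(geo$cat_all)) 0L else nrow(geo$cat_all)
  if (!ring_bonded && ncat) {
    for (k in seq_len(ncat)) {
      cp <- geo$cat_all[k, ]
      v <- cp - geo$frame$centroid
      if (sqrt(sum(v^2)) >= 5) next
      if (geo$region %in% c("A", "B") && sideof(cp) != -geo$side) next
      if (fold(ang_deg(v, geo$frame$normal)) > t$sector_iii) next
      if (d(cp, geo$rep) <= t$d_anion_cation_close) next
      flags <- c(flags, "iii"); break
    }
  }
  # (iv)
  if (nmet) {
    for (k in seq_len(nmet)) {
      mp <- geo$metals[k, ]
      if (min(apply(geo$parent_xyz, 1, d, b = mp)) < t$d_cation_ring_coord &&
          d(mp, geo$rep) > t$d_anion_cation_far) {
        flags <- c(flags, "iv"); break
      }
    }
  }
  # (v)
  for (dn in geo$donors) {
    hit <- FALSE
    for (ai in seq_len(nrow(geo$site_xyz))) {
      acc <- geo$site_xyz[ai, ]
      if (d(acc, dn$D) >= t$hb_d_acc_donor || d(acc, dn$D) < 0.1) next
      if (d(acc, dn$H) >= t$hb_d_acc_h) next
      if (ang_deg(dn$D - dn$H, acc - dn$H) > t$hb_angle_min) hit <- TRUE
    }
    if (hit) { flags <- c(flags, "v"); break }
  }
  # (vi) and (vii)
  for (r2 in geo$rings2) {
    v <- r2$centroid - geo$frame$centroid
    dcc <- sqrt(sum(v^2))
    if (dcc < t$pp_par_dcc &&
        fold(ang_deg(geo$frame$normal, r2$normal)) < t$pp_par_angle_max) {
      hh <- abs(sum(v * geo$frame$normal))
      xx <- sqrt(max(0, dcc^2 - hh^2))
      if (hh > t$pp_par_hmin && xx < t$pp_par_xmax &&
          fold(ang_deg(v, geo$frame$normal)) <= t$sector_vi) {
        flags <- c(flags, "vi")
      }
    }
    if (dcc < 5 &&
        fold(ang_deg(geo$frame$normal, r2$normal)) > t$pp_perp_angle_min &&
        fold(ang_deg(geo$frame$normal, v)) > t$pp_perp_angle_min) {
      pn <- c(v[2] * geo$frame$normal[3] - v[3] * geo$frame$normal[2],
              v[3] * geo$frame$normal[1] - v[1] * geo$frame$normal[3],
              v[1] * geo$frame$normal[2] - v[2] * geo$frame$normal[1])
      if (sqrt(sum(pn^2)) > 1e-9 &&
          fold(ang_deg(pn, r2$normal)) > t$pp_perp_angle_min) {
        flags <- c(flags, "vii")
      }
    }
  }
  unique(flags)
}

# assemble a pair_ctx plus matching raw-geometry description for a random
# configuration around a benzene ring with a random rigid frame
random_pair_geometry <- function() {
  R <- rand_rotation()
  tr <- runif(3, -20, 20)
  place <- function(p) as.numeric(R %*% p + tr)
  ring_xyz <- t(apply(hexagon(), 1, place))
  frame <- ring_frame(ring_xyz)
  # anion site: 1-3 atoms, representative = nearest to centroid
  n_site <- sample(1:3, 1)
  base <- c(runif(1, 0, 4.5), 0, 0)
  az <- runif(1, 0, 2 * pi)
  hgt <- runif(1, -4.5, 4.5)
  p0 <- c(base[1] * cos(az), base[1] * sin(az), hgt)
  site <- t(vapply(seq_len(n_site), function(k) {
    place(p0 + (k - 1) * runif(3, 0.4, 0.9))
  }, numeric(3)))
  dcen <- apply(site, 1, vdist, b = frame$centroid)
  rep_i <- which.min(dcen)
  pos <- project_to_ring_frame(frame, site[rep_i, ])
  if (pos$r > 5) return(NULL)
  region <- assign_region(pos$x, pos$h)
  metals <- t(vapply(1:2, function(k) place(runif(3, -6, 6)), numeric(3)))
  argk <- t(vapply(1:2, function(k) place(runif(3, -6, 6)), numeric(3)))
  donors <- lapply(1:2, function(k) {
    D <- place(runif(3, -4, 4))
    H <- D + 1.0 * (function(v) v / sqrt(sum(v^2)))(rnorm(3))
    list(D = D, H = H)
  })
  rings2 <- lapply(1:2, function(k) {
    co <- t(apply(hexagon(), 1, function(v) {
      as.numeric(rand_rotation() %*% v + place(runif(3, -5, 5)))
    }))
    fr <- ring_frame(co)
    list(coords = co, centroid = fr$centroid, normal = fr$normal)
  })
  list(frame = frame, ring_xyz = ring_xyz, parent_xyz = ring_xyz,
       rep = site[rep_i, ], site_xyz = site, rep_i = rep_i,
       side = pos$side, region = region,
       metals = metals, cat_all = rbind(metals, argk), argk = argk,
       donors = donors, rings2 = rings2)
}

# package-side context and inputs equivalent to a random_pair_geometry()
ctx_from_geometry <- function(geo) {
  ctx <- structure(list(
    frame = geo$frame, ring_coords = geo$ring_xyz,
    parent_coords = geo$parent_xyz, ring_res_key = "A|1||BNZ",
    ring_idx = 1L, anion_res_key = "X|100||ANI",
    rep = geo$rep, site_coords = geo$site_xyz,
    side = geo$side, region = geo$region), class = "pair_ctx")
  cations <- c(
    lapply(seq_len(nrow(geo$metals)), function(k) {
      structure(list(kind = "metal", element = "ZN",
                     position = geo$metals[k, ], res_key = paste0("M", k),
                     atom_idx = k), class = "cation_site")
    }),
    lapply(seq_len(nrow(geo$argk)), function(k) {
      structure(list(kind = "Arg-guanidinium", element = NA_character_,
                     position = geo$argk[k, ], res_key = paste0("R", k),
                     atom_idx = k), class = "cation_site")
    }))
  donors <- lapply(seq_along(geo$donors), function(k) {
    list(atom_idx = k, position = geo$donors[[k]]$D,
         h_pos = matrix(geo$donors[[k]]$H, 1), res_key = paste0("D", k),
         resid = "SER", name = "OG")
  })
  rings <- c(list(list(coords = geo$ring_xyz, res_key = "A|1||BNZ",
                       ring_code = "BNZ.L1")),
             lapply(seq_along(geo$rings2), function(k) {
               list(coords = geo$rings2[[k]]$coords,
                    res_key = paste0("B|", k, "||BNZ"),
                    ring_code = "BNZ.L1")
             }))
  frames <- c(list(geo$frame),
              lapply(geo$rings2, function(r2) ring_frame(r2$coords)))
  list(ctx = ctx, cations = cations, donors = donors,
       rings = rings, frames = frames)
}
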