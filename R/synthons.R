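#' Geometric thresholds for ternary synthon classification
#'
#' All distances in Angstrom, all angles in degrees.  The defaults are the
#' printed detection criteria for the seven co-existing motifs: the
#' close/far anion-cation distances (3.25 / 3.5), the metal-ring coordination
#' cutoff (3.0, a typical coordination bond length), the hydrogen-bond
#' criteria (donor-H...acceptor angle > 130, acceptor-donor < 3.2,
#' acceptor-H < 2.2), the parallel-stack criteria (inter-plane angle < 15,
#' centroid distance < 5, offset h > 1.6 and x < 2.2), the perpendicular
#' (T-shaped) angle floor (70), and the spherical-sector half-angles for the
#' cation-pi (45) and parallel-stack (15) tests.
#'
#' @param ... override any named threshold.
#' @return named list of class `synthon_thresholds`.
#' @export
default_synthon_thresholds <- function(...) {
  t <- list(
    d_anion_cation_close = 3.25,
    d_anion_cation_far = 3.5,
    d_cation_ring_coord = 3.0,
    hb_angle_min = 130,
    hb_d_acc_donor = 3.2,
    hb_d_acc_h = 2.2,
    pp_par_angle_max = 15,
    pp_par_dcc = 5,
    pp_par_hmin = 1.6,
    pp_par_xmax = 2.2,
    pp_perp_angle_min = 70,
    sector_iii = 45,
    sector_vi = 15
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(t)))
  t[names(ov)] <- ov
  stopifnot(all(unlist(t) > 0), t$hb_angle_min < 180)
  class(t) <- "synthon_thresholds"
  t
}

#' Assemble the geometric context of one pair record
#'
#' @param ps a `pair_set` from [find_pairs()].
#' @param k row index into `ps$pairs`.
#' @return list of class `pair_ctx` with the ring frame, ring member and
#'   parent-residue coordinates, the anion representative position, all anion
#'   site-atom coordinates, the pair's side and region.
#' @export
pair_context <- function(ps, k) {
  row <- ps$pairs[k, ]
  rg <- ps$rings[[row$ring_idx]]
  a <- ps$anions[[row$anion_idx]]
  ctx <- list(
    frame = ps$frames[[row$ring_idx]],
    ring_coords = rg$coords,
    parent_coords = rg$parent_coords,
    ring_res_key = rg$res_key,
    ring_idx = row$ring_idx,
    anion_res_key = a$res_key,
    rep = a$coords[row$rep_i, ],
    site_coords = a$coords,
    side = row$side,
    region = row$region
  )
  class(ctx) <- "pair_ctx"
  ctx
}

.dist <- function(a, b) sqrt(sum((a - b)^2))

.min_dist_to <- function(coords, p) {
  min(sqrt(colSums((t(coords) - p)^2)))
}

.metal_cations <- function(cations) {
  Filter(function(cc) cc$kind == "metal", cations)
}

# is any metal cation coordinated to a ring member atom?
.ring_metal_bonded <- function(pair, cations, t) {
  for (cc in .metal_cations(cations)) {
    if (.min_dist_to(pair$ring_coords, cc$position) < t$d_cation_ring_coord) {
      return(TRUE)
    }
  }
  FALSE
}

.side_of <- function(frame, p) {
  raw <- sum((p - frame$centroid) * frame$normal)
  if (raw >= 0) 1L else -1L
}

#' @name synthon_classifiers
#' @title The seven co-existing ternary motifs
#' @description
#' Each classifier tests one accompanying-interaction motif of a ring-anion
#' pair and returns `NULL` (no flag) or a list of satisfying partners with
#' their key distances/angles.  The motif sets are not disjoint; a pair
#' matching none of them belongs to "rest".
#'
#' * `classify_i`   ring...anion...cation: a metal within 3.25 A of the
#'   anion, on the same side of the ring plane (side test waived in region
#'   C); rings directly metal-coordinated are excluded.
#' * `classify_ii`  anion...ring-cation: a metal coordinated to a ring atom
#'   and within 3.25 A of the anion.
#' * `classify_iii` anion...ring...cation: a cation (metal, Arg CZ, Lys NZ)
#'   within 5 A of the centroid inside the 45 degree sector, opposite side
#'   from the anion (waived in C), anion-cation distance above 3.25 A.
#' * `classify_iv`  anion...ring- - -cation: a metal coordinated anywhere on
#'   the quadrupole residue, anion-cation distance above 3.5 A.
#' * `classify_v`   ring...anion...H-donor: a strong hydrogen bond to any
#'   anion site atom (angle > 130 deg, acceptor-donor < 3.2 A,
#'   acceptor-H < 2.2 A); all satisfying donors are recorded.
#' * `classify_vi`  anion...ring...ring parallel: second ring with
#'   inter-plane angle < 15 deg, centroid distance < 5 A, offset h > 1.6 A
#'   and x < 2.2 A, inside the 15 degree sector.
#' * `classify_vii` anion...ring...ring perpendicular: centroids closer than
#'   5 A and the three >70 degree angle conditions of the T-shaped motif.
#'
#' @param pair a `pair_ctx` from [pair_context()].
#' @param cations list from [detect_cation_sites()].
#' @param donors list from [detect_h_donors()].
#' @param rings,frames candidate rings and their precomputed frames.
#' @param primary_idx index of the pair's own ring within `rings`.
#' @param t a [default_synthon_thresholds()].
#' @return `NULL` or a list of partner evidence records.
NULL

#' @rdname synthon_classifiers
#' @export
classify_i <- function(pair, cations, t = default_synthon_thresholds()) {
  if (.ring_metal_bonded(pair, cations, t)) return(NULL)
  hits <- list()
  for (cc in .metal_cations(cations)) {
    d <- .dist(cc$position, pair$rep)
    if (d >= t$d_anion_cation_close) next
    if (pair$region %in% c("A", "B") &&
        .side_of(pair$frame, cc$position) != pair$side) next
    hits[[length(hits) + 1L]] <- list(partner = cc$res_key,
                                      element = cc$element, d = d)
  }
  if (length(hits)) hits else NULL
}

#' @rdname synthon_classifiers
#' @export
classify_ii <- function(pair, cations, t = default_synthon_thresholds()) {
  hits <- list()
  for (cc in .metal_cations(cations)) {
    dring <- .min_dist_to(pair$ring_coords, cc$position)
    d <- .dist(cc$position, pair$rep)
    if (dring < t$d_cation_ring_coord && d < t$d_anion_cation_close) {
      hits[[length(hits) + 1L]] <- list(partner = cc$res_key,
                                        element = cc$element,
                                        d_ring = dring, d = d)
    }
  }
  if (length(hits)) hits else NULL
}

#' @rdname synthon_classifiers
#' @export
classify_iii <- function(pair, cations, t = default_synthon_thresholds()) {
  if (.ring_metal_bonded(pair, cations, t)) return(NULL)
  want_side <- if (pair$region %in% c("A", "B")) -pair$side else "any"
  hits <- list()
  for (cc in cations) {
    dc <- .dist(cc$position, pair$frame$centroid)
    if (dc >= 5) next
    if (!in_spherical_sector(pair$frame, cc$position, t$sector_iii,
                             same_side_as = want_side)) next
    d <- .dist(cc$position, pair$rep)
    if (d <= t$d_anion_cation_close) next
    hits[[length(hits) + 1L]] <- list(partner = cc$res_key, kind = cc$kind,
                                      d_centroid = dc, d = d)
  }
  if (length(hits)) hits else NULL
}

#' @rdname synthon_classifiers
#' @export
classify_iv <- function(pair, cations, t = default_synthon_thresholds()) {
  hits <- list()
  for (cc in .metal_cations(cations)) {
    dq <- .min_dist_to(pair$parent_coords, cc$position)
    if (dq >= t$d_cation_ring_coord) next
    d <- .dist(cc$position, pair$rep)
    if (d <= t$d_anion_cation_far) next
    hits[[length(hits) + 1L]] <- list(partner = cc$res_key,
                                      element = cc$element,
                                      d_quadrupole = dq, d = d)
  }
  if (length(hits)) hits else NULL
}

#' @rdname synthon_classifiers
#' @export
classify_v <- function(pair, donors, t = default_synthon_thresholds()) {
  hits <- list()
  for (dn in donors) {
    found <- FALSE
    for (ai in seq_len(nrow(pair$site_coords))) {
      acc <- pair$site_coords[ai, ]
      d_ad <- .dist(acc, dn$position)
      if (d_ad < 0.1 || d_ad >= t$hb_d_acc_donor) next
      for (hi in seq_len(nrow(dn$h_pos))) {
        hp <- dn$h_pos[hi, ]
        if (.dist(acc, hp) >= t$hb_d_acc_h) next
        v1 <- dn$position - hp
        v2 <- acc - hp
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang > t$hb_angle_min) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) {
      hits[[length(hits) + 1L]] <- list(partner = dn$res_key,
                                        donor_atom = dn$name, d = d_ad)
    }
  }
  if (length(hits)) hits else NULL
}

#' @rdname synthon_classifiers
#' @export
classify_vi <- function(pair, rings, frames, primary_idx,
                        t = default_synthon_thresholds()) {
  hits <- list()
  for (j in seq_along(rings)) {
    if (j == primary_idx) next
    f2 <- frames[[j]]
    dcc <- .dist(f2$centroid, pair$frame$centroid)
    if (dcc >= t$pp_par_dcc) next
    ang <- plane_angle(pair$frame$normal, f2$normal)
    if (ang >= t$pp_par_angle_max) next
    pos <- project_to_ring_frame(pair$frame, f2$centroid)
    if (pos$h <= t$pp_par_hmin || pos$x >= t$pp_par_xmax) next
    if (!in_spherical_sector(pair$frame, f2$centroid, t$sector_vi)) next
    hits[[length(hits) + 1L]] <- list(partner = rings[[j]]$res_key,
                                      ring_code = rings[[j]]$ring_code,
                                      dcc = dcc, angle = ang,
                                      h = pos$h, x = pos$x)
  }
  if (length(hits)) hits else NULL
}

#' @rdname synthon_classifiers
#' @export
classify_vii <- function(pair, rings, frames, primary_idx,
                         t = default_synthon_thresholds()) {
  n1 <- pair$frame$normal
  hits <- list()
  for (j in seq_along(rings)) {
    if (j == primary_idx) next
    f2 <- frames[[j]]
    cc <- f2$centroid - pair$frame$centroid
    dcc <- sqrt(sum(cc * cc))
    if (dcc >= 5) next
    a_nn <- plane_angle(n1, f2$normal)
    if (a_nn <= t$pp_perp_angle_min) next
    a_nc <- plane_angle(n1, cc)  # folded angle normal vs centroid vector
    if (a_nc <= t$pp_perp_angle_min) next
    pn <- .cross(cc, n1)
    if (sqrt(sum(pn * pn)) < 1e-9) next
    a_p <- plane_angle(pn, f2$normal)
    if (a_p <= t$pp_perp_angle_min) next
    hits[[length(hits) + 1L]] <- list(partner = rings[[j]]$res_key,
                                      ring_code = rings[[j]]$ring_code,
                                      dcc = dcc, angle_nn = a_nn,
                                      angle_nc = a_nc, angle_plane = a_p)
  }
  if (length(hits)) hits else NULL
}

#' Classify one pair against all seven motifs
#'
#' @param pair a `pair_ctx`.
#' @param context list with elements `cations`, `donors`, `rings`, `frames`.
#' @param t a [default_synthon_thresholds()].
#' @return list with `flags` (character subset of `i`..`vii`; empty means
#'   "rest") and `partners` (evidence per flag).
#' @export
classify_all <- function(pair, context, t = default_synthon_thresholds()) {
  res <- list(
    i = classify_i(pair, context$cations, t),
    ii = classify_ii(pair, context$cations, t),
    iii = classify_iii(pair, context$cations, t),
    iv = classify_iv(pair, context$cations, t),
    v = classify_v(pair, context$donors, t),
    vi = classify_vi(pair, context$rings, context$frames, pair$ring_idx, t),
    vii = classify_vii(pair, context$rings, context$frames, pair$ring_idx, t)
  )
  keep <- !vapply(res, is.null, logical(1))
  list(flags = names(res)[keep], partners = res[keep])
}

#' Classify every pair of a pair set
#'
#' Fills the `synthons` column of the pair table with the comma-joined motif
#' flags (empty string means "rest") and returns the evidence alongside.
#'
#' @param ps a `pair_set`.
#' @param cations,donors perception output for the same structure.
#' @param t a [default_synthon_thresholds()].
#' @return the `pair_set`, with `$pairs$synthons` filled and an `$evidence`
#'   list of per-pair partner records.
#' @export
classify_pairs <- function(ps, cations, donors,
                           t = default_synthon_thresholds()) {
  stopifnot(inherits(ps, "pair_set"))
  context <- list(cations = cations, donors = donors,
                  rings = ps$rings, frames = ps$frames)
  ev <- vector("list", nrow(ps$pairs))
  for (k in seq_len(nrow(ps$pairs))) {
    cl <- classify_all(pair_context(ps, k), context, t)
    ps$pairs$synthons[k] <- paste(cl$flags, collapse = ",")
    ev[[k]] <- cl$partners
  }
  ps$evidence <- ev
  ps
}
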