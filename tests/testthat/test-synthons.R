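# minimal hand-built context: benzene ring at the origin (plane z = 0),
# anion representative at `rep` (default: region A, side +1)
mk_ctx <- function(rep = c(0.8, 0, 3.3), site = rbind(rep),
                   region = NULL, side = NULL) {
  co <- hexagon()
  fr <- ring_frame(co)
  pos <- project_to_ring_frame(fr, rep)
  structure(list(frame = fr, ring_coords = co, parent_coords = co,
                 ring_res_key = "A|1||BNZ", ring_idx = 1L,
                 anion_res_key = "X|100||ANI", rep = rep, site_coords = site,
                 side = if (is.null(side)) pos$side else side,
                 region = if (is.null(region)) assign_region(pos$x, pos$h)
                   else region),
            class = "pair_ctx")
}

metal_at <- function(p, el = "ZN", key = "M1") {
  structure(list(kind = "metal", element = el, position = p, res_key = key,
                 atom_idx = 1L), class = "cation_site")
}

argcz_at <- function(p, key = "R1") {
  structure(list(kind = "Arg-guanidinium", element = NA_character_,
                 position = p, res_key = key, atom_idx = 1L),
            class = "cation_site")
}

donor_at <- function(D, H, key = "D1") {
  list(atom_idx = 1L, position = D, h_pos = matrix(H, 1), res_key = key,
       resid = "SER", name = "OG")
}

ring2_at <- function(center, tilt_deg = 0) {
  co <- placed_hexagon(center, tilt_deg)
  list(coords = co, res_key = "B|2||BNZ", ring_code = "BNZ.L1")
}

test_that("motif (i): close same-side metal, waived side in region C", {
  t <- default_synthon_thresholds()
  ctx <- mk_ctx()                                   # anion at (0.8, 0, 3.3), A
  near <- function(d) metal_at(ctx$rep + c(0, 0, d))
  expect_false(is.null(classify_i(ctx, list(near(3.24)), t)))
  expect_null(classify_i(ctx, list(near(3.26)), t))  # beyond 3.25
  # opposite side in region A: rejected
  below <- metal_at(c(0.8, 0, -2.0))
  expect_null(classify_i(ctx, list(below), t))
  # region C: side condition waived
  ctxC <- mk_ctx(rep = c(4.2, 0, 0.4))
  oppo <- metal_at(c(4.2, 0, -2.0))
  expect_equal(ctxC$region, "C")
  expect_false(is.null(classify_i(ctxC, list(oppo), t)))
  # a ring directly coordinated to a metal is excluded entirely
  bonded <- metal_at(c(1.39 + 2.0, 0, 0))
  expect_null(classify_i(ctx, list(bonded, near(2.0)), t))
})

test_that("motif (ii): metal coordinated to the ring and close to the anion", {
  t <- default_synthon_thresholds()
  ctx <- mk_ctx(rep = c(1.39, 0, 3.0))
  # metal 2.1 A above a ring atom, 2.2 from the anion (His-Zn-like geometry)
  zn <- metal_at(c(1.39, 0, 0.9))
  expect_false(is.null(classify_ii(ctx, list(zn), t)))
  # anion too far (> 3.25)
  ctx_far <- mk_ctx(rep = c(1.39, 0, 4.2))
  expect_null(classify_ii(ctx_far, list(zn), t))
  # metal not coordinated (2.99 vs 3.01 from the nearest ring atom)
  zn_on <- metal_at(c(1.39, 0, 2.99))
  zn_off <- metal_at(c(1.39, 0, 3.01))
  ctx2 <- mk_ctx(rep = c(1.39, 0, 3.2))
  expect_false(is.null(classify_ii(ctx2, list(zn_on), t)))
  expect_null(classify_ii(ctx2, list(zn_off), t))
})

test_that("motif (iii): opposite-side cation inside the 45 degree sector", {
  t <- default_synthon_thresholds()
  ctx <- mk_ctx()                                    # side +1, region A
  # Arg CZ 3.6 A below the ring on the axis: sector angle 0, d > 3.25
  expect_false(is.null(classify_iii(ctx, list(argcz_at(c(0, 0, -3.6))), t)))
  # at 46 vs 44 degrees off-axis
  p46 <- 3.6 * c(sin(46 * pi / 180), 0, -cos(46 * pi / 180))
  p44 <- 3.6 * c(sin(44 * pi / 180), 0, -cos(44 * pi / 180))
  expect_null(classify_iii(ctx, list(argcz_at(p46)), t))
  expect_false(is.null(classify_iii(ctx, list(argcz_at(p44)), t)))
  # same side as the anion (region A): rejected
  expect_null(classify_iii(ctx, list(argcz_at(c(0, 0, 3.6 + 3.3))), t))
  # close ion pairs (<= 3.25) belong to motif (i), not (iii): in region C the
  # side condition is waived, so an in-sector cation can sit near the anion
  ctxC <- mk_ctx(rep = c(4.2, 0, 0.4))
  expect_equal(ctxC$region, "C")
  cat_far <- argcz_at(c(0.5, 0, 1.0))     # d(anion) = 3.75, sector 26.6 deg
  cat_close <- argcz_at(c(2.0, 0, 2.5))   # d(anion) = 3.04, sector 38.7 deg
  expect_gt(vdist(cat_far$position, ctxC$rep), 3.25)
  expect_lt(vdist(cat_close$position, ctxC$rep), 3.25)
  expect_false(is.null(classify_iii(ctxC, list(cat_far), t)))
  expect_null(classify_iii(ctxC, list(cat_close), t))
  # metal-bonded rings excluded
  bonded <- metal_at(c(1.39 + 2.0, 0, 0))
  expect_null(classify_iii(ctx, list(bonded, argcz_at(c(0, 0, -3.6))), t))
  # cation beyond 5 A of the centroid does not count
  expect_null(classify_iii(ctx, list(argcz_at(c(0, 0, -5.1))), t))
  expect_false(is.null(classify_iii(ctx, list(argcz_at(c(0, 0, -4.9))), t)))
})

test_that("motif (iv): metal on the quadrupole residue, distant anion", {
  t <- default_synthon_thresholds()
  co <- hexagon()
  fr <- ring_frame(co)
  # quadrupole residue has a tail atom away from the ring; metal binds there
  tail <- c(3.5, 0, 0)
  ctx <- structure(list(frame = fr, ring_coords = co,
                        parent_coords = rbind(co, tail),
                        ring_res_key = "A|1||LIG", ring_idx = 1L,
                        anion_res_key = "X|100||ANI",
                        rep = c(-0.5, 0, 3.3),
                        site_coords = rbind(c(-0.5, 0, 3.3)),
                        side = 1L, region = "A"), class = "pair_ctx")
  mn_tail <- metal_at(tail + c(2.9, 0, 0), el = "MN")
  expect_false(is.null(classify_iv(ctx, list(mn_tail), t)))   # d ~ 7.7 > 3.5
  # metal too far from every quadrupole atom: no coordination
  expect_null(classify_iv(ctx, list(metal_at(tail + c(3.1, 0, 0))), t))
  # anion-cation distance boundary: metal bound to the tail, anion above it
  ctx2 <- ctx
  ctx2$rep <- tail + c(0, 0, 3.45)
  ctx2$site_coords <- rbind(ctx2$rep)
  m_near <- metal_at(tail + c(0, 0, -0.02))   # d(anion) = 3.47 <= 3.5
  m_far <- metal_at(tail + c(0, 0, -0.20))    # d(anion) = 3.65 >  3.5
  expect_null(classify_iv(ctx2, list(m_near), t))
  expect_false(is.null(classify_iv(ctx2, list(m_far), t)))
})

test_that("motif (v): strong hydrogen bonds at the printed criteria", {
  t <- default_synthon_thresholds()
  acc <- c(0.8, 0, 3.3)
  ctx <- mk_ctx(rep = acc)
  # linear D-H...A: d(D,A) = 2.9, d(H,A) = 1.9, angle 180
  D <- acc + c(2.9, 0, 0)
  H <- acc + c(1.9, 0, 0)
  expect_false(is.null(classify_v(ctx, list(donor_at(D, H)), t)))
  # angle 129 vs 131 degrees (D-H 1.0, H...A 1.9)
  mk_don <- function(ang_deg) {
    # D-H...A angle at H: H->A is -x, so H->D at (-cos a, sin a) gives angle a
    th <- ang_deg * pi / 180
    H <- acc + c(1.9, 0, 0)
    D <- H + c(-cos(th), sin(th), 0)
    donor_at(D, H)
  }
  expect_null(classify_v(ctx, list(mk_don(129)), t))
  expect_false(is.null(classify_v(ctx, list(mk_don(131)), t)))
  # acceptor-H distance 2.19 vs 2.21 (linear geometry)
  hb <- function(dh) donor_at(acc + c(dh + 1.0, 0, 0), acc + c(dh, 0, 0))
  expect_false(is.null(classify_v(ctx, list(hb(2.19)), t)))
  expect_null(classify_v(ctx, list(hb(2.21)), t))
  # acceptor-donor distance 3.19 vs 3.21 (H on the line, within 2.2)
  da <- function(dd) donor_at(acc + c(dd, 0, 0), acc + c(dd - 1.0, 0, 0))
  expect_false(is.null(classify_v(ctx, list(da(3.19)), t)))
  expect_null(classify_v(ctx, list(da(3.21)), t))
  # two satisfying donors: one flag, both recorded
  got <- classify_v(ctx, list(donor_at(D, H),
                              donor_at(acc + c(0, 2.9, 0),
                                       acc + c(0, 1.9, 0), key = "D2")), t)
  expect_length(got, 2L)
})

test_that("motif (vi): parallel stacked ring inside the 15 degree sector", {
  t <- default_synthon_thresholds()
  ctx <- mk_ctx()
  r2 <- function(center, tilt = 0) {
    rr <- ring2_at(center, tilt)
    list(rings = list(NULL, rr), frames = list(NULL, ring_frame(rr$coords)))
  }
  chk <- function(center, tilt = 0) {
    e <- r2(center, tilt)
    classify_vi(ctx, e$rings, e$frames, 1L, t)
  }
  expect_false(is.null(chk(c(0.8, 0, 3.4))))        # canonical stack
  expect_null(chk(c(0.8, 0, 3.4), tilt = 16))        # angle 16 > 15
  expect_false(is.null(chk(c(0.8, 0, 3.4), tilt = 14)))
  expect_null(chk(c(0.3, 0, 1.59)))                  # h below 1.6
  expect_false(is.null(chk(c(0.3, 0, 1.61))))
  expect_null(chk(c(2.21, 0, 4.0)))                  # x beyond 2.2 (and sector)
  expect_null(chk(c(1.0, 0, 3.4)))                   # sector: 16.4 deg off axis
  expect_false(is.null(chk(c(0.9, 0, 3.4))))         # 14.8 deg: inside
  expect_null(chk(c(0.3, 0, 5.0)))                   # dcc 5.009 >= 5
  expect_false(is.null(chk(c(0.3, 0, 4.97))))        # dcc 4.979 < 5
  # the default 15-degree sector caps x at ~1.3, so isolate the 2.2 A offset
  # boundary under a widened sector
  t2 <- default_synthon_thresholds(sector_vi = 60)
  e219 <- r2(c(2.19, 0, 4.0)); e221 <- r2(c(2.21, 0, 4.0))
  expect_false(is.null(classify_vi(ctx, e219$rings, e219$frames, 1L, t2)))
  expect_null(classify_vi(ctx, e221$rings, e221$frames, 1L, t2))
})

test_that("motif (vii): T-shaped ring pair via the three angle conditions", {
  t <- default_synthon_thresholds()
  ctx <- mk_ctx()
  chk <- function(center, tilt, axis = c(0, 1, 0)) {
    co <- placed_hexagon(center, tilt, axis)
    rr <- list(coords = co, res_key = "B|2||BNZ", ring_code = "BNZ.L1")
    classify_vii(ctx, list(NULL, rr), list(NULL, ring_frame(co)), 1L, t)
  }
  # edge-to-face: second ring perpendicular, centroid in the primary plane
  expect_false(is.null(chk(c(4.9, 0, 0), 90)))
  expect_null(chk(c(4.9, 0, 0), 0))                  # parallel: angle 0
  expect_null(chk(c(5.1, 0, 0), 90))                 # centroids beyond 5 A
  # inter-normal angle 69 vs 71
  expect_null(chk(c(4.9, 0, 0), 69))
  expect_false(is.null(chk(c(4.9, 0, 0), 71)))
  # angle(normal1, centroid vector) must exceed 70: lift the second centroid
  up45 <- c(3.4, 0, 3.4)
  expect_null(chk(up45, 90))
  # third condition: perpendicular ring whose plane contains the centroid
  # vector and the primary normal (tilt about x through the c-c direction)
  expect_null(chk(c(4.9, 0, 0), 90, axis = c(1, 0, 0)))
})

test_that("classification agrees with brute-force geometry on random fixtures", {
  t <- default_synthon_thresholds()
  set.seed(1234)
  n_done <- 0L
  while (n_done < 1000L) {
    geo <- random_pair_geometry()
    if (is.null(geo)) next
    n_done <- n_done + 1L
    want <- sort(bf_synthons(geo, t))
    e <- ctx_from_geometry(geo)
    got <- sort(classify_all(e$ctx, list(cations = e$cations,
                                         donors = e$donors,
                                         rings = e$rings,
                                         frames = e$frames), t)$flags)
    if (!identical(got, want)) {
      fail(sprintf("flag mismatch at fixture %d: got {%s}, want {%s}",
                   n_done, paste(got, collapse = ","),
                   paste(want, collapse = ",")))
      break
    }
  }
  expect_equal(n_done, 1000L)
  succeed()
})

test_that("multi-motif fixtures keep non-disjoint flags and rest bookkeeping", {
  pl <- data.frame(entity = c("ACT", "ZN", "donor", "ring"),
                   x = c(0.8, 1.2, 2.0, 0.5), h = c(3.3, 4.8, 3.3, 3.4),
                   azimuth = c(0, 20, 180, 90), side = c(1L, 1L, 1L, -1L),
                   plane_angle = 0)
  m <- make_fixture(fixture_spec("BNZ", pl, seed = 3))$model
  ps <- find_pairs(m, detect_aromatic_rings(m), detect_anion_sites(m))
  ps <- classify_pairs(ps, detect_cation_sites(m), detect_h_donors(m))
  flags <- strsplit(ps$pairs$synthons, ",")[[1]]
  expect_true(all(c("i", "v") %in% flags))  # co-occurring motifs
  # isolated pair: rest
  iso <- make_fixture(fixture_spec("BNZ",
                                   data.frame(entity = "CL", x = 1, h = 3)))
  ps2 <- find_pairs(iso$model, detect_aromatic_rings(iso$model),
                    detect_anion_sites(iso$model))
  ps2 <- classify_pairs(ps2, detect_cation_sites(iso$model),
                        detect_h_donors(iso$model))
  expect_equal(ps2$pairs$synthons, "")
  # |rest| + |flagged| = total and rest is disjoint from every flag
  all_pairs <- rbind(ps$pairs, ps2$pairs)
  n_rest <- sum(!nzchar(all_pairs$synthons))
  n_flag <- sum(nzchar(all_pairs$synthons))
  expect_equal(n_rest + n_flag, nrow(all_pairs))
})
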