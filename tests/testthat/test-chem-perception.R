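test_that("ring perception finds planar 5/6-cycles and rejects puckered ones", {
  # ideal benzene ligand
  m <- mk_model(benzene_block())
  rings <- detect_aromatic_rings(m)
  expect_length(rings, 1L)
  expect_equal(rings[[1]]$size, 6L)
  expect_equal(rings[[1]]$ring_class, "ligand")
  # tryptophan: indole contributes a 5- and a 6-membered ring
  trp <- make_fixture(fixture_spec("TRP"))$model
  rings <- detect_aromatic_rings(trp)
  expect_length(rings, 2L)
  expect_setequal(vapply(rings, function(r) r$size, 1L), c(5L, 6L))
  expect_setequal(vapply(rings, function(r) r$ring_code, ""),
                  c("TRP.5", "TRP.6"))
  # cyclohexane chair: max plane deviation ~0.25 A exceeds the tolerance
  th <- seq(0, 300, by = 60) * pi / 180
  chair <- data.frame(elety = paste0("C", 1:6), elesy = "C", resid = "CHX",
                      chain = "A", resno = 1L,
                      x = 1.46 * cos(th), y = 1.46 * sin(th),
                      z = 0.25 * rep(c(1, -1), 3))
  d <- as.matrix(dist(chair[, c("x", "y", "z")]))
  expect_equal(d[1, 2], 1.54, tolerance = 0.02)   # realistic C-C bonds
  expect_length(detect_aromatic_rings(mk_model(chair)), 0L)
  # purine nucleotide: 6- and 5-membered rings reported separately
  g <- make_gnra_fixture("GAGA")$model
  codes <- vapply(detect_aromatic_rings(g), function(r) r$ring_code, "")
  expect_true(all(c("G.6", "G.5", "A.6", "A.5") %in% codes))
})

test_that("template rings are reproduced by generic perception on ligands", {
  for (kind in c("PHE", "HIS", "TRP")) {
    fx <- make_fixture(fixture_spec(kind))$model
    t_rings <- detect_aromatic_rings(fx)
    lig <- fx
    lig$atom$resid <- "LIG"
    lig$atom$type <- "HETATM"
    g_rings <- detect_aromatic_rings(lig)
    expect_length(g_rings, length(t_rings))
    t_sets <- lapply(t_rings, function(r) sort(r$names))
    g_sets <- lapply(g_rings, function(r) sort(r$names))
    for (s in t_sets) {
      expect_true(any(vapply(g_sets, identical, logical(1), y = s)),
                  label = paste(kind, "ring", paste(s, collapse = "+")))
    }
  }
})

test_that("anion sites cover carboxylates, phosphates and dictionary ligands", {
  asp <- data.frame(
    elety = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    elesy = c("N", "C", "C", "O", "C", "C", "O", "O"),
    resid = "ASP", chain = "A", resno = 1L,
    x = c(0, 1.2, 2.0, 1.9, 1.4, 2.2, 3.4, 1.6),
    y = c(0, 0.9, 0, 0.9, 2.2, 3.4, 3.5, 4.4),
    z = 0, type = "ATOM")
  s <- detect_anion_sites(mk_model(asp))
  expect_length(s, 1L)
  expect_setequal(s[[1]]$site_names, c("OD1", "OD2"))
  expect_equal(s[[1]]$planarity, "planar")
  expect_false(s[[1]]$metal_bound)
  # sulfate: four oxygens, not planar
  so4 <- make_fixture(fixture_spec("BNZ",
                                   data.frame(entity = "SO4", x = 4, h = 0.5)))
  s <- detect_anion_sites(so4$model)
  expect_length(s, 1L)
  expect_length(s[[1]]$site_names, 4L)
  expect_equal(s[[1]]$planarity, "other")
  # acetate 2.1 A from an iron becomes metal-bound
  act <- .subset2(make_fixture(fixture_spec(
    "BNZ", data.frame(entity = "ACT", x = 0.5, h = 3.3))), "model")
  anchor <- act$atom[act$atom$elety == "O" & act$atom$resid == "ACT", ]
  fe <- data.frame(eleno = max(act$atom$eleno) + 1L, elety = "FE",
                   elesy = "FE", alt = NA, resid = "FE", chain = "Z",
                   resno = 900L, insert = NA, x = anchor$x + 2.1,
                   y = anchor$y, z = anchor$z, o = 1, type = "HETATM")
  act$atom <- rbind(act$atom, fe)
  s <- detect_anion_sites(act)
  expect_true(s[[1]]$metal_bound)
  # nucleotide phosphates: charged oxygens only, ester oxygens excluded
  g <- make_gnra_fixture("GAGA", anion_pos = 3)$model
  ss <- detect_anion_sites(g)
  expect_length(ss, 3L)  # residues 2-4 carry phosphates
  expect_true(all(vapply(ss, function(a)
    all(a$site_names %in% c("OP1", "OP2")), logical(1))))
  # unknown ligands yield no site
  m <- mk_model(benzene_block(resid = "XYZ"))
  expect_length(detect_anion_sites(m), 0L)
})

test_that("cation sites: metals by element, Arg at CZ, Lys at NZ", {
  zn <- make_fixture(fixture_spec("BNZ",
                                  data.frame(entity = "ZN", x = 0, h = 3)))
  cs <- detect_cation_sites(zn$model)
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$kind, "metal")
  expect_equal(cs[[1]]$element, "ZN")
  # ideal guanidinium: CZ coincides with the nitrogen centroid
  arg <- data.frame(
    elety = c("NE", "CZ", "NH1", "NH2"), elesy = c("N", "C", "N", "N"),
    resid = "ARG", chain = "A", resno = 5L,
    x = c(-1.33, 0, 0.665, 0.665), y = c(0, 0, 1.152, -1.152), z = 0,
    type = "ATOM")
  cs <- detect_cation_sites(mk_model(arg))
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$kind, "Arg-guanidinium")
  ncen <- colMeans(arg[arg$elesy == "N", c("x", "y", "z")])
  expect_lt(vdist(unlist(cs[[1]]$position), unlist(ncen)), 0.1)
  # dictionary controls which elements count as metals
  na <- mk_model(chloride_block(c(0, 0, 0)))
  na$atom$elety <- "NA"; na$atom$elesy <- "NA"; na$atom$resid <- "NA"
  dict_no_na <- default_chem_dictionary(
    metal_elements = c("ZN", "MG", "FE"))
  expect_length(detect_cation_sites(na, dict_no_na), 0L)
  expect_length(detect_cation_sites(na), 1L)
})

test_that("hydrogen-bond donors require an attached hydrogen", {
  ser <- data.frame(
    elety = c("CB", "OG", "HG", "C", "O"),
    elesy = c("C", "O", "H", "C", "O"),
    resid = "SER", chain = "A", resno = 1L,
    x = c(0, 1.2, 2.0, -1.5, -2.2), y = c(0, 0.6, 0.2, 0.4, -0.5), z = 0,
    type = "ATOM")
  dn <- detect_h_donors(mk_model(ser))
  expect_length(dn, 1L)
  expect_equal(dn[[1]]$name, "OG")       # carbonyl O has no H: not a donor
  # ligand N-H counts once the hydrogen is present in the file
  lig <- data.frame(
    elety = c("N1", "HN1", "C2"), elesy = c("N", "H", "C"),
    resid = "LIG", chain = "B", resno = 2L,
    x = c(0, 0.9, -1.3), y = c(0, 0.4, 0.5), z = 0, type = "HETATM")
  dn <- detect_h_donors(mk_model(lig))
  expect_length(dn, 1L)
  expect_equal(dn[[1]]$resid, "LIG")
})

test_that("methyl sites cover the aliphatic amino acids", {
  df <- data.frame(
    elety = c("CB", "CG1", "CG2", "CB"), elesy = "C",
    resid = c("ALA", "VAL", "VAL", "PHE"), chain = "A",
    resno = c(1L, 2L, 2L, 3L),
    x = c(0, 5, 6, 10), y = 0, z = 0, type = "ATOM")
  ms <- detect_methyl_sites(mk_model(df))
  expect_length(ms, 3L)  # Phe CB is not a methyl
  expect_setequal(vapply(ms, function(s) s$resid, ""), c("ALA", "VAL"))
})

test_that("perception is invariant under rigid motion", {
  pl <- data.frame(entity = c("ACT", "ZN"), x = c(0.8, 4.0), h = c(3.3, 0.5),
                   azimuth = c(10, 200), side = 1L, plane_angle = c(20, 0))
  m <- make_fixture(fixture_spec("BNZ", pl, seed = 11))$model
  set.seed(42)
  R <- rand_rotation()
  tr <- c(13.1, -7.2, 4.4)
  m2 <- m
  co <- as.matrix(m$atom[, c("x", "y", "z")]) %*% t(R)
  m2$atom$x <- co[, 1] + tr[1]
  m2$atom$y <- co[, 2] + tr[2]
  m2$atom$z <- co[, 3] + tr[3]
  for (mm in list(m, m2)) {
    expect_length(detect_aromatic_rings(mm), 1L)
    a <- detect_anion_sites(mm)
    expect_length(a, 1L)
    expect_equal(a[[1]]$planarity, "planar")
    expect_length(detect_cation_sites(mm), 1L)
  }
  p1 <- find_pairs(m, detect_aromatic_rings(m), detect_anion_sites(m))$pairs
  p2 <- find_pairs(m2, detect_aromatic_rings(m2), detect_anion_sites(m2))$pairs
  expect_equal(p1$x, p2$x, tolerance = 1e-9)
  expect_equal(p1$h, p2$h, tolerance = 1e-9)
  expect_equal(p1$orientation_angle, p2$orientation_angle, tolerance = 1e-6)
})

test_that("anion and cation sites never share a parent atom", {
  pl <- data.frame(entity = c("ACT", "ZN", "CL"), x = c(0.8, 4.0, 4.5),
                   h = c(3.3, 0.5, 1.0), azimuth = c(10, 120, 260),
                   side = 1L, plane_angle = 0)
  m <- make_fixture(fixture_spec("BNZ", pl, seed = 12))$model
  an <- detect_anion_sites(m)
  ca <- detect_cation_sites(m)
  an_keys <- unlist(lapply(an, function(a) a$res_key))
  ca_keys <- vapply(ca, function(cc) cc$res_key, "")
  expect_length(intersect(an_keys, ca_keys), 0L)
})
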