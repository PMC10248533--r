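# Superposition, SASA, interface burial, salt bridges, cis peptides,
# hydrophobicity and cavity volume.

test_that("Kabsch superposition is exact on rigid copies and matches the quaternion oracle", {
  set.seed(401)
  pts <- matrix(rnorm(60), 20, 3)
  sp0 <- kabschSuperpose(pts, pts)
  expect_equal(sp0@rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0@rotation, diag(3), tolerance = 1e-8)
  expect_equal(sp0@translation, rep(0, 3), tolerance = 1e-8)
  # rigid-transformed copy superposes to zero
  moved <- random_rigid(pts, seed = 402)
  sp1 <- kabschSuperpose(pts, moved)
  expect_lt(sp1@rmsd, 1e-9)
  expect_lt(max(abs(applySuperposition(sp1, moved) - pts)), 1e-8)
  # 50 random noisy pairs agree with the quaternion method to 1e-8
  for (i in 1:50) {
    a <- matrix(rnorm(60), 20, 3)
    b <- random_rigid(a) + matrix(rnorm(60, sd = 0.3), 20, 3)
    sp <- kabschSuperpose(a, b)
    expect_equal(sp@rmsd, oracle_quaternion_rmsd(a, b),
                 tolerance = 1e-8)
    expect_equal(det(sp@rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabschSuperpose(pts[1:2, ], pts[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("backbone RMSD pairs chains and handles renames", {
  s <- makeToyDimer(8, seed = 3, n_res = 10)
  expect_equal(backboneRmsd(s, s)$rmsd, 0, tolerance = 1e-9)
  # chain renaming is absorbed by identity-based pairing
  s2 <- s
  a <- atomTable(s2)
  a$chain <- chartr("AB", "XY", a$chain)
  s2 <- new("StructureModel", atoms = a)
  expect_equal(backboneRmsd(s, s2)$rmsd, 0, tolerance = 1e-9)
  # rigid motion of the whole dimer leaves the backbone RMSD at zero
  a3 <- atomTable(s)
  xyz <- random_rigid(as.matrix(a3[c("x", "y", "z")]), seed = 404)
  a3[c("x", "y", "z")] <- xyz
  s3 <- new("StructureModel", atoms = a3)
  expect_lt(backboneRmsd(s, s3)$rmsd, 1e-6)
})

test_that("single-atom and far-pair SASA match the analytic sphere", {
  one <- new("StructureModel", atoms = data.frame(
    chain = "A", resno = 1L, insert = "", resid = "ALA", atom = "CA",
    element = "C", x = 0, y = 0, z = 0, occ = 1))
  a1 <- shrakeRupleySasa(one, probe = 1.4, n_points = 960)
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  two <- new("StructureModel", atoms = data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "ALA", atom = "CA",
    element = "C", x = c(0, 100), y = 0, z = 0, occ = 1))
  expect_equal(sum(shrakeRupleySasa(two)), 2 * 4 * pi * 3.1^2,
               tolerance = 0.01)
  # two overlapping atoms against a dense-sampling oracle
  over <- new("StructureModel", atoms = data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "ALA", atom = "CA",
    element = "C", x = c(0, 2.0), y = 0, z = 0, occ = 1))
  coarse <- sum(shrakeRupleySasa(over, n_points = 960))
  dense <- sum(shrakeRupleySasa(over, n_points = 20000))
  expect_equal(coarse, dense, tolerance = 0.02)
  # SASA never increases when atoms are added
  expect_lte(sum(shrakeRupleySasa(over)),
             sum(shrakeRupleySasa(one)) * 2 + 1e-6)
  # unknown element falls back with a warning
  odd <- new("StructureModel", atoms = data.frame(
    chain = "A", resno = 1L, insert = "", resid = "UNK", atom = "Q1",
    element = "Q", x = 0, y = 0, z = 0, occ = 1))
  expect_warning(shrakeRupleySasa(odd), "unknown element")
})

test_that("interface burial is symmetric, vanishes at distance, and shrinks with separation", {
  far <- makeToyDimer(100, seed = 5, n_res = 8)
  rep_far <- buriedInterfaceArea(far, "A", "B", n_points = 480)
  expect_lt(rep_far@deltaSasaTotal, 1.0)
  near <- makeToyDimer(8, seed = 5, n_res = 8)
  rep_near <- buriedInterfaceArea(near, "A", "B", n_points = 480)
  expect_gt(rep_near@deltaSasaTotal, 50)
  expect_equal(rep_near@deltaSasaHalf, rep_near@deltaSasaTotal / 2)
  # label swap symmetry is exact
  swapped <- buriedInterfaceArea(near, "B", "A", n_points = 480)
  expect_equal(swapped@deltaSasaTotal, rep_near@deltaSasaTotal,
               tolerance = 1e-9)
  # monotone decrease with separation
  areas <- vapply(c(8, 10, 12, 20), function(sep) {
    s <- makeToyDimer(sep, seed = 5, n_res = 8)
    buriedInterfaceArea(s, "A", "B", n_points = 480)@deltaSasaTotal
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  # rigid motion invariance
  a <- atomTable(near)
  a[c("x", "y", "z")] <- random_rigid(as.matrix(a[c("x", "y", "z")]),
                                      seed = 406)
  moved <- new("StructureModel", atoms = a)
  # the sampling lattice is fixed in space, so rigid motion moves the
  # sample points relative to the atoms: invariance holds to the
  # point-sampling resolution, not to machine precision
  rep_mv <- buriedInterfaceArea(moved, "A", "B", n_points = 480)
  expect_equal(rep_mv@deltaSasaTotal, rep_near@deltaSasaTotal,
               tolerance = 0.01)
  expect_error(buriedInterfaceArea(near, "A", "A"), "overlap")
})

test_that("salt bridges are detected inside and not outside the cutoff", {
  close_pair <- makeToyDimer(30, seed = 7, n_res = 6,
                             salt_bridge_distance = 3.5)
  sb <- detectSaltBridges(close_pair, "A", "B")
  expect_gte(nrow(sb), 1L)
  expect_true(all(sb$type == "salt bridge"))
  far_pair <- makeToyDimer(30, seed = 7, n_res = 6,
                           salt_bridge_distance = 6.0)
  expect_equal(nrow(detectSaltBridges(far_pair, "A", "B")), 0L)
  # the interface report carries contact types
  rep_near <- buriedInterfaceArea(close_pair, "A", "B",
                                  n_points = 240)
  expect_true("salt bridge" %in% rep_near@contacts$type)
})

omega_fixture <- function(omega_deg) {
  # CA-C-N-CA with an exactly prescribed omega dihedral: the C-N bond
  # lies along +x, CA1 sits in the xy-plane, CA2 is rotated about the
  # bond axis by omega relative to CA1's side
  th <- omega_deg * pi / 180
  atoms <- data.frame(
    chain = "A", resno = c(1L, 1L, 2L, 2L), insert = "",
    resid = c("GLY", "GLY", "PRO", "PRO"),
    atom = c("CA", "C", "N", "CA"),
    element = c("C", "C", "N", "C"),
    x = c(-0.5, 0, 1.33, 1.83),
    y = c(1.4, 0, 0, 1.45 * cos(th)),
    z = c(0, 0, 0, 1.45 * sin(th)),
    occ = 1, stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms)
}

test_that("cis-peptide detection pins omega near 0 and skips chain breaks", {
  cis <- detectCisPeptides(omega_fixture(0))
  expect_equal(nrow(cis), 1L)
  expect_lt(abs(cis$omega), 5)
  expect_identical(cis$resid, "PRO")
  trans <- detectCisPeptides(omega_fixture(180))
  expect_equal(nrow(trans), 0L)
  expect_equal(nrow(detectCisPeptides(omega_fixture(29))), 1L)
  expect_equal(nrow(detectCisPeptides(omega_fixture(31))), 0L)
  # a broken chain (C-N > 2.5 A) is skipped
  s <- omega_fixture(0)
  a <- atomTable(s)
  a$x[a$resno == 2] <- a$x[a$resno == 2] + 10
  broken <- new("StructureModel", atoms = a)
  expect_equal(nrow(detectCisPeptides(broken)), 0L)
})

test_that("hydrophobicity map reproduces the published scale", {
  atoms <- data.frame(
    chain = "A", resno = 1:3, insert = "",
    resid = c("ILE", "ARG", "GLY"), atom = "CA", element = "C",
    x = 0, y = 0, z = as.numeric(1:3), occ = 1,
    stringsAsFactors = FALSE)
  s <- new("StructureModel", atoms = atoms)
  h <- hydrophobicityMap(s)
  expect_equal(h$hydropathy, c(4.5, -4.5, -0.4))
  odd <- atoms
  odd$resid <- "XXX"
  expect_warning(h2 <- hydrophobicityMap(
    new("StructureModel", atoms = odd)), "unknown residue")
  expect_true(all(h2$hydropathy == 0))
})

shell_structure <- function(r_inner = 6, n = 200) {
  # spherical shell of carbon atoms enclosing a cavity; atom centres
  # sit far enough out that the probe-inflated shell stays closed
  pts <- Get3Atlas:::sphere_points(n) * (r_inner + 1.7 + 1.4)
  new("StructureModel", atoms = data.frame(
    chain = "A", resno = seq_len(n), insert = "", resid = "ALA",
    atom = "CA", element = "C", x = pts[, 1], y = pts[, 2],
    z = pts[, 3], occ = 1, stringsAsFactors = FALSE))
}

test_that("cavity volume matches the analytic hollow shell and converges", {
  s <- shell_structure(6)
  cv <- cavityVolume(s, grid = 0.5)
  expect_equal(cv$volume, 4 / 3 * pi * 6^3, tolerance = 0.10)
  # solid cluster has no cavity
  solid <- makeToyDimer(8, seed = 9, n_res = 6)
  expect_equal(cavityVolume(solid, grid = 0.6)$volume, 0)
  # halving the grid changes the shell volume by < 5%
  cv2 <- cavityVolume(s, grid = 0.25)
  expect_lt(abs(cv2$volume - cv$volume) / cv2$volume, 0.05)
  # capacity estimate uses the documented constant
  expect_equal(cv$capacity_residues, cv$volume / 170)
})
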