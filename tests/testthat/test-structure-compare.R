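fixture <- gen_two_domain_fixture(shift = c(2, 0, 0), n_per_domain = 20,
                                  seed = 99)

test_that("PDB and mmCIF renderings of a fixture parse identically", {
  a_pdb <- load_structure(fixture$stateA_pdb)
  a_cif <- load_structure(fixture$stateA_cif)
  expect_equal(nrow(a_pdb), 40)
  expect_equal(a_pdb$resno, a_cif$resno)
  expect_equal(a_pdb[, c("x", "y", "z")], a_cif[, c("x", "y", "z")],
               tolerance = 1e-6)
  expect_error(load_structure(fixture$stateA_pdb, chain = "Z"), "not present")
  expect_error(load_structure("nothing.xyz"), "unknown structure format")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   3       2.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- suppressWarnings(load_structure(f))
  expect_equal(nrow(m), 3)
  expect_equal(m$x[m$resno == 1], 5)  # occupancy 0.60 conformer kept
})

test_that("superposition removes rigid motion and is transform-invariant", {
  a <- load_structure(fixture$stateA_pdb)
  # self-superposition: identity transform, zero RMSD
  s <- superpose(a, a)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$R, diag(3), tolerance = 1e-10)
  # pure translation is removed exactly
  b <- a; b$x <- b$x + 3; b$y <- b$y + 4
  st <- superpose(b, a)
  expect_equal(st$rmsd, 0, tolerance = 1e-9)
  expect_equal(st$t, c(-3, -4, 0), tolerance = 1e-9)
  # RMSD invariant under arbitrary rigid transforms of the mobile model
  set.seed(41)
  b2 <- load_structure(fixture$stateB_pdb)
  base_rmsd <- superpose(b2, a)$rmsd
  for (i in 1:5) {
    ang <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                   0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                   sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
    R <- Rx %*% Rz
    xyz <- as.matrix(as.data.frame(b2)[, c("x", "y", "z")]) %*% R
    b3 <- b2; b3$x <- xyz[, 1] + runif(1, -9, 9)
    b3$y <- xyz[, 2]; b3$z <- xyz[, 3] + runif(1, -9, 9)
    expect_equal(superpose(b3, a)$rmsd, base_rmsd, tolerance = 1e-8)
  }
  expect_error(superpose(a, a, selection = 1:2), ">= 3 common")
})

test_that("the Kabsch rotation agrees with the bio3d reference", {
  set.seed(42)
  P <- matrix(rnorm(45), 15)
  th <- 0.9
  R0 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  Q <- P %*% R0
  ours <- cicrfit:::.kabsch(P, Q)
  # bio3d returns the fitted coordinates of xx, not the rotation itself
  ref <- matrix(bio3d::rot.lsq(xx = as.vector(t(P)), yy = as.vector(t(Q))),
                ncol = 3, byrow = TRUE)
  expect_equal(P %*% ours, Q, tolerance = 1e-8)
  expect_equal(unname(P %*% ours), unname(ref), tolerance = 1e-6)
})

test_that("domain displacement reports the constructed rigid shift", {
  a <- load_structure(fixture$stateA_pdb)
  b <- load_structure(fixture$stateB_pdb)
  # identical states: zero displacement
  d0 <- domain_displacement(a, a, fixture$domains$A, fixture$domains$B)
  expect_equal(d0$mean_displacement, 0, tolerance = 1e-10)
  # 2 A shift of domain B, frame = domain A
  d <- domain_displacement(a, b, fixture$domains$A, fixture$domains$B)
  expect_equal(d$mean_displacement, 2, tolerance = 1e-9)
  expect_equal(d$centroid_shift, c(2, 0, 0), tolerance = 1e-9)
  expect_equal(d$frame_rmsd, 0, tolerance = 1e-9)
  expect_error(domain_displacement(a, b, fixture$domains$A, 900:950),
               "no shared")
})

test_that("residue pair distances come out in both modes", {
  a <- load_structure(fixture$stateA_pdb)
  expect_equal(residue_pair_distance(a, 1, 1), 0)
  d12 <- residue_pair_distance(a, 1, 2)
  xyz <- as.data.frame(a)
  manual <- sqrt(sum((xyz[xyz$resno == 1, c("x", "y", "z")] -
                        xyz[xyz$resno == 2, c("x", "y", "z")])^2))
  expect_equal(d12, manual, tolerance = 1e-9)
  # single-atom residues: centroid mode equals min mode
  expect_equal(residue_pair_distance(a, 1, 2, mode = "centroid"), d12,
               tolerance = 1e-9)
  expect_error(residue_pair_distance(a, 1, 999), "absent")
})

test_that("the pocket gauge is exact on a square and scales quadratically", {
  mk <- function(xy, z = 0) {
    structure(data.frame(chain = "A", resno = seq_len(nrow(xy)), insert = "",
                         resid = "GLU", elety = "OE1",
                         x = xy[, 1], y = xy[, 2], z = z, o = 1),
              class = c("structure_model", "data.frame"))
  }
  sq <- matrix(c(0, 0, 2, 0, 2, 2, 0, 2), ncol = 2, byrow = TRUE)
  g1 <- pocket_gauge(mk(sq), 1:4)
  expect_equal(g1$area, 4)
  expect_equal(g1$distances["1:OE1", "2:OE1"], 2)
  # uniform x2 scaling quadruples the area
  expect_equal(pocket_gauge(mk(2 * sq), 1:4)$area, 16)
  # shrinking toward the centroid by 10% scales the area by 0.81
  ctr <- colMeans(sq)
  shrunk <- sweep(sweep(sq, 2, ctr), 1:2, 0.9, "*")
  shrunk <- sweep(shrunk, 2, ctr, "+")
  expect_equal(pocket_gauge(mk(shrunk), 1:4)$area, 4 * 0.81, tolerance = 1e-9)
  # rotation/translation invariance (rotate the square out of plane)
  th <- 0.6
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3,
              byrow = TRUE)
  P3 <- cbind(sq, 0) %*% R
  m2 <- mk(P3[, 1:2]); m2$z <- P3[, 3]; m2$x <- P3[, 1] + 5; m2$y <- P3[, 2] - 2
  expect_equal(pocket_gauge(m2, 1:4)$area, 4, tolerance = 1e-9)
  expect_error(pocket_gauge(mk(sq[1:2, , drop = FALSE]), 1:2), ">= 3 gauge")
})

test_that("domain and site dictionaries are internally consistent", {
  d <- ryr1_domains()
  expect_equal(range(d$csol), c(3667, 4253))
  expect_equal(range(d$ctd), c(4957, 5037))
  ov <- combn(names(d), 2, function(nm) length(intersect(d[[nm[1]]], d[[nm[2]]])))
  expect_true(all(ov == 0))
  sites <- ryr1_ryr2_sites()
  expect_true(!any(duplicated(stats::na.omit(sites$ryr2))))
  expect_equal(sites$ryr1[sites$aa == "W"], 4716)
  expect_match(sites$note[sites$ryr1 == 4996], "4966")
})
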