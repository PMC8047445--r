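# build a 3-residue backbone with prescribed central phi/psi via the internal
# chain builder, bypassing the sampling layer
analytic_traj <- function(phi, psi) {
  mdl <- rep(list(list(phi = list(mu = phi, kappa = 1e9, w = 1),
                       psi = list(mu = psi, kappa = 1e9, w = 1))), 3)
  names(mdl) <- paste0("R", 1:3)
  gen_peptide_traj(1, mdl, seed = 1)
}

test_that("phi/psi are recovered from analytically constructed coordinates", {
  np <- slimbind:::nerf_place
  # hand-built chain: residue-2 phi = -60, psi = -45
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  xyz <- matrix(0, 9, 3)
  xyz[1, ] <- c(0, 0, 0); xyz[2, ] <- c(b_nca, 0, 0)
  th <- 111 * pi / 180
  xyz[3, ] <- xyz[2, ] + b_cac * c(-cos(th), sin(th), 0)
  xyz[4, ] <- np(xyz[1, ], xyz[2, ], xyz[3, ], b_cn, 116.2, 135)   # psi1
  xyz[5, ] <- np(xyz[2, ], xyz[3, ], xyz[4, ], b_nca, 121.7, 180)  # omega
  xyz[6, ] <- np(xyz[3, ], xyz[4, ], xyz[5, ], b_cac, 111.0, -60)  # phi2
  xyz[7, ] <- np(xyz[4, ], xyz[5, ], xyz[6, ], b_cn, 116.2, -45)   # psi2
  xyz[8, ] <- np(xyz[5, ], xyz[6, ], xyz[7, ], b_nca, 121.7, 180)
  xyz[9, ] <- np(xyz[6, ], xyz[7, ], xyz[8, ], b_cac, 111.0, 170)
  atoms <- data.frame(res_id = rep(1:3, each = 3), res_name = "ALA",
                      atom_name = rep(c("N", "CA", "C"), 3))
  tr <- peptide_trajectory(array(xyz, c(9, 3, 1)), atoms)
  dh <- compute_phi_psi(tr, 2)
  expect_equal(dh$phi, -60, tolerance = 1e-6)
  expect_equal(dh$psi, -45, tolerance = 1e-6)
})

test_that("dihedral sign convention matches an independent torsion routine", {
  skip_if_not_installed("bio3d")
  tr <- gen_peptide_traj(3, ixiv_peptide_model("broad"), seed = 4)
  dh <- compute_phi_psi(tr, 4)
  for (k in 1:3) {
    x <- tr$coords[, , k]
    expect_equal(dh$phi[k], bio3d::torsion.xyz(as.vector(t(x[9:12, ]))),
                 tolerance = 1e-6)
    expect_equal(dh$psi[k], bio3d::torsion.xyz(as.vector(t(x[10:13, ]))),
                 tolerance = 1e-6)
  }
})

test_that("an all-trans zig-zag backbone has psi = 180", {
  tr <- analytic_traj(180, 180)
  dh <- compute_phi_psi(tr, 2)
  expect_equal(abs(dh$psi), 180, tolerance = 1e-4)
  expect_equal(abs(dh$phi), 180, tolerance = 1e-4)
})

test_that("degenerate and terminal dihedrals raise errors", {
  atoms <- data.frame(res_id = rep(1:2, each = 3), res_name = "GLY",
                      atom_name = rep(c("N", "CA", "C"), 2))
  lin <- array(cbind(seq_len(6), 0, 0), c(6, 3, 1))
  tr <- peptide_trajectory(lin, atoms)
  expect_error(compute_phi_psi(tr, 2), "psi undefined|degenerate")
  tr2 <- gen_peptide_traj(1, seed = 1)
  expect_error(compute_phi_psi(tr2, 1), "phi undefined")
  expect_error(compute_phi_psi(tr2, 8), "psi undefined")
  expect_error(slimbind:::dihedral_angle(matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0,
                                                  3, 1, 0), 4, 3, byrow = TRUE)),
               "degenerate")
})

test_that("dihedrals are invariant under global rotation and translation", {
  tr <- gen_peptide_traj(2, seed = 9)
  dh <- compute_phi_psi(tr, 4)
  ang <- c(0.4, -1.1, 2.2)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Rx
  tr2 <- tr
  for (k in 1:2) tr2$coords[, , k] <- t(R %*% t(tr$coords[, , k])) + 5
  dh2 <- compute_phi_psi(tr2, 4)
  expect_equal(dh2$phi, dh$phi, tolerance = 1e-9)
  expect_equal(dh2$psi, dh$psi, tolerance = 1e-9)
})

test_that("free-energy surfaces reference the most populated bin to zero", {
  one_bin <- data.frame(phi = rep(-64, 40), psi = rep(151, 40))
  f <- free_energy_surface(one_bin)
  expect_equal(sum(!is.na(f$dg)), 1)
  expect_equal(min(f$dg, na.rm = TRUE), 0)

  # two bins, 73 vs 27 counts, at 310.15 K
  two <- data.frame(phi = c(rep(-64, 73), rep(56, 27)),
                    psi = c(rep(151, 73), rep(41, 27)))
  f2 <- free_energy_surface(two, temperature = 310.15)
  dgs <- sort(as.vector(f2$dg[!is.na(f2$dg)]))
  expect_equal(dgs[1], 0)
  expect_equal(dgs[2], 8.31446e-3 * 310.15 * log(73 / 27), tolerance = 1e-4)
  expect_true(all(is.finite(f2$dg[!is.na(f2$dg)])))
})

test_that("free-energy surfaces are invariant under frame duplication", {
  tr <- gen_peptide_traj(150, seed = 3)
  dh <- compute_phi_psi(tr, 4)
  f1 <- free_energy_surface(dh)
  f2 <- free_energy_surface(rbind(dh, dh))
  expect_equal(f1$dg, f2$dg, tolerance = 1e-12)
  expect_identical(f2$counts, 2L * f1$counts)
})

test_that("uniform angle sampling yields a nearly flat surface", {
  set.seed(8)
  unif <- data.frame(phi = runif(40000, -180, 180),
                     psi = runif(40000, -180, 180))
  f <- free_energy_surface(unif, n_bins = 12)
  expect_equal(sum(is.na(f$dg)), 0)
  expect_lt(max(f$dg, na.rm = TRUE), 1.0)  # kJ/mol; sampling noise only
})

test_that("superposition recovers exact rigid transforms and matches Horn", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  s0 <- superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  ang <- 1.1
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, byrow = TRUE)
  Y <- t(R %*% t(X)) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  expect_lt(superpose(Y, X)$rmsd, 1e-9)
  for (i in 1:20) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(superpose(A, B)$rmsd, quaternion_rmsd(A, B), tolerance = 1e-9)
  }
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("combined PCA separates broad from narrow ensembles", {
  trn <- gen_peptide_traj(150, ixiv_peptide_model("narrow"), seed = 6)
  trb <- gen_peptide_traj(150, ixiv_peptide_model("broad"), seed = 6)
  ref <- slimbind:::ca_coords(trn)[, , 1]
  p <- pca_combined(trn, trb, ref, labels = c("narrow", "broad"))
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_equal(sum(p$explained), 1)
  expect_equal(crossprod(p$components), diag(ncol(p$components)),
               tolerance = 1e-8)
  spread <- tapply(p$projections$pc1^2 + p$projections$pc2^2,
                   p$projections$source, mean)
  expect_gt(spread[["broad"]], spread[["narrow"]])
  # identical inputs give identical clouds
  p2 <- pca_combined(trn, trn, ref)
  pr <- p2$projections
  expect_equal(pr$pc1[pr$source == "a"], pr$pc1[pr$source == "b"])
})

test_that("PCA on frames varying along one direction loads PC1 fully", {
  tr <- gen_peptide_traj(1, seed = 2)
  coords <- array(rep(tr$coords[, , 1], 20), c(dim(tr$coords)[1], 3, 20))
  shift <- seq(0, 5, length.out = 20)
  # move one CA along x only (no rigid-body component once superposed)
  for (k in 1:20) coords[11, 1, k] <- coords[11, 1, k] + shift[k]
  tr2 <- peptide_trajectory(coords, tr$atoms)
  ref <- slimbind:::ca_coords(tr2)[, , 1]
  p <- pca_combined(tr2, tr2, ref)
  expect_gt(p$explained[1], 0.99)
})

test_that("narrow ensembles occupy fewer Ramachandran bins than broad ones", {
  for (s in c(1, 2)) {
    fn <- free_energy_surface(compute_phi_psi(
      gen_peptide_traj(300, ixiv_peptide_model("narrow"), seed = s), 4))
    fb <- free_energy_surface(compute_phi_psi(
      gen_peptide_traj(300, ixiv_peptide_model("broad"), seed = s), 4))
    expect_lt(sum(!is.na(fn$dg)), sum(!is.na(fb$dg)))
  }
})
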