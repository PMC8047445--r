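#' Peptide trajectory container
#'
#' Multi-frame coordinates with a constant atom table. Coordinates are held
#' internally in Angstrom; nm inputs are converted on construction.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`.
#' @param atoms data.frame with columns `res_id` (integer residue index),
#'   `res_name`, `atom_name`.
#' @param dt_ps frame spacing in ps.
#' @param unit `"angstrom"` or `"nm"` (input unit of `coords`).
#' @export
peptide_trajectory <- function(coords, atoms, dt_ps = 1, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[1] == nrow(atoms))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (unit == "nm") coords <- coords * 10
  req <- c("res_id", "res_name", "atom_name")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table missing: ", paste(miss, collapse = ", "))
  structure(list(coords = coords, atoms = as.data.frame(atoms)[req],
                 dt_ps = dt_ps),
            class = "peptide_trajectory")
}

#' @export
print.peptide_trajectory <- function(x, ...) {
  cat(sprintf("peptide_trajectory: %d atoms, %d residues, %d frames (dt = %g ps)\n",
              dim(x$coords)[1], length(unique(x$atoms$res_id)),
              dim(x$coords)[3], x$dt_ps))
  invisible(x)
}

# signed dihedral (degrees) for four points (rows of a 4x3 matrix)
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("degenerate (collinear) atoms; dihedral undefined")
  # IUPAC sign: atan2((n1 x n2).b2hat, n1.n2)
  n1xn2 <- c(n1[2] * n2[3] - n1[3] * n2[2],
             n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(n1xn2 * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  # wrap into (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedral series for one residue
#'
#' phi is the C(i-1)-N-CA-C torsion, psi the N-CA-C-N(i+1) torsion; both
#' require the neighbouring residue's backbone atom, so terminal residues
#' raise an error naming the missing dihedral.
#'
#' @param traj a [peptide_trajectory()].
#' @param residue residue index (as in the atom table's `res_id`).
#' @return A data.frame with per-frame `phi` and `psi` in degrees, wrapped to
#'   `(-180, 180]`; class `dihedral_series`.
#' @export
compute_phi_psi <- function(traj, residue) {
  at <- traj$atoms
  idx <- function(res, name) {
    i <- which(at$res_id == res & at$atom_name == name)
    if (length(i) != 1) NA_integer_ else i
  }
  iCp <- idx(residue - 1, "C")
  iN <- idx(residue, "N"); iCA <- idx(residue, "CA"); iC <- idx(residue, "C")
  iNn <- idx(residue + 1, "N")
  if (any(is.na(c(iN, iCA, iC)))) stop("residue ", residue, " lacks backbone atoms")
  if (is.na(iCp)) stop("phi undefined for residue ", residue, ": no preceding C")
  if (is.na(iNn)) stop("psi undefined for residue ", residue, ": no following N")
  nf <- dim(traj$coords)[3]
  phi <- psi <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k]
    phi[k] <- dihedral_angle(xyz[c(iCp, iN, iCA, iC), ])
    psi[k] <- dihedral_angle(xyz[c(iN, iCA, iC, iNn), ])
  }
  structure(data.frame(frame = seq_len(nf), phi = phi, psi = psi),
            residue = residue, class = c("dihedral_series", "data.frame"))
}

#' Ramachandran free-energy surface
#'
#' Bins (phi, psi) on a periodic grid and converts occupancies to relative
#' free energies `dG = -kB T ln(n / n_max)`, so the most populated bin sits
#' at 0. Empty bins are masked (NA), never infinite.
#'
#' @param dihedrals a [compute_phi_psi()] result (or any data.frame with
#'   `phi`, `psi` in degrees).
#' @param n_bins bins per axis (default 36, i.e. 10-degree bins).
#' @param temperature in K (default 310.15).
#' @return A `free_energy_surface`: `dg` matrix (kJ/mol, NA = unoccupied),
#'   `counts`, `breaks`, `temperature`.
#' @export
free_energy_surface <- function(dihedrals, n_bins = 36, temperature = 310.15) {
  stopifnot(n_bins >= 4, nrow(dihedrals) >= 1)
  wrap <- function(a) ((a + 180) %% 360) - 180  # into [-180, 180)
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  bin <- function(a) pmin(pmax(findInterval(wrap(a), breaks,
                                            rightmost.closed = TRUE), 1), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  ij <- cbind(bin(dihedrals$phi), bin(dihedrals$psi))
  for (k in seq_len(nrow(ij))) counts[ij[k, 1], ij[k, 2]] <-
    counts[ij[k, 1], ij[k, 2]] + 1L
  dg <- matrix(NA_real_, n_bins, n_bins)
  occ <- counts > 0
  dg[occ] <- -.kB_kJ * temperature * log(counts[occ] / max(counts))
  structure(list(dg = dg, counts = counts, breaks = breaks,
                 temperature = temperature),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface: %dx%d bins, %d occupied, max dG %.2f kJ/mol (T = %g K)\n",
              nrow(x$dg), ncol(x$dg), sum(!is.na(x$dg)),
              max(x$dg, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' Least-squares rigid-body superposition
#'
#' Optimal rotation + translation (Kabsch, via SVD with reflection guard)
#' of `frame` onto `reference`.
#'
#' @param frame,reference `n x 3` coordinate matrices, n >= 3.
#' @return List: `coords` (aligned frame), `rmsd`, `rotation`, `translation`.
#' @export
superpose <- function(frame, reference) {
  stopifnot(nrow(frame) == nrow(reference), nrow(frame) >= 3)
  cf <- colMeans(frame); cr <- colMeans(reference)
  A <- sweep(frame, 2, cf); B <- sweep(reference, 2, cr)
  if (min(svd(A)$d) < 1e-10 * max(svd(A)$d))
    stop("degenerate (collinear) point set")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  aligned <- t(R %*% t(A)) + matrix(cr, nrow(frame), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((aligned - reference)^2)))
  list(coords = aligned, rmsd = rmsd, rotation = R, translation = cr - cf)
}

# CA coordinates (n_res x 3 x n_frames), optionally without terminal residues
ca_coords <- function(traj, exclude_terminal = TRUE) {
  res <- sort(unique(traj$atoms$res_id))
  if (exclude_terminal) {
    if (length(res) <= 2) stop("too few residues after terminal exclusion")
    res <- res[-c(1, length(res))]
  }
  idx <- vapply(res, function(r)
    which(traj$atoms$res_id == r & traj$atoms$atom_name == "CA"), integer(1))
  traj$coords[idx, , , drop = FALSE]
}

#' Combined-trajectory principal-component analysis
#'
#' Concatenates two trajectories, extracts CA atoms (N-/C-terminal residues
#' excluded by default), superposes every frame on a reference conformation,
#' and eigendecomposes the covariance of the flattened coordinates. Frame
#' projections on PC1/PC2 are labelled by source trajectory.
#'
#' @param traj_a,traj_b [peptide_trajectory()] objects with matching CA counts.
#' @param reference `n_ca x 3` reference CA coordinates (e.g. a bound-state
#'   conformation), after the same terminal exclusion.
#' @param exclude_terminal drop first and last residue (default TRUE).
#' @param labels length-2 source labels.
#' @return A `pca_result`: `components`, `explained`, `projections`
#'   (data.frame `pc1`, `pc2`, `source`), `total_variance`.
#' @export
pca_combined <- function(traj_a, traj_b, reference, exclude_terminal = TRUE,
                         labels = c("a", "b")) {
  ca_a <- ca_coords(traj_a, exclude_terminal)
  ca_b <- ca_coords(traj_b, exclude_terminal)
  if (dim(ca_a)[1] != dim(ca_b)[1]) stop("CA atom-count mismatch")
  if (nrow(reference) != dim(ca_a)[1])
    stop("reference CA count mismatch: got ", nrow(reference),
         ", need ", dim(ca_a)[1])
  na <- dim(ca_a)[3]; nb <- dim(ca_b)[3]
  flat <- matrix(0, na + nb, 3 * dim(ca_a)[1])
  for (k in seq_len(na))
    flat[k, ] <- as.vector(t(superpose(ca_a[, , k], reference)$coords))
  for (k in seq_len(nb))
    flat[na + k, ] <- as.vector(t(superpose(ca_b[, , k], reference)$coords))
  mu <- colMeans(flat)
  X <- sweep(flat, 2, mu)
  cv <- crossprod(X) / (nrow(X) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  proj <- X %*% eig$vectors[, 1:2]
  structure(list(components = eig$vectors,
                 explained = ev / sum(ev),
                 eigenvalues = ev,
                 total_variance = sum(ev),
                 projections = data.frame(pc1 = proj[, 1], pc2 = proj[, 2],
                                          source = rep(labels, c(na, nb)))),
            class = "pca_result")
}
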