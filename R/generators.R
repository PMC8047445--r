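#' Human-like amino-acid frequencies
#'
#' Rounded composition of a typical human proteome, used as the generator
#' default; sums to 1.
#' @export
aa_frequencies_human <- function() {
  f <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
         H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
         P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
         W = 0.012, Y = 0.027)
  f / sum(f)
}

# deterministic per-item sub-seed so plantings are order-independent
sub_seed <- function(seed, k) (seed * 48271 + k * 69621) %% 2147483563L

#' Synthetic NMR titration series
#'
#' Emulates a 2D 1H-15N titration at fixed protein concentration. Fast-exchange
#' residues move with the two-state bound fraction of protein
#' (`shift = apo + fb * ddmax` per axis, Gaussian noise added); slow-exchange
#' residues keep their apo position and lose intensity as `1 - fb`.
#'
#' @param kd planted dissociation constant (uM).
#' @param residues data.frame with columns `residue`, `ddmax_h`, `ddmax_n`
#'   (ppm, per-axis maximum shift changes).
#' @param protein_total protein concentration (uM).
#' @param ligand_ladder increasing ligand concentrations (uM), starting at 0.
#' @param noise_sd Gaussian shift noise on the weighted scale (ppm): sd
#'   `noise_sd` on 1H and `noise_sd / 0.2` on 15N, so each weighted axis
#'   contributes `noise_sd` to the CSP.
#' @param slow_residues labels (subset of `residues$residue`) planted as
#'   slow-exchange (broadening) peaks.
#' @param seed generator seed.
#' @return A [titration_series()] with a `truth` attribute (planted kd,
#'   per-residue combined ddmax, apo positions, scenario parameters).
#' @export
gen_titration <- function(kd, residues, protein_total, ligand_ladder,
                          noise_sd = 0.002, slow_residues = character(),
                          seed = 1) {
  stopifnot(kd > 0, all(diff(ligand_ladder) > 0), ligand_ladder[1] == 0)
  residues <- as.data.frame(residues)
  rows <- list()
  for (k in seq_len(nrow(residues))) {
    r <- residues$residue[k]
    rows[[k]] <- local_seed(sub_seed(seed, k), {
      apo_h <- runif(1, 7.5, 9.5)
      apo_n <- runif(1, 105, 130)
      fb <- expected_bound_fraction(kd, ligand_ladder, protein_total)
      m <- length(ligand_ladder)
      if (r %in% slow_residues) {
        data.frame(residue = r,
                   h_ppm = apo_h + rnorm(m, 0, noise_sd),
                   n_ppm = apo_n + rnorm(m, 0, noise_sd / 0.2),
                   intensity = pmax((1 - fb) + rnorm(m, 0, 0.01), 1e-3),
                   ligand_uM = ligand_ladder, protein_uM = protein_total)
      } else {
        data.frame(residue = r,
                   h_ppm = apo_h + fb * residues$ddmax_h[k] +
                     rnorm(m, 0, noise_sd),
                   n_ppm = apo_n + fb * residues$ddmax_n[k] +
                     rnorm(m, 0, noise_sd / 0.2),
                   intensity = pmax(1 + rnorm(m, 0, 0.01), 1e-3),
                   ligand_uM = ligand_ladder, protein_uM = protein_total)
      }
    })
  }
  out <- do.call(rbind, rows)
  series <- titration_series(out)
  attr(series, "truth") <- list(
    kd = kd, protein_total = protein_total, ladder = ligand_ladder,
    noise_sd = noise_sd, slow_residues = slow_residues,
    ddmax_combined = setNames(
      sqrt(residues$ddmax_h^2 + (0.2 * residues$ddmax_n)^2),
      residues$residue))
  series
}

#' Default CPMG frequency grid
#'
#' 18 distinct CPMG frequencies plus one duplicate (19 values total), each an
#' integer echo count in `t_cpmg`, spanning roughly 13-1000 Hz for the default
#' 39-ms relaxation delay.
#'
#' @param t_cpmg relaxation delay (s).
#' @param dup_index which distinct value to duplicate (default 4).
#' @export
nu_grid_default <- function(t_cpmg = 0.039, dup_index = 4) {
  n_echo <- c(1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 17, 21, 26, 32, 39, 48, 59, 78)
  nu <- n_echo / (2 * t_cpmg)
  sort(c(nu, nu[dup_index]))
}

#' Synthetic CPMG dispersion dataset
#'
#' Simulates peak intensities through the Bloch-McConnell forward model
#' (`I = I0 exp(-R2eff * TCPMG)`), adds Gaussian intensity noise, and converts
#' back to R2,eff; the duplicated frequency supplies the error estimate, as in
#' a real acquisition.
#'
#' @param params_per_residue named list of [exchange_params()].
#' @param fields 1H Larmor frequencies (MHz), default `c(500, 600)`.
#' @param nu_grid CPMG frequencies including one duplicate.
#' @param t_cpmg relaxation delay (s).
#' @param intensity_noise_sd Gaussian sd of intensities relative to `I0 = 1`
#'   (default 0.007, giving sigma(R2eff) of roughly 0.3 /s at the plateau of
#'   a typical profile).
#' @param seed generator seed.
#' @return A [dispersion_dataset()] with a `truth` attribute.
#' @export
gen_cpmg <- function(params_per_residue, fields = c(500, 600),
                     nu_grid = nu_grid_default(t_cpmg), t_cpmg = 0.039,
                     intensity_noise_sd = 0.007, seed = 1) {
  stopifnot(length(fields) >= 1, !is.null(names(params_per_residue)))
  rows <- list()
  k <- 0
  for (ri in seq_along(params_per_residue)) {
    r <- names(params_per_residue)[ri]
    pars <- params_per_residue[[ri]]
    for (f in fields) {
      k <- k + 1
      rows[[k]] <- local_seed(sub_seed(seed, ri * 131 + match(f, fields)), {
        r2 <- simulate_dispersion(pars, nu_grid, f, t_cpmg)
        i <- exp(-r2 * t_cpmg) + rnorm(length(nu_grid), 0, intensity_noise_sd)
        i <- pmax(i, 1e-6)
        data.frame(residue = r, field_mhz = f, nu_cpmg = nu_grid,
                   r2eff = r2eff_from_intensity(i, 1, t_cpmg))
      })
    }
  }
  ds <- dispersion_dataset(do.call(rbind, rows), t_cpmg = t_cpmg)
  attr(ds, "truth") <- list(params = params_per_residue, fields = fields,
                            t_cpmg = t_cpmg,
                            intensity_noise_sd = intensity_noise_sd)
  ds
}

#' Synthetic proteome with disorder mask and planted motifs
#'
#' Draws i.i.d. sequences from the given amino-acid frequencies, marks one
#' contiguous disorder interval per protein covering about `disorder_fraction`
#' of its length (only when that is >= 20 residues), and overwrites recorded
#' positions with planted motifs. Each planting is rejection-checked: it must
#' create exactly one new match of its family in the target database and no
#' unrecorded extra matches nearby (up to 1000 attempts, then an error).
#'
#' @param n_proteins number of proteins.
#' @param length_range protein lengths drawn uniformly from this range.
#' @param aa_frequencies named frequency vector over the 20 standard residues.
#' @param disorder_fraction approximate fraction of residues inside disorder
#'   intervals.
#' @param planted_motifs list of `list(query=, database=, count=)`, with
#'   `database` one of `"disordered"`, `"structured"`, `"proteome"`.
#' @param seed generator seed.
#' @return List: `proteome` ([proteome_set()]), `mask` ([disorder_mask()]),
#'   `truth` (planted positions and per-(query, database) background counts).
#' @export
gen_proteome <- function(n_proteins = 100, length_range = c(200, 600),
                         aa_frequencies = aa_frequencies_human(),
                         disorder_fraction = 0.3, planted_motifs = list(),
                         seed = 1) {
  stopifnot(abs(sum(aa_frequencies) - 1) < 1e-6)
  aa_frequencies <- aa_frequencies[.AA20]
  seqs <- character(n_proteins)
  ivs <- list()
  for (k in seq_len(n_proteins)) {
    local_seed(sub_seed(seed, k), {
      len <- sample(length_range[1]:length_range[2], 1)
      seqs[k] <- paste(sample(.AA20, len, replace = TRUE,
                               prob = aa_frequencies), collapse = "")
      target <- round(disorder_fraction * len)
      if (target >= 20) {
        start <- sample(0:(len - target), 1)
        ivs[[paste0("P", k)]] <- matrix(c(start, start + target), 1)
      }
    })
  }
  names(seqs) <- paste0("P", seq_len(n_proteins))

  # background counts of each planted (query, database) before planting
  count_in_db <- function(seqs, ivs, query, database) {
    n <- length(query)
    tot <- 0
    for (id in names(seqs)) {
      pos <- scan_motifs(seqs[[id]], query)
      if (!length(pos)) next
      dis <- disorder_vector(nchar(seqs[[id]]), ivs[[id]])
      in_dis <- vapply(pos, function(p) all(dis[(p + 1):(p + n)]), logical(1))
      tot <- tot + switch(database, proteome = length(pos),
                          disordered = sum(in_dis),
                          structured = sum(!in_dis))
    }
    tot
  }
  truth_planted <- list()
  background <- list()
  if (length(planted_motifs)) {
    used <- list()  # per-protein occupied positions (with flanks)
    for (pm_i in seq_along(planted_motifs)) {
      pm <- planted_motifs[[pm_i]]
      query <- pm$query
      n <- length(query)
      background[[paste(deparse_query(query), pm$database, sep = "|")]] <-
        count_in_db(seqs, ivs, query, pm$database)
      planted <- 0
      attempts <- 0
      rec <- list()
      local_seed(sub_seed(seed, 7919 + pm_i), {
        while (planted < pm$count) {
          attempts <- attempts + 1
          if (attempts > 1000 * pm$count)
            stop("infeasible planting after 1000 attempts per motif")
          id <- sample(names(seqs), 1)
          len <- nchar(seqs[[id]])
          dis <- disorder_vector(len, ivs[[id]])
          ok_window <- switch(pm$database,
            proteome = rep(TRUE, len - n + 1),
            disordered = vapply(seq_len(len - n + 1), function(p)
              all(dis[p:(p + n - 1)]), logical(1)),
            structured = vapply(seq_len(len - n + 1), function(p)
              all(!dis[p:(p + n - 1)]), logical(1)))
          cand <- which(ok_window)
          cand <- setdiff(cand, unlist(used[[id]]))
          if (!length(cand)) next
          p1 <- sample(cand, 1)  # 1-based window start
          motif <- vapply(query, function(aa)
            sample(aa, 1, prob = aa_frequencies[aa] /
                     sum(aa_frequencies[aa])), character(1))
          old <- seqs[[id]]
          lo <- max(1, p1 - n + 1); hi <- min(len - n + 1, p1 + n - 1)
          before_n <- length(scan_motifs(substr(old, lo, hi + n - 1), query))
          new <- old
          substr(new, p1, p1 + n - 1) <- paste(motif, collapse = "")
          after_pos <- scan_motifs(substr(new, lo, hi + n - 1), query)
          # exactly the planted window must be new in the neighbourhood
          if (length(after_pos) != before_n + 1 ||
              !((p1 - lo) %in% after_pos)) next
          seqs[[id]] <- new
          used[[id]] <- c(used[[id]], list((p1 - n + 1):(p1 + n - 1)))
          planted <- planted + 1
          rec[[planted]] <- data.frame(protein_id = id, start0 = p1 - 1,
                                       database = pm$database,
                                       motif = paste(motif, collapse = ""))
        }
      })
      truth_planted[[pm_i]] <- do.call(rbind, rec)
    }
  }
  proteome <- proteome_set(seqs, provenance = sprintf("synthetic (seed %d)", seed))
  mask <- disorder_mask(ivs, proteome)
  list(proteome = proteome, mask = mask,
       truth = list(planted = truth_planted, background = background,
                    aa_frequencies = aa_frequencies,
                    disorder_fraction = disorder_fraction, seed = seed))
}

deparse_query <- function(query) {
  paste(vapply(query, function(aa) {
    if (length(aa) == 20) "x"
    else if (length(aa) == 1) aa
    else paste0("[", paste(aa, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Von Mises sampler
#'
#' Best-Fisher rejection sampler on the circle; used by the trajectory
#' generator. `kappa = 0` gives the uniform distribution.
#'
#' @param n draws.
#' @param mu mean direction (degrees).
#' @param kappa concentration (>= 0).
#' @return Angles in degrees, wrapped to `(-180, 180]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  mu_r <- mu * pi / 180
  if (kappa < 1e-8) {
    th <- runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u <- runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        c0 <- kappa * (r - f)
        if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
          th[i] <- sign(u[3] - 0.5) * acos(f)
          break
        }
      }
    }
    th <- th + mu_r
  }
  ang <- th * 180 / pi
  ang <- ((ang + 180) %% 360) - 180
  ang[ang == -180] <- 180
  ang
}

# sample one angle from a mixture of von Mises components
r_mixture <- function(n, comp) {
  w <- comp$w / sum(comp$w)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (j in unique(idx)) {
    sel <- idx == j
    out[sel] <- rvonmises(sum(sel), comp$mu[j], comp$kappa[j])
  }
  out
}

#' Backbone angular models for an IxI/V peptide
#'
#' An 8-residue model mirroring the ITIPVTFE motif context. The central
#' (4th) residue samples either a narrow, proline-like polyproline-II basin
#' (tight von Mises around phi = -65) or a broad, leucine-like mixture over
#' alpha, beta and left-handed basins; flanking residues use a generic coil
#' mixture.
#'
#' @param central `"narrow"` (Pro-like) or `"broad"` (Leu-like).
#' @param n_res number of residues (default 8; central at `ceiling(n/2)`).
#' @export
ixiv_peptide_model <- function(central = c("narrow", "broad"), n_res = 8) {
  central <- match.arg(central)
  coil <- list(phi = list(mu = c(-100, -65), kappa = c(6, 8), w = c(0.6, 0.4)),
               psi = list(mu = c(140, -40), kappa = c(4, 6), w = c(0.65, 0.35)))
  ctr <- if (central == "narrow") {
    list(phi = list(mu = -65, kappa = 60, w = 1),
         psi = list(mu = 150, kappa = 30, w = 1))
  } else {
    list(phi = list(mu = c(-65, -120, 55), kappa = c(8, 6, 10),
                    w = c(0.5, 0.3, 0.2)),
         psi = list(mu = c(-40, 140), kappa = c(5, 4), w = c(0.4, 0.6)))
  }
  mdl <- rep(list(coil), n_res)
  mdl[[ceiling(n_res / 2)]] <- ctr
  names(mdl) <- paste0("R", seq_len(n_res))
  mdl
}

# place atom D from A, B, C with bond length r (C-D), bond angle theta
# (B-C-D, degrees) and torsion chi (A-B-C-D, degrees)
nerf_place <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  M <- cbind(bc, m2, n)
  C + as.vector(M %*% d2)
}

#' Synthetic peptide trajectory
#'
#' Samples per-residue (phi, psi) angles from the backbone model each frame
#' and rebuilds Cartesian N/CA/C coordinates from ideal internal coordinates
#' (bond lengths 1.458/1.525/1.329 A, angles 121.7/111.0/116.2 degrees,
#' omega fixed at 180), so [compute_phi_psi()] inverts the sampled angles.
#'
#' @param n_frames number of frames.
#' @param backbone_model per-residue angular model, e.g.
#'   [ixiv_peptide_model()].
#' @param dt_ps frame spacing (ps).
#' @param seed generator seed.
#' @return A [peptide_trajectory()] with a `truth` attribute holding the
#'   sampled angles (`phi`, `psi`: frame x residue matrices).
#' @export
gen_peptide_traj <- function(n_frames, backbone_model = ixiv_peptide_model(),
                             dt_ps = 10, seed = 1) {
  n_res <- length(backbone_model)
  stopifnot(n_res >= 3, n_frames >= 1)
  phi <- psi <- matrix(NA_real_, n_frames, n_res)
  for (k in seq_len(n_res)) {
    local_seed(sub_seed(seed, 331 + k), {
      phi[, k] <- r_mixture(n_frames, backbone_model[[k]]$phi)
      psi[, k] <- r_mixture(n_frames, backbone_model[[k]]$psi)
    })
  }
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_cnca <- 121.7; a_ncac <- 111.0; a_cacn <- 116.2
  n_atoms <- 3 * n_res
  coords <- array(0, dim = c(n_atoms, 3, n_frames))
  for (fr in seq_len(n_frames)) {
    xyz <- matrix(0, n_atoms, 3)
    # residue 1: N at origin, CA on x, C in the xy-plane
    xyz[1, ] <- c(0, 0, 0)
    xyz[2, ] <- c(b_nca, 0, 0)
    th <- a_ncac * pi / 180
    xyz[3, ] <- xyz[2, ] + b_cac * c(-cos(th), sin(th), 0)
    for (k in 2:n_res) {
      iNp <- 3 * (k - 2) + 1; iCAp <- iNp + 1; iCp <- iNp + 2
      iN <- 3 * (k - 1) + 1; iCA <- iN + 1; iC <- iN + 2
      xyz[iN, ] <- nerf_place(xyz[iNp, ], xyz[iCAp, ], xyz[iCp, ],
                              b_cn, a_cacn, psi[fr, k - 1])
      xyz[iCA, ] <- nerf_place(xyz[iCAp, ], xyz[iCp, ], xyz[iN, ],
                               b_nca, a_cnca, 180)
      xyz[iC, ] <- nerf_place(xyz[iCp, ], xyz[iN, ], xyz[iCA, ],
                              b_cac, a_ncac, phi[fr, k])
    }
    coords[, , fr] <- xyz
  }
  atoms <- data.frame(
    res_id = rep(seq_len(n_res), each = 3),
    res_name = rep(names(backbone_model), each = 3),
    atom_name = rep(c("N", "CA", "C"), n_res))
  traj <- peptide_trajectory(coords, atoms, dt_ps = dt_ps, unit = "angstrom")
  attr(traj, "truth") <- list(phi = phi, psi = psi, seed = seed)
  traj
}
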