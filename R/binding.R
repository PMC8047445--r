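#' Titration series container
#'
#' Bundles picked peak positions and intensities from a 2D 1H-15N titration
#' of a fixed protein concentration with increasing ligand (peptide). One row
#' per (residue, ligand concentration); the zero-ligand row is the apo
#' reference for that residue.
#'
#' @param points data.frame with columns `residue`, `h_ppm`, `n_ppm`,
#'   `intensity`, `ligand_uM`, `protein_uM`.
#' @return A `titration_series` (validated data.frame).
#' @export
titration_series <- function(points) {
  req <- c("residue", "h_ppm", "n_ppm", "intensity", "ligand_uM", "protein_uM")
  miss <- setdiff(req, names(points))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  points <- as.data.frame(points)[req]
  points$residue <- as.character(points$residue)
  if (!all(is.finite(points$h_ppm)) || !all(is.finite(points$n_ppm)))
    stop("non-finite chemical shifts")
  if (any(points$ligand_uM < 0)) stop("ligand_uM must be >= 0")
  if (any(points$protein_uM <= 0)) stop("protein_uM must be > 0")
  for (r in unique(points$residue)) {
    lig <- points$ligand_uM[points$residue == r]
    if (sum(lig == 0) != 1)
      stop("residue ", r, " must have exactly one apo (ligand = 0) point")
    if (anyDuplicated(lig))
      stop("residue ", r, " has duplicated ligand concentrations")
  }
  points <- points[order(points$residue, points$ligand_uM), ]
  rownames(points) <- NULL
  class(points) <- c("titration_series", "data.frame")
  points
}

#' Weighted amide chemical-shift perturbation
#'
#' Combined 1H/15N CSP, `sqrt(dH^2 + (0.2 dN)^2)`; the 0.2 weight on the 15N
#' difference compensates for the wider 15N shift range. Vectorized.
#'
#' @param shift_h_apo,shift_n_apo,shift_h_holo,shift_n_holo shifts in ppm.
#' @return CSP in ppm (>= 0).
#' @export
compute_csp <- function(shift_h_apo, shift_n_apo, shift_h_holo, shift_n_holo) {
  stopifnot(is.finite(shift_h_apo), is.finite(shift_n_apo),
            is.finite(shift_h_holo), is.finite(shift_n_holo))
  dh <- shift_h_holo - shift_h_apo
  dn <- shift_n_holo - shift_n_apo
  sqrt(dh^2 + (0.2 * dn)^2)
}

# Per-residue CSP profile vs the apo reference; long data.frame
# (residue, ligand_uM, protein_uM, csp, intensity, apo_intensity).
csp_profile <- function(series) {
  out <- lapply(split(series, series$residue), function(d) {
    d <- d[order(d$ligand_uM), ]
    apo <- d[d$ligand_uM == 0, ]
    holo <- d[d$ligand_uM > 0, ]
    data.frame(residue = holo$residue,
               ligand_uM = holo$ligand_uM,
               protein_uM = holo$protein_uM,
               csp = compute_csp(apo$h_ppm, apo$n_ppm, holo$h_ppm, holo$n_ppm),
               intensity = holo$intensity,
               apo_intensity = apo$intensity)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select residues traceable in fast exchange
#'
#' A residue qualifies when its peak stays followable across the whole
#' titration: intensity at every point at least `min_intensity_fraction` of
#' the apo intensity, and the CSP step between consecutive titration points
#' no larger than `max_step`. Residues broadening out (slow/intermediate
#' exchange) fail the intensity rule.
#'
#' @param series a [titration_series()].
#' @param min_intensity_fraction minimum intensity relative to apo (default 0.3).
#' @param max_step maximum per-step CSP in ppm (default 0.15).
#' @return Character vector of residue labels (possibly empty).
#' @export
select_fast_exchange <- function(series, min_intensity_fraction = 0.3,
                                 max_step = 0.15) {
  keep <- vapply(split(series, series$residue), function(d) {
    d <- d[order(d$ligand_uM), ]
    apo <- d[d$ligand_uM == 0, ]
    if (any(d$intensity < min_intensity_fraction * apo$intensity)) return(FALSE)
    steps <- compute_csp(d$h_ppm[-nrow(d)], d$n_ppm[-nrow(d)],
                         d$h_ppm[-1], d$n_ppm[-1])
    all(steps <= max_step)
  }, logical(1))
  names(keep)[keep]
}

#' Expected bound fraction under two-state binding
#'
#' Fraction of protein bound at equilibrium from total concentrations and Kd,
#' by the quadratic solution of the mass-balance equations:
#' `((Kd + L + P) - sqrt((Kd + L + P)^2 - 4 L P)) / (2 P)`.
#'
#' @param kd dissociation constant (same units as the concentrations).
#' @param ligand_total,protein_total total concentrations.
#' @return Bound fraction in `[0, min(1, L/P)]`. Vectorized.
#' @export
expected_bound_fraction <- function(kd, ligand_total, protein_total) {
  stopifnot(all(kd > 0), all(ligand_total >= 0), all(protein_total > 0))
  b <- kd + ligand_total + protein_total
  disc <- b^2 - 4 * ligand_total * protein_total
  if (any(disc < -1e-8 * b^2)) stop("negative discriminant beyond tolerance")
  disc <- pmax(disc, 0)
  pmax((b - sqrt(disc)) / (2 * protein_total), 0)
}

#' Global two-state Kd from fast-exchange CSPs
#'
#' Fits one dissociation constant shared across residues, with one maximum
#' CSP (ddmax) per residue, to CSP vs total-ligand curves:
#' `csp = ddmax * fb(L; Kd, P)` with `fb` the two-state bound fraction of
#' protein. Because ddmax enters linearly, it is profiled out exactly and the
#' fit reduces to a 1-D optimization over log(Kd). Kd uncertainty comes from a
#' residue-level bootstrap (resampling residues with replacement).
#'
#' @param series a [titration_series()].
#' @param residues residue labels to fit (e.g. from [select_fast_exchange()]).
#' @param n_boot bootstrap draws for the Kd standard deviation (default 200).
#' @param boot_seed seed for the bootstrap (default 0).
#' @return A `binding_fit` list: `kd`, `kd_sd`, `ddmax_per_residue`,
#'   `residues_used`, `residual_norm`, `converged`.
#' @export
fit_global_kd <- function(series, residues, n_boot = 200, boot_seed = 0) {
  if (length(residues) == 0) stop("no residues to fit")
  prof <- csp_profile(series)
  prof <- prof[prof$residue %in% residues, ]
  if (!all(residues %in% prof$residue))
    stop("residues absent from series: ",
         paste(setdiff(residues, prof$residue), collapse = ", "))
  if (length(unique(prof$ligand_uM)) < 3)
    stop("need at least 3 non-zero ligand concentrations")

  by_res <- split(prof, prof$residue)
  sse_at <- function(log_kd, keep) {
    kd <- exp(log_kd)
    s <- 0
    for (r in keep) {
      d <- by_res[[r]]
      f <- expected_bound_fraction(kd, d$ligand_uM, d$protein_uM)
      dd <- sum(f * d$csp) / sum(f^2)
      s <- s + sum((d$csp - dd * f)^2)
    }
    s
  }
  lig_pos <- prof$ligand_uM[prof$ligand_uM > 0]
  lo <- log(min(lig_pos)) - log(1e3)
  hi <- log(max(lig_pos)) + log(1e3)
  fit_once <- function(keep) {
    opt <- optimize(sse_at, c(lo, hi), keep = keep, tol = 1e-9)
    opt
  }
  opt <- fit_once(unique(prof$residue))
  log_kd <- opt$minimum
  kd <- exp(log_kd)

  # identifiability: interior optimum with genuine curvature on the log scale
  scale <- sum(prof$csp^2)
  curv <- (sse_at(log_kd + 0.5, unique(prof$residue)) +
           sse_at(log_kd - 0.5, unique(prof$residue)) - 2 * opt$objective)
  converged <- (log_kd - lo > 0.05) && (hi - log_kd > 0.05) &&
    (curv > 1e-8 * max(scale, .Machine$double.eps))

  ddmax <- vapply(by_res, function(d) {
    f <- expected_bound_fraction(kd, d$ligand_uM, d$protein_uM)
    sum(f * d$csp) / sum(f^2)
  }, numeric(1))

  res_labels <- names(by_res)
  kd_sd <- local_seed(boot_seed, {
    draws <- vapply(seq_len(n_boot), function(i) {
      keep <- sample(res_labels, length(res_labels), replace = TRUE)
      exp(fit_once(keep)$minimum)
    }, numeric(1))
    sd(draws)
  })

  structure(list(kd = kd, kd_sd = kd_sd,
                 ddmax_per_residue = ddmax[res_labels],
                 residues_used = res_labels,
                 residual_norm = sqrt(opt$objective),
                 converged = converged, n_boot = n_boot),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Global two-state fit: Kd = %.4g +/- %.2g uM (%d residues)%s\n",
              x$kd, x$kd_sd, length(x$residues_used),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Binding free-energy difference from a Kd ratio
#'
#' `R T ln(kd_b / kd_a)` in kJ/mol; positive when b binds more weakly.
#'
#' @param kd_a,kd_b dissociation constants (same units).
#' @param temperature in K (default 298.15).
#' @return Energy difference in kJ/mol.
#' @export
delta_delta_g <- function(kd_a, kd_b, temperature = 298.15) {
  stopifnot(kd_a > 0, kd_b > 0, temperature > 0)
  .kB_kJ * temperature * log(kd_b / kd_a)
}

# Run code with a temporarily-set RNG seed, restoring the caller's stream.
local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
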