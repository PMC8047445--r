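#' Two-state exchange parameters
#'
#' Shared state for simulation and fitting of chemical exchange between a
#' major (free, A) and minor (bound, B) state.
#'
#' @param p_b minor-state fraction, in `[0, 0.5]`.
#' @param k_ex total exchange rate `kon*[L]free + koff` (/s).
#' @param dw_ppm magnitude of the 15N chemical-shift difference (ppm); CPMG
#'   data do not determine the sign.
#' @param r2_a,r2_b intrinsic transverse relaxation rates of each state (/s);
#'   `r2_b` defaults to `r2_a` (the usual dR2 = 0 assumption).
#' @return An `exchange_params` list.
#' @export
exchange_params <- function(p_b, k_ex, dw_ppm, r2_a, r2_b = r2_a) {
  stopifnot(p_b >= 0, p_b <= 0.5, k_ex > 0, dw_ppm >= 0, r2_a >= 0, r2_b >= 0)
  structure(list(p_b = p_b, k_ex = k_ex, dw_ppm = dw_ppm,
                 r2_a = r2_a, r2_b = r2_b),
            class = "exchange_params")
}

#' Effective transverse relaxation rate from peak intensities
#'
#' `R2,eff = -ln(I / I0) / TCPMG` with `I0` the reference intensity recorded
#' without the relaxation delay. Negative values (noise pushing `I` above
#' `I0`) are returned as-is. Vectorized over `i`.
#'
#' @param i peak intensity with the CPMG delay.
#' @param i0 reference intensity (> 0).
#' @param t_cpmg constant relaxation delay (s).
#' @export
r2eff_from_intensity <- function(i, i0, t_cpmg) {
  stopifnot(i0 > 0, t_cpmg > 0)
  if (any(i <= 0)) stop("non-positive intensity; R2eff undefined (drop point)")
  -log(i / i0) / t_cpmg
}

# 15N angular shift difference (rad/s) from ppm at a 1H Larmor field in MHz
dw_rad_per_s <- function(dw_ppm, field_mhz) {
  dw_ppm * 1e-6 * (field_mhz * 1e6 * .GAMMA_N_OVER_H) * 2 * pi
}

#' Simulate a two-state CPMG relaxation-dispersion profile
#'
#' Propagates in-phase two-site transverse magnetization through the CPMG echo
#' train: free precession under the exchange/relaxation/shift matrix between
#' ideal 180-degree refocusing pulses (complex conjugation), starting from the
#' population-weighted equilibrium, detecting total amplitude at `t_cpmg`.
#' Each `nu` must correspond to an integer echo count `2 * nu * t_cpmg`.
#'
#' @param params an [exchange_params()].
#' @param nu_grid CPMG frequencies (Hz).
#' @param field_mhz 1H Larmor frequency (MHz); 15N frequencies are derived via
#'   the gyromagnetic ratio.
#' @param t_cpmg constant relaxation delay (s).
#' @return R2,eff (/s) at each `nu`.
#' @export
simulate_dispersion <- function(params, nu_grid, field_mhz, t_cpmg = 0.039) {
  stopifnot(inherits(params, "exchange_params"), t_cpmg > 0, all(nu_grid > 0))
  .cpmg_r2eff_cpp(params$p_b, params$k_ex,
                  dw_rad_per_s(params$dw_ppm, field_mhz),
                  params$r2_a, params$r2_b, as.numeric(nu_grid), t_cpmg)
}

#' Carver-Richard closed form (test oracle)
#'
#' Approximate closed-form R2,eff for two-site CPMG exchange; kept as an
#' independent cross-check of the matrix propagation, not used in fitting.
#'
#' @inheritParams simulate_dispersion
#' @param nu CPMG frequency (Hz), vectorized.
#' @export
carver_richard <- function(params, nu, field_mhz) {
  p_a <- 1 - params$p_b
  p_b <- params$p_b
  kex <- params$k_ex
  dw <- dw_rad_per_s(params$dw_ppm, field_mhz)
  r2a <- params$r2_a
  r2b <- params$r2_b
  tcp <- 1 / (2 * nu)  # delay between successive 180 pulses
  g <- r2a - r2b - p_a * kex + p_b * kex
  psi <- g^2 - dw^2 + 4 * p_a * p_b * kex^2
  zeta <- 2 * dw * g
  root <- sqrt(psi^2 + zeta^2)
  eta_p <- (tcp / sqrt(2)) * sqrt(pmax(psi + root, 0))
  eta_m <- (tcp / sqrt(2)) * sqrt(pmax(-psi + root, 0))
  d_p <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  d_m <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  0.5 * (r2a + r2b + kex -
           (1 / tcp) * acosh(pmax(d_p * cosh(eta_p) - d_m * cos(eta_m), 1)))
}

#' Dispersion amplitude Rex
#'
#' Difference between R2,eff at the lowest and the highest CPMG frequency of
#' a curve; duplicated frequencies are averaged first.
#'
#' @param curve data.frame with columns `nu_cpmg` and `r2eff` (one residue at
#'   one field).
#' @export
rex_amplitude <- function(curve) {
  stopifnot(all(c("nu_cpmg", "r2eff") %in% names(curve)))
  agg <- tapply(curve$r2eff, curve$nu_cpmg, mean)
  nu <- as.numeric(names(agg))
  if (length(nu) < 2) stop("need >= 2 distinct nu values")
  unname(agg[which.min(nu)] - agg[which.max(nu)])
}

#' Dispersion dataset container
#'
#' Long-format R2,eff profiles: one row per (residue, field, nu) with a
#' per-point sigma. `t_cpmg` is carried as an attribute.
#'
#' When no `sigma` column is supplied it is derived from the duplicated
#' CPMG frequencies: duplicate-pair deviations are pooled on the intensity
#' scale (`I = exp(-R2eff * TCPMG)`, the scale on which the noise is
#' additive) and propagated back per point via the R2,eff definition, so
#' points with stronger attenuation correctly get larger errors:
#' `sigma_k = sigma_I * exp(R2eff_k * TCPMG) / TCPMG`. Without any
#' duplicates a flat floor of `sigma_floor` is used.
#'
#' @param data data.frame with columns `residue`, `field_mhz`, `nu_cpmg`,
#'   `r2eff` and optionally `sigma`.
#' @param t_cpmg relaxation delay (s).
#' @param sigma_floor flat sigma when no duplicates are present (default
#'   0.3 /s); also the per-point lower bound is `sigma_floor / 6`.
#' @export
dispersion_dataset <- function(data, t_cpmg, sigma_floor = 0.3) {
  req <- c("residue", "field_mhz", "nu_cpmg", "r2eff")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data$residue <- as.character(data$residue)
  rownames(data) <- NULL
  if (is.null(data$sigma)) {
    key <- interaction(data$residue, data$field_mhz, drop = TRUE)
    dev_i <- unlist(lapply(levels(key), function(k) {
      d <- data[key == k, ]
      dup_nu <- unique(d$nu_cpmg[duplicated(d$nu_cpmg)])
      vapply(dup_nu, function(nu) {
        ipair <- exp(-d$r2eff[d$nu_cpmg == nu] * t_cpmg)
        diff(range(ipair)) / sqrt(2)
      }, numeric(1))
    }))
    if (length(dev_i)) {
      sigma_i <- sqrt(mean(dev_i^2))
      data$sigma <- pmax(sigma_i * exp(data$r2eff * t_cpmg) / t_cpmg,
                         sigma_floor / 6)
    } else {
      data$sigma <- sigma_floor
    }
  }
  structure(data, t_cpmg = t_cpmg, class = c("dispersion_dataset", "data.frame"))
}

#' Global two-state fit of CPMG dispersion profiles
#'
#' Weighted least-squares fit of the Bloch-McConnell forward model to R2,eff
#' profiles recorded at two or more static fields. In `naive` mode all
#' residues share `p_b` and `k_ex`, with local `|dw|` and `r2_a`
#' (`r2_b = r2_a`, i.e. dR2 = 0). In `constrained` mode `p_b` is fixed to
#' `fixed_p_b` (e.g. expected from an independently measured Kd and the known
#' concentrations), `k_ex` is shared, and `|dw|`, `r2_a` and `r2_b` are local,
#' letting dR2 = r2_b - r2_a absorb exchange within the bound state.
#' Multi-start Levenberg-Marquardt over a log-spaced `k_ex` grid.
#'
#' Supplying `fixed_p_b` in `naive` mode pins `p_b` while keeping
#' `r2_b = r2_a`; this variant backs the profile-chi-squared uncertainty of
#' `p_b`, which (the population being a shallow, strongly correlated
#' direction of the exchange surface) is reported from the `chi2_min + 1`
#' crossings rather than from local curvature alone.
#'
#' @param dataset a [dispersion_dataset()] spanning >= 2 fields.
#' @param mode `"naive"` or `"constrained"`.
#' @param fixed_p_b required in constrained mode; optional in naive mode
#'   (pins the population).
#' @param kex_starts multi-start grid (/s).
#' @param start_seed seed for start jitter.
#' @param pb_uncertainty `"profile"` (default) or `"curvature"` for the
#'   reported `p_b_sd` in free-population naive fits.
#' @return A `dispersion_fit` list: `p_b`, `p_b_sd`, `k_ex`, `k_ex_sd`,
#'   per-residue `dw_ppm`, `r2_a`, `r2_b`, `reduced_chi2`, `mode`, `cov_pk`
#'   (covariance of (p_b, k_ex)), `converged`, `at_bound`.
#' @export
fit_dispersion_global <- function(dataset, mode = c("naive", "constrained"),
                                  fixed_p_b = NULL,
                                  kex_starts = exp(seq(log(100), log(10000),
                                                       length.out = 5)),
                                  start_seed = 0,
                                  pb_uncertainty = c("profile", "curvature")) {
  mode <- match.arg(mode)
  pb_uncertainty <- match.arg(pb_uncertainty)
  stopifnot(inherits(dataset, "dispersion_dataset"))
  if (length(unique(dataset$field_mhz)) < 2)
    stop("need dispersion data at >= 2 static fields")
  if (mode == "constrained" && is.null(fixed_p_b))
    stop("constrained mode requires fixed_p_b")
  pb_free <- (mode == "naive") && is.null(fixed_p_b)
  t_cpmg <- attr(dataset, "t_cpmg")
  residues <- unique(dataset$residue)
  n_res <- length(residues)
  curves <- split(as.data.frame(dataset),
                  interaction(dataset$residue, dataset$field_mhz, drop = TRUE))

  # crude per-residue starts from the profiles themselves
  r2a0 <- vapply(residues, function(r) {
    d <- dataset[dataset$residue == r, ]
    min(tapply(d$r2eff, interaction(d$field_mhz, d$nu_cpmg, drop = TRUE), mean))
  }, numeric(1))
  rex0 <- vapply(residues, function(r) {
    d <- dataset[dataset$residue == r, ]
    f1 <- d$field_mhz == min(d$field_mhz)
    max(rex_amplitude(data.frame(nu_cpmg = d$nu_cpmg[f1], r2eff = d$r2eff[f1])),
        0.5)
  }, numeric(1))

  unpack <- function(theta, pb_fix = fixed_p_b) {
    if (mode == "naive") {
      if (pb_free)
        list(p_b = theta[1], k_ex = theta[2],
             dw = theta[2 + seq_len(n_res)],
             r2a = theta[2 + n_res + seq_len(n_res)],
             r2b = theta[2 + n_res + seq_len(n_res)])
      else
        list(p_b = pb_fix, k_ex = theta[1],
             dw = theta[1 + seq_len(n_res)],
             r2a = theta[1 + n_res + seq_len(n_res)],
             r2b = theta[1 + n_res + seq_len(n_res)])
    } else {
      list(p_b = pb_fix, k_ex = theta[1],
           dw = theta[1 + seq_len(n_res)],
           r2a = theta[1 + n_res + seq_len(n_res)],
           r2b = theta[1 + 2 * n_res + seq_len(n_res)])
    }
  }
  make_resid <- function(pb_fix) function(theta) {
    p <- unpack(theta, pb_fix)
    unlist(lapply(curves, function(d) {
      ri <- match(d$residue[1], residues)
      sim <- .cpmg_r2eff_cpp(p$p_b, p$k_ex,
                             dw_rad_per_s(p$dw[ri], d$field_mhz[1]),
                             p$r2a[ri], p$r2b[ri], d$nu_cpmg, t_cpmg)
      (d$r2eff - sim) / d$sigma
    }), use.names = FALSE)
  }
  resid_fn <- make_resid(fixed_p_b)

  n_obs <- nrow(dataset)
  if (pb_free) {
    lower <- c(1e-6, 1, rep(0, n_res), rep(0.05, n_res))
    upper <- c(0.5, 1e5, rep(20, n_res), rep(200, n_res))
  } else if (mode == "naive") {
    lower <- c(1, rep(0, n_res), rep(0.05, n_res))
    upper <- c(1e5, rep(20, n_res), rep(200, n_res))
  } else {
    lower <- c(1, rep(0, n_res), rep(0.05, n_res), rep(0.05, n_res))
    upper <- c(1e5, rep(20, n_res), rep(200, n_res), rep(500, n_res))
  }
  n_par <- length(lower)
  dof <- max(n_obs - n_par, 1)

  lm_fit <- function(theta0, fn, lo = lower, up = upper) {
    minpack.lm::nls.lm(
      par = pmin(pmax(theta0, lo), up), fn = fn,
      lower = lo, upper = up,
      control = minpack.lm::nls.lm.control(maxiter = 300, ptol = 1e-10))
  }
  best <- NULL
  local_seed(start_seed, {
    for (kex0 in kex_starts) {
      pb0 <- if (pb_free) 0.02 * exp(rnorm(1, 0, 0.2)) else fixed_p_b
      dw0 <- sqrt(pmax(rex0 * kex0, 1e-4) / max(pb0 * (1 - pb0), 1e-6))
      dw0 <- pmin(pmax(dw0 / dw_rad_per_s(1, 500), 0.2), 10)  # to ppm at low field
      theta0 <- if (pb_free) {
        c(pb0, kex0, dw0, pmax(r2a0, 0.5))
      } else if (mode == "naive") {
        c(kex0, dw0, pmax(r2a0, 0.5))
      } else {
        c(kex0, dw0, pmax(r2a0, 0.5), pmax(r2a0, 0.5) + 5)
      }
      fit <- try(lm_fit(theta0, resid_fn), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      if (fit$deviance / dof < 1.3) break
    }
  })
  if (is.null(best)) stop("dispersion fit failed from every start")

  theta <- best$par
  p <- unpack(theta)
  red_chi2 <- best$deviance / dof

  # covariance from a numerical Jacobian at the optimum; the duplicate-derived
  # sigmas act as relative weights, so the covariance is scaled by the reduced
  # chi-squared (the standard weighted-least-squares convention), which
  # re-estimates the absolute noise level from the full residual set
  J <- num_jacobian(resid_fn, theta)
  cv <- try(solve(crossprod(J)) * red_chi2, silent = TRUE)
  if (inherits(cv, "try-error")) cv <- matrix(NA_real_, n_par, n_par)

  at_bound <- any(abs(theta - lower) < 1e-8 * pmax(abs(lower), 1)) ||
    any(abs(theta - upper) < 1e-8 * pmax(abs(upper), 1))
  if (pb_free) {
    p_b_sd <- sqrt(cv[1, 1]); k_ex_sd <- sqrt(cv[2, 2])
    cov_pk <- cv[1:2, 1:2]
  } else {
    p_b_sd <- 0; k_ex_sd <- sqrt(cv[1, 1])
    cov_pk <- matrix(c(0, 0, 0, cv[1, 1]), 2)
  }

  if (pb_free && pb_uncertainty == "profile" && is.finite(p_b_sd)) {
    # half-width of the chi2_min + 1 interval from warm-started pinned-pb
    # refits, stepping outward in curvature-sd units and interpolating
    warm <- theta[-1]
    dev_at <- function(pb) {
      fn_pin <- function(th) {
        pp <- list(p_b = pb, k_ex = th[1], dw = th[1 + seq_len(n_res)],
                   r2a = th[1 + n_res + seq_len(n_res)],
                   r2b = th[1 + n_res + seq_len(n_res)])
        unlist(lapply(curves, function(d) {
          ri <- match(d$residue[1], residues)
          sim <- .cpmg_r2eff_cpp(pp$p_b, pp$k_ex,
                                 dw_rad_per_s(pp$dw[ri], d$field_mhz[1]),
                                 pp$r2a[ri], pp$r2b[ri], d$nu_cpmg, t_cpmg)
          (d$r2eff - sim) / d$sigma
        }), use.names = FALSE)
      }
      f <- try(lm_fit(warm, fn_pin, lower[-1], upper[-1]), silent = TRUE)
      if (inherits(f, "try-error")) return(NA_real_)
      f$deviance
    }
    cross <- function(dir) {
      prev_pb <- p$p_b; prev_dev <- best$deviance
      for (k in seq(1, 4, by = 0.75)) {
        pb_k <- p$p_b + dir * k * p_b_sd
        if (pb_k <= 0 || pb_k >= 0.5) break
        dv <- dev_at(pb_k)
        if (!is.finite(dv)) break
        if (dv >= best$deviance + 1) {
          frac <- (best$deviance + 1 - prev_dev) / (dv - prev_dev)
          return(abs(prev_pb + frac * (pb_k - prev_pb) - p$p_b))
        }
        prev_pb <- pb_k; prev_dev <- dv
      }
      NA_real_
    }
    lo_w <- cross(-1); hi_w <- cross(+1)
    prof <- mean(c(lo_w, hi_w), na.rm = TRUE)
    if (is.finite(prof) && prof > p_b_sd) {
      infl <- prof / p_b_sd
      p_b_sd <- prof
      cov_pk[1, 1] <- cov_pk[1, 1] * infl^2
      cov_pk[1, 2] <- cov_pk[1, 2] * infl
      cov_pk[2, 1] <- cov_pk[2, 1] * infl
    }
  }

  structure(list(p_b = unname(p$p_b), p_b_sd = unname(p_b_sd),
                 k_ex = unname(p$k_ex), k_ex_sd = unname(k_ex_sd),
                 dw_ppm = setNames(p$dw, residues),
                 r2_a = setNames(p$r2a, residues),
                 r2_b = setNames(p$r2b, residues),
                 reduced_chi2 = red_chi2, mode = mode,
                 cov_pk = cov_pk,
                 converged = best$info %in% 1:4 && !at_bound,
                 at_bound = at_bound),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("Global CPMG fit (%s): pB = %.4f +/- %.4f, kex = %.1f +/- %.1f /s, red.chi2 = %.2f\n",
              x$mode, x$p_b, x$p_b_sd, x$k_ex, x$k_ex_sd, x$reduced_chi2))
  invisible(x)
}

# central-difference Jacobian of a residual function
num_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(abs(theta[j]), 1e-3)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' Binding rate constants from exchange parameters
#'
#' Converts a fitted minor-state fraction and exchange rate into kinetic
#' rate constants under a bimolecular binding model:
#' `Lfree = Lt - pB*Pt`, `koff = (1 - pB) kex`, `kon = pB kex / Lfree`,
#' `Kd = koff / kon`. Uncertainties (if `p_b_sd`/`k_ex_sd` given) by
#' first-order propagation, including the (p_b, k_ex) covariance.
#'
#' @param p_b minor-state fraction (0 < p_b < 1).
#' @param k_ex exchange rate (/s).
#' @param ligand_total,protein_total total concentrations (any shared unit;
#'   rates come out in /s and the Kd in that concentration unit).
#' @param p_b_sd,k_ex_sd optional one-sd uncertainties.
#' @param cov_pk optional 2x2 covariance of (p_b, k_ex); overrides the sds.
#' @return A `kinetic_rates` list: `k_on`, `k_off`, `kd`, `l_free` (+ `_sd`).
#' @export
rates_from_exchange <- function(p_b, k_ex, ligand_total, protein_total,
                                p_b_sd = NULL, k_ex_sd = NULL, cov_pk = NULL) {
  stopifnot(p_b > 0, p_b < 1, k_ex > 0)
  l_free <- ligand_total - p_b * protein_total
  if (l_free <= 0) stop("more bound ligand than supplied (Lfree <= 0)")
  k_off <- (1 - p_b) * k_ex
  k_on <- p_b * k_ex / l_free
  kd <- k_off / k_on
  out <- list(k_on = k_on, k_off = k_off, kd = kd, l_free = l_free)

  if (is.null(cov_pk) && !is.null(p_b_sd) && !is.null(k_ex_sd))
    cov_pk <- diag(c(p_b_sd^2, k_ex_sd^2))
  if (!is.null(cov_pk)) {
    # gradients wrt (p_b, k_ex)
    g_off <- c(-k_ex, 1 - p_b)
    g_on <- c(k_ex / l_free + p_b * k_ex * protein_total / l_free^2,
              p_b / l_free)
    g_kd <- c((kd / k_off) * g_off[1] - (kd / k_on) * g_on[1],
              (kd / k_off) * g_off[2] - (kd / k_on) * g_on[2])
    qf <- function(g) sqrt(max(drop(t(g) %*% cov_pk %*% g), 0))
    out$k_off_sd <- qf(g_off)
    out$k_on_sd <- qf(g_on)
    out$kd_sd <- qf(g_kd)
  }
  structure(out, class = "kinetic_rates")
}
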