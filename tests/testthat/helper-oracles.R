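# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Horn quaternion method for optimal superposition RMSD
quaternion_rmsd <- function(frame, reference) {
  A <- sweep(frame, 2, colMeans(frame))
  B <- sweep(reference, 2, colMeans(reference))
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(frame)
  sqrt(max(msd, 0))
}

# nested-loop motif scan (0-based starts), no vectorization shared with the
# implementation
scan_motifs_bruteforce <- function(sequence, query) {
  v <- strsplit(toupper(sequence), "")[[1]]
  n <- length(query)
  hits <- integer(0)
  if (length(v) < n) return(hits)
  for (i in seq_len(length(v) - n + 1)) {
    ok <- TRUE
    for (q in seq_len(n)) {
      if (!(v[i + q - 1] %in% query[[q]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# bound fraction by numeric root-solve of the mass balance (no quadratic)
bound_fraction_root <- function(kd, L, P) {
  if (L == 0) return(0)
  f <- function(c) (P - c) * (L - c) - kd * c
  c_root <- uniroot(f, c(0, min(P, L)), tol = 1e-14)$root
  c_root / P
}

# standard residue/parameter fixtures
fast_residue_table <- function(n = 16, seed = 42) {
  set.seed(seed)
  data.frame(residue = paste0("R", seq_len(n)),
             ddmax_h = runif(n, 0.02, 0.12),
             ddmax_n = runif(n, 0.1, 0.6))
}

geometric_ladder <- function(top = 2000, n = 9) c(0, top / 2^((n - 1):0))

cpmg_param_set <- function(p_b, k_ex, n = 10, seed = 1) {
  set.seed(seed)
  dw <- runif(n, 1, 3)
  setNames(lapply(seq_len(n), function(i)
    exchange_params(p_b = p_b, k_ex = k_ex, dw_ppm = dw[i],
                    r2_a = runif(1, 8, 16))),
    paste0("R", 100 + seq_len(n)))
}
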