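#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses consume,
# with planted ground truth mirroring the study conditions: titrations at the
# fitted Kd values (124 / 1030 uM), two-field CPMG datasets at the measured
# populations and off-rates, a proteome with disordered [V/I]P[V/I] plantings,
# and narrow (Pro-like) vs broad (Leu-like) peptide ensembles.

suppressMessages(library(slimbind))
set.seed(1)
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

residues <- data.frame(residue = paste0("R", 1:16),
                       ddmax_h = runif(16, 0.02, 0.12),
                       ddmax_n = runif(16, 0.1, 0.6))
ladder <- c(0, 2000 / 2^(8:0))

wt_ser <- gen_titration(124, residues, 200, ladder, noise_sd = 0.002,
                        slow_residues = character(), seed = 11)
mut_ser <- gen_titration(1030, residues, 200, ladder, noise_sd = 0.002,
                         seed = 12)
write_peak_table(wt_ser, file.path(out, "titration_wt.tsv"))
write_peak_table(mut_ser, file.path(out, "titration_p182l.tsv"))

cpmg_pars <- function(p_b, k_ex, seed) {
  set.seed(seed)
  dw <- runif(10, 1, 3)
  setNames(lapply(1:10, function(k)
    exchange_params(p_b = p_b, k_ex = k_ex, dw_ppm = dw[k],
                    r2_a = runif(1, 8, 16))), paste0("R", 100 + 1:10))
}
wt_ds <- gen_cpmg(cpmg_pars(0.024, 515 / 0.976, 21), seed = 21)
mut_ds <- gen_cpmg(cpmg_pars(0.020, 610 / 0.980, 22), seed = 22)
write_dispersion_table(wt_ds, file.path(out, "cpmg_wt.tsv"))
write_dispersion_table(mut_ds, file.path(out, "cpmg_p182l.tsv"))

gp <- gen_proteome(n_proteins = 150, length_range = c(200, 600),
                   disorder_fraction = 0.3,
                   planted_motifs = list(list(query = slim_query("[VI]P[VI]"),
                                              database = "disordered",
                                              count = 80)), seed = 31)
write_fasta(gp$proteome, file.path(out, "proteome.fasta"))
write_mask(gp$mask, file.path(out, "disorder_mask.tsv"))
saveRDS(gp$truth, "scratch/proteome_truth.rds")  # scratch only; not shipped

write_trajectory(gen_peptide_traj(2000, ixiv_peptide_model("narrow"), seed = 41),
                 file.path(out, "traj_wt.txt"))
write_trajectory(gen_peptide_traj(2000, ixiv_peptide_model("broad"), seed = 41),
                 file.path(out, "traj_p182l.txt"))

cat("Synthetic inputs written to", out, "\n")
cat(sprintf("  titrations: Kd 124 / 1030 uM, 16 residues, ladder 0-2000 uM\n"))
cat(sprintf("  CPMG: pB 2.4%%/2.0%%, koff 515/610 per s, fields 500/600 MHz\n"))
cat(sprintf("  proteome: 150 proteins, 80 planted disordered [V/I]P[V/I]\n"))
cat(sprintf("  trajectories: 2000 frames each, narrow vs broad residue 4\n"))
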