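# slimbind

Quantitative analysis of weak short-linear-motif (SLiM) interactions of the
IxI/V class — the `[V/I]x[V/I]` motifs that small heat-shock proteins such as
HSP27 carry in their disordered C-terminal regions and dock into the β4/β8
groove of their α-crystallin core domain. Interactions in this family sit in
the 100 µM–1 mM range, so the package implements the four quantitative layers
such a system demands, for NMR spectroscopists and structural
bioinformaticians:

1. **Titration thermodynamics** — weighted amide chemical-shift perturbations
   `Δδ = sqrt(ΔH² + (0.2 ΔN)²)` and a global two-state fit of
   `Δδ(L) = Δδmax · ((Kd+L+P) − sqrt((Kd+L+P)² − 4LP)) / 2P`
   across fast-exchange residues (one shared `Kd`, per-residue `Δδmax`,
   residue-bootstrap uncertainty), plus bound fractions and
   `ΔΔG = RT·ln(Kd ratio)`.
2. **CPMG relaxation-dispersion kinetics** — exact two-site Bloch–McConnell
   propagation of the echo train (compiled), global two-field fits in a naive
   (shared `pB`, `kex`, `ΔR2 = 0`) and a constrained mode (fixed `pB`, free
   `ΔR2`), and conversion to rate constants:
   `koff = (1−pB)·kex`, `kon = pB·kex/Lfree`, `Kd = koff/kon`.
3. **Proteome census** — counts of the IxI, IxV, VxI, VxV families per
   central residue in whole proteomes vs ≥20-residue disordered regions,
   expected counts `N = M·Πq p(AAq)` from amino-acid frequencies, the total
   χ² test on ν = 76 degrees of freedom, enrichment profiles, and an
   interactor screen for disordered `[V/I]P[V/I]` carriers.
4. **Trajectory analysis** — backbone φ/ψ dihedrals, Ramachandran
   free-energy surfaces `ΔG = −kB·T·ln(n/nmax)`, Kabsch superposition, and
   combined-trajectory Cα PCA.

A synthetic-data module (`gen_titration`, `gen_cpmg`, `gen_proteome`,
`gen_peptide_traj`) generates every input class with planted ground truth,
so the entire pipeline is testable offline.

## Worked example

The numbered scripts under `analysis/` run the whole study pipeline on
synthetic inputs planted at realistic values (`Rscript analysis/01_simulate.R`
… `05_trajectory.R`, writing tables under `results/`). Stage 2–3 print, for
titrations planted at Kd = 124 / 1030 µM and dispersions planted at
pB = 2.4% / 2.0% with koff = 515 / 610 s⁻¹:

```
WT-like:    Kd = 130 +/- 6 uM (16 residues)
P182L-like: Kd = 940 +/- 68 uM (16 residues)
ddG(25C) = 4.91 kJ/mol -- an order-of-magnitude affinity loss

wt     pB = 2.37%, kex = 551 /s, koff = 538 +/- 15 /s, Kd(CPMG) = 1826 uM
p182l  pB = 2.04%, kex = 620 /s, koff = 607 +/- 18 /s, Kd(CPMG) = 8153 uM
```

The fitted titration affinities and CPMG populations/off-rates recover the
planted values within their uncertainties; the ~4.9 kJ/mol energy difference
is the thermodynamic cost of the mutation-like Kd shift; and the Kd implied
by CPMG exceeds the titration Kd by an order of magnitude — the hallmark of a
minor-state population smaller than two-state mass balance predicts, i.e. of
a third state hiding in the bound ensemble. Stage 4–5 then report a planted
disorder enrichment of Pro-centred motifs (χ²tot = 503.3 at ν = 76 in
disordered regions, null retained in structured ones) and a 14× larger
occupied Ramachandran area for the broad, Leu-like central residue than for
the narrow, Pro-like one.

In code, a single fit looks like:

```r
library(slimbind)
ser <- read_peak_table("results/inputs/titration_wt.tsv")
fit <- fit_global_kd(ser, select_fast_exchange(ser))
fit
#> Global two-state fit: Kd = 130.1 +/- 6 uM (16 residues)
expected_bound_fraction(125, 80, 1500)   # 0.049: 4.9% bound at CPMG conditions
```

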