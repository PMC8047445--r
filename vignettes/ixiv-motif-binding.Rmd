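---
title: "Quantifying weak IxI/V motif binding: models, fits, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying weak IxI/V motif binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimbind)
```

## The problem

Small heat-shock proteins such as HSP27 carry a short linear motif (SLiM) of
the [V/I]x[V/I] class — the IxI/V motif — in their disordered C-terminal
region. The motif docks weakly and transiently into the β4/β8 groove of the
structured α-crystallin domain (ACD), and this self-association regulates
oligomer size and the availability of the groove for other IxI/V-bearing
partners. Disease mutations that weaken the interaction (such as a central
Pro→Leu substitution) shift the equilibrium toward exposed grooves and larger
assemblies. Because the interaction is in the 100 µM–1 mM range, its
thermodynamics and kinetics are only accessible to solution NMR; its sequence
context is a question for proteome-scale statistics; and the conformational
cost of the central residue is a question for trajectory analysis. `slimbind`
implements all four quantitative layers behind that kind of study, plus
synthetic generators that make every layer testable without any external
data.

## Titration thermodynamics

A 2D ¹H-¹⁵N titration reports binding through chemical-shift perturbations
(CSPs),

$$\Delta\delta = \sqrt{(\Delta H)^2 + (0.2\,\Delta N)^2},$$

with the fixed 0.2 weight compensating the wider ¹⁵N shift range
(`compute_csp()`; the weight is deliberately not a tuning knob so that CSPs
remain comparable between datasets). Residues in fast exchange trace a
population-weighted path; `select_fast_exchange()` keeps residues whose peak
stays traceable (intensity ≥ 30% of apo at every point, per-step CSP ≤ 0.15
ppm by default — the thresholds are heuristics standing in for the by-hand
residue lists of practice, and an explicit list can be supplied instead).
Fast-exchange CSPs follow the two-state mass balance

$$\Delta\delta(L) = \Delta\delta_\max \cdot
  \frac{(K_d + L + P) - \sqrt{(K_d + L + P)^2 - 4 L P}}{2P},$$

which `fit_global_kd()` fits with one shared $K_d$ and one
$\Delta\delta_\max$ per residue. Because the per-residue amplitudes enter
linearly they are profiled out exactly, reducing the fit to a 1-D search over
$\log K_d$ — there is no multi-parameter optimizer to mis-converge, and
ill-determined (saturated) designs are flagged by a curvature check rather
than silently returned. The $K_d$ uncertainty comes from a residue-level
bootstrap (200 draws, seed 0 by default), since residues — not points — are
the exchangeable unit of this design. Per-residue $\Delta\delta_\max$ (rather
than a shared amplitude) is the standard choice, as each site senses a
different shift change. With a fresh sample per titration point no dilution
correction is applied; concentrations are taken as true totals. The two-state
concurrent-binding picture is assumed throughout; CSP data of this kind
cannot distinguish it from sequential binding, and no sequential model is
fitted.

The same quadratic gives the expected bound fraction of protein at any
condition (`expected_bound_fraction()`), and affinity differences convert to
energies as $\Delta\Delta G = RT\ln(K_{d,b}/K_{d,a})$ (`delta_delta_g()`).

## CPMG relaxation-dispersion kinetics

¹⁵N CPMG experiments measure the effective transverse relaxation rate

$$R_{2,\mathrm{eff}}(\nu_\mathrm{CPMG}) =
  -\frac{1}{T_\mathrm{CPMG}}\ln\frac{I(\nu_\mathrm{CPMG})}{I_0}$$

as a function of refocusing frequency. `simulate_dispersion()` propagates
two-site in-phase magnetization through the echo train exactly: free
precession under the 2×2 complex exchange/relaxation/shift matrix, ideal
180° pulses as complex conjugation, one echo unit $(\tau-180-\tau)$ with
$\nu_\mathrm{CPMG} = n/(2T_\mathrm{CPMG})$ for $n$ echo units. Magnetization
starts on the population-weighted equilibrium and the total transverse
amplitude is detected at $T_\mathrm{CPMG}$ — the common convention for
in-phase ¹⁵N experiments. Off-resonance effects, scalar coupling, and pulse
imperfections are outside the model. The propagation is compiled (C++), so
the multi-replicate fits below run in seconds.

The Carver–Richard closed form (`carver_richard()`) is kept purely as an
independent test oracle. It tracks the propagation to better than 1% where
it is a valid approximation — minor population ≤ 5% and
$k_{ex} \gtrsim 1.5\,|\Delta\omega|$ (rad/s) — but in slow exchange with a
10% minor state the two conventions legitimately diverge by up to ~12%,
because the closed form describes the major-peak decay while the propagation
detects total amplitude. The test suite asserts the 1% agreement inside the
validity region and only bounds the deviation outside it.

`fit_dispersion_global()` fits profiles from two (or more) static fields at
once:

* **naive mode** — all residues share $p_B$ and $k_{ex}$; $|\Delta\omega|$
  and $R_{2,A}$ are local; $\Delta R_2 = 0$.
* **constrained mode** — $p_B$ is fixed (e.g. to the value the titration
  $K_d$ and the known concentrations imply), $k_{ex}$ is shared, and
  $R_{2,B}$ floats locally, so $\Delta R_2 = R_{2,B} - R_{2,A} > 0$ can
  absorb exchange within the bound state. This is the pragmatic surrogate
  for a full three-state analysis, which needs far more data than two fields
  provide.

The minimizer is bounded Levenberg–Marquardt with five log-spaced
$k_{ex}$ starts between 100 and 10 000 /s (the exchange surface is
multimodal); CPMG determines only $|\Delta\omega|$, stored non-negative.
Fitted exchange parameters convert to rate constants via
$L_\text{free} = L_t - p_B P_t$, $k_\text{off} = (1-p_B)k_{ex}$,
$k_\text{on} = p_B k_{ex}/L_\text{free}$, $K_d = k_\text{off}/k_\text{on}$
(`rates_from_exchange()`), with first-order error propagation including the
$(p_B, k_{ex})$ covariance.

Three numerical choices matter for honest uncertainties and are worth
stating. First, the error model: each acquisition carries one duplicated
$\nu_\mathrm{CPMG}$ point; duplicate deviations are pooled on the intensity
scale — where the noise is actually additive — and propagated per point, so
$\sigma(R_{2,\mathrm{eff}})$ grows as $e^{R_{2,\mathrm{eff}}T_\mathrm{CPMG}}$
along the profile. A flat 0.3 /s floor is used only when no duplicates exist.
Second, the parameter covariance is scaled by the reduced $\chi^2$, the
standard weighted-least-squares convention: the duplicate-derived sigmas act
as relative weights and the absolute noise level is re-estimated from the
full residual set, which is far better determined than a handful of
duplicate pairs. Third, the reported $p_B$ uncertainty is additionally
checked against a profile-$\chi^2$ interval (refitting with $p_B$ pinned
until the deviance rises by 1) and the larger of the two is reported — the
population is the shallowest direction of the exchange surface.

## The proteome census

`census()` counts the four motif families IxI, IxV, VxI, VxV, stratified by
the central residue, in three databases: the whole proteome, its disordered
regions (intervals of ≥ 20 predicted-disordered residues; disorder prediction
itself is upstream of this package), and the structured remainder obtained by
exact subtraction. A motif counts as disordered only when all three residues
lie inside one interval — the accessibility argument behind the census
concerns the whole motif — so straddling motifs land in the structured
stratum via the subtraction. All overlapping windows are counted; windows are
the natural unit of the expectation model

$$N_{r,n} = M_{r,n}\prod_{q=1}^{n} p_{r,AA_q},$$

with $M_{r,n}$ the number of length-$n$ windows and $p_{r,AA}$ the residue
frequencies of database $r$ (windows containing ambiguous letters are
excluded from both counts and denominators). Departure from the
frequency-only null is tested with

$$\chi^2_\mathrm{tot} = \sum_{j=1}^{4}\sum_{i=1}^{20}
  \frac{(M_{i,\mathrm{obs}} - N_{i,\mathrm{exp}})_j^2}{(N_{i,\mathrm{exp}})_j},$$

on $\nu = 80 - 4 = 76$ degrees of freedom (one totals constraint per
family), with the p-value from the upper $\chi^2$ tail. One caveat the test
suite makes explicit: overlapping windows are positively correlated (a run
of Ile creates several IxI windows at once), so under a fully i.i.d. null
the mean of $\chi^2_\mathrm{tot}$ sits a few percent above 76 and its
variance above $2\nu$. The calibration test therefore checks the null mean
to 5% relative rather than to the i.i.d. standard error; the enrichment
conclusions of interest are orders of magnitude away from this subtlety.

`enrichment_profile()` expresses disorder preference per central residue as
a difference of within-stratum percentages (summing to zero by
construction), and `intersect_interactors()` screens a candidate binder list
for proteins carrying at least one disordered [V/I]P[V/I] motif, reporting
per-protein counts.

## Trajectory analysis

`compute_phi_psi()` computes backbone dihedrals with the standard IUPAC sign
convention (cross-checked in the tests against an independent torsion
routine), `free_energy_surface()` turns a (φ, ψ) sample into
$\Delta G = -k_B T \ln(n/n_\max)$ on a 36×36 periodic grid (10° bins; the
bin width is a display/robustness compromise, not fitted), with empty bins
masked rather than set to infinity, and the default temperature 310.15 K
matching simulations run at 37 °C. `pca_combined()` concatenates two
trajectories, extracts Cα atoms with N-/C-terminal residues excluded,
superposes every frame on a user-supplied reference conformation
(least-squares Kabsch rotation, `superpose()`, verified against a quaternion
oracle), and eigendecomposes the flattened-coordinate covariance; projections
carry a source label so the spread of each ensemble can be compared. The
reference is deliberately an argument — in practice it is a bound-state
crystal conformation; the tests use a generator-emitted frame so nothing is
downloaded.

## What the generators emulate — and what they do not

`gen_titration()` plants a known $K_d$ and per-axis $\Delta\delta_\max$,
moving fast-exchange peaks with the bound fraction and collapsing
slow-exchange peaks' intensity as $1 - f_b$; Gaussian shift noise of 0.002
ppm (¹H scale; ¹⁵N noise is scaled by 1/0.2 so both weighted axes contribute
equally) matches well-resolved spectra. The ligand ladder is geometric from
0 to 2000 µM at 200 µM protein — the exact experimental concentrations
beyond stock and endpoint are not part of the public record, and a geometric
ladder is the standard stand-in covering both the linear and saturating
regimes. `gen_cpmg()` pushes intensities through the exact forward model at
500 and 600 MHz (¹H) with $T_\mathrm{CPMG}$ = 39 ms and 19 $\nu$ values
including one duplicate; intensity noise 0.007 (relative to $I_0$)
corresponds to σ(R₂) ≈ 0.3 /s at a typical plateau. `gen_proteome()` draws
i.i.d. residues from a stated frequency vector (default: human-like
composition), places one contiguous ≥ 20-residue disorder interval per
protein covering ≈ the requested fraction, and plants motifs with a
rejection check guaranteeing each planting adds exactly one recorded match
of its family. `gen_peptide_traj()` samples per-residue (φ, ψ) from von
Mises (mixtures) — tight polyproline-like for a Pro-like centre, a broad
α/β/αL mixture for a Leu-like centre — and rebuilds Cartesian backbones from
ideal internal coordinates, so the dihedral computation inverts the sampled
angles exactly.

Every generator is a pure function of its seed (sub-streams are split per
residue/protein so plantings are order-independent) and attaches a
machine-readable ground-truth ledger that the test suite consumes.

What passing tests on these inputs shows is that the estimators are correct
and calibrated under their stated models. What they cannot show: real
titrations have assignment errors and overlapped peaks; real dispersion data
have off-resonance and pulse-imperfection artefacts the ideal-pulse model
ignores; real proteomes have phylogenetic and compositional correlation far
richer than i.i.d. letters; and a two-state analysis of data containing a
third state reports apparent constants (which is precisely why the
constrained fitting mode exists).

## Problem sizes and reproducibility

The recovery benchmarks (run both by the test suite and by
`scripts/acceptance.R`) use: 50 seeded titration replicates (16 residues,
10-point ladder, 0.002 ppm noise) per planted $K_d$ (124 and 1030 µM), and
50 seeded two-field CPMG replicates (10 residues, 19 ν values, duplicate
noise as above) per planted condition ($p_B$ 2.4% with $k_{ex}$ 1000 /s;
$k_\mathrm{off}$ 610 /s at $p_B$ 2.0%). Null calibration of the census uses
200 seeded proteomes of 40 proteins × 250–450 residues. These sizes give
stable medians and coverage estimates while keeping a full run in the
minutes range on one CPU. The analysis workflow under `analysis/` is a
larger, narrative-sized version of the same pipeline (150-protein census,
2000-frame trajectories).

## Known limitations

* Two-site exchange only; the three-state model is deliberately out of
  scope, with the fixed-$p_B$/free-$\Delta R_2$ fit as its surrogate.
* Ideal 180° pulses; no off-resonance or CEST/R1ρ physics.
* The census takes disorder masks as given and does not model selective
  pressure (the independence assumption of the expectation is explicit).
* The trajectory layer analyses ensembles; it does not generate dynamics —
  frames are i.i.d. draws, so time-correlation quantities are meaningless on
  synthetic trajectories.
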