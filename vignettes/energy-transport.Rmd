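---
title: "Vibrational energy transport and mechanical stability in coarse-grained protein models"
author: "vedmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrational energy transport and mechanical stability in coarse-grained protein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vedmap)
```

# What the package computes

`vedmap` asks how a post-translational modification — a phosphoryl group
covalently attached to an aspartate side chain — changes the way vibrational
energy moves through a protein, and how that relates to thermal and
mechanical stability. The pipeline has four stages:

1. **Normal-mode analysis** of a harmonic model (an elastic network or an
   explicit spring list): staged energy minimisation, an analytic
   mass-weighted Hessian, and its eigendecomposition.
2. **Energy transport**: a per-mode vibrational energy diffusivity built
   from harmonic heat-flux matrix elements, averaged over frequency bands
   and temperatures, and projected onto residue pairs as a *communication
   map*.
3. **Fluctuation metrics**: RMSD/RMSF with Kabsch superposition, salt-bridge
   and hydrogen-bond detection, and the quantum harmonic heat capacity.
4. **Mechanical probing**: constant-velocity pulling of a bead–spring chain
   whose stabilising cross-links break irreversibly, with rupture-force
   analysis.

Because crystallographic inputs are optional, a synthetic-structure module
generates every object the pipeline needs with known ground truth; all
quantitative statements below are checked by the test suite against
independent oracles (closed forms, central differences, brute-force
dynamics).

# The harmonic model

Structures are point masses (all-atom or one bead per residue). Two
potentials are supported: an **elastic network** (`enm_model()`), which
places a spring of constant `k` (default 1 kcal mol⁻¹ Å⁻², the standard
residue-level value) between every pair within a cutoff (default 12 Å) with
the observed pair distance as rest length, and an **explicit spring list**
(`spring_model()`), used for chains, cross-linked models and tests. Internal
units are kcal/mol, Å, amu; the mass-weighted Hessian is stored in ps⁻², so
an eigenvalue λ gives an angular frequency ω = √λ ps⁻¹ and a wavenumber
ω/(2πc) = 5.30884 ω cm⁻¹. The composite conversion, √(kcal mol⁻¹ Å⁻²
amu⁻¹) → 108.591 cm⁻¹, is carried to machine precision internally
(`vedmap_constants`).

Zero (rigid-body) modes are identified scale-freely, |λ| < 10⁻⁸ · max|λ|;
a 3-D non-collinear network has exactly six, a collinear chain more, and
every transport or thermodynamic sum excludes them. An eigenvalue more
negative than that tolerance means the structure is not at a minimum and is
an error, not a warning. Eigenvector sign follows a lexicographic
convention (first component above 10⁻⁶ is positive) so decompositions are
reproducible across platforms.

Minimisation (`minimize()`) runs a staged schedule — steepest descent
(10,000-step budget), conjugate gradient (50,000 steps to 10⁻⁶ kcal/mol),
then L-BFGS (500,000 steps to 10⁻⁷ kcal/mol) — with the budgets treated as
caps and early exit on the energy tolerance. Convergence is verified by an
explicit probe: one further descent step must change the energy by less
than the final tolerance. Elastic networks are built at their minimum, so
for them the schedule exits immediately; the machinery matters for
perturbed or hand-built spring systems.

# Mode diffusivity and its oracle

For each non-zero mode α the package computes an Allen–Feldman-style
diffusivity

$$D_\alpha = \frac{\pi}{d\,\omega_\alpha^2} \sum_{\beta \neq \alpha}
  |S_{\alpha\beta}|^2\, g_\eta(\omega_\alpha - \omega_\beta),
\qquad
S_{\alpha\beta} = \frac{\omega_\alpha + \omega_\beta}
  {4\sqrt{\omega_\alpha \omega_\beta}}
  \sum_{i,j} (\mathbf r_i - \mathbf r_j)\,
  \mathbf e_{\alpha,i}^{\mathsf T} \Phi_{ij}\, \mathbf e_{\beta,j},$$

with Φ the mass-weighted force-constant blocks, **e** the mass-weighted
eigenvectors, g_η a unit-area Gaussian of width η, and d the transport
dimensionality (3 for a network, 1 for a chain; the factor is the isotropic
average of the squared heat-flux vector). The 1/√(ω_α ω_β) normalisation is
the standard harmonic-oscillator amplitude convention; it is what makes
D carry Å² ps⁻¹ and lets an independent dynamical measurement confirm the
absolute scale (below).

Two numerical choices matter:

* **Broadening.** η defaults to 3× the local mean mode spacing (a ±5-mode
  window). Finite systems have discrete spectra; η well below the spacing
  extinguishes all couplings, η far above blurs the frequency resolution.
  A per-mode flag records whether D moves by less than 1.5× when η is
  doubled — for a perfectly ordered chain D scales as 1/η (the ballistic
  harmonic-crystal divergence) and such modes are reported as unconverged
  rather than silently returned.
* **Zero modes** never enter either index of the double sum.

The independent check is `wavepacket_oracle()`: exact harmonic dynamics
(solved mode-by-mode, so total energy is conserved to round-off) started
from a kinetic excitation at one site, site energies assigned as kinetic
plus half of each incident spring's energy, and D read off as half the
slope (per dimension) of the mean-square energy displacement. Two
protocol details make the comparison meaningful on a 64-bead disordered
chain: the excitation can be band-passed to the frequency window being
compared, and the propagation must stop before the boundary reflection —
the fit window is capped at 0.7× the source-to-end distance divided by the
chain's sound speed (taken from the top of its spectrum), beyond which the
mean-square displacement saturates at the ends and no longer measures bulk
transport. `transport_crosscheck()` packages this comparison; across five
mass-disorder seeds (masses uniform in [0.8, 1.2]) the band-averaged
Allen–Feldman value agrees with the wave-packet estimate within 25%, which
is also what the test suite asserts.

# Communication maps

A communication map resolves transport onto residue pairs. With the mode
participation of residue I, $P_{\alpha I} = \sum_{i \in I}
|\mathbf e_{\alpha,i}|^2$ (participations sum to one per mode), the map is

$$M_{IJ} = \sum_b w_b\, \frac{1}{n_b} \sum_{\alpha \in b}
  D_\alpha\, P_{\alpha I}\, P_{\alpha J}.$$

This projection is the package's committed convention because it is the
only residue-pair decomposition that satisfies all three required
invariants *exactly*: symmetry, non-negativity, and completeness — the
grand sum over residue pairs equals the thermally averaged band mean of
D. (A signed per-pair split of the heat-flux double sum sums correctly but
can be locally negative.) Decoupled sub-networks get exactly zero
cross-blocks, because every mode lives entirely in one component.

**Bands.** Reporting uses six bands of ten modes each. The band centres
(50, 100, 150, 200, 300, 400 cm⁻¹) address an all-atom vibrational
spectrum, which extends to roughly 4000 cm⁻¹ — they select its low-frequency
collective end. A residue-level elastic network's spectrum tops out near
40–80 cm⁻¹, so taking those centres verbatim would collapse all six bands
onto the same ten stiffest local modes, which is a degenerate reading.
`scale_band_centers()` therefore places the centres at the same *relative*
spectral position (centre/4000 × the model's top frequency), i.e. again on
the low-frequency collective modes; that is what the pipeline uses for bead
models, while `band_spec()` keeps the nominal centres for all-atom-scale
spectra. "Ten nearest modes" is read literally (ties toward lower
frequency) so band membership is deterministic and auditable; a
Gaussian-weighted window is available behind a flag.

**Thermal averaging** is classical by default (equipartition: uniform band
weights, optional amplitude factor T/T_ref that makes maps linear in T, so
the 340 K − 300 K difference map equals (340/300 − 1) × the 300 K map).
Bose occupation weights are available for the quantum-weighted variant;
at 300 K they down-weight a 400 cm⁻¹ band relative to 50 cm⁻¹ by the
occupation ratio.

**Colour classes.** The reporting scale classifies values as red above
10⁷, orange in [9×10⁶, 10⁷] (both endpoints included), blue in
[8×10⁶, 9×10⁶), and below-range otherwise. Two caveats are deliberate:
the printed unit on that scale, "Å/ps", is dimensionally inconsistent with
a diffusivity (Å²/ps) and is treated as a label on the colour scale, not a
unit conversion; and synthetic bead maps live on a much smaller numeric
scale, so `rescale_thresholds()` maps the three colour cuts onto quantiles
of the profile at hand (blue at the 90th percentile by default). The
per-residue profile (`ved_profile()`) is the map's row sum — the total
transport coupling a residue participates in.

# The synthetic homolog pair

`make_homolog_pair()` emulates the study contrast: two structurally
identical 128-residue Cα helices (rise 1.5 Å, 100° twist, radius 2.3 Å,
bead mass 110 amu) that differ in exactly two respects. Model A carries
nine cross-links in its C-terminal region (residues 79–128) — standing in
for the nine stabilising hydrogen bonds of the stronger homolog — plus a
phospho-like modification at residue 55: 79 amu of extra mass (the PO₃
group) and one hydrogen-bond-class spring to residue 62, the
phosphoaspartate-to-aspartate core contact. Model B carries only the first
two of those cross-links and no modification. Backbone coordinates are
identical, so maps are directly comparable entry by entry.

Stiffness defaults are physical: elastic-network background 1 kcal mol⁻¹
Å⁻², cross-links 5000 kJ mol⁻¹ nm⁻² (≈ 12 kcal mol⁻¹ Å⁻², the
hydrogen-bond class), and the phospho contact in the same class. The
contact's distinguishing features are its location and the added mass, not
an order-of-magnitude stiffness difference — a much stiffer single bond
would isolate the modified bead in frequency and (in the transport maps)
suppress rather than enhance its participation, an interesting regime but
not the one this benchmark plants. Under these conditions the planted
signal is recovered robustly: the modified model shows the larger
site–partner map entry and the higher site VED in essentially every seed
(the suite requires at least 4 of 5).

Harmonic trajectories (`simulate_harmonic_trajectory()`) draw frames
independently from the classical equilibrium distribution — each non-zero
mode Gaussian with variance k_BT/ω² in mass-weighted coordinates, rigid
modes unexcited, frame 1 the reference. They are fluctuation benchmarks,
not kinetics: no time correlation, no anharmonicity, no solvent. What
passing RMSF tests show is that the estimator reproduces the analytic
harmonic covariance (within 5% at 20,000 frames) and that RMSD amplitudes
scale as √T; they say nothing about real force-field dynamics.
`make_backbone_helix()` adds an idealised N/H/CA/C/O backbone whose i→i+4
hydrogen-bond count is known by construction (n − 4), which is how the
geometric hydrogen-bond counter (3.5 Å donor–acceptor, 120° donor–H–
acceptor, covalent neighbours excluded) is validated.

# Pulling and rupture

`build_cg_model()` turns a bead structure into a chain with stiff backbone
springs (default 10× the stiffest cross-link, so unfolding proceeds by
link rupture, not backbone stretching) and breakable cross-links; a link is
removed permanently once stretched 0.3 nm beyond its rest length.
`run_pull()` integrates Langevin dynamics (BAOAB splitting, friction
1 ps⁻¹) in GROMACS units (nm, ps, amu, kJ/mol — a consistent system, so no
conversion constants enter the integrator) with a harmonic restraint
(1500 kJ mol⁻¹ nm⁻²) coupling the axis-projected centre-of-mass separation
of the two pull groups to a virtual point moving at 0.01 nm ps⁻¹; the time
step is 2 fs and the force is recorded every 1 ps. The thermostat's O-step
is applied every 10 steps using the exact Ornstein–Uhlenbeck update over
the 0.02 ps stride — still fifty times shorter than the friction time —
which removes most of the random-number cost without changing the sampled
ensemble. With the thermostat off the integrator is velocity Verlet and
conserves energy (the suite checks 10⁻⁴ relative over 100 ps).

Two termination rules bound the run: the configured maximum extension
(3× the initial separation), and — decisive in practice — a stop 50 ps
after the last cross-link has ruptured. Without the second rule a run whose
extension target exceeds the geometrically reachable separation degenerates
into stretching the intact backbone, and that terminal ramp dwarfs the
rupture peaks the analysis is about. Rupture analysis reads peak forces
from an 11-ps running-mean of the force curve (`max_force(smooth = 11)`):
the raw 1-ps samples carry restraint-noise extremes that grow with
temperature and can mask the genuine thermal softening of the rupture
force. `detect_ruptures()` flags drops of ≥ 20% of the preceding local
maximum on the smoothed curve, ignores peaks below 25% of the profile
maximum (the low-force regime is all noise in relative terms), and merges
with the integrator's logged breakages.

At these settings the nine-link model sustains a higher mean peak force
than the two-link model at 300 K and 340 K, and each model's mean peak
force does not increase on heating — the qualitative mechanical ordering
the pipeline is designed to recover. Only orderings and trends are claimed
at this scale; the absolute forces belong to the coarse model, not to any
real protein.

# Heat capacity

`heat_capacity()` evaluates the quantum harmonic form
C_v = k_B Σ x²eˣ/(eˣ−1)², x = hcν/(k_BT), over non-zero modes, with the
classical limit (number of internal modes × k_B) attached for reference.
It is monotone in T, vanishes at T → 0, and reaches the classical limit
within 0.1% at high T; the scalar case reduces to the Einstein heat
capacity.

# Problem sizes, determinism, degenerate inputs

The suite and the acceptance script run on deliberately desk-scale
problems chosen as the smallest sizes at which each property is
informative: 50-bead chains for analytic spectra, 64-bead disordered
chains for the transport cross-check, the 128-residue pair for contrast
recovery, 20,000 frames for the RMSF closed form, five seeds per
stochastic claim, and a 48-residue pair for the end-to-end determinism
check. Every stochastic stage takes an explicit integer seed and restores
the caller's RNG state; rerunning the pipeline with one seed reproduces
byte-identical TSV outputs, and the run manifest lists every file with an
MD5 checksum.

Degenerate inputs are rejected rather than patched: structures with zero
atoms after filtering, atoms with no neighbours under the elastic-network
cutoff (floppy fragments), collinear point sets in superposition,
saddle-point Hessians, infeasible cross-link counts, pull groups that
overlap, and configurations without temperatures all raise errors naming
the offending stage.

# Limitations

The harmonic picture has no anharmonic relaxation, no solvent damping and
no mode–mode energy exchange beyond near-resonant harmonic coupling; the
diffusivity is a harmonic-theory transport coefficient, not a measured
conductivity. The synthetic homolog pair reproduces counts and contrasts
(9 vs 2 links, one modified site), not the geometry of any real structure,
and the coarse pulling model maps hydrogen bonds onto breakable springs
with a hard extension threshold rather than a smooth bond potential.
Salt-bridge output reports map values for detected acid–base contacts and
leaves their interpretation to the user. The printed colour thresholds are
meaningful only on the all-atom reporting scale; synthetic maps use the
quantile-rescaled thresholds.

```{r example, eval = FALSE}
# end-to-end run on the default study conditions
cfg <- pipeline_config(outdir = "vedmap_out", seed = 1)
bundle <- run_pipeline(cfg)
render_report(bundle)
```
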