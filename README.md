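# vedmap

Vibrational energy diffusivity and residue–residue communication maps for
coarse-grained protein models, with structural-stability metrics and
constant-velocity pulling.

## The problem

Phosphorylation can rigidify a protein: a phosphoaspartate buried in the
core forms extra contacts that change both how vibrational energy spreads
through the residue network and how much force the fold withstands before
unravelling. Probing that link requires three calculations that are usually
scattered across tools: normal-mode analysis of a harmonic model,
frequency-resolved energy-transport ("communication") maps between
residues, and steered pulling with rupture analysis. `vedmap` implements
all three as one tested R pipeline, together with a synthetic-structure
module that generates homologous model pairs — identical backbones, one
carrying a phospho-like modification and nine stabilising cross-links, the
other only two — so every stage runs and is verifiable without any external
structure files. It is aimed at structural-bioinformatics users who want
desk-scale, reproducible transport and rupture calculations on elastic
networks and bead–spring chains.

## The quantities at the core

For a mass-weighted Hessian with modes $(\omega_\alpha, \mathbf e_\alpha)$,
the per-mode energy diffusivity is the Allen–Feldman form

$$D_\alpha = \frac{\pi}{d\,\omega_\alpha^2} \sum_{\beta\neq\alpha}
 |S_{\alpha\beta}|^2\, g_\eta(\omega_\alpha-\omega_\beta),\qquad
 S_{\alpha\beta} = \frac{\omega_\alpha+\omega_\beta}{4\sqrt{\omega_\alpha\omega_\beta}}
 \sum_{i,j}(\mathbf r_i-\mathbf r_j)\,\mathbf e_{\alpha,i}^{\mathsf T}\Phi_{ij}\mathbf e_{\beta,j},$$

validated against a brute-force wave-packet oracle (exact harmonic
dynamics of a localised excitation; the two agree within 25% on disordered
chains). Band averages over the ten modes nearest each centre, thermally
weighted, are projected onto residue pairs through mode participations
$P_{\alpha I}=\sum_{i\in I}|\mathbf e_{\alpha,i}|^2$, giving a symmetric,
non-negative communication map whose grand sum equals the thermally
averaged total diffusivity exactly. Pulling uses Langevin dynamics with a
moving harmonic restraint (1500 kJ mol⁻¹ nm⁻², 0.01 nm ps⁻¹, 2 fs steps)
and cross-links that break irreversibly at a 0.3 nm overstretch; rupture
forces are read from the lightly smoothed force curve. See the vignette
`vignettes/energy-transport.Rmd` for every convention and its rationale.

## Worked example

```r
library(vedmap)

# the homolog pair: identical 128-residue helices, 9 vs 2 C-terminal
# cross-links, model A phosphorylated at residue 55
pair <- make_homolog_pair(n_residues = 128, strong_links = 9,
                          weak_links = 2, seed = 1)

fit <- nma(pair$A$structure, enm_with_links(pair$A$structure, pair$A$crosslinks))
fit
#> <nma: 128 atoms, 384 modes (6 zero); frequencies 0.12..66.18 cm^-1>

D <- mode_diffusivity(fit)
D
#> <ModeDiffusivity: 384 modes (6 zero excluded); D 0.114..100 A^2/ps>

map300 <- communication_map(fit, D, pair$A$structure,
                            scale_band_centers(fit), temperature = 300)
map300
#> <CommunicationMap: 128 residues, T = 300 K, total 75.48 A^2/ps>

prof <- ved_profile(map300)
head(top_residues(prof, rescale_thresholds(prof)))
#>   ordinal label     value  class
#> 1       0    A1 1.7412712    red
#> 2     127  A128 1.7393533    red
#> 3       1    A2 1.1596915 orange
#> 4     126  A127 1.0876335 orange
#> 5      54   A55 1.0352423 orange
#> 6       2    A3 0.9677859   blue

cg <- build_cg_model(pair$A$structure, pair$A$crosslinks)
pull <- run_pull(cg, pull_protocol(temperature = 300, seed = 1))
max_force(pull$profile, smooth = 11)
#> [1] 2667.947
#> attr(,"time")
#> [1] 1712
nrow(pull$events)
#> [1] 10
```

Reading the output: the mode set spans 0.12–66 cm⁻¹ (six rigid-body modes
excluded); per-mode diffusivities reach 100 Å²/ps on the most conducting
collective modes. In the 300 K communication map the chain termini are the
strongest hubs — they sit on the softest, most delocalised modes — and the
phosphorylated residue 55 ranks among the top vibrationally active sites
(orange class under profile-quantile thresholds), which its unmodified
counterpart does not. The pull of the nine-link model peaks at about
2.7 × 10³ kJ mol⁻¹ nm⁻¹ at 1712 ps, after all ten breakable contacts
(nine C-terminal links plus the phospho contact) have ruptured.

The one-call version of all of this is

```r
bundle <- run_pipeline(pipeline_config(outdir = "vedmap_out", seed = 1))
render_report(bundle)
```

which writes maps, VED profiles, RMSF profiles, force curves and rupture
tables as TSV plus a checksummed manifest, for both models at 300 K and
340 K.

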