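# lipidfoam

Quantitative analysis of **lipid-foam tissue mimetics**: quasi-2D packings of
micrometre-scale aqueous compartments bounded by lipid bilayers that meet at
three-way junctions, hybridized with encapsulated swimming bacteria that
drive active tension fluctuations. The package is aimed at experimentalists
and modellers working on synthetic tissues, active foams, and vertex-model
mechanics who need a validated chain from raw two-channel timelapses (or
simulated ground truth) to mechanical parameters.

## What it computes

**Geometry and mechanics.** Foam networks (`foam_network`) with the
compartment shape index `s = p/√A` (3.722 for hexagonal packing, ≈3.81 at
the rigidity transition), the monolayer/bilayer tension balance
`γ_B = 2 γ_ML cos φ`, micropipette aspiration tension via the Laplace law,
junction force balance and relaxation (120° at equal tensions), and T1
topological transitions (detection in edge-length series and the topology
operator).

**Fluctuation statistics.** 60-s blocked vertex displacement and edge
deviation statistics, Welch spectra, and the effective-temperature spectrum

    S(f) = 4 k_B T_eff / b / [(2π)² (f² + f0²)]

fitted in log-log space. Active and heat-killed spectra are fitted jointly
with shared drag `b` and corner frequency `f0` — the only way both `b` and
`T_eff/T` can be identified from amplitudes.

**The swim-pressure displacement law.** Vectorial occupancy
`Φ = |Σ Φ_n(cos φ_n, sin φ_n)|` on directions 120° apart, the predicted
junction displacement

    Δϑ = c · (3 η τ A / 4R²) · (v² Φ / γ_e),

zero-intercept slope fitting, and the exact inversion for the
swimmer–bilayer interaction radius `R`. A membrane point-force bound shows
why mN/m bilayers deform only sub-nanometre under a swimmer's thrust.

**Spatial structure.** Pairwise displacement cross-correlation versus
distance with a permutation null band, correlation length, and 60-s hotspot
maps.

**Synthetic data.** Ornstein–Uhlenbeck vertex dynamics, full-network
Langevin dynamics (tension + compartment area elasticity + per-compartment
active forcing), confined active Brownian swimmers with collision logs,
truncated-Poisson occupancy sampling, and rendered two-channel micrograph
stacks with ground truth — so every estimator can be validated end to end.

## Worked example

```r
library(lipidfoam)

net <- build_hexagonal_lattice(3, 3, 20)   # 9 compartments, 20 um sides
net
#> <foam_network> 30 vertices (8 interior), 38 edges, 9 compartments
head(shape_stats(net), 1)
#>   compartment perimeter_um area_um2 shape_index interior
#> 1           5          120  1039.23    3.722419     TRUE

stability_ratios(1.5, 1.0)$regime          # gamma_B / gamma_ML = 1.5
#> [1] "confluent-jammed"
contact_angle(1.532, 1.0)                  # gamma_B = 1.532, gamma_ML = 1 mN/m
#> [1] 40.00396

active  <- generate_scenario(scenario_config(mode = "active",
                                             duration_s = 300,
                                             render = FALSE, seed = 1))
passive <- generate_scenario(scenario_config(mode = "heat-killed",
                                             duration_s = 300,
                                             render = FALSE, seed = 1))
pipeline_analyze(active, passive_bundle = passive)
#> <foam_report: active> 8 vertices, <s> = 3.722
#>   edge SD 1.31 um, gamma_e 2.39e-09 N/m
#>   PSD fit: b = 0.473 uNs/m, f0 = 2.12e-07 Hz, Teff/T = 4.5
#>   displacement law: slope 19.6 um (R^2 0.01), R = 1.82 um
#>   lcorr 43.3 um; largest hotspot 3.68 um
```

Reading the report: the drag `b ≈ 0.47 µNs/m` is recovered from the paired
active/heat-killed spectra (the generator used 0.5); `Teff/T = 4.5` reflects
the activity level of this particular occupancy draw; the displacement-law
slope and its inversion give an interaction radius `R ≈ 1.8 µm` (generator:
2 µm); vertex motion is positively correlated up to `l_corr ≈ 43 µm`, about
one compartment diameter, because vertices of a compartment share its active
forcing. The corner frequency is reported but is not identifiable from
10-minute records (see the methods vignette).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/lipidfoam-pipeline.R`
(`simulate` / `analyze` / `report`, each taking `--config`, `--seed`,
`--out`).

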